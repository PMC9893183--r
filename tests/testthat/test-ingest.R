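test_that("parse_obo extracts terms, hierarchy, xrefs, and rejects id-less stanzas", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: MONDO:0000001", "name: disease", "",
    "[Term]", "id: MONDO:0000002", "name: subtype disease",
    "is_a: MONDO:0000001 ! disease",
    "xref: UMLS:C0001234",
    'def: "a synthetic definition" []', "",
    "[Term]", "id: MONDO:0000003", "name: gone", "is_obsolete: true",
    "is_a: MONDO:0000001", ""
  ), f)
  ont <- parse_obo(f)
  expect_equal(nrow(ont$terms), 3)
  expect_equal(ont$edges, tibble::tibble(
    child_id = "MONDO:0000002", parent_id = "MONDO:0000001"
  ))
  expect_equal(ont$xrefs$foreign_id, "UMLS:C0001234")
  expect_equal(
    ont$terms$definition[ont$terms$id == "MONDO:0000002"],
    "a synthetic definition"
  )
  # obsolete terms contribute no outgoing is_a edges
  expect_false("MONDO:0000003" %in% ont$edges$child_id)

  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "name: nameless"), bad)
  expect_error(parse_obo(bad), class = "kgcraft_parse_error")
  expect_error(parse_obo(bad), "line 1")
})

test_that("parse_obo counts match the fixture generator's planted truth", {
  fx <- tiny_overlap_fixture()
  planted <- fx$truth$partition
  expect_equal(nrow(fx$disease$terms), nrow(planted))
  n_xref_overlap <- sum(fx$truth$overlap$evidence == "xref-mapped")
  expect_equal(
    sum(startsWith(fx$disease$xrefs$foreign_id, "HP:")),
    n_xref_overlap
  )
})

test_that("expression-call filter applies quality, FDR <= 0.01 and rank < 25000", {
  base <- tibble::tibble(
    anatomy_id = "UBERON:0000001", gene_id = "1001",
    call = "present", quality = "gold quality", fdr = 0.005, rank = 10000
  )
  expect_equal(nrow(filter_expression_calls(base)), 1)
  expect_equal(filter_expression_calls(base)$relation, "anatomy_protein_present")

  # strict inequality at the rank boundary
  boundary <- dplyr::mutate(base, rank = 25000)
  expect_equal(nrow(filter_expression_calls(boundary)), 0)
  # inclusive FDR boundary
  fdr_edge <- dplyr::mutate(base, fdr = 0.01)
  expect_equal(nrow(filter_expression_calls(fdr_edge)), 1)

  absent <- dplyr::mutate(base, call = "absent")
  expect_equal(filter_expression_calls(absent)$relation, "anatomy_protein_absent")

  bad <- dplyr::mutate(base, fdr = "n/a")
  out <- filter_expression_calls(bad)
  expect_equal(nrow(out), 0)
  log <- drop_log(out)
  expect_equal(log$n[log$reason == "non_numeric_fdr_or_rank"], 1L)
})

test_that("expression filter survivor count equals planted truth with row conservation", {
  spec <- shared_spec()
  expr <- readr::read_tsv(
    file.path(shared_bundle_dir(), "expression_calls.tsv"),
    show_col_types = FALSE
  )
  out <- filter_expression_calls(expr)
  expect_equal(nrow(out), spec$n_expression_pass)
  expect_equal(nrow(out) + sum(drop_log(out)$n), nrow(expr))
})

test_that("relaxing expression thresholds never decreases retained rows", {
  expr <- readr::read_tsv(
    file.path(shared_bundle_dir(), "expression_calls.tsv"),
    show_col_types = FALSE
  )
  strict <- nrow(filter_expression_calls(expr, ingest_config()))
  looser_fdr <- nrow(filter_expression_calls(expr, ingest_config(bgee_fdr_max = 0.1)))
  looser_rank <- nrow(filter_expression_calls(expr, ingest_config(bgee_rank_max = 50000)))
  expect_gte(looser_fdr, strict)
  expect_gte(looser_rank, strict)
})

test_that("disorder concept selection keeps the 11 Disorder-group types only", {
  expect_length(umls_disorder_types(), 11)
  conso <- tibble::tibble(
    cui = c("C1", "C1", "C2", "C3"),
    language = c("ENG", "FRE", "ENG", "ENG"),
    name = c("a", "a-fr", "b", "c")
  )
  sty <- tibble::tibble(
    cui = c("C1", "C2", "C3"),
    semantic_type = c("Disease or Syndrome", "Finding", "Neoplastic Process")
  )
  defs <- tibble::tibble(
    cui = c("C1", "C3"), source = "S", language = "ENG",
    definition = c("def1", "def3")
  )
  out <- select_umls_disorders(conso, sty, defs)
  expect_setequal(out$cui, c("C1", "C3"))
  expect_equal(out$definition[out$cui == "C1"], "def1")

  spec <- shared_spec()
  rd <- function(f) {
    readr::read_delim(file.path(shared_bundle_dir(), f),
      delim = "|",
      show_col_types = FALSE
    )
  }
  out2 <- select_umls_disorders(rd("concepts.rrf"), rd("semantic_types.rrf"), rd("definitions.rrf"))
  expect_equal(nrow(out2), spec$n_umls_disorders)
})

test_that("identifier mapping expands one-to-many, drops unmapped with a log", {
  t <- triples_table(tibble::tibble(
    x_id = c("DB001", "DB002", "DB003"), x_type = "drug", x_source = "DrugBank",
    relation = "drug_protein",
    y_id = c("P12345", "P99999", "P11111"), y_type = "gene/protein",
    y_source = "UniProt"
  ))
  vocab <- xref_map(
    tibble::tibble(from = c("P12345", "P11111", "P11111"), to = c("1017", "2001", "2002")),
    from_ns = "UniProt", to_ns = "NCBI"
  )
  out <- map_identifiers(t, vocab, side = "y", new_source = "NCBI")
  expect_equal(sort(out$y_id), c("1017", "2001", "2002"))
  expect_true(all(out$y_source == "NCBI"))
  log <- drop_log(out)
  expect_equal(log$n[log$reason == "unmapped"], 1L)
  # conservation before expansion: input = distinct mapped origins + drops
  expect_equal(2 + sum(log$n), nrow(t))

  # one-to-many under policy = drop
  out2 <- map_identifiers(t, vocab, side = "y", policy = "drop")
  expect_equal(out2$y_id, "1017")
  expect_true("ambiguous" %in% drop_log(out2)$reason)

  # wrong namespace for the chosen side is a contract error
  expect_error(
    map_identifiers(t, vocab, side = "x"),
    class = "kgcraft_contract_error"
  )
})

test_that("drug-protein partner union deduplicates exact pairs", {
  mk <- function(pairs) {
    triples_table(tibble::tibble(
      x_id = pairs$d, x_type = "drug", x_source = "DrugBank",
      relation = "drug_protein",
      y_id = pairs$g, y_type = "gene/protein", y_source = "NCBI"
    ))
  }
  targets <- mk(tibble::tibble(d = c("DB1", "DB2"), g = c("1", "2")))
  enzymes <- mk(tibble::tibble(d = c("DB3", "DB4", "DB1"), g = c("3", "4", "1")))
  carriers <- targets[0, ]
  transporters <- mk(tibble::tibble(d = "DB5", g = "5"))
  out <- merge_drug_protein_partners(targets, enzymes, carriers, transporters)
  # 2 + 3 + 0 + 1 with one shared pair -> 5 unique
  expect_equal(nrow(out), 5)
  expect_true(all(out$relation == "drug_protein"))
})

test_that("drug interaction parsing deduplicates mirrored records", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<?xml version=\"1.0\"?>", "<drugs>",
    "<drug><drugbank-id>DB1</drugbank-id><name>alpha</name>",
    "<drug-interactions>",
    "<drug-interaction><drugbank-id>DB2</drugbank-id><name>beta</name></drug-interaction>",
    "</drug-interactions></drug>",
    "<drug><drugbank-id>DB2</drugbank-id><name>beta</name>",
    "<drug-interactions>",
    "<drug-interaction><drugbank-id>DB1</drugbank-id><name>alpha</name></drug-interaction>",
    "<drug-interaction><drugbank-id>DB3</drugbank-id><name>gamma</name></drug-interaction>",
    "</drug-interactions></drug>",
    "<drug><drugbank-id>DB3</drugbank-id><name>gamma</name></drug>",
    "</drugs>"
  ), f)
  out <- parse_drug_interactions(f)
  expect_equal(nrow(out), 2) # DB1-DB2 mirrored once, DB2-DB3
  expect_true(all(out$x_id < out$y_id))

  spec <- shared_spec()
  bundle_out <- parse_drug_interactions(file.path(shared_bundle_dir(), "drugs.xml"))
  expect_equal(nrow(bundle_out), spec$n_drug_interactions)
})

test_that("side-effect filter keeps preferred terms and drops broken chains", {
  table <- tibble::tibble(
    drug_stitch_id = c("CID1", "CID1", "CID2"),
    meddra_level = c("PT", "LLT", "PT"),
    phenotype_id = c("HP:1", "HP:1", "HP:2")
  )
  s2a <- xref_map(tibble::tibble(from = "CID1", to = "A01"))
  a2d <- xref_map(tibble::tibble(from = "A01", to = "DB1"))
  out <- filter_side_effects(table, s2a, a2d)
  expect_equal(nrow(out), 1)
  expect_equal(out$x_id, "DB1")
  log <- drop_log(out)
  expect_equal(log$n[log$reason == "not_preferred_term"], 1L)
  expect_equal(log$n[log$reason == "unmapped_to_atc"], 1L)

  spec <- shared_spec()
  rd <- function(f) {
    readr::read_tsv(file.path(shared_bundle_dir(), f), show_col_types = FALSE)
  }
  out2 <- filter_side_effects(
    rd("side_effects.tsv"),
    xref_map(rd("vocab_stitch2atc.tsv")), xref_map(rd("vocab_atc2drug.tsv"))
  )
  expect_equal(nrow(out2), spec$n_side_effect_pass)
})

test_that("adapters are pure: identical input yields identical output", {
  expr <- readr::read_tsv(
    file.path(shared_bundle_dir(), "expression_calls.tsv"),
    show_col_types = FALSE
  )
  a <- filter_expression_calls(expr)
  b <- filter_expression_calls(expr)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
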