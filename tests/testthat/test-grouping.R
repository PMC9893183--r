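test_that("base-phrase extraction drops numeric, roman, short and type endings", {
  expect_equal(
    extract_base_phrase("Autism, susceptibility to, 1"),
    "autism susceptibility to"
  )
  expect_equal(
    extract_base_phrase("mucopolysaccharidosis type II"),
    "mucopolysaccharidosis type"
  )
  expect_equal(extract_base_phrase("retinitis pigmentosa 2a"), "retinitis pigmentosa")
  expect_equal(extract_base_phrase("anemia type x"), "anemia type")
  expect_true(is.na(extract_base_phrase("asthma")))
  expect_true(is.na(extract_base_phrase("chronic kidney failure")))
})

test_that("string matching groups subtype families and leaves others alone", {
  autism <- c(
    a1 = "Autism, susceptibility to, 1",
    a2 = "Autism, susceptibility to, 2",
    ax = "Autism, susceptibility to, x-linked"
  )
  g <- string_match_groups(autism)
  expect_length(unique(g$partition$group_id), 1)

  bag <- c(d1 = "Diabetes mellitus type 1", d2 = "type 1 diabetes mellitus")
  g2 <- string_match_groups(bag)
  expect_length(unique(g2$partition$group_id), 1)

  single <- c(s1 = "asthma", s2 = "psoriasis")
  g3 <- string_match_groups(single)
  expect_length(unique(g3$partition$group_id), 2)
  # singleton groups keep the original disease name
  expect_setequal(g3$group_names$group_name, c("asthma", "psoriasis"))
})

test_that("names sharing no normalized tokens are never merged", {
  set.seed(9)
  nms <- c(
    a = "zanthoria type 1", b = "zanthoria type 2",
    c = "quellin fever", d = "morbus 1"
  )
  g <- string_match_groups(nms)
  part <- stats::setNames(g$partition$group_id, g$partition$disease_id)
  expect_equal(part[["a"]], part[["b"]])
  expect_false(part[["c"]] == part[["a"]])
  expect_false(part[["d"]] == part[["a"]])
})

test_that("trigram embedder is deterministic with unit self-similarity", {
  e <- trigram_embedder()
  m1 <- embed_names(e, c("asthma", "severe asthma", "psoriasis"))
  m2 <- embed_names(e, c("asthma", "severe asthma", "psoriasis"))
  expect_identical(m1, m2)
  expect_equal(sum(m1[1, ]^2), 1)
  expect_equal(sum(m1[1, ] * m1[1, ]), 1)
  expect_lt(sum(m1[1, ] * m1[3, ]), 0.9)
})

test_that("embedding refinement proposes identical and near-duplicate names only", {
  nms <- c(
    g1 = "cystinosis nephropathic", g2 = "cystinosis nephropathic",
    g3 = "entirely unrelated illness"
  )
  g <- string_match_groups(nms)
  res <- embedding_refine(g, trigram_embedder(), grouping_config())
  expect_equal(nrow(res$proposals), 1)
  expect_equal(res$proposals$similarity, 1)
  expect_length(unique(res$grouping$partition$group_id), 2)

  # orthogonal toy embedder: no proposals
  toy <- structure(list(model_tag = "toy"), class = c("toy_embedder", "name_embedder"))
  registerS3method("embed_names", "toy_embedder",
    function(embedder, names) diag(length(names)),
    envir = asNamespace("kgcraft")
  )
  res2 <- embedding_refine(g, toy, grouping_config())
  expect_equal(nrow(res2$proposals), 0)
})

test_that("lowering the similarity cutoff never decreases merge proposals", {
  set.seed(4)
  nms <- stats::setNames(
    paste(
      sample(c("alpha", "beta", "gamma", "delta"), 20, replace = TRUE),
      sample(c("storage", "kidney", "nerve"), 20, replace = TRUE),
      "condition"
    ),
    paste0("id", 1:20)
  )
  g <- string_match_groups(nms)
  n_props <- vapply(c(0.999, 0.9, 0.5, 0), function(cut) {
    nrow(embedding_refine(g, trigram_embedder(), grouping_config(similarity_cutoff = cut))$proposals)
  }, integer(1))
  expect_true(all(diff(n_props) >= 0))
})

test_that("review workflow gates merges and assigns names", {
  nms <- c(g1 = "porphyria cutanea", g2 = "porphyria cutanea")
  g <- string_match_groups(nms)
  cfg <- grouping_config(require_review = TRUE)
  res <- embedding_refine(g, trigram_embedder(), cfg)
  expect_length(unique(res$grouping$partition$group_id), 2) # nothing approved yet

  review <- res$proposals
  review$decision <- "approve"
  review$assigned_name <- "porphyria cutanea (grouped)"
  res2 <- embedding_refine(g, trigram_embedder(), cfg, review = review)
  expect_length(unique(res2$grouping$partition$group_id), 1)
  expect_equal(res2$grouping$group_names$group_name, "porphyria cutanea (grouped)")

  # review file round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_review_file(review, f)
  expect_equal(read_review_file(f)$decision, "approve")

  # unknown group ids in the review are an error
  bad <- review
  bad$group_a <- "nonexistent"
  expect_error(
    embedding_refine(g, trigram_embedder(), cfg, review = bad),
    class = "kgcraft_contract_error"
  )
})

test_that("the full grouping pipeline is idempotent", {
  fx <- tiny_overlap_fixture()
  names_df <- tibble::tibble(
    disease_id = fx$truth$partition$id, name = fx$truth$partition$name
  )
  first <- group_diseases(names_df)
  regroup_input <- first$grouping$group_names
  second <- group_diseases(tibble::tibble(
    disease_id = regroup_input$group_id, name = regroup_input$group_name
  ))
  expect_equal(
    length(unique(second$grouping$partition$group_id)),
    nrow(regroup_input)
  )
})

test_that("grouping recovers the planted partition on subtype fixtures", {
  fx <- tiny_overlap_fixture()
  names_df <- tibble::tibble(
    disease_id = fx$truth$partition$id, name = fx$truth$partition$name
  )
  res <- group_diseases(names_df)
  recovered <- res$grouping$partition$group_id[
    match(fx$truth$partition$id, res$grouping$partition$disease_id)
  ]
  expect_gte(partition_ari(recovered, fx$truth$partition$family), 0.95)
})

test_that("applying a grouping relabels, deduplicates and removes self-edges", {
  t <- triples_table(dplyr::bind_rows(
    tibble::tibble(
      x_id = c("MONDO:1", "MONDO:2"), x_type = "disease", x_source = "MONDO",
      x_name = c("flu type 1", "flu type 2"),
      relation = "disease_protein",
      y_id = "1001", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = "MONDO:1", x_type = "disease", x_source = "MONDO",
      x_name = "flu type 1",
      relation = "disease_disease",
      y_id = "MONDO:2", y_type = "disease", y_source = "MONDO",
      y_name = "flu type 2"
    )
  ))
  g <- string_match_groups(c("MONDO:1" = "flu type 1", "MONDO:2" = "flu type 2"))
  out <- apply_grouping(t, g)
  # two members collapse: one disease-protein edge survives, the intra-group
  # hierarchy edge becomes a logged self-edge
  expect_equal(nrow(out), 1)
  expect_equal(out$relation, "disease_protein")
  expect_equal(out$x_id, "MONDO:1_MONDO:2")
  expect_true("grouped_self_edge" %in% drop_log(out)$reason)

  # identity partition leaves tables unchanged up to (possibly) nothing
  ident <- string_match_groups(c("MONDO:1" = "alpha illness", "MONDO:2" = "beta illness"))
  out2 <- apply_grouping(t, ident)
  expect_equal(nrow(out2), nrow(t))

  # a disease id missing from the partition is a contract error
  expect_error(
    apply_grouping(t, string_match_groups(c("MONDO:1" = "flu type 1"))),
    class = "kgcraft_contract_error"
  )
})

test_that("apply_grouping matches a brute-force relabel-then-dedup oracle", {
  fx <- tiny_overlap_fixture()
  names_df <- tibble::tibble(
    disease_id = fx$truth$partition$id, name = fx$truth$partition$name
  )
  g <- group_diseases(names_df)$grouping
  set.seed(11)
  t <- triples_table(tibble::tibble(
    x_id = sample(names_df$disease_id, 40, replace = TRUE),
    x_type = "disease", x_source = "MONDO",
    relation = "disease_protein",
    y_id = as.character(sample(1:8, 40, replace = TRUE)),
    y_type = "gene/protein", y_source = "NCBI"
  ))
  out <- apply_grouping(t, g)

  gid <- stats::setNames(g$partition$group_id, g$partition$disease_id)
  oracle <- unique(data.frame(
    x = unname(gid[t$x_id]), y = t$y_id, stringsAsFactors = FALSE
  ))
  expect_equal(nrow(out), nrow(oracle))
  expect_setequal(paste(out$x_id, out$y_id), paste(oracle$x, oracle$y))
})
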