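mini_ontology <- function(terms, xrefs = NULL) {
  structure(
    list(
      terms = tibble::tibble(
        id = terms, name = paste("term", terms),
        definition = NA_character_, is_obsolete = FALSE
      ),
      edges = tibble::tibble(child_id = character(), parent_id = character()),
      xrefs = if (is.null(xrefs)) {
        tibble::tibble(
          term_id = character(), foreign_namespace = character(),
          foreign_id = character()
        )
      } else {
        xrefs
      },
      subsets = tibble::tibble(term_id = character(), subset = character()),
      synonyms = tibble::tibble(term_id = character(), synonym = character())
    ),
    class = "ontology_graph"
  )
}

test_that("overlap membership follows the numeric-id and xref rules", {
  hp <- mini_ontology(c("HP:0000123", "HP:0009999", "HP:0005555"))
  mondo <- mini_ontology(
    c("MONDO:0000123", "MONDO:0777777"),
    xrefs = tibble::tibble(
      term_id = "MONDO:0777777", foreign_namespace = "HP",
      foreign_id = "HP:0009999"
    )
  )
  P <- compute_overlap_set(hp, mondo)
  expect_setequal(P$phenotype_id, c("HP:0000123", "HP:0009999"))
  expect_equal(P$evidence[P$phenotype_id == "HP:0000123"], "same-numeric-id")
  expect_equal(P$evidence[P$phenotype_id == "HP:0009999"], "xref-mapped")

  m <- overlap_disease_map(P, mondo)
  expect_equal(m$to[m$from == "HP:0000123"], "MONDO:0000123")
  expect_equal(m$to[m$from == "HP:0009999"], "MONDO:0777777")
})

test_that("planted overlap set is recovered exactly from fixture ontologies", {
  fx <- tiny_overlap_fixture()
  P <- compute_overlap_set(fx$phenotype, fx$disease)
  expect_setequal(P$phenotype_id, fx$truth$overlap$phenotype_id)
  recovered <- P$evidence[match(fx$truth$overlap$phenotype_id, P$phenotype_id)]
  expect_equal(recovered, fx$truth$overlap$evidence)
})

overlap_case_tables <- function() {
  # HP:a, HP:b in P (mapped to MONDO:a2, MONDO:b2); HP:c outside P
  triples_table(dplyr::bind_rows(
    tibble::tibble(
      x_id = "HP:a", x_type = "effect/phenotype", x_source = "HPO",
      relation = "phenotype_phenotype",
      y_id = "HP:c", y_type = "effect/phenotype", y_source = "HPO"
    ),
    tibble::tibble(
      x_id = "HP:a", x_type = "effect/phenotype", x_source = "HPO",
      relation = "phenotype_phenotype",
      y_id = "HP:b", y_type = "effect/phenotype", y_source = "HPO"
    ),
    tibble::tibble(
      x_id = "HP:b", x_type = "effect/phenotype", x_source = "HPO",
      relation = "phenotype_protein",
      y_id = "1001", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = "DB1", x_type = "drug", x_source = "DrugBank",
      relation = "drug_effect",
      y_id = "HP:a", y_type = "effect/phenotype", y_source = "HPO"
    ),
    tibble::tibble(
      x_id = "MONDO:z", x_type = "disease", x_source = "MONDO",
      relation = "disease_phenotype_positive",
      y_id = "HP:b", y_type = "effect/phenotype", y_source = "HPO"
    ),
    tibble::tibble(
      x_id = "HP:c", x_type = "effect/phenotype", x_source = "HPO",
      relation = "phenotype_protein",
      y_id = "1002", y_type = "gene/protein", y_source = "NCBI"
    )
  ))
}

overlap_case_P <- function() {
  structure(
    tibble::tibble(
      phenotype_id = c("HP:a", "HP:b"),
      evidence = "same-numeric-id"
    ),
    class = c("overlap_set", "tbl_df", "tbl", "data.frame")
  )
}

overlap_case_map <- function() {
  xref_map(tibble::tibble(
    from = c("HP:a", "HP:b"), to = c("MONDO:a2", "MONDO:b2"),
    to_name = c("disease a2", "disease b2")
  ))
}

test_that("the four rewiring rules convert and drop as stated", {
  res <- rewire_edges(overlap_case_tables(), overlap_case_P(), overlap_case_map())
  out <- res$triples

  # one endpoint in P: phenotype-phenotype -> disease-phenotype
  conv1 <- out[out$relation == "disease_phenotype_positive" & out$x_id == "MONDO:a2", ]
  expect_equal(conv1$y_id, "HP:c")
  expect_equal(conv1$x_type, "disease")

  # both endpoints in P -> disease-disease
  dd <- out[out$relation == "disease_disease", ]
  expect_equal(nrow(dd), 1)
  expect_setequal(c(dd$x_id, dd$y_id), c("MONDO:a2", "MONDO:b2"))

  # protein-phenotype with phenotype in P -> protein-disease, removed from
  # phenotype-protein
  pd <- out[out$relation == "disease_protein", ]
  expect_equal(pd$x_id, "MONDO:b2")
  expect_equal(pd$y_id, "1001")
  expect_false(any(out$relation == "phenotype_protein" & out$x_id == "HP:b"))

  # drug-phenotype and disease-phenotype with phenotype in P -> dropped
  expect_false(any(out$y_id %in% c("HP:a", "HP:b")))
  dropped <- res$log[res$log$action == "dropped", ]
  expect_equal(nrow(dropped), 2)
  expect_setequal(dropped$original_relation, c("drug_effect", "disease_phenotype_positive"))

  # edges with no endpoint in P are bitwise unchanged
  untouched <- out[out$x_id == "HP:c" & out$relation == "phenotype_protein", ]
  input_row <- overlap_case_tables()
  expect_identical(
    as.data.frame(untouched),
    as.data.frame(input_row[input_row$x_id == "HP:c" & input_row$relation == "phenotype_protein", ])
  )
})

test_that("rewiring conserves edges and reaches a fixed point", {
  t <- overlap_case_tables()
  res <- rewire_edges(t, overlap_case_P(), overlap_case_map())
  n_dropped <- sum(res$log$action == "dropped")
  expect_equal(nrow(t), nrow(res$triples) + n_dropped)

  # fixed point: a second pass changes nothing
  res2 <- rewire_edges(res$triples, overlap_case_P(), overlap_case_map())
  expect_equal(
    as.data.frame(dplyr::arrange(res2$triples, x_id, relation, y_id)),
    as.data.frame(dplyr::arrange(res$triples, x_id, relation, y_id))
  )
  expect_equal(nrow(res2$log), 0)
})

test_that("an overlap member without a disease mapping is a contract error", {
  partial_map <- xref_map(tibble::tibble(from = "HP:a", to = "MONDO:a2"))
  expect_error(
    rewire_edges(overlap_case_tables(), overlap_case_P(), partial_map),
    class = "kgcraft_contract_error"
  )
})
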