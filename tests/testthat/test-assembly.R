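ppi_row <- function(a, b, rel = "protein_protein") {
  tibble::tibble(
    x_id = a, x_type = "gene/protein", x_name = a, x_source = "NCBI",
    relation = rel,
    y_id = b, y_type = "gene/protein", y_name = b, y_source = "NCBI",
    resource = "t"
  )
}

test_that("merge_tables concatenates with provenance and rejects type conflicts", {
  a <- triples_table(ppi_row("1", "2"))
  b <- triples_table(dplyr::bind_rows(ppi_row("3", "4"), ppi_row("1", "2")))
  merged <- merge_tables(list(a, b))
  expect_equal(nrow(merged), 3) # duplicates survive until clean_edges

  conflict <- triples_table(tibble::tibble(
    x_id = "1", x_type = "drug", x_source = "NCBI",
    relation = "drug_drug",
    y_id = "9", y_type = "drug", y_source = "NCBI"
  ))
  expect_error(merge_tables(list(a, conflict)), class = "kgcraft_contract_error")
})

test_that("clean_edges executes the stated sequence in order", {
  # single edge: reverse row added
  r <- clean_edges(triples_table(ppi_row("a", "b")))
  expect_equal(nrow(r$triples), 2)
  expect_setequal(paste(r$triples$x_id, r$triples$y_id), c("a b", "b a"))

  # already-symmetric input does not double
  r2 <- clean_edges(dplyr::bind_rows(
    triples_table(ppi_row("a", "b")), triples_table(ppi_row("b", "a"))
  ))
  expect_equal(nrow(r2$triples), 2)
  expect_equal(unname(r2$report["duplicates_dropped_2"]), 2)

  # self-loops removed
  # the reversed duplicate of a self-loop is caught by the second dedup pass,
  # so exactly one self-loop row remains to be removed
  r3 <- clean_edges(triples_table(ppi_row("a", "a")))
  expect_equal(nrow(r3$triples), 0)
  expect_equal(unname(r3$report["self_loops_removed"]), 1)
  expect_equal(unname(r3$report["duplicates_dropped_2"]), 1)

  # missing endpoints dropped first
  withnan <- dplyr::bind_rows(ppi_row("a", "b"), ppi_row("c", "d"))
  withnan$y_id[2] <- NA
  r4 <- clean_edges(withnan)
  expect_equal(unname(r4$report["nan_dropped"]), 1)
  expect_equal(nrow(r4$triples), 2)

  # exact duplicates collapse in the first pass
  r5 <- clean_edges(dplyr::bind_rows(
    triples_table(ppi_row("a", "b")), triples_table(ppi_row("a", "b"))
  ))
  expect_equal(unname(r5$report["duplicates_dropped_1"]), 1)
  expect_equal(nrow(r5$triples), 2)
})

test_that("clean_edges is idempotent", {
  set.seed(3)
  t <- dplyr::bind_rows(lapply(1:30, function(i) {
    ppi_row(
      as.character(sample(1:10, 1)),
      as.character(sample(1:10, 1))
    )
  }))
  once <- clean_edges(t)$triples
  twice <- clean_edges(once)
  expect_equal(
    as.data.frame(dplyr::arrange(twice$triples, x_id, y_id)),
    as.data.frame(dplyr::arrange(once, x_id, y_id))
  )
  expect_equal(unname(twice$report["nan_dropped"]), 0)
  expect_equal(unname(twice$report["self_loops_removed"]), 0)
})

test_that("largest component is selected with the documented tie-break", {
  conn <- clean_edges(dplyr::bind_rows(
    ppi_row("a", "b"), ppi_row("b", "c")
  ))$triples
  r <- largest_connected_component(conn)
  expect_equal(nrow(r$triples), nrow(conn))
  expect_equal(unname(r$report["edge_fraction"]), 1)

  # components of 5 and 3 nodes: keep the 5-node one
  two <- clean_edges(dplyr::bind_rows(
    ppi_row("a", "b"), ppi_row("b", "c"), ppi_row("c", "d"), ppi_row("d", "e"),
    ppi_row("x", "y"), ppi_row("y", "z")
  ))$triples
  r2 <- largest_connected_component(two)
  expect_equal(unname(r2$report["nodes_retained"]), 5)
  expect_false(any(r2$triples$x_id %in% c("x", "y", "z")))

  # equal node and edge counts: keep the component with the smallest id
  tie <- clean_edges(dplyr::bind_rows(
    ppi_row("m", "n"), ppi_row("a", "b")
  ))$triples
  r3 <- largest_connected_component(tie)
  expect_setequal(unique(c(r3$triples$x_id, r3$triples$y_id)), c("a", "b"))

  # empty input: fraction defined as 1
  r4 <- largest_connected_component(conn[0, ])
  expect_equal(unname(r4$report["edge_fraction"]), 1)
})

test_that("component membership equals the union-find oracle on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:150, 1)
    m <- sample(20:300, 1)
    from <- as.character(sample(n, m, replace = TRUE))
    to <- as.character(sample(n, m, replace = TRUE))
    keep <- from != to
    t <- clean_edges(ppi_row(from[keep], to[keep]))$triples
    r <- largest_connected_component(t)

    memb <- oracle_components(from[keep], to[keep])
    sizes <- tabulate(memb)
    if (sum(sizes == max(sizes)) > 1) next # tie-break covered elsewhere
    biggest <- names(memb)[memb == which.max(sizes)]
    expect_setequal(unique(c(r$triples$x_id, r$triples$y_id)), biggest)
  }
})

test_that("node indices are consecutive, sorted and order-independent", {
  t <- triples_table(dplyr::bind_rows(
    tibble::tibble(
      x_id = "DB1", x_type = "drug", x_source = "DrugBank",
      relation = "drug_protein",
      y_id = "1001", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = "UBERON:1", x_type = "anatomy", x_source = "UBERON",
      relation = "anatomy_protein_present",
      y_id = "1001", y_type = "gene/protein", y_source = "NCBI"
    )
  ))
  cleaned <- clean_edges(t)$triples
  kg <- assign_node_indices(cleaned)
  expect_equal(kg$nodes$node_index, 0:2)
  # sorted by (node_type, node_source, node_id)
  expect_equal(kg$nodes$node_type, c("anatomy", "drug", "gene/protein"))

  perm <- cleaned[rev(seq_len(nrow(cleaned))), ]
  kg2 <- assign_node_indices(perm)
  expect_equal(as.data.frame(kg$nodes), as.data.frame(kg2$nodes))
  expect_same_graph(kg, kg2)

  # determinism across repeated runs
  for (i in 1:5) {
    expect_same_graph(assign_node_indices(cleaned), kg)
  }
})

test_that("assembly report stage counts reconcile on fixtures", {
  built <- shared_build()
  expect_true(assembly_report_reconciles(built$report))
  cl <- built$report$cleaning
  expect_equal(
    unname(cl["rows_in"] - cl["nan_dropped"] - cl["duplicates_dropped_1"] +
      cl["reverse_added"] - cl["duplicates_dropped_2"] - cl["self_loops_removed"]),
    unname(cl["rows_out"])
  )
})
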