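# Small star-and-chain graphs assembled through the package's own path.
drug_disease_row <- function(drug, disease, rel = "indication") {
  tibble::tibble(
    x_id = drug, x_type = "drug", x_source = "DrugBank",
    relation = rel,
    y_id = disease, y_type = "disease", y_source = "MONDO"
  )
}

star_kg <- function(n_diseases = 5) {
  # drug - gene hub - every disease: each disease at distance 2
  rows <- dplyr::bind_rows(
    tibble::tibble(
      x_id = "DB1", x_type = "drug", x_source = "DrugBank",
      relation = "drug_protein",
      y_id = "hub", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = paste0("MONDO:", seq_len(n_diseases)), x_type = "disease",
      x_source = "MONDO", relation = "disease_protein",
      y_id = "hub", y_type = "gene/protein", y_source = "NCBI"
    )
  )
  assemble_kg(list(triples_table(rows)))$kg_raw
}

node_idx <- function(kg, id) kg$nodes$node_index[kg$nodes$node_id == id]

test_that("hop distances agree with an independent BFS oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:60, 1)
    from <- as.character(sample(n, 2 * n, replace = TRUE))
    to <- as.character(sample(n, 2 * n, replace = TRUE))
    keep <- from != to
    t <- triples_table(tibble::tibble(
      x_id = from[keep], x_type = "gene/protein", x_source = "NCBI",
      relation = "protein_protein",
      y_id = to[keep], y_type = "gene/protein", y_source = "NCBI"
    ))
    kg <- assemble_kg(list(t))$kg_raw
    src_id <- kg$nodes$node_id[1]
    d_oracle <- oracle_bfs(from[keep], to[keep], src_id)
    for (target in sample(kg$nodes$node_id, 5)) {
      got <- shortest_path_distance(kg, node_idx(kg, src_id), node_idx(kg, target))
      expect_equal(got, unname(d_oracle[target]))
    }
  }
})

test_that("distance is 1 for a direct edge, 2 through a protein, Inf across components", {
  kg <- assemble_kg(list(triples_table(dplyr::bind_rows(
    drug_disease_row("DB1", "MONDO:1"),
    tibble::tibble(
      x_id = "DB1", x_type = "drug", x_source = "DrugBank",
      relation = "drug_protein",
      y_id = "g1", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = "MONDO:2", x_type = "disease", x_source = "MONDO",
      relation = "disease_protein",
      y_id = "g1", y_type = "gene/protein", y_source = "NCBI"
    ),
    tibble::tibble(
      x_id = "3001", x_type = "gene/protein", x_source = "NCBI",
      relation = "protein_protein",
      y_id = "3002", y_type = "gene/protein", y_source = "NCBI"
    )
  ))))$kg_raw
  expect_equal(shortest_path_distance(kg, node_idx(kg, "DB1"), node_idx(kg, "MONDO:1")), 1)
  expect_equal(shortest_path_distance(kg, node_idx(kg, "DB1"), node_idx(kg, "MONDO:2")), 2)
  expect_equal(shortest_path_distance(kg, node_idx(kg, "DB1"), node_idx(kg, "3001")), Inf)
  expect_equal(shortest_path_distance(kg, node_idx(kg, "DB1"), node_idx(kg, "DB1")), 0)
  expect_error(shortest_path_distance(kg, node_idx(kg, "DB1"), 999L),
    class = "kgcraft_contract_error"
  )
})

test_that("permutation null samples candidates exhaustively and reproducibly", {
  kg <- star_kg(4)
  drug <- node_idx(kg, "DB1")
  indicated <- node_idx(kg, "MONDO:1")
  # 3 non-indicated diseases, n = 3: exhaustive, all at distance 2
  d <- permutation_null(kg, drug, indicated, proximity_config(n_permutations = 3, rng_seed = 1))
  expect_equal(d, c(2, 2, 2))
  # fewer candidates than draws: sampling with replacement kicks in
  d2 <- permutation_null(kg, drug, indicated, proximity_config(n_permutations = 10, rng_seed = 1))
  expect_length(d2, 10)
  # fixed seed, identical sample
  expect_equal(
    permutation_null(kg, drug, indicated, proximity_config(n_permutations = 10, rng_seed = 7)),
    permutation_null(kg, drug, indicated, proximity_config(n_permutations = 10, rng_seed = 7))
  )
})

test_that("direct-indication pairs are flagged, excluded and uncounted", {
  rows <- dplyr::bind_rows(
    drug_disease_row("DB1", "MONDO:1"),
    lapply(2:6, function(i) {
      tibble::tibble(
        x_id = "MONDO:1", x_type = "disease", x_source = "MONDO",
        relation = "disease_disease",
        y_id = paste0("MONDO:", i), y_type = "disease", y_source = "MONDO"
      )
    })
  )
  kg <- assemble_kg(list(triples_table(rows)))$kg_raw
  pairs <- tibble::tibble(
    drug_index = node_idx(kg, "DB1"),
    disease_index = c(node_idx(kg, "MONDO:1"), node_idx(kg, "MONDO:2"))
  )
  res <- proximity_test(kg, pairs, proximity_config(n_permutations = 4, rng_seed = 1))
  expect_true(res$has_indication_edge[1])
  expect_equal(res$d_observed[1], 1)
  expect_true(is.na(res$p_raw[1])) # the dash row: no p for direct pairs
  expect_equal(res$n_tested_pairs[1], 1) # multiplicity counts tested pairs only
  expect_false(is.na(res$p_raw[2]))
  expect_equal(res$p_adjusted[2], min(1, res$p_raw[2] * 1))
})

test_that("a planted two-hop indication against a far background is significant", {
  tb <- make_proximity_testbed("power", n_diseases = 80, rng_seed = 5)
  res <- proximity_test(tb$kg, tb$pairs, proximity_config(n_permutations = 1000, rng_seed = 9))
  expect_equal(res$d_observed, 2)
  expect_equal(res$p_raw, 1 / 1001)
  expect_true(res$significant)
  expect_gte(res$null_mean, 4)
  expect_true(res$ci_low <= res$null_mean && res$null_mean <= res$ci_high)
})

test_that("p_raw is non-increasing as the observed distance decreases", {
  d_rand <- c(2, 3, 3, 4, 5, 5, 6)
  p_for <- function(d_obs) (1 + sum(d_rand <= d_obs)) / (length(d_rand) + 1)
  ps <- vapply(c(6, 5, 4, 3, 2, 1), p_for, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("results are deterministic for identical inputs and seed", {
  tb <- make_proximity_testbed("calibration", n_diseases = 40, rng_seed = 2)
  dis <- tb$kg$nodes$node_index[tb$kg$nodes$node_type == "disease"]
  pairs <- tibble::tibble(
    drug_index = tb$kg$nodes$node_index[tb$kg$nodes$node_type == "drug"],
    disease_index = dis[5]
  )
  cfg <- proximity_config(n_permutations = 50, rng_seed = 123)
  r1 <- proximity_test(tb$kg, pairs, cfg)
  r2 <- proximity_test(tb$kg, pairs, cfg)
  expect_equal(as.data.frame(tidy(r1)), as.data.frame(tidy(r2)))
})

test_that("tidiers and autoplot summarize a proximity result", {
  tb <- make_proximity_testbed("power", n_diseases = 30, rng_seed = 4)
  res <- proximity_test(tb$kg, tb$pairs, proximity_config(n_permutations = 100, rng_seed = 1))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "proximity_result"))
  gl <- glance(res)
  expect_equal(gl$n_pairs, 1)
  expect_equal(gl$n_permutations, 100L)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
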