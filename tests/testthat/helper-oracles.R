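# Independent oracles kept deliberately naive: they re-derive quantities the
# package computes through igraph or vectorized code.

# Union-find connected components over an edge list of string endpoints.
# Returns a membership integer vector named by node.
oracle_components <- function(from, to) {
  nodes <- sort(unique(c(from, to)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (k in seq_along(from)) {
    ri <- find(match(from[k], nodes))
    rj <- find(match(to[k], nodes))
    if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  stats::setNames(match(roots, sort(unique(roots))), nodes)
}

# Plain queue BFS hop distances from `source` over an undirected edge list.
oracle_bfs <- function(from, to, source) {
  nodes <- sort(unique(c(from, to)))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), identity)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Random valid knowledge graph: random typed triples assembled through the
# package's own cleaning path (symmetry and dedup by construction), used for
# serialization round-trips where the oracle is the identity.
random_triples <- function(seed, n_edges = 60) {
  set.seed(seed)
  reg <- kg_relation_types()
  rel <- sample(reg$relation, n_edges, replace = TRUE)
  idx <- match(rel, reg$relation)
  mk_id <- function(type) {
    paste0(gsub("[^a-z]", "", type), sample.int(12, length(type), replace = TRUE))
  }
  tibble::tibble(
    x_id = mk_id(reg$type_a[idx]), x_type = reg$type_a[idx],
    x_source = "SRC", relation = rel,
    y_id = mk_id(reg$type_b[idx]), y_type = reg$type_b[idx],
    y_source = "SRC"
  ) |> triples_table(resource = "random")
}

random_kg <- function(seed, n_edges = 60) {
  assemble_kg(list(random_triples(seed, n_edges)))$kg_raw
}

# Tiny two-ontology fixture with a planted overlap set, built in code.
tiny_overlap_fixture <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  truth <- make_mock_ontologies(
    fixture_spec(
      rng_seed = 7, n_subtype_families = 4, n_distractor_diseases = 12,
      n_phenotypes = 30, overlap_fraction = 0.2
    ),
    dir
  )
  list(
    dir = dir, truth = truth,
    disease = parse_obo(file.path(dir, "disease.obo")),
    phenotype = parse_obo(file.path(dir, "phenotype.obo"))
  )
}

expect_same_graph <- function(a, b) {
  ca <- kg_canonicalize(a)
  cb <- kg_canonicalize(b)
  expect_equal(as.data.frame(ca$nodes), as.data.frame(cb$nodes))
  expect_equal(as.data.frame(ca$edges), as.data.frame(cb$edges))
}

# Adjusted Rand index between two labelings (independent implementation in
# mclust, used as the partition-recovery oracle).
partition_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
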