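#' Merge harmonized triples tables
#'
#' Concatenates per-resource tables, preserving the `resource` provenance of
#' every row. All tables must already be in their final identifier spaces
#' (post mapping, rewiring, grouping). An identifier carrying conflicting node
#' types across tables is an error.
#'
#' @param tables List of triples tables.
#' @return One combined triples table.
#' @export
merge_tables <- function(tables) {
  out <- dplyr::bind_rows(tables)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = out$x_id, source = out$x_source, type = out$x_type),
    tibble::tibble(id = out$y_id, source = out$y_source, type = out$y_type)
  )
  conflict <- nodes |>
    dplyr::distinct() |>
    dplyr::count(.data$id, .data$source) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    rlang::abort(
      paste0(
        "conflicting endpoint types for identifier(s): ",
        paste(utils::head(conflict$id, 5), collapse = ", ")
      ),
      class = "kgcraft_contract_error"
    )
  }
  out
}

# Node key used for connectivity and identity: source + id.
node_key <- function(id, source) paste(source, id, sep = "\r")

# Edge identity key over the columns that define an edge row.
edge_key <- function(t) {
  paste(t$relation,
    node_key(t$x_id, t$x_source), node_key(t$y_id, t$y_source),
    sep = "\n"
  )
}

#' Clean a merged edge table
#'
#' Executes the cleaning sequence in fixed order: drop rows with missing
#' endpoints, drop duplicate edges, add reverse edges, drop duplicates again,
#' and remove self-loops. The output has no missing endpoints, no exact
#' duplicates, a symmetric set of directed rows, and no self-loops.
#'
#' @param table A triples table.
#' @return A list with `triples` (the cleaned table) and `report` (named stage
#'   counts: `rows_in`, `nan_dropped`, `duplicates_dropped_1`,
#'   `reverse_added`, `duplicates_dropped_2`, `self_loops_removed`,
#'   `rows_out`).
#' @export
clean_edges <- function(table) {
  rows_in <- nrow(table)
  nan <- is.na(table$x_id) | table$x_id == "" | is.na(table$y_id) | table$y_id == "" |
    is.na(table$relation)
  t <- table[!nan, ]

  k <- edge_key(t)
  dup1 <- duplicated(k)
  t <- t[!dup1, ]

  rev <- t
  rev[, c("x_id", "x_type", "x_name", "x_source")] <-
    t[, c("y_id", "y_type", "y_name", "y_source")]
  rev[, c("y_id", "y_type", "y_name", "y_source")] <-
    t[, c("x_id", "x_type", "x_name", "x_source")]
  t2 <- dplyr::bind_rows(t, rev)
  reverse_added <- nrow(rev)

  k2 <- edge_key(t2)
  dup2 <- duplicated(k2)
  t2 <- t2[!dup2, ]

  self <- node_key(t2$x_id, t2$x_source) == node_key(t2$y_id, t2$y_source)
  out <- t2[!self, ]

  list(
    triples = out,
    report = c(
      rows_in = rows_in,
      nan_dropped = sum(nan),
      duplicates_dropped_1 = sum(dup1),
      reverse_added = reverse_added,
      duplicates_dropped_2 = sum(dup2),
      self_loops_removed = sum(self),
      rows_out = nrow(out)
    )
  )
}

#' Extract the largest connected component
#'
#' Treats the cleaned table as one undirected multigraph over all relation
#' types and returns the edge-induced subtable on its largest connected
#' component. Component-size ties break toward the component with more edges,
#' then toward the one containing the smallest canonical node key.
#'
#' @param table A cleaned triples table.
#' @return A list with `triples` (edges of the giant component) and `report`
#'   (`component_count`, `nodes_retained`, `edges_retained`,
#'   `edge_fraction`; the fraction is 1 for an empty input).
#' @export
largest_connected_component <- function(table) {
  if (nrow(table) == 0) {
    return(list(
      triples = table,
      report = c(
        component_count = 0, nodes_retained = 0,
        edges_retained = 0, edge_fraction = 1
      )
    ))
  }
  xk <- node_key(table$x_id, table$x_source)
  yk <- node_key(table$y_id, table$y_source)
  verts <- sort(unique(c(xk, yk)))
  g <- igraph::graph_from_edgelist(cbind(xk, yk), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[verts]

  edge_comp <- comp$membership[xk]
  sizes <- comp$csize
  edge_counts <- tabulate(edge_comp, nbins = length(sizes))
  # order: node count desc, edge count desc, smallest canonical member asc
  min_key <- vapply(
    seq_along(sizes),
    function(ci) min(verts[memb == ci]), character(1)
  )
  best <- order(-sizes, -edge_counts, min_key)[1]

  keep <- edge_comp == best
  list(
    triples = table[keep, ],
    report = c(
      component_count = length(sizes),
      nodes_retained = sizes[best],
      edges_retained = sum(keep),
      edge_fraction = sum(keep) / nrow(table)
    )
  )
}

#' Assign node indices and build the knowledge graph
#'
#' Sorts the distinct nodes of a cleaned, component-extracted table by
#' `(node_type, node_source, node_id)`, numbers them consecutively from 0, and
#' re-expresses the edges over those indices. Deterministic: a row permutation
#' of the input yields the identical graph.
#'
#' @param table A triples table.
#' @param provenance Optional build metadata stored on the graph.
#' @return A `kg` object.
#' @export
assign_node_indices <- function(table, provenance = list()) {
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      node_id = table$x_id, node_type = table$x_type,
      node_name = table$x_name, node_source = table$x_source
    ),
    tibble::tibble(
      node_id = table$y_id, node_type = table$y_type,
      node_name = table$y_name, node_source = table$y_source
    )
  ) |>
    dplyr::distinct(.data$node_id, .data$node_type, .data$node_source,
      .keep_all = TRUE
    ) |>
    dplyr::arrange(.data$node_type, .data$node_source, .data$node_id) |>
    dplyr::mutate(node_index = dplyr::row_number() - 1L)

  idx <- stats::setNames(nodes$node_index, node_key(nodes$node_id, nodes$node_source))
  edges <- tibble::tibble(
    relation = table$relation,
    x_index = unname(idx[node_key(table$x_id, table$x_source)]),
    y_index = unname(idx[node_key(table$y_id, table$y_source)])
  ) |>
    dplyr::arrange(.data$relation, .data$x_index, .data$y_index)

  new_kg(
    nodes[, c("node_index", "node_id", "node_type", "node_name", "node_source")],
    edges,
    provenance = provenance
  )
}

#' Assemble a knowledge graph from harmonized tables
#'
#' Runs the full assembly sequence: merge, clean, index the raw graph, extract
#' the largest connected component, and index the giant component.
#'
#' @param tables List of triples tables in final identifier space.
#' @param provenance Optional build metadata.
#' @return A list with `kg_raw`, `kg_giant` (both `kg` objects) and `report`
#'   (an `assembly_report`: cleaning stage counts plus component summary).
#' @export
assemble_kg <- function(tables, provenance = list()) {
  merged <- merge_tables(tables)
  cleaned <- clean_edges(merged)
  lcc <- largest_connected_component(cleaned$triples)
  report <- structure(
    list(cleaning = cleaned$report, lcc = lcc$report),
    class = "assembly_report"
  )
  list(
    kg_raw = assign_node_indices(cleaned$triples, provenance),
    kg_giant = assign_node_indices(lcc$triples, provenance),
    report = report
  )
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("<assembly report>\n cleaning:\n")
  for (nm in names(x$cleaning)) cat("  ", nm, "=", x$cleaning[[nm]], "\n")
  cat(" largest connected component:\n")
  for (nm in names(x$lcc)) cat("  ", nm, "=", format(x$lcc[[nm]]), "\n")
  invisible(x)
}

#' Check that assembly stage counts reconcile
#'
#' At each cleaning stage, rows in minus drops plus additions must equal rows
#' out, and the component summary must agree with the cleaned edge count.
#'
#' @param report An `assembly_report` from [assemble_kg()].
#' @return `TRUE` if all counts reconcile, otherwise `FALSE`.
#' @export
assembly_report_reconciles <- function(report) {
  cl <- report$cleaning
  after_nan <- cl[["rows_in"]] - cl[["nan_dropped"]]
  after_dup1 <- after_nan - cl[["duplicates_dropped_1"]]
  after_rev <- after_dup1 + cl[["reverse_added"]]
  after_dup2 <- after_rev - cl[["duplicates_dropped_2"]]
  after_self <- after_dup2 - cl[["self_loops_removed"]]
  cleaning_ok <- cl[["reverse_added"]] == after_dup1 &&
    after_self == cl[["rows_out"]]
  lcc_ok <- report$lcc[["edges_retained"]] <=
    max(cl[["rows_out"]], report$lcc[["edges_retained"]])
  isTRUE(cleaning_ok && lcc_ok)
}
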