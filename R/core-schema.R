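#' Create a knowledge graph object
#'
#' A knowledge graph is a node table plus a directed edge table in which every
#' undirected edge is stored as two directed rows (the deposited-file
#' convention), together with free-form build provenance.
#'
#' @param nodes Tibble with columns `node_index` (consecutive integers from 0),
#'   `node_id`, `node_type`, `node_name`, `node_source`.
#' @param edges Tibble with columns `relation`, `x_index`, `y_index`.
#' @param provenance Named list of build metadata (resource versions, seeds).
#' @return An object of class `kg`.
#' @export
new_kg <- function(nodes, edges, provenance = list()) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  need_n <- c("node_index", "node_id", "node_type", "node_name", "node_source")
  need_e <- c("relation", "x_index", "y_index")
  if (!all(need_n %in% names(nodes))) {
    rlang::abort("nodes must have node_index, node_id, node_type, node_name, node_source",
      class = "kgcraft_schema_error"
    )
  }
  if (!all(need_e %in% names(edges))) {
    rlang::abort("edges must have relation, x_index, y_index",
      class = "kgcraft_schema_error"
    )
  }
  nodes$node_index <- as.integer(nodes$node_index)
  edges$x_index <- as.integer(edges$x_index)
  edges$y_index <- as.integer(edges$y_index)
  structure(
    list(
      nodes = nodes[, need_n],
      edges = edges[, need_e],
      provenance = provenance
    ),
    class = "kg"
  )
}

#' @export
print.kg <- function(x, ...) {
  cat(
    "<knowledge graph>", nrow(x$nodes), "nodes |",
    nrow(x$edges), "directed edge rows\n"
  )
  nt <- sort(table(x$nodes$node_type), decreasing = TRUE)
  cat("node types:", paste0(names(nt), " (", nt, ")", collapse = ", "), "\n")
  cat("relation types:", length(unique(x$edges$relation)), "of 30\n")
  invisible(x)
}

#' Canonicalize a knowledge graph
#'
#' Orders nodes by `node_index` and edges lexicographically by
#' `(relation, x_index, y_index)`. Two graphs are equal exactly when their
#' canonical node and edge tables are equal.
#'
#' @param kg A `kg` object.
#' @return The same graph with canonically ordered tables and provenance
#'   dropped.
#' @export
kg_canonicalize <- function(kg) {
  nodes <- dplyr::arrange(kg$nodes, .data$node_index)
  edges <- dplyr::arrange(kg$edges, .data$relation, .data$x_index, .data$y_index)
  new_kg(nodes, edges, provenance = list())
}

#' Validate a knowledge graph
#'
#' Checks the five structural rules of the cleaned-graph contract: no dangling
#' edge endpoints, no self-loops, a symmetric directed edge multiset (every
#' `(r, x, y)` is mirrored by `(r, y, x)`), no exact duplicate edge rows, and
#' endpoint node types matching each relation's declared pair.
#'
#' @param kg A `kg` object.
#' @return A tibble with columns `rule`, `row`, `detail`; zero rows if and only
#'   if the graph is clean.
#' @export
validate_kg <- function(kg) {
  nodes <- kg$nodes
  edges <- kg$edges
  report <- list()

  known <- nodes$node_index
  dangling <- which(!(edges$x_index %in% known) | !(edges$y_index %in% known))
  if (length(dangling) > 0) {
    report$dangling <- tibble::tibble(
      rule = "dangling_endpoint", row = dangling,
      detail = paste0(
        edges$relation[dangling], ": ",
        edges$x_index[dangling], " -> ", edges$y_index[dangling]
      )
    )
  }

  loops <- which(edges$x_index == edges$y_index)
  if (length(loops) > 0) {
    report$loops <- tibble::tibble(
      rule = "self_loop", row = loops,
      detail = paste0(edges$relation[loops], ": ", edges$x_index[loops])
    )
  }

  key <- paste(edges$relation, edges$x_index, edges$y_index, sep = "\r")
  rev_key <- paste(edges$relation, edges$y_index, edges$x_index, sep = "\r")
  asym <- which(!(rev_key %in% key))
  if (length(asym) > 0) {
    report$asym <- tibble::tibble(
      rule = "asymmetric_edge", row = asym,
      detail = paste0(
        "missing reverse of ", edges$relation[asym], ": ",
        edges$x_index[asym], " -> ", edges$y_index[asym]
      )
    )
  }

  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    report$dup <- tibble::tibble(
      rule = "duplicate_row", row = dup,
      detail = paste0(
        edges$relation[dup], ": ",
        edges$x_index[dup], " -> ", edges$y_index[dup]
      )
    )
  }

  type_of <- nodes$node_type[match(edges$x_index, nodes$node_index)]
  type_of_y <- nodes$node_type[match(edges$y_index, nodes$node_index)]
  checkable <- !is.na(type_of) & !is.na(type_of_y)
  ok <- endpoints_admissible(edges$relation, type_of, type_of_y)
  mism <- which(checkable & !ok)
  if (length(mism) > 0) {
    report$mism <- tibble::tibble(
      rule = "endpoint_type_mismatch", row = mism,
      detail = paste0(
        edges$relation[mism], ": ", type_of[mism], " -- ", type_of_y[mism]
      )
    )
  }

  out <- dplyr::bind_rows(report)
  if (nrow(out) == 0) {
    out <- tibble::tibble(rule = character(), row = integer(), detail = character())
  }
  out
}

# Denormalized edge table in the 12-column deposited layout, canonical order.
kg_edge_export <- function(kg) {
  reg <- kg_relation_types()
  nodes <- kg$nodes
  edges <- dplyr::arrange(kg$edges, .data$relation, .data$x_index, .data$y_index)
  xi <- match(edges$x_index, nodes$node_index)
  yi <- match(edges$y_index, nodes$node_index)
  tibble::tibble(
    relation = edges$relation,
    display_relation = reg$display_relation[match(edges$relation, reg$relation)],
    x_index = edges$x_index,
    x_id = nodes$node_id[xi],
    x_type = nodes$node_type[xi],
    x_name = nodes$node_name[xi],
    x_source = nodes$node_source[xi],
    y_index = edges$y_index,
    y_id = nodes$node_id[yi],
    y_type = nodes$node_type[yi],
    y_name = nodes$node_name[yi],
    y_source = nodes$node_source[yi]
  )
}

#' Write a knowledge graph to CSV
#'
#' Writes the edge table in the deposited 12-column layout (`relation`,
#' `display_relation`, then denormalized `x_` and `y_` node columns), in
#' canonical `(relation, x_index, y_index)` order, UTF-8, with a header row.
#' Optionally also writes a separate node file.
#'
#' @param kg A `kg` object; must pass [validate_kg()].
#' @param destination Path for the edge CSV.
#' @param nodes_destination Optional path for a node CSV with columns
#'   `node_index`, `node_id`, `node_type`, `node_name`, `node_source`.
#' @return Invisibly, `destination`.
#' @export
write_kg <- function(kg, destination, nodes_destination = NULL) {
  report <- validate_kg(kg)
  if (nrow(report) > 0) {
    msg <- paste(utils::head(paste0(report$rule, ": ", report$detail), 10), collapse = "; ")
    rlang::abort(
      paste0("graph fails validation (", nrow(report), " violation(s)): ", msg),
      class = "kgcraft_validation_error"
    )
  }
  readr::write_csv(kg_edge_export(kg), destination, progress = FALSE)
  if (!is.null(nodes_destination)) {
    readr::write_csv(
      dplyr::arrange(kg$nodes, .data$node_index), nodes_destination,
      progress = FALSE
    )
  }
  invisible(destination)
}

#' Read a knowledge graph from CSV
#'
#' Reads a file in the layout produced by [write_kg()] and reconstructs the
#' graph. Unknown relation or node-type labels are rejected with an error
#' naming the offending label and row, never coerced.
#'
#' @param source Path to an edge CSV written by [write_kg()].
#' @return A `kg` object.
#' @export
read_kg <- function(source) {
  df <- readr::read_csv(source,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c(
    "relation", "x_index", "x_id", "x_type", "x_name", "x_source",
    "y_index", "y_id", "y_type", "y_name", "y_source"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "kgcraft_schema_error"
    )
  }

  bad_rel <- which(!(df$relation %in% kg_relation_types()$relation))
  if (length(bad_rel) > 0) {
    rlang::abort(
      paste0(
        "unknown relation label '", df$relation[bad_rel[1]],
        "' at row ", bad_rel[1]
      ),
      class = "kgcraft_schema_error"
    )
  }
  bad_type <- which(!(df$x_type %in% kg_node_types()) | !(df$y_type %in% kg_node_types()))
  if (length(bad_type) > 0) {
    lbl <- setdiff(c(df$x_type[bad_type[1]], df$y_type[bad_type[1]]), kg_node_types())[1]
    rlang::abort(
      paste0("unknown node type label '", lbl, "' at row ", bad_type[1]),
      class = "kgcraft_schema_error"
    )
  }

  x_nodes <- dplyr::distinct(tibble::tibble(
    node_index = as.integer(df$x_index), node_id = df$x_id,
    node_type = df$x_type, node_name = df$x_name, node_source = df$x_source
  ))
  y_nodes <- dplyr::distinct(tibble::tibble(
    node_index = as.integer(df$y_index), node_id = df$y_id,
    node_type = df$y_type, node_name = df$y_name, node_source = df$y_source
  ))
  nodes <- dplyr::distinct(dplyr::bind_rows(x_nodes, y_nodes))
  if (anyDuplicated(nodes$node_index) > 0) {
    rlang::abort("conflicting node attributes for one node_index",
      class = "kgcraft_schema_error"
    )
  }
  edges <- tibble::tibble(
    relation = df$relation,
    x_index = as.integer(df$x_index),
    y_index = as.integer(df$y_index)
  )
  kg_canonicalize(new_kg(nodes, edges))
}
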