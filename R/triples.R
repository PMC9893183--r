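#' Construct a harmonized triples table
#'
#' A triples table holds per-resource relation records in source-ontology
#' identifier space, before graph assembly. Each row links an `x` entity to a
#' `y` entity through one of the thirty relation labels
#' (see [kg_relation_types()]).
#'
#' @param df Data frame with at least `x_id`, `x_type`, `x_source`, `relation`,
#'   `y_id`, `y_type`, `y_source`. Optional `x_name` / `y_name` default to the
#'   identifiers; optional `resource` tags provenance.
#' @param resource Resource tag recorded on every row when the input has no
#'   `resource` column.
#' @return A tibble with columns `x_id`, `x_type`, `x_name`, `x_source`,
#'   `relation`, `y_id`, `y_type`, `y_name`, `y_source`, `resource`.
#' @export
#' @examples
#' triples_table(
#'   data.frame(
#'     x_id = "DB0001", x_type = "drug", x_source = "DrugBank",
#'     relation = "indication",
#'     y_id = "MONDO:0000001", y_type = "disease", y_source = "MONDO"
#'   ),
#'   resource = "example"
#' )
triples_table <- function(df, resource = "unspecified") {
  df <- tibble::as_tibble(df)
  required <- c("x_id", "x_type", "x_source", "relation", "y_id", "y_type", "y_source")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("triples table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "kgcraft_schema_error"
    )
  }
  if (!"x_name" %in% names(df)) df$x_name <- df$x_id
  if (!"y_name" %in% names(df)) df$y_name <- df$y_id
  if (!"resource" %in% names(df)) df$resource <- resource

  bad_id <- is.na(df$x_id) | df$x_id == "" | is.na(df$y_id) | df$y_id == ""
  if (any(bad_id)) {
    rlang::abort(
      paste0(sum(bad_id), " row(s) have empty or missing identifiers"),
      class = "kgcraft_schema_error"
    )
  }
  unknown <- setdiff(unique(df$relation), kg_relation_types()$relation)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("unknown relation label(s): ", paste(unknown, collapse = ", ")),
      class = "kgcraft_schema_error"
    )
  }
  ok <- endpoints_admissible(df$relation, df$x_type, df$y_type)
  if (!all(ok)) {
    bad <- utils::head(which(!ok), 5)
    rlang::abort(
      paste0(
        "endpoint types inconsistent with relation declaration at row(s): ",
        paste(bad, collapse = ", ")
      ),
      class = "kgcraft_schema_error"
    )
  }
  df[, c(
    "x_id", "x_type", "x_name", "x_source", "relation",
    "y_id", "y_type", "y_name", "y_source", "resource"
  )]
}

# Empty triples table with the canonical columns.
empty_triples <- function() {
  tibble::tibble(
    x_id = character(), x_type = character(), x_name = character(),
    x_source = character(), relation = character(),
    y_id = character(), y_type = character(), y_name = character(),
    y_source = character(), resource = character()
  )
}

# Attach (or extend) the per-adapter drop log kept in the "drops" attribute.
# Conservation invariant: |input| = |output before expansion| + |dropped|.
add_drop_log <- function(out, dropped, reason) {
  log <- attr(out, "drops")
  if (is.null(log)) {
    log <- tibble::tibble(reason = character(), n = integer())
  }
  if (nrow(dropped) > 0 || reason == "") {
    log <- dplyr::bind_rows(log, tibble::tibble(reason = reason, n = nrow(dropped)))
  }
  attr(out, "drops") <- log
  attr(out, "dropped_rows") <- dplyr::bind_rows(attr(out, "dropped_rows"), dropped)
  out
}

#' Drop log of an adapter result
#'
#' Every ingest adapter records the rows it removed, with a reason, in an
#' attribute of its output so that row conservation
#' (`input = output + dropped`) can be audited.
#'
#' @param x A triples table (or filtered table) returned by an adapter.
#' @return A tibble with columns `reason` and `n`; zero rows when nothing was
#'   dropped.
#' @export
drop_log <- function(x) {
  log <- attr(x, "drops")
  if (is.null(log)) tibble::tibble(reason = character(), n = integer()) else log
}
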