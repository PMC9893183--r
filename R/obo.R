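#' Parse an OBO-format ontology file
#'
#' Reads `[Term]` stanzas from OBO 1.2/1.4 text and extracts term identifiers,
#' names, definitions, the `is_a` hierarchy, cross-references, subsets and
#' synonyms. Stanza keys outside this set are ignored. Obsolete terms are kept
#' in the term table (flagged) but contribute no outgoing `is_a` edges.
#'
#' @param source Path to an OBO text file.
#' @return An object of class `ontology_graph`: a list with tibbles `terms`
#'   (`id`, `name`, `definition`, `is_obsolete`), `edges` (`child_id`,
#'   `parent_id`), `xrefs` (`term_id`, `foreign_namespace`, `foreign_id`),
#'   `subsets` (`term_id`, `subset`) and `synonyms` (`term_id`, `synonym`).
#' @export
parse_obo <- function(source) {
  lines <- readr::read_lines(source, progress = FALSE)
  stanza_starts <- which(lines == "[Term]")
  terms <- list()
  edges <- list()
  xrefs <- list()
  subsets <- list()
  synonyms <- list()

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    from <- stanza_starts[s] + 1L
    to <- bounds[s + 1L] - 1L
    block <- lines[seq(from, to)]
    # stop at the next non-Term stanza header, if any
    hdr <- grep("^\\[", block)
    if (length(hdr) > 0) block <- block[seq_len(hdr[1] - 1L)]
    block <- block[block != ""]
    keys <- sub(":.*$", "", block)
    vals <- stringr::str_trim(sub("^[^:]+:", "", block))

    id <- vals[keys == "id"][1]
    if (is.na(id) || id == "") {
      rlang::abort(
        paste0("malformed [Term] stanza without id at line ", stanza_starts[s]),
        class = "kgcraft_parse_error"
      )
    }
    name <- vals[keys == "name"][1]
    def <- vals[keys == "def"][1]
    if (!is.na(def)) {
      # def lines look like: def: "text" [refs]
      def <- stringr::str_match(def, '^"(.*)"')[, 2]
    }
    obsolete <- any(keys == "is_obsolete" & tolower(vals) == "true")
    terms[[s]] <- tibble::tibble(
      id = id,
      name = ifelse(is.na(name), id, name),
      definition = ifelse(is.na(def), NA_character_, def),
      is_obsolete = obsolete
    )
    if (!obsolete) {
      parents <- vals[keys == "is_a"]
      if (length(parents) > 0) {
        # strip trailing "! comment"
        parents <- stringr::str_trim(sub("!.*$", "", parents))
        edges[[s]] <- tibble::tibble(child_id = id, parent_id = parents)
      }
    }
    xr <- vals[keys == "xref"]
    if (length(xr) > 0) {
      xr <- stringr::str_trim(sub("!.*$", "", xr))
      xr <- sub("\\s.*$", "", xr) # drop optional quoted description
      xrefs[[s]] <- tibble::tibble(
        term_id = id,
        foreign_namespace = sub(":.*$", "", xr),
        foreign_id = xr
      )
    }
    ss <- vals[keys == "subset"]
    if (length(ss) > 0) subsets[[s]] <- tibble::tibble(term_id = id, subset = ss)
    syn <- vals[keys == "synonym"]
    if (length(syn) > 0) {
      syn <- stringr::str_match(syn, '^"(.*)"')[, 2]
      synonyms[[s]] <- tibble::tibble(term_id = id, synonym = syn)
    }
  }

  terms <- if (length(terms)) dplyr::bind_rows(terms) else {
    tibble::tibble(
      id = character(), name = character(),
      definition = character(), is_obsolete = logical()
    )
  }
  out <- structure(
    list(
      terms = terms,
      edges = if (length(edges)) dplyr::bind_rows(edges) else {
        tibble::tibble(child_id = character(), parent_id = character())
      },
      xrefs = if (length(xrefs)) dplyr::bind_rows(xrefs) else {
        tibble::tibble(
          term_id = character(), foreign_namespace = character(),
          foreign_id = character()
        )
      },
      subsets = if (length(subsets)) dplyr::bind_rows(subsets) else {
        tibble::tibble(term_id = character(), subset = character())
      },
      synonyms = if (length(synonyms)) dplyr::bind_rows(synonyms) else {
        tibble::tibble(term_id = character(), synonym = character())
      }
    ),
    class = "ontology_graph"
  )
  out
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(
    "<ontology>", nrow(x$terms), "terms |", nrow(x$edges), "is_a edges |",
    nrow(x$xrefs), "xrefs\n"
  )
  invisible(x)
}

#' Hierarchy edges of an ontology as a triples table
#'
#' Converts the `is_a` parent-child edges of a parsed ontology into relation
#' rows of a single homogeneous relation type (e.g. `disease_disease` for a
#' disease ontology, `anatomy_anatomy` for an anatomy ontology).
#'
#' @param ontology An `ontology_graph` from [parse_obo()].
#' @param relation One of the homogeneous hierarchy relation labels.
#' @param node_type Node type of all terms in this ontology.
#' @param node_source Source-ontology label recorded on the nodes.
#' @param resource Provenance tag.
#' @return A triples table of child-parent rows; edges referencing terms absent
#'   from the term table are dropped and logged.
#' @export
ontology_to_triples <- function(ontology, relation, node_type, node_source,
                                resource = node_source) {
  ed <- ontology$edges
  names_of <- stats::setNames(ontology$terms$name, ontology$terms$id)
  known <- ed$child_id %in% ontology$terms$id & ed$parent_id %in% ontology$terms$id
  kept <- ed[known, ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$child_id, x_type = node_type,
      x_name = unname(names_of[kept$child_id]), x_source = node_source,
      relation = relation,
      y_id = kept$parent_id, y_type = node_type,
      y_name = unname(names_of[kept$parent_id]), y_source = node_source
    ),
    resource = resource
  )
  add_drop_log(out, ed[!known, ], reason = "dangling_is_a")
}
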