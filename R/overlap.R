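#' Compute the phenotype/disease overlap set
#'
#' A phenotype term belongs to the overlap set P when (i) the numeric part of
#' its identifier equals the numeric part of some disease identifier (both
#' ontologies descend from the same initiative and share numbering), or
#' (ii) the term is listed as a cross-reference of a disease term in the
#' disease ontology. Membership evidence records which rule(s) applied.
#'
#' @param phenotype_ontology,disease_ontology `ontology_graph` objects.
#' @param phenotype_prefix CURIE prefix of the phenotype namespace (used to
#'   recognize phenotype-directed xrefs in the disease ontology).
#' @return Tibble of class `overlap_set` with columns `phenotype_id` and
#'   `evidence` (`"same-numeric-id"`, `"xref-mapped"`, or `"both"`).
#' @export
compute_overlap_set <- function(phenotype_ontology, disease_ontology,
                                phenotype_prefix = "HP:") {
  pheno_ids <- phenotype_ontology$terms$id
  dis_ids <- disease_ontology$terms$id
  numeric_part <- function(x) sub("^[^:]*:", "", x)

  same_num <- numeric_part(pheno_ids) %in% numeric_part(dis_ids)
  xref_targets <- disease_ontology$xrefs$foreign_id[
    startsWith(disease_ontology$xrefs$foreign_id, phenotype_prefix)
  ]
  via_xref <- pheno_ids %in% xref_targets

  member <- same_num | via_xref
  out <- tibble::tibble(
    phenotype_id = pheno_ids[member],
    evidence = dplyr::case_when(
      same_num[member] & via_xref[member] ~ "both",
      same_num[member] ~ "same-numeric-id",
      TRUE ~ "xref-mapped"
    )
  )
  class(out) <- c("overlap_set", class(out))
  out
}

#' Map overlap-set members to disease identifiers
#'
#' Builds the phenotype-to-disease identifier map used for edge rewiring:
#' same-numeric-id members map to the disease term sharing their zero-padded
#' numeric suffix; xref-mapped members map to every disease term that
#' cross-references them.
#'
#' @param overlap An `overlap_set` from [compute_overlap_set()].
#' @param disease_ontology The disease `ontology_graph`.
#' @param phenotype_prefix CURIE prefix of the phenotype namespace.
#' @return An [xref_map()] from phenotype identifiers to disease identifiers
#'   (possibly one-to-many), with mapped names in `to_name`.
#' @export
overlap_disease_map <- function(overlap, disease_ontology,
                                phenotype_prefix = "HP:") {
  numeric_part <- function(x) sub("^[^:]*:", "", x)
  dis <- disease_ontology$terms
  by_num <- tibble::tibble(
    num = numeric_part(dis$id), to = dis$id, to_name = dis$name
  )
  num_map <- dplyr::inner_join(
    tibble::tibble(from = overlap$phenotype_id, num = numeric_part(overlap$phenotype_id)),
    by_num,
    by = "num", relationship = "many-to-many"
  )[, c("from", "to", "to_name")]

  xr <- disease_ontology$xrefs[
    startsWith(disease_ontology$xrefs$foreign_id, phenotype_prefix),
  ]
  xr_map <- tibble::tibble(
    from = xr$foreign_id,
    to = xr$term_id,
    to_name = dis$name[match(xr$term_id, dis$id)]
  )
  xr_map <- xr_map[xr_map$from %in% overlap$phenotype_id, ]
  xref_map(dplyr::distinct(dplyr::bind_rows(num_map, xr_map)),
    from_ns = "HPO", to_ns = "MONDO"
  )
}

# Replace one phenotype endpoint with its mapped disease identifier(s);
# one-to-many maps duplicate the edge per target (deduplicated at assembly).
swap_endpoint_to_disease <- function(rows, side, pheno_to_disease) {
  id_col <- paste0(side, "_id")
  joined <- dplyr::inner_join(rows, pheno_to_disease,
    by = stats::setNames("from", id_col),
    relationship = "many-to-many"
  )
  joined[[id_col]] <- as.character(joined$to)
  joined[[paste0(side, "_type")]] <- rep("disease", nrow(joined))
  joined[[paste0(side, "_source")]] <- rep("MONDO", nrow(joined))
  if ("to_name" %in% names(joined)) {
    nm <- as.character(joined$to_name)
    joined[[paste0(side, "_name")]] <- as.character(
      ifelse(is.na(nm), joined$to, nm)
    )
  }
  joined[, setdiff(names(rows), c("to", "to_name"))]
}

#' Rewire edges touching the phenotype/disease overlap set
#'
#' Applies the overlap-resolution rules so that no entity is represented both
#' as a phenotype and as a disease:
#' phenotype-phenotype edges with one endpoint in P become
#' disease-phenotype edges and with both endpoints in P become disease-disease
#' edges; protein-phenotype edges with the phenotype in P become
#' protein-disease edges; disease-phenotype and drug-phenotype edges whose
#' phenotype is in P are dropped. All other edges pass through unchanged.
#'
#' @param tables A triples table (bind multiple tables first).
#' @param overlap An `overlap_set`.
#' @param pheno_to_disease An [xref_map()] covering every member of P
#'   (see [overlap_disease_map()]); a member without a mapping is a contract
#'   error raised before any rewiring.
#' @return A list with `triples` (the rewired table) and `log` (one row per
#'   affected input edge: original endpoints, action `converted`/`dropped`,
#'   new relation or drop reason).
#' @export
rewire_edges <- function(tables, overlap, pheno_to_disease) {
  P <- overlap$phenotype_id
  unmapped <- setdiff(P, pheno_to_disease$from)
  if (length(unmapped) > 0) {
    rlang::abort(
      paste0(
        "overlap member(s) without disease mapping: ",
        paste(utils::head(unmapped, 5), collapse = ", ")
      ),
      class = "kgcraft_contract_error"
    )
  }

  t <- tables
  x_in <- t$relation == "phenotype_phenotype" & t$x_id %in% P
  y_in <- t$relation == "phenotype_phenotype" & t$y_id %in% P

  log <- list()
  note <- function(rows, action, new_relation = NA_character_, reason = NA_character_) {
    if (nrow(rows) == 0) {
      return(NULL)
    }
    tibble::tibble(
      original_x = rows$x_id, original_relation = rows$relation,
      original_y = rows$y_id, action = action,
      new_relation = new_relation, reason = reason
    )
  }

  # phenotype-phenotype: both endpoints in P -> disease_disease
  pp_both <- t[x_in & y_in, ]
  pp_both_new <- swap_endpoint_to_disease(pp_both, "x", pheno_to_disease)
  pp_both_new <- swap_endpoint_to_disease(pp_both_new, "y", pheno_to_disease)
  pp_both_new$relation <- "disease_disease"
  log$pp_both <- note(pp_both, "converted", "disease_disease")

  # phenotype-phenotype: one endpoint in P -> disease-phenotype
  pp_x <- t[x_in & !y_in, ]
  pp_x_new <- swap_endpoint_to_disease(pp_x, "x", pheno_to_disease)
  pp_x_new$relation <- "disease_phenotype_positive"
  log$pp_x <- note(pp_x, "converted", "disease_phenotype_positive")
  pp_y <- t[!x_in & y_in, ]
  pp_y_new <- swap_endpoint_to_disease(pp_y, "y", pheno_to_disease)
  # keep disease on the x side for the declared endpoint order
  pp_y_new <- pp_y_new[, names(t)]
  tmp <- pp_y_new
  pp_y_new[, c("x_id", "x_type", "x_name", "x_source")] <-
    tmp[, c("y_id", "y_type", "y_name", "y_source")]
  pp_y_new[, c("y_id", "y_type", "y_name", "y_source")] <-
    tmp[, c("x_id", "x_type", "x_name", "x_source")]
  pp_y_new$relation <- "disease_phenotype_positive"
  log$pp_y <- note(pp_y, "converted", "disease_phenotype_positive")

  # protein-phenotype with phenotype in P -> protein-disease
  prot_in <- t$relation == "phenotype_protein" & t$x_id %in% P
  pr <- t[prot_in, ]
  pr_new <- swap_endpoint_to_disease(pr, "x", pheno_to_disease)
  pr_new$relation <- "disease_protein"
  log$prot <- note(pr, "converted", "disease_protein")

  # disease-phenotype and drug-phenotype with phenotype in P -> dropped
  drop_rel <- c("disease_phenotype_positive", "disease_phenotype_negative", "drug_effect")
  drop_in <- t$relation %in% drop_rel & t$y_id %in% P
  dropped <- t[drop_in, ]
  log$dropped <- note(dropped, "dropped", reason = "phenotype_in_overlap_set")

  touched <- (x_in | y_in) | prot_in | drop_in
  out <- dplyr::bind_rows(
    t[!touched, ],
    pp_both_new, pp_x_new, pp_y_new, pr_new
  )
  log <- dplyr::bind_rows(log)
  if (is.null(log) || nrow(log) == 0) {
    log <- tibble::tibble(
      original_x = character(), original_relation = character(),
      original_y = character(), action = character(),
      new_relation = character(), reason = character()
    )
  }
  list(triples = out, log = log)
}
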