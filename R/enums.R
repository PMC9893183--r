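#' Node type vocabulary
#'
#' The ten admissible node type labels of the knowledge graph, stored verbatim
#' in the lowercase-with-slash convention of the deposited file format
#' (e.g. `"gene/protein"`, `"effect/phenotype"`).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' kg_node_types()
kg_node_types <- function() {
  c(
    "anatomy", "biological_process", "cellular_component", "disease",
    "drug", "effect/phenotype", "exposure", "gene/protein",
    "molecular_function", "pathway"
  )
}

#' Relation type registry
#'
#' The thirty admissible relation labels together with their declared endpoint
#' node types and a human-readable display name. Undirected semantics are
#' stored as two directed rows per edge, so an edge `(relation, x, y)` is valid
#' when `{x_type, y_type}` equals the declared endpoint pair in either order.
#'
#' @return A tibble with columns `relation`, `display_relation`, `type_a`,
#'   `type_b` (30 rows).
#' @export
#' @examples
#' kg_relation_types()
kg_relation_types <- function() {
  tibble::tribble(
    ~relation,                    ~display_relation,         ~type_a,              ~type_b,
    "anatomy_anatomy",            "parent-child",            "anatomy",            "anatomy",
    "anatomy_protein_absent",     "expression absent",       "anatomy",            "gene/protein",
    "anatomy_protein_present",    "expression present",      "anatomy",            "gene/protein",
    "bioprocess_bioprocess",      "parent-child",            "biological_process", "biological_process",
    "bioprocess_protein",         "interacts with",          "biological_process", "gene/protein",
    "cellcomp_cellcomp",          "parent-child",            "cellular_component", "cellular_component",
    "cellcomp_protein",           "interacts with",          "cellular_component", "gene/protein",
    "contraindication",           "contraindication",        "drug",               "disease",
    "disease_disease",            "parent-child",            "disease",            "disease",
    "disease_phenotype_negative", "phenotype absent",        "disease",            "effect/phenotype",
    "disease_phenotype_positive", "phenotype present",       "disease",            "effect/phenotype",
    "disease_protein",            "associated with",         "disease",            "gene/protein",
    "drug_drug",                  "synergistic interaction", "drug",               "drug",
    "drug_effect",                "side effect",             "drug",               "effect/phenotype",
    "drug_protein",               "target",                  "drug",               "gene/protein",
    "exposure_bioprocess",        "interacts with",          "exposure",           "biological_process",
    "exposure_cellcomp",          "interacts with",          "exposure",           "cellular_component",
    "exposure_disease",           "linked to",               "exposure",           "disease",
    "exposure_exposure",          "parent-child",            "exposure",           "exposure",
    "exposure_molfunc",           "interacts with",          "exposure",           "molecular_function",
    "exposure_protein",           "interacts with",          "exposure",           "gene/protein",
    "indication",                 "indication",              "drug",               "disease",
    "molfunc_molfunc",            "parent-child",            "molecular_function", "molecular_function",
    "molfunc_protein",            "interacts with",          "molecular_function", "gene/protein",
    "off-label use",              "off-label use",           "drug",               "disease",
    "pathway_pathway",            "parent-child",            "pathway",            "pathway",
    "pathway_protein",            "interacts with",          "pathway",            "gene/protein",
    "phenotype_phenotype",        "parent-child",            "effect/phenotype",   "effect/phenotype",
    "phenotype_protein",          "associated with",         "effect/phenotype",   "gene/protein",
    "protein_protein",            "ppi",                     "gene/protein",       "gene/protein"
  )
}

# Lookup of declared endpoint pair for one relation label; errors on unknown.
relation_endpoints <- function(relation) {
  reg <- kg_relation_types()
  hit <- reg[reg$relation == relation, ]
  if (nrow(hit) != 1) {
    rlang::abort(paste0("unknown relation label: '", relation, "'"),
      class = "kgcraft_schema_error"
    )
  }
  c(hit$type_a, hit$type_b)
}

# TRUE where the unordered endpoint-type pair matches the declaration.
endpoints_admissible <- function(relation, x_type, y_type) {
  reg <- kg_relation_types()
  idx <- match(relation, reg$relation)
  a <- reg$type_a[idx]
  b <- reg$type_b[idx]
  !is.na(idx) & ((x_type == a & y_type == b) | (x_type == b & y_type == a))
}
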