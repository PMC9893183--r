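#' The eleven Disorder-group semantic types
#'
#' Semantic types from the concept metathesaurus that belong to the Disorder
#' semantic group; concepts carrying at least one of these types are retained
#' as disorder concepts.
#'
#' @return Character vector of 11 lowercase semantic-type labels.
#' @export
umls_disorder_types <- function() {
  c(
    "congenital abnormality", "acquired abnormality", "injury or poisoning",
    "pathologic function", "disease or syndrome",
    "mental or behavioral dysfunction", "cell or molecular dysfunction",
    "experimental model of disease", "signs and symptoms",
    "anatomical abnormality", "neoplastic process"
  )
}

#' Ingest configuration
#'
#' Thresholds and selections applied by the resource adapters.
#'
#' @param bgee_fdr_max Maximum FDR-corrected p-value for an expression call to
#'   be kept (inclusive); default 0.01.
#' @param bgee_rank_max Expression-rank cutoff; calls are kept when
#'   `rank < bgee_rank_max` (strict); default 25000.
#' @param bgee_quality Quality label retained; default `"gold quality"`.
#' @param bgee_rank_applies_to_absent Whether the rank filter also applies to
#'   `absent` calls; default `TRUE` (all three filters uniform).
#' @param umls_semantic_types Semantic types whose concepts are retained;
#'   default the 11 Disorder-group types ([umls_disorder_types()]).
#' @param language Language code retained for concept atoms and definitions;
#'   default `"ENG"`.
#' @return A list of class `ingest_config`.
#' @export
ingest_config <- function(bgee_fdr_max = 0.01,
                          bgee_rank_max = 25000,
                          bgee_quality = "gold quality",
                          bgee_rank_applies_to_absent = TRUE,
                          umls_semantic_types = umls_disorder_types(),
                          language = "ENG") {
  stopifnot(bgee_fdr_max > 0, bgee_fdr_max < 1, bgee_rank_max > 0)
  structure(
    list(
      bgee_fdr_max = bgee_fdr_max,
      bgee_rank_max = bgee_rank_max,
      bgee_quality = bgee_quality,
      bgee_rank_applies_to_absent = bgee_rank_applies_to_absent,
      umls_semantic_types = tolower(umls_semantic_types),
      language = language
    ),
    class = "ingest_config"
  )
}

#' Filter gene-expression calls into anatomy-protein relations
#'
#' Retains gold-quality expression calls with FDR-corrected p-value at or below
#' the configured maximum and expression rank strictly below the configured
#' cutoff, and emits one anatomy-protein row per surviving call, labelled
#' `present` or `absent` according to the call column.
#'
#' @param table Data frame with columns `anatomy_id`, `gene_id`, `call`
#'   (`"present"`/`"absent"`), `quality`, `fdr`, `rank`. Optional
#'   `anatomy_name`, `gene_name`.
#' @param cfg An [ingest_config()].
#' @return A triples table of `anatomy_protein_present` / `_absent` rows with a
#'   drop log (see [drop_log()]).
#' @export
filter_expression_calls <- function(table, cfg = ingest_config()) {
  table <- tibble::as_tibble(table)
  fdr <- suppressWarnings(as.numeric(table$fdr))
  rank <- suppressWarnings(as.numeric(table$rank))
  non_numeric <- is.na(fdr) | is.na(rank)

  keep_quality <- !non_numeric & table$quality == cfg$bgee_quality
  keep_fdr <- keep_quality & fdr <= cfg$bgee_fdr_max
  rank_ok <- rank < cfg$bgee_rank_max
  if (!cfg$bgee_rank_applies_to_absent) {
    rank_ok <- rank_ok | table$call == "absent"
  }
  keep <- keep_fdr & rank_ok

  kept <- table[which(keep), ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$anatomy_id, x_type = "anatomy",
      x_name = if ("anatomy_name" %in% names(kept)) kept$anatomy_name else kept$anatomy_id,
      x_source = "UBERON",
      relation = ifelse(kept$call == "present",
        "anatomy_protein_present", "anatomy_protein_absent"
      ),
      y_id = as.character(kept$gene_id), y_type = "gene/protein",
      y_name = if ("gene_name" %in% names(kept)) kept$gene_name else as.character(kept$gene_id),
      y_source = "NCBI"
    ),
    resource = "expression_calls"
  )
  out <- add_drop_log(out, table[which(non_numeric), ], "non_numeric_fdr_or_rank")
  out <- add_drop_log(out, table[which(!non_numeric & !keep_quality), ], "quality")
  out <- add_drop_log(out, table[which(keep_quality & !keep_fdr), ], "fdr")
  add_drop_log(out, table[which(keep_fdr & !keep), ], "rank")
}

#' Select disorder concepts and their definitions
#'
#' From RRF-style concept, semantic-type, and definition tables, retains
#' concept atoms in the configured language, keeps concept identifiers whose
#' semantic type belongs to the configured Disorder-group set, and attaches
#' definitions from sources in the configured language.
#'
#' @param concept_rows Data frame with `cui`, `language`, `name`.
#' @param semtype_rows Data frame with `cui`, `semantic_type`.
#' @param def_rows Data frame with `cui`, `source`, `language`, `definition`.
#' @param cfg An [ingest_config()].
#' @return Tibble with `cui`, `name`, `definition` (one row per kept concept;
#'   multiple definitions collapse to distinct rows), plus a drop log.
#' @export
select_umls_disorders <- function(concept_rows, semtype_rows, def_rows,
                                  cfg = ingest_config()) {
  concept_rows <- tibble::as_tibble(concept_rows)
  eng <- concept_rows[concept_rows$language == cfg$language, ]
  disorder_cuis <- unique(
    semtype_rows$cui[tolower(semtype_rows$semantic_type) %in% cfg$umls_semantic_types]
  )
  kept <- eng[eng$cui %in% disorder_cuis, ]
  kept <- dplyr::distinct(kept, .data$cui, .keep_all = TRUE)

  defs <- tibble::as_tibble(def_rows)
  defs <- defs[defs$language == cfg$language, c("cui", "definition")]
  out <- dplyr::left_join(kept[, c("cui", "name")], dplyr::distinct(defs), by = "cui")
  out <- add_drop_log(
    out, concept_rows[concept_rows$language != cfg$language, ],
    "non_english"
  )
  add_drop_log(out, eng[!(eng$cui %in% disorder_cuis), ], "non_disorder_semantic_type")
}

#' Build an identifier cross-reference map
#'
#' @param df Data frame with columns `from` and `to` (and optionally `to_name`).
#' @param from_ns,to_ns Namespace labels recorded for contract checking.
#' @return A tibble of class `xref_map`.
#' @export
xref_map <- function(df, from_ns = NULL, to_ns = NULL) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("from", "to") %in% names(df)))
  out <- dplyr::distinct(df)
  attr(out, "from_ns") <- from_ns
  attr(out, "to_ns") <- to_ns
  class(out) <- c("xref_map", class(out))
  out
}

#' Map one endpoint of a triples table through a vocabulary
#'
#' Replaces identifiers on the `x` or `y` side with their mapped values.
#' One-to-many mappings expand to one row per target under the default
#' `"expand"` policy, or are dropped as ambiguous under `"drop"`. Unmapped
#' identifiers are always dropped and logged with reason `"unmapped"`.
#'
#' @param table A triples table.
#' @param vocab An [xref_map()].
#' @param side `"x"` or `"y"`.
#' @param policy `"expand"` (default) or `"drop"` for one-to-many mappings.
#' @param new_source,new_type Optional replacement source / node type for the
#'   mapped side.
#' @return A triples table with a drop log; expansions recorded in the
#'   `"expansions"` attribute with multiplicity.
#' @export
map_identifiers <- function(table, vocab, side = c("x", "y"),
                            policy = c("expand", "drop"),
                            new_source = NULL, new_type = NULL) {
  side <- match.arg(side)
  policy <- match.arg(policy)
  id_col <- paste0(side, "_id")
  src_col <- paste0(side, "_source")
  type_col <- paste0(side, "_type")

  from_ns <- attr(vocab, "from_ns")
  if (!is.null(from_ns) && nrow(table) > 0 &&
    !any(table[[src_col]] %in% from_ns)) {
    rlang::abort(
      paste0(
        "vocabulary maps namespace '", from_ns, "' but side '", side,
        "' carries: ", paste(unique(table[[src_col]]), collapse = ", ")
      ),
      class = "kgcraft_contract_error"
    )
  }

  mapped <- dplyr::inner_join(
    dplyr::mutate(table, .row = dplyr::row_number()),
    vocab,
    by = stats::setNames("from", id_col),
    relationship = "many-to-many"
  )
  unmapped <- table[!(table[[id_col]] %in% vocab$from), ]

  multiplicity <- dplyr::count(mapped, .data$.row, name = "n_targets")
  if (policy == "drop") {
    ambiguous_rows <- multiplicity$.row[multiplicity$n_targets > 1]
    dropped_amb <- table[ambiguous_rows, ]
    mapped <- mapped[!(mapped$.row %in% ambiguous_rows), ]
  } else {
    dropped_amb <- table[0, ]
  }

  mapped[[id_col]] <- as.character(mapped$to)
  if ("to_name" %in% names(mapped)) {
    mapped[[paste0(side, "_name")]] <- mapped$to_name
  }
  if (!is.null(new_source)) mapped[[src_col]] <- new_source
  if (!is.null(new_type)) mapped[[type_col]] <- new_type
  out <- mapped[, names(table)]
  out <- tibble::as_tibble(out)
  out <- add_drop_log(out, unmapped, "unmapped")
  if (policy == "drop") out <- add_drop_log(out, dropped_amb, "ambiguous")
  attr(out, "expansions") <- multiplicity[multiplicity$n_targets > 1, ]
  out
}

#' Union drug-protein partner tables
#'
#' Combines the target, enzyme, carrier, and transporter partner tables into
#' one `drug_protein` triples table with exact duplicates removed.
#'
#' @param targets,enzymes,carriers,transporters Triples tables in
#'   drug-by-protein space (relation `drug_protein`).
#' @return A deduplicated `drug_protein` triples table.
#' @export
merge_drug_protein_partners <- function(targets, enzymes, carriers, transporters) {
  all_tabs <- dplyr::bind_rows(targets, enzymes, carriers, transporters)
  if (nrow(all_tabs) > 0 && !all(all_tabs$relation == "drug_protein")) {
    rlang::abort("all partner tables must carry relation drug_protein",
      class = "kgcraft_contract_error"
    )
  }
  out <- dplyr::distinct(all_tabs, .data$x_id, .data$y_id, .keep_all = TRUE)
  out$resource <- "drug_protein_partners"
  out
}

#' Parse synergistic drug-drug interactions from an XML export
#'
#' Reads a drug knowledgebase XML dialect in which each `<drug>` element lists
#' interaction partners, and emits one undirected drug-drug pair per
#' interaction. Mirrored records (A lists B and B lists A) are deduplicated to
#' a single pair; symmetry is restored later at assembly.
#'
#' @param source Path to the XML file.
#' @return A `drug_drug` triples table with one row per unordered pair.
#' @export
parse_drug_interactions <- function(source) {
  doc <- xml2::read_xml(source)
  drugs <- xml2::xml_find_all(doc, ".//drug[drugbank-id]")
  rows <- purrr::map_dfr(drugs, function(d) {
    id <- xml2::xml_text(xml2::xml_find_first(d, "./drugbank-id"))
    nm <- xml2::xml_text(xml2::xml_find_first(d, "./name"))
    partners <- xml2::xml_find_all(d, "./drug-interactions/drug-interaction")
    if (length(partners) == 0) {
      return(tibble::tibble(
        x_id = character(), x_name = character(),
        y_id = character(), y_name = character()
      ))
    }
    tibble::tibble(
      x_id = id, x_name = nm,
      y_id = purrr::map_chr(partners, ~ xml2::xml_text(xml2::xml_find_first(.x, "./drugbank-id"))),
      y_name = purrr::map_chr(partners, ~ xml2::xml_text(xml2::xml_find_first(.x, "./name")))
    )
  })
  if (nrow(rows) > 0) {
    swap <- rows$x_id > rows$y_id
    rows[swap, c("x_id", "y_id", "x_name", "y_name")] <-
      rows[swap, c("y_id", "x_id", "y_name", "x_name")]
    rows <- dplyr::distinct(rows, .data$x_id, .data$y_id, .keep_all = TRUE)
  }
  triples_table(
    tibble::tibble(
      x_id = rows$x_id, x_type = "drug", x_name = rows$x_name, x_source = "DrugBank",
      relation = "drug_drug",
      y_id = rows$y_id, y_type = "drug", y_name = rows$y_name, y_source = "DrugBank"
    ),
    resource = "drug_interactions"
  )
}

#' Filter side-effect records to preferred-term level and map drugs
#'
#' Keeps adverse-event rows coded at the preferred term level, then maps drug
#' identifiers through the two-step chain (compound identifier to ATC class,
#' ATC class to drug accession) and emits drug-phenotype (`drug_effect`) rows.
#' Rows with a broken mapping chain are dropped with a reason.
#'
#' @param table Data frame with `drug_stitch_id`, `meddra_level`,
#'   `phenotype_id` and optionally `phenotype_name`.
#' @param stitch_to_atc,atc_to_drug [xref_map()]s for the two mapping steps.
#' @param preferred_level Label of the preferred term level (default `"PT"`).
#' @return A `drug_effect` triples table with a drop log.
#' @export
filter_side_effects <- function(table, stitch_to_atc, atc_to_drug,
                                preferred_level = "PT") {
  table <- tibble::as_tibble(table)
  pt <- table[table$meddra_level == preferred_level, ]
  dropped_level <- table[table$meddra_level != preferred_level, ]

  step1 <- dplyr::inner_join(pt, stitch_to_atc,
    by = c(drug_stitch_id = "from"),
    relationship = "many-to-many"
  )
  broken1 <- pt[!(pt$drug_stitch_id %in% stitch_to_atc$from), ]
  names(step1)[names(step1) == "to"] <- "atc"
  step1$to_name <- NULL
  step2 <- dplyr::inner_join(step1, atc_to_drug,
    by = c(atc = "from"),
    relationship = "many-to-many"
  )
  broken2 <- step1[!(step1$atc %in% atc_to_drug$from), names(pt)]

  out <- triples_table(
    tibble::tibble(
      x_id = step2$to, x_type = "drug",
      x_name = if ("to_name" %in% names(step2)) step2$to_name else step2$to,
      x_source = "DrugBank",
      relation = "drug_effect",
      y_id = step2$phenotype_id, y_type = "effect/phenotype",
      y_name = if ("phenotype_name" %in% names(step2)) step2$phenotype_name else step2$phenotype_id,
      y_source = "HPO"
    ),
    resource = "side_effects"
  )
  out <- dplyr::distinct(out, .data$x_id, .data$y_id, .keep_all = TRUE)
  out <- add_drop_log(out, dropped_level, "not_preferred_term")
  out <- add_drop_log(out, broken1, "unmapped_to_atc")
  add_drop_log(out, dplyr::distinct(broken2), "unmapped_to_drug")
}

#' Gene-disease and gene-phenotype association adapter
#'
#' Thin adapter: rows whose subject identifier is in the disease namespace
#' become `disease_protein` rows; rows in the phenotype namespace become
#' `phenotype_protein` rows.
#'
#' @param table Data frame with `gene_id`, `id`, and optionally `gene_name`,
#'   `name`.
#' @param disease_prefix,phenotype_prefix CURIE prefixes distinguishing the two
#'   namespaces.
#' @return A triples table with a drop log for unrecognized namespaces.
#' @export
ingest_gene_disease <- function(table, disease_prefix = "MONDO:",
                                phenotype_prefix = "HP:") {
  table <- tibble::as_tibble(table)
  is_dis <- startsWith(table$id, disease_prefix)
  is_phe <- startsWith(table$id, phenotype_prefix)
  kept <- table[is_dis | is_phe, ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$id,
      x_type = ifelse(startsWith(kept$id, disease_prefix), "disease", "effect/phenotype"),
      x_name = if ("name" %in% names(kept)) kept$name else kept$id,
      x_source = ifelse(startsWith(kept$id, disease_prefix), "MONDO", "HPO"),
      relation = ifelse(startsWith(kept$id, disease_prefix),
        "disease_protein", "phenotype_protein"
      ),
      y_id = as.character(kept$gene_id), y_type = "gene/protein",
      y_name = if ("gene_name" %in% names(kept)) kept$gene_name else as.character(kept$gene_id),
      y_source = "NCBI"
    ),
    resource = "gene_disease"
  )
  add_drop_log(out, table[!(is_dis | is_phe), ], "unrecognized_namespace")
}

#' Drug-disease label adapter
#'
#' Emits indication, contraindication, and off-label use rows from an exported
#' relation table.
#'
#' @param table Data frame with `drug_id`, `disease_id`, `label` (one of
#'   `"indication"`, `"contraindication"`, `"off-label use"`), optionally
#'   `drug_name`, `disease_name`.
#' @param drug_source,disease_source Source labels for the endpoints.
#' @return A triples table with a drop log for unknown labels.
#' @export
ingest_drug_disease_labels <- function(table, drug_source = "DrugBank",
                                       disease_source = "MONDO") {
  table <- tibble::as_tibble(table)
  ok <- table$label %in% c("indication", "contraindication", "off-label use")
  kept <- table[ok, ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$drug_id, x_type = "drug",
      x_name = if ("drug_name" %in% names(kept)) kept$drug_name else kept$drug_id,
      x_source = drug_source,
      relation = kept$label,
      y_id = kept$disease_id, y_type = "disease",
      y_name = if ("disease_name" %in% names(kept)) kept$disease_name else kept$disease_id,
      y_source = disease_source
    ),
    resource = "drug_disease_labels"
  )
  add_drop_log(out, table[!ok, ], "unknown_label")
}

#' Protein-protein interaction union adapter
#'
#' Treats all sources as unweighted and undirected; deduplicates on unordered
#' gene pairs across sources.
#'
#' @param ... Data frames with columns `gene_a`, `gene_b`.
#' @return A `protein_protein` triples table, one row per unordered pair.
#' @export
ingest_ppi <- function(...) {
  tabs <- dplyr::bind_rows(lapply(list(...), tibble::as_tibble))
  tabs$gene_a <- as.character(tabs$gene_a)
  tabs$gene_b <- as.character(tabs$gene_b)
  swap <- tabs$gene_a > tabs$gene_b
  tabs[swap, c("gene_a", "gene_b")] <- tabs[swap, c("gene_b", "gene_a")]
  tabs <- dplyr::distinct(tabs, .data$gene_a, .data$gene_b)
  tabs <- tabs[tabs$gene_a != tabs$gene_b, ]
  triples_table(
    tibble::tibble(
      x_id = tabs$gene_a, x_type = "gene/protein", x_source = "NCBI",
      relation = "protein_protein",
      y_id = tabs$gene_b, y_type = "gene/protein", y_source = "NCBI"
    ),
    resource = "ppi"
  )
}

#' Exposure association adapter
#'
#' @param table Data frame with `exposure_id`, `partner_id`, `partner_type`
#'   (a node type label), optionally `exposure_name`, `partner_name`,
#'   `partner_source`.
#' @return A triples table of `exposure_*` rows; rows with partner types
#'   outside the six admissible ones are dropped and logged.
#' @export
ingest_exposures <- function(table) {
  table <- tibble::as_tibble(table)
  rel_of <- c(
    "exposure" = "exposure_exposure",
    "gene/protein" = "exposure_protein",
    "disease" = "exposure_disease",
    "biological_process" = "exposure_bioprocess",
    "molecular_function" = "exposure_molfunc",
    "cellular_component" = "exposure_cellcomp"
  )
  ok <- table$partner_type %in% names(rel_of)
  kept <- table[ok, ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$exposure_id, x_type = "exposure",
      x_name = if ("exposure_name" %in% names(kept)) kept$exposure_name else kept$exposure_id,
      x_source = "CTD",
      relation = unname(rel_of[kept$partner_type]),
      y_id = kept$partner_id, y_type = kept$partner_type,
      y_name = if ("partner_name" %in% names(kept)) kept$partner_name else kept$partner_id,
      y_source = if ("partner_source" %in% names(kept)) kept$partner_source else "CTD"
    ),
    resource = "exposures"
  )
  add_drop_log(out, table[!ok, ], "unknown_partner_type")
}

#' Gene-to-ontology-term annotation adapter
#'
#' @param table Data frame with `gene_id`, `go_id`, `go_type` (one of the three
#'   gene-function node types), optionally `gene_name`, `go_name`.
#' @return A triples table of `bioprocess_protein` / `molfunc_protein` /
#'   `cellcomp_protein` rows.
#' @export
ingest_gene_annotations <- function(table) {
  table <- tibble::as_tibble(table)
  rel_of <- c(
    "biological_process" = "bioprocess_protein",
    "molecular_function" = "molfunc_protein",
    "cellular_component" = "cellcomp_protein"
  )
  ok <- table$go_type %in% names(rel_of)
  kept <- table[ok, ]
  out <- triples_table(
    tibble::tibble(
      x_id = kept$go_id, x_type = kept$go_type,
      x_name = if ("go_name" %in% names(kept)) kept$go_name else kept$go_id,
      x_source = "GO",
      relation = unname(rel_of[kept$go_type]),
      y_id = as.character(kept$gene_id), y_type = "gene/protein",
      y_name = if ("gene_name" %in% names(kept)) kept$gene_name else as.character(kept$gene_id),
      y_source = "NCBI"
    ),
    resource = "gene_annotations"
  )
  add_drop_log(out, table[!ok, ], "unknown_go_type")
}

#' Pathway hierarchy and membership adapter
#'
#' @param relations Data frame with `child_id`, `parent_id` (pathway-pathway
#'   hierarchy), optionally names.
#' @param memberships Data frame with `gene_id`, `pathway_id`, optionally
#'   `pathway_name`, `gene_name`.
#' @return A triples table of `pathway_pathway` and `pathway_protein` rows.
#' @export
ingest_pathways <- function(relations, memberships) {
  relations <- tibble::as_tibble(relations)
  memberships <- tibble::as_tibble(memberships)
  hier <- triples_table(
    tibble::tibble(
      x_id = relations$child_id, x_type = "pathway",
      x_name = if ("child_name" %in% names(relations)) relations$child_name else relations$child_id,
      x_source = "REACTOME",
      relation = "pathway_pathway",
      y_id = relations$parent_id, y_type = "pathway",
      y_name = if ("parent_name" %in% names(relations)) relations$parent_name else relations$parent_id,
      y_source = "REACTOME"
    ),
    resource = "pathways"
  )
  memb <- triples_table(
    tibble::tibble(
      x_id = memberships$pathway_id, x_type = "pathway",
      x_name = if ("pathway_name" %in% names(memberships)) memberships$pathway_name else memberships$pathway_id,
      x_source = "REACTOME",
      relation = "pathway_protein",
      y_id = as.character(memberships$gene_id), y_type = "gene/protein",
      y_name = if ("gene_name" %in% names(memberships)) memberships$gene_name else as.character(memberships$gene_id),
      y_source = "NCBI"
    ),
    resource = "pathways"
  )
  dplyr::bind_rows(hier, memb)
}

#' Disease-phenotype annotation adapter
#'
#' @param table Data frame with `disease_id`, `phenotype_id`, `qualifier`
#'   (`""` for a positive association, `"NOT"` for a negative one), optionally
#'   names.
#' @return A triples table of `disease_phenotype_positive` / `_negative` rows.
#' @export
ingest_disease_phenotypes <- function(table) {
  table <- tibble::as_tibble(table)
  table$qualifier[is.na(table$qualifier)] <- ""
  triples_table(
    tibble::tibble(
      x_id = table$disease_id, x_type = "disease",
      x_name = if ("disease_name" %in% names(table)) table$disease_name else table$disease_id,
      x_source = "MONDO",
      relation = ifelse(table$qualifier == "NOT",
        "disease_phenotype_negative", "disease_phenotype_positive"
      ),
      y_id = table$phenotype_id, y_type = "effect/phenotype",
      y_name = if ("phenotype_name" %in% names(table)) table$phenotype_name else table$phenotype_id,
      y_source = "HPO"
    ),
    resource = "disease_phenotypes"
  )
}
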