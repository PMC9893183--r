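#' Build a knowledge graph from a resource bundle
#'
#' Runs the full construction pipeline on a bundle directory in the layout of
#' [make_mock_resources()]: parse the ontologies, run every resource adapter
#' with its stated filters and identifier mappings, resolve the
#' phenotype/disease overlap by edge rewiring, group disease entities, and
#' assemble the graph (clean, index, extract the largest connected component).
#'
#' @param dir Bundle directory.
#' @param grouping_cfg A [grouping_config()].
#' @param ingest_cfg An [ingest_config()].
#' @param embedder Name embedder for the grouping refinement stage.
#' @param review Optional review tibble for grouping proposals.
#' @return A list with `kg_raw`, `kg_giant`, `report` (assembly report),
#'   `overlap` (overlap set), `rewire_log`, `grouping`, `proposals`, and
#'   `tables` (the harmonized pre-assembly triples).
#' @export
build_kg_from_bundle <- function(dir,
                                 grouping_cfg = grouping_config(),
                                 ingest_cfg = ingest_config(),
                                 embedder = trigram_embedder(),
                                 review = NULL) {
  p <- function(f) file.path(dir, f)
  read_tsv_q <- function(f) readr::read_tsv(p(f), show_col_types = FALSE, progress = FALSE)
  read_csv_q <- function(f) readr::read_csv(p(f), show_col_types = FALSE, progress = FALSE)

  mondo <- parse_obo(p("disease.obo"))
  hp <- parse_obo(p("phenotype.obo"))
  uberon <- parse_obo(p("anatomy.obo"))
  go <- list(
    biological_process = parse_obo(p("go_bi.obo")),
    molecular_function = parse_obo(p("go_mo.obo")),
    cellular_component = parse_obo(p("go_ce.obo"))
  )

  uniprot2gene <- xref_map(read_tsv_q("vocab_uniprot2gene.tsv"), from_ns = "UniProt", to_ns = "NCBI")
  cas2drug <- xref_map(read_tsv_q("vocab_cas2drug.tsv"), from_ns = "CAS", to_ns = "DrugBank")
  stitch2atc <- xref_map(read_tsv_q("vocab_stitch2atc.tsv"))
  atc2drug <- xref_map(read_tsv_q("vocab_atc2drug.tsv"))

  go_rel <- c(
    biological_process = "bioprocess_bioprocess",
    molecular_function = "molfunc_molfunc",
    cellular_component = "cellcomp_cellcomp"
  )
  tables <- list(
    disease_hierarchy = ontology_to_triples(mondo, "disease_disease", "disease", "MONDO"),
    phenotype_hierarchy = ontology_to_triples(hp, "phenotype_phenotype", "effect/phenotype", "HPO"),
    anatomy_hierarchy = ontology_to_triples(uberon, "anatomy_anatomy", "anatomy", "UBERON"),
    expression = filter_expression_calls(read_tsv_q("expression_calls.tsv"), ingest_cfg),
    gene_disease = ingest_gene_disease(read_tsv_q("gene_disease.tsv")),
    disease_phenotypes = ingest_disease_phenotypes(read_tsv_q("disease_phenotypes.tsv")),
    ppi = ingest_ppi(read_tsv_q("ppi_source1.tsv"), read_tsv_q("ppi_source2.tsv")),
    drug_interactions = parse_drug_interactions(p("drugs.xml")),
    side_effects = filter_side_effects(
      read_tsv_q("side_effects.tsv"), stitch2atc, atc2drug
    ),
    exposures = ingest_exposures(read_csv_q("exposures.csv")),
    gene2go = ingest_gene_annotations(read_tsv_q("gene2go.tsv")),
    pathways = ingest_pathways(
      read_tsv_q("pathway_relations.tsv"), read_tsv_q("pathway_members.tsv")
    )
  )
  for (ns in names(go)) {
    tables[[paste0("go_", ns)]] <- ontology_to_triples(go[[ns]], go_rel[[ns]], ns, "GO")
  }

  # drug-disease labels arrive keyed by CAS registry number
  labels <- ingest_drug_disease_labels(
    dplyr::rename(read_csv_q("drug_disease.csv"), drug_id = "cas_id"),
    drug_source = "CAS"
  )
  tables$drug_disease <- map_identifiers(labels, cas2drug,
    side = "x",
    new_source = "DrugBank"
  )

  # drug-protein partners: four files in UniProt space, mapped then unioned
  partner_files <- paste0("partners_", c("targets", "enzymes", "carriers", "transporters"), ".csv")
  partners <- lapply(partner_files, function(f) {
    raw <- read_csv_q(f)
    t <- triples_table(
      tibble::tibble(
        x_id = raw$drug_id, x_type = "drug", x_source = "DrugBank",
        relation = "drug_protein",
        y_id = raw$uniprot_id, y_type = "gene/protein", y_source = "UniProt"
      ),
      resource = sub("\\.csv$", "", f)
    )
    map_identifiers(t, uniprot2gene, side = "y", new_source = "NCBI")
  })
  tables$drug_protein <- do.call(merge_drug_protein_partners, partners)

  combined <- dplyr::bind_rows(tables)
  overlap <- compute_overlap_set(hp, mondo)
  p2d <- overlap_disease_map(overlap, mondo)
  rewired <- rewire_edges(combined, overlap, p2d)

  disease_names <- mondo$terms[!mondo$terms$is_obsolete, ]
  grouped <- group_diseases(
    tibble::tibble(disease_id = disease_names$id, name = disease_names$name),
    cfg = grouping_cfg, embedder = embedder, review = review
  )
  final_tables <- apply_grouping(rewired$triples, grouped$grouping)

  built <- assemble_kg(list(final_tables), provenance = list(bundle = dir))
  c(built, list(
    overlap = overlap, rewire_log = rewired$log,
    grouping = grouped$grouping, proposals = grouped$proposals,
    tables = final_tables
  ))
}

#' Attach clinical features from a bundle to a built graph
#'
#' Processes the drug and disease feature files of a bundle (reference-token
#' cleaning, half-life nullification, numeric-to-text rendering, symptom
#' splitting, name matching) and attaches them to the nodes of a built graph.
#'
#' @param dir Bundle directory.
#' @param kg A `kg` object built from the same bundle.
#' @param grouping The `disease_grouping` used in the build.
#' @param ingest_cfg An [ingest_config()] (language selection for concept
#'   definitions).
#' @return As [attach_features()], with drug text features cleaned and numeric
#'   descriptors rendered to sentences.
#' @export
build_clinical_features <- function(dir, kg, grouping,
                                    ingest_cfg = ingest_config()) {
  p <- function(f) file.path(dir, f)
  read_csv_q <- function(f) readr::read_csv(p(f), show_col_types = FALSE, progress = FALSE)
  mondo <- parse_obo(p("disease.obo"))
  cas2drug <- xref_map(
    readr::read_tsv(p("vocab_cas2drug.tsv"), show_col_types = FALSE, progress = FALSE)
  )

  feats <- read_csv_q("drug_features.csv")
  feats$description <- clean_reference_tokens(feats$description)
  feats$half_life <- normalize_half_life(feats$half_life)
  num <- read_csv_q("drugcentral_numeric.csv")
  num$drug_id <- cas2drug$to[match(num$cas_id, cas2drug$from)]
  num <- num[!is.na(num$drug_id), ]
  drug_name <- stats::setNames(
    kg$nodes$node_name[kg$nodes$node_type == "drug"],
    kg$nodes$node_id[kg$nodes$node_type == "drug"]
  )
  num$molecular_weight_text <- vapply(seq_len(nrow(num)), function(i) {
    numeric_to_text(
      drug_name[num$drug_id[i]] %||% num$drug_id[i],
      "molecular_weight", num$molecular_weight[i]
    )
  }, character(1))
  num$tpsa_text <- vapply(seq_len(nrow(num)), function(i) {
    numeric_to_text(drug_name[num$drug_id[i]] %||% num$drug_id[i], "tpsa", num$tpsa[i])
  }, character(1))
  num$clogp_text <- vapply(seq_len(nrow(num)), function(i) {
    numeric_to_text(drug_name[num$drug_id[i]] %||% num$drug_id[i], "clogp", num$clogp[i])
  }, character(1))
  drug_records <- dplyr::left_join(
    feats, num[, c("drug_id", "molecular_weight_text", "tpsa_text", "clogp_text")],
    by = "drug_id"
  )

  # disease records: ontology definitions, concept descriptions via
  # cross-references, rare-disease registry features via cross-references,
  # and name-matched synthetic clinic features
  defs <- mondo$terms[!is.na(mondo$terms$definition), ]
  disease_records <- tibble::tibble(
    disease_id = defs$id, feature = "ontology_definition", value = defs$definition
  )

  conso <- readr::read_delim(p("concepts.rrf"), delim = "|", show_col_types = FALSE, progress = FALSE)
  sty <- readr::read_delim(p("semantic_types.rrf"), delim = "|", show_col_types = FALSE, progress = FALSE)
  mrdef <- readr::read_delim(p("definitions.rrf"), delim = "|", show_col_types = FALSE, progress = FALSE)
  disorders <- select_umls_disorders(conso, sty, mrdef, ingest_cfg)
  cui_xr <- mondo$xrefs[mondo$xrefs$foreign_namespace == "UMLS", ]
  umls_rec <- dplyr::inner_join(
    disorders,
    tibble::tibble(cui = sub("^UMLS:C", "C", cui_xr$foreign_id), disease_id = cui_xr$term_id),
    by = "cui"
  )
  disease_records <- dplyr::bind_rows(
    disease_records,
    tibble::tibble(
      disease_id = umls_rec$disease_id, feature = "concept_description",
      value = umls_rec$definition
    )
  )

  orpha <- read_csv_q("orphanet_synthetic.csv")
  orpha_xr <- mondo$xrefs[mondo$xrefs$foreign_namespace == "Orphanet", ]
  orpha$disease_id <- orpha_xr$term_id[match(orpha$orpha_id, orpha_xr$foreign_id)]
  orpha_long <- tidyr::pivot_longer(
    orpha[!is.na(orpha$disease_id), setdiff(names(orpha), "orpha_id")],
    -"disease_id",
    names_to = "feature", values_to = "value"
  )
  disease_records <- dplyr::bind_rows(
    disease_records,
    dplyr::mutate(orpha_long, feature = paste0("orphanet_", .data$feature))
  )

  mayo <- read_csv_q("mayo_synthetic.csv")
  dis_nodes <- kg$nodes[kg$nodes$node_type == "disease", ]
  matched <- match_disease_names(
    mayo$name,
    stats::setNames(dis_nodes$node_name, dis_nodes$node_id)
  )
  mayo <- dplyr::inner_join(mayo, matched$mapping, by = c(name = "source_name"))
  split <- lapply(mayo$symptoms, split_when_to_see_doctor)
  mayo$symptoms <- vapply(split, `[[`, character(1), "symptoms")
  mayo$when_to_see_doctor <- vapply(split, `[[`, character(1), "when_to_see_doctor")
  mayo_long <- tidyr::pivot_longer(
    mayo[, c(
      "target_id", "symptoms", "causes", "risk_factors", "complications",
      "prevention", "when_to_see_doctor"
    )],
    -"target_id",
    names_to = "feature", values_to = "value"
  )
  # clinic features are matched against grouped node names, so they key
  # directly by node_id (already in final identifier space)
  mayo_records <- tibble::tibble(
    disease_id = mayo_long$target_id,
    feature = paste0("clinic_", mayo_long$feature), value = mayo_long$value
  )

  out <- attach_features(kg, drug_records, disease_records, grouping = grouping)
  dis_direct <- dplyr::inner_join(
    dis_nodes[, c("node_index", "node_id")], mayo_records,
    by = c(node_id = "disease_id")
  )
  dis_direct$member_id <- dis_direct$node_id
  out$disease_features <- dplyr::bind_rows(out$disease_features, dis_direct)
  out
}

#' Bar chart of graph composition
#'
#' Node counts by node type and directed edge-row counts by relation type.
#'
#' @param kg A `kg` object.
#' @return A ggplot object (two facets).
#' @export
plot_kg_composition <- function(kg) {
  df <- dplyr::bind_rows(
    dplyr::count(kg$nodes, label = .data$node_type) |>
      dplyr::mutate(panel = "nodes by type"),
    dplyr::count(kg$edges, label = .data$relation) |>
      dplyr::mutate(panel = "directed edge rows by relation")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = stats::reorder(.data$label, .data$n))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}
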