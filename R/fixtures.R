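#' Fixture specification
#'
#' Controls the miniature synthetic resource bundle: entity counts, the
#' planted disease subtype families, the planted phenotype/disease overlap
#' fraction, and per-resource row counts with planted survivor counts.
#'
#' @param rng_seed Integer seed; the bundle is byte-identical for a fixed
#'   seed and spec.
#' @param n_subtype_families Number of planted disease subtype families.
#' @param family_size_range Inclusive range of members per family.
#' @param n_distractor_diseases Singleton disease names with no subtype
#'   structure.
#' @param n_phenotypes Number of phenotype terms.
#' @param overlap_fraction Fraction of phenotype terms planted into the
#'   phenotype/disease overlap set (half by shared numeric id, half by
#'   cross-reference).
#' @param n_proteins,n_drugs,n_anatomy,n_exposures,n_pathways,n_go_terms
#'   Entity counts (GO terms per namespace).
#' @param n_expression_rows,n_expression_pass Expression-call rows and planted
#'   filter survivors.
#' @param n_side_effect_rows,n_side_effect_pass Side-effect rows and planted
#'   survivors of the preferred-term filter plus mapping chain.
#' @param n_drug_interactions Planted unordered drug-drug interaction pairs.
#' @param n_umls_concepts,n_umls_disorders Concept rows and planted
#'   Disorder-group survivors.
#' @param isolated_pocket Whether to plant a small disconnected disease pocket
#'   (excluded from the giant component by construction).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 42,
                         n_subtype_families = 40,
                         family_size_range = c(3, 8),
                         n_distractor_diseases = 100,
                         n_phenotypes = 60,
                         overlap_fraction = 0.2,
                         n_proteins = 60,
                         n_drugs = 25,
                         n_anatomy = 20,
                         n_exposures = 10,
                         n_pathways = 12,
                         n_go_terms = 8,
                         n_expression_rows = 100,
                         n_expression_pass = 37,
                         n_side_effect_rows = 12,
                         n_side_effect_pass = 5,
                         n_drug_interactions = 9,
                         n_umls_concepts = 20,
                         n_umls_disorders = 8,
                         isolated_pocket = TRUE) {
  stopifnot(
    overlap_fraction >= 0, overlap_fraction <= 1,
    n_expression_pass <= n_expression_rows,
    n_side_effect_pass <= n_side_effect_rows,
    n_umls_disorders <= n_umls_concepts
  )
  structure(as.list(environment()), class = "fixture_spec")
}

# Deterministic pseudo-Latin word pools. Families, distractors and phenotypes
# draw from disjoint syllable pools so accidental cross-matches are impossible.
fixture_words <- function(syllables, n) {
  combos <- expand.grid(a = syllables, b = syllables, stringsAsFactors = FALSE)
  words <- unique(paste0(combos$a, combos$b))
  if (n > length(words)) {
    combos3 <- expand.grid(
      a = syllables, b = syllables, c = syllables,
      stringsAsFactors = FALSE
    )
    words <- unique(c(words, paste0(combos3$a, combos3$b, combos3$c)))
  }
  stopifnot(n <= length(words))
  words[seq_len(n)]
}

family_word_pool <- function(n) {
  fixture_words(c("vex", "dor", "lum", "pha", "crin", "tor"), n)
}
distractor_word_pool <- function(n) {
  fixture_words(c("bli", "gron", "sek", "mur", "zap", "quel"), n)
}
phenotype_word_pool <- function(n) {
  fixture_words(c("hyp", "ost", "nev", "card", "derm", "alg"), n)
}

pad_id <- function(prefix, num, width = 7) {
  sprintf("%s%0*d", prefix, width, num)
}

# --- entity frame ------------------------------------------------------------

# All entity identifiers and names, plus planted grouping / overlap truth.
# Everything downstream (OBO files, resource tables) is derived from this.
fixture_entities <- function(spec) {
  set.seed(spec$rng_seed)

  # disease subtype families
  n_fam <- spec$n_subtype_families
  bases <- paste(
    family_word_pool(n_fam),
    rep(c("syndrome", "deficiency", "dystrophy", "malformation"), length.out = n_fam)
  )
  size_choices <- seq(spec$family_size_range[1], spec$family_size_range[2])
  fam_sizes <- size_choices[sample.int(length(size_choices), n_fam, replace = TRUE)]
  patterns <- sample(c("arabic", "roman", "susceptibility"), n_fam, replace = TRUE)
  fam_members <- purrr::map_dfr(seq_len(n_fam), function(i) {
    k <- fam_sizes[i]
    nm <- switch(patterns[i],
      arabic = paste0(bases[i], " type ", seq_len(k)),
      roman = paste0(bases[i], " type ", as.character(utils::as.roman(seq_len(k)))),
      susceptibility = paste0(bases[i], ", susceptibility to, ", seq_len(k))
    )
    tibble::tibble(name = nm, family = paste0("family_", i))
  })

  distractors <- tibble::tibble(
    name = paste(
      distractor_word_pool(spec$n_distractor_diseases),
      rep(c("disease", "disorder", "anomaly", "fever"),
        length.out = spec$n_distractor_diseases
      )
    ),
    family = paste0("singleton_", seq_len(spec$n_distractor_diseases))
  )

  diseases <- dplyr::bind_rows(fam_members, distractors)
  diseases$id <- pad_id("MONDO:", 5000000 + seq_len(nrow(diseases)))

  pocket <- tibble::tibble(
    name = c("pocket condition alpha", "pocket condition beta"),
    family = c("pocket_1", "pocket_2"),
    id = pad_id("MONDO:", c(8888881, 8888882))
  )

  phen_words <- phenotype_word_pool(spec$n_phenotypes)
  phenotypes <- tibble::tibble(
    name = paste(phen_words, rep(c("atrophy", "pain", "rigidity", "edema"),
      length.out = spec$n_phenotypes
    )),
    id = pad_id("HP:", 4000000 + seq_len(spec$n_phenotypes))
  )

  # planted overlap: first half of members share the numeric suffix of a
  # distractor disease; second half are cross-referenced from one
  n_overlap <- floor(spec$overlap_fraction * spec$n_phenotypes)
  n_same <- ceiling(n_overlap / 2)
  overlap_idx <- seq_len(n_overlap)
  dis_idx <- nrow(fam_members) + seq_len(n_overlap) # distractor rows
  phenotypes$id[overlap_idx[seq_len(n_same)]] <-
    sub("^MONDO:", "HP:", diseases$id[dis_idx[seq_len(n_same)]])
  overlap <- tibble::tibble(
    phenotype_id = phenotypes$id[overlap_idx],
    disease_id = diseases$id[dis_idx],
    evidence = c(
      rep("same-numeric-id", n_same),
      rep("xref-mapped", n_overlap - n_same)
    )
  )

  genes <- tibble::tibble(
    id = as.character(1000 + seq_len(spec$n_proteins)),
    name = paste0("GN", seq_len(spec$n_proteins))
  )
  genes$uniprot <- sprintf("P%05d", 10000 + seq_len(spec$n_proteins))
  drugs <- tibble::tibble(
    id = sprintf("DB%05d", seq_len(spec$n_drugs)),
    name = paste0(
      fixture_words(c("pra", "zol", "mib", "stat", "vir", "mab"), spec$n_drugs),
      "umab"
    )
  )
  drugs$cas <- sprintf("%04d-%02d-%d", 1000 + seq_len(spec$n_drugs), 11, 5)
  drugs$stitch <- sprintf("CID%09d", seq_len(spec$n_drugs))
  drugs$atc <- sprintf("L%02dAB%02d", seq_len(spec$n_drugs) %% 9 + 1, seq_len(spec$n_drugs))

  list(
    diseases = diseases, pocket = pocket, phenotypes = phenotypes,
    overlap = overlap, genes = genes, drugs = drugs,
    anatomy = tibble::tibble(
      id = pad_id("UBERON:", seq_len(spec$n_anatomy)),
      name = paste0("anatomy part ", seq_len(spec$n_anatomy))
    ),
    exposures = tibble::tibble(
      id = sprintf("D%06d", seq_len(spec$n_exposures)),
      name = paste0("exposure agent ", seq_len(spec$n_exposures))
    ),
    pathways = tibble::tibble(
      id = sprintf("R-HSA-%04d", seq_len(spec$n_pathways)),
      name = paste0("pathway ", seq_len(spec$n_pathways))
    ),
    go = tibble::tibble(
      id = pad_id("GO:", seq_len(3 * spec$n_go_terms)),
      name = paste0("go term ", seq_len(3 * spec$n_go_terms)),
      namespace = rep(
        c("biological_process", "molecular_function", "cellular_component"),
        each = spec$n_go_terms
      )
    )
  )
}

# --- OBO writers -------------------------------------------------------------

write_obo <- function(path, terms, edges, xrefs = NULL, header = "format-version: 1.2") {
  lines <- c(header, "")
  for (i in seq_len(nrow(terms))) {
    lines <- c(lines, "[Term]", paste0("id: ", terms$id[i]), paste0("name: ", terms$name[i]))
    if ("definition" %in% names(terms) && !is.na(terms$definition[i])) {
      lines <- c(lines, paste0('def: "', terms$definition[i], '" []'))
    }
    par <- edges$parent_id[edges$child_id == terms$id[i]]
    lines <- c(lines, paste0("is_a: ", par))
    if (!is.null(xrefs)) {
      xr <- xrefs$foreign_id[xrefs$term_id == terms$id[i]]
      lines <- c(lines, paste0("xref: ", xr))
    }
    lines <- c(lines, "")
  }
  readr::write_lines(lines, path)
}

# Random tree over ids: each term's parent drawn among earlier terms.
tree_edges <- function(ids) {
  if (length(ids) < 2) {
    return(tibble::tibble(child_id = character(), parent_id = character()))
  }
  parent <- ids[vapply(
    seq_along(ids)[-1],
    function(i) sample.int(i - 1L, 1L), integer(1)
  )]
  tibble::tibble(child_id = ids[-1], parent_id = parent)
}

#' Generate mock disease and phenotype ontologies
#'
#' Writes a disease ontology with planted subtype families (named by the
#' subtype patterns the grouping stage targets) plus singleton distractors,
#' and a phenotype ontology in which a planted fraction of terms overlap the
#' disease namespace by shared numeric identifier or by cross-reference.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a truth fragment: `partition` (planted disease
#'   grouping), `overlap` (planted overlap set with evidence and disease
#'   mapping), `pocket_ids` (diseases disconnected by construction) and the
#'   file paths.
#' @export
make_mock_ontologies <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ent <- fixture_entities(spec)
  set.seed(spec$rng_seed + 1)

  dis_all <- dplyr::bind_rows(
    tibble::tibble(id = "MONDO:0000001", name = "disease root", family = "root"),
    ent$diseases,
    if (spec$isolated_pocket) ent$pocket
  )
  dis_edges <- tree_edges(c("MONDO:0000001", ent$diseases$id))
  if (spec$isolated_pocket) {
    dis_edges <- dplyr::bind_rows(
      dis_edges,
      tibble::tibble(child_id = ent$pocket$id[2], parent_id = ent$pocket$id[1])
    )
  }
  dis_all$definition <- paste0("synthetic definition of ", dis_all$name)
  xr <- ent$overlap[ent$overlap$evidence == "xref-mapped", ]
  dis_xrefs <- tibble::tibble(term_id = xr$disease_id, foreign_id = xr$phenotype_id)
  # UMLS and rare-disease registry xrefs used by the clinical-feature mapping
  n_cui <- min(spec$n_umls_disorders, nrow(ent$diseases))
  dis_xrefs <- dplyr::bind_rows(
    dis_xrefs,
    tibble::tibble(
      term_id = ent$diseases$id[seq_len(n_cui)],
      foreign_id = sprintf("UMLS:C%07d", seq_len(n_cui))
    ),
    tibble::tibble(
      term_id = ent$diseases$id[seq_len(10)],
      foreign_id = sprintf("Orphanet:%04d", seq_len(10))
    )
  )
  write_obo(file.path(dir, "disease.obo"), dis_all, dis_edges, dis_xrefs)

  ph_all <- dplyr::bind_rows(
    tibble::tibble(id = "HP:4000000", name = "phenotype root"),
    ent$phenotypes
  )
  ph_edges <- tree_edges(c("HP:4000000", ent$phenotypes$id))
  write_obo(file.path(dir, "phenotype.obo"), ph_all, ph_edges)

  truth <- list(
    partition = dplyr::bind_rows(
      ent$diseases[, c("id", "name", "family")],
      tibble::tibble(
        id = "MONDO:0000001", name = "disease root",
        family = "singleton_root"
      ),
      if (spec$isolated_pocket) ent$pocket[, c("id", "name", "family")]
    ),
    overlap = ent$overlap,
    pocket_ids = if (spec$isolated_pocket) ent$pocket$id else character(),
    files = c(
      disease = file.path(dir, "disease.obo"),
      phenotype = file.path(dir, "phenotype.obo")
    )
  )
  invisible(truth)
}

# --- resource bundle ---------------------------------------------------------

#' Generate the mock resource file bundle
#'
#' Emits miniature files in every consumed format — expression-call TSV with
#' planted filter survivors, gene-disease TSV, drug-disease label table,
#' PPI edge lists, side-effect table with mixed coding levels, RRF-style
#' concept/semantic-type/definition tables, a drug XML with interactions and
#' partner tables, identifier vocabularies, and synthetic clinical-feature
#' CSVs — together with the ontologies of [make_mock_ontologies()] and a
#' manifest. All survivor counts are planted and recorded in the truth
#' fragment; [verify_fixture_bundle()] re-derives them through the adapters.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, the planted-truth list (also written as
#'   `planted_truth.json`).
#' @export
make_mock_resources <- function(spec, dir) {
  truth <- make_mock_ontologies(spec, dir)
  ent <- fixture_entities(spec)
  set.seed(spec$rng_seed + 2)
  genes <- ent$genes
  drugs <- ent$drugs
  dis <- ent$diseases
  phe <- ent$phenotypes

  # expression calls: exactly n_expression_pass survivors; failures split
  # across quality, fdr, and rank (including the rank boundary itself)
  n <- spec$n_expression_rows
  n_pass <- spec$n_expression_pass
  fail_kind <- sample(c("quality", "fdr", "rank", "boundary"), n - n_pass,
    replace = TRUE
  )
  expr <- tibble::tibble(
    anatomy_id = sample(ent$anatomy$id, n, replace = TRUE),
    anatomy_name = NA_character_,
    gene_id = sample(genes$id, n, replace = TRUE),
    gene_name = NA_character_,
    call = sample(c("present", "absent"), n, replace = TRUE, prob = c(0.8, 0.2)),
    quality = c(rep("gold quality", n_pass), ifelse(fail_kind == "quality", "silver quality", "gold quality")),
    fdr = c(
      round(stats::runif(n_pass, 0.0001, 0.009), 5),
      ifelse(fail_kind == "fdr", 0.05, 0.001)
    ),
    rank = c(
      sample(1000:24000, n_pass, replace = TRUE),
      dplyr::case_when(
        fail_kind == "rank" ~ 30000L,
        fail_kind == "boundary" ~ 25000L,
        TRUE ~ 5000L
      )
    )
  )
  expr$anatomy_name <- ent$anatomy$name[match(expr$anatomy_id, ent$anatomy$id)]
  expr$gene_name <- genes$name[match(expr$gene_id, genes$id)]
  readr::write_tsv(expr, file.path(dir, "expression_calls.tsv"), progress = FALSE)

  # gene-disease / gene-phenotype associations; includes overlap phenotypes
  # (rewired to protein-disease later) and regular phenotypes
  ov_ids <- ent$overlap$phenotype_id
  plain_phe <- setdiff(phe$id, ov_ids)
  if (length(ov_ids) == 0) ov_ids <- plain_phe
  n_gd <- 60
  targets <- c(
    sample(dis$id, 35, replace = TRUE),
    sample(ov_ids, 10, replace = TRUE),
    sample(plain_phe, 15, replace = TRUE)
  )
  gd <- tibble::tibble(
    gene_id = sample(genes$id, n_gd, replace = TRUE),
    gene_name = NA_character_,
    id = targets,
    name = NA_character_
  )
  gd$gene_name <- genes$name[match(gd$gene_id, genes$id)]
  gd$name <- dplyr::coalesce(
    dis$name[match(gd$id, dis$id)],
    phe$name[match(gd$id, phe$id)]
  )
  readr::write_tsv(gd, file.path(dir, "gene_disease.tsv"), progress = FALSE)

  # drug-disease labels keyed by CAS registry number (mapped at build time)
  labels <- tibble::tibble(
    cas_id = sample(drugs$cas, 40, replace = TRUE),
    disease_id = sample(dis$id, 40, replace = TRUE),
    disease_name = NA_character_,
    label = sample(c("indication", "contraindication", "off-label use"), 40,
      replace = TRUE, prob = c(0.6, 0.25, 0.15)
    )
  )
  labels$disease_name <- dis$name[match(labels$disease_id, dis$id)]
  readr::write_csv(labels, file.path(dir, "drug_disease.csv"), progress = FALSE)

  # PPI: a spanning chain over all genes (keeps the protein layer connected)
  # plus random extras, split across two "sources" with mirrored duplicates
  chain <- tibble::tibble(gene_a = genes$id[-nrow(genes)], gene_b = genes$id[-1])
  extra <- tibble::tibble(
    gene_a = sample(genes$id, 40, replace = TRUE),
    gene_b = sample(genes$id, 40, replace = TRUE)
  )
  extra <- extra[extra$gene_a != extra$gene_b, ]
  ppi1 <- dplyr::bind_rows(chain, extra[seq_len(floor(nrow(extra) / 2)), ])
  ppi2 <- dplyr::bind_rows(
    extra[(floor(nrow(extra) / 2) + 1):nrow(extra), ],
    # mirrored duplicates of chain rows; the union must deduplicate these
    tibble::tibble(gene_a = chain$gene_b[1:5], gene_b = chain$gene_a[1:5])
  )
  readr::write_tsv(ppi1, file.path(dir, "ppi_source1.tsv"), progress = FALSE)
  readr::write_tsv(ppi2, file.path(dir, "ppi_source2.tsv"), progress = FALSE)
  all_ppi <- dplyr::bind_rows(ppi1, ppi2)
  swp <- all_ppi$gene_a > all_ppi$gene_b
  all_ppi[swp, c("gene_a", "gene_b")] <- all_ppi[swp, c("gene_b", "gene_a")]
  truth$ppi_unique_pairs <- nrow(dplyr::distinct(all_ppi[all_ppi$gene_a != all_ppi$gene_b, ]))

  # side effects: planted survivors are preferred-term rows with a complete
  # stitch -> ATC -> drug accession chain; failures are LLT rows or broken
  # chains; one survivor uses an overlap phenotype (dropped later at rewiring)
  n_se <- spec$n_side_effect_rows
  n_sp <- spec$n_side_effect_pass
  se_drugs <- sample(seq_len(nrow(drugs) - 1), n_se, replace = TRUE)
  se <- tibble::tibble(
    drug_stitch_id = drugs$stitch[se_drugs],
    meddra_level = c(rep("PT", n_sp), sample(c("LLT", "PT"), n_se - n_sp, replace = TRUE)),
    phenotype_id = c(
      ov_ids[1],
      sample(plain_phe, n_se - 1, replace = TRUE)
    ),
    phenotype_name = NA_character_
  )
  # break the chain for the non-survivor PT rows by pointing at the one drug
  # missing from the stitch->ATC vocabulary
  broken <- which(se$meddra_level == "PT")
  broken <- broken[broken > n_sp]
  se$drug_stitch_id[broken] <- drugs$stitch[nrow(drugs)]
  se$phenotype_name <- phe$name[match(se$phenotype_id, phe$id)]
  readr::write_tsv(se, file.path(dir, "side_effects.tsv"), progress = FALSE)
  truth$side_effect_survivors <- n_sp

  # vocabularies
  readr::write_tsv(
    tibble::tibble(from = genes$uniprot, to = genes$id, to_name = genes$name),
    file.path(dir, "vocab_uniprot2gene.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(from = drugs$cas, to = drugs$id, to_name = drugs$name),
    file.path(dir, "vocab_cas2drug.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(
      from = drugs$stitch[-nrow(drugs)],
      to = drugs$atc[-nrow(drugs)]
    ),
    file.path(dir, "vocab_stitch2atc.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(from = drugs$atc, to = drugs$id, to_name = drugs$name),
    file.path(dir, "vocab_atc2drug.tsv"),
    progress = FALSE
  )

  # drug XML: interactions (with mirrored records) and partner links
  ints <- tibble::tibble(
    a = drugs$id[seq_len(spec$n_drug_interactions)],
    b = drugs$id[seq_len(spec$n_drug_interactions) + 1]
  )
  partner_tabs <- purrr::map(
    stats::setNames(
      c("targets", "enzymes", "carriers", "transporters"),
      c("targets", "enzymes", "carriers", "transporters")
    ),
    function(kind) {
      k <- sample(5:9, 1)
      tibble::tibble(
        drug_id = sample(drugs$id, k, replace = TRUE),
        uniprot_id = sample(genes$uniprot, k, replace = TRUE)
      )
    }
  )
  # a shared pair across two partner files exercises the union dedup
  partner_tabs$enzymes <- dplyr::bind_rows(
    partner_tabs$enzymes, partner_tabs$targets[1, ]
  )
  xml_lines <- c("<?xml version=\"1.0\"?>", "<drugs>")
  for (i in seq_len(nrow(drugs))) {
    xml_lines <- c(
      xml_lines, "  <drug>",
      paste0("    <drugbank-id>", drugs$id[i], "</drugbank-id>"),
      paste0("    <name>", drugs$name[i], "</name>"),
      "    <drug-interactions>"
    )
    partners <- c(ints$b[ints$a == drugs$id[i]], ints$a[ints$b == drugs$id[i]])
    for (p in partners) {
      xml_lines <- c(
        xml_lines, "      <drug-interaction>",
        paste0("        <drugbank-id>", p, "</drugbank-id>"),
        paste0("        <name>", drugs$name[match(p, drugs$id)], "</name>"),
        "      </drug-interaction>"
      )
    }
    xml_lines <- c(xml_lines, "    </drug-interactions>", "  </drug>")
  }
  xml_lines <- c(xml_lines, "</drugs>")
  readr::write_lines(xml_lines, file.path(dir, "drugs.xml"))
  for (kind in names(partner_tabs)) {
    readr::write_csv(partner_tabs[[kind]],
      file.path(dir, paste0("partners_", kind, ".csv")),
      progress = FALSE
    )
  }
  pt <- dplyr::bind_rows(partner_tabs)
  truth$drug_protein_unique_pairs <- nrow(dplyr::distinct(pt))
  truth$drug_interactions <- nrow(ints)

  # exposures across all six partner types
  exp_rows <- purrr::map_dfr(
    list(
      c("exposure", "CTD"), c("gene/protein", "NCBI"), c("disease", "MONDO"),
      c("biological_process", "GO"), c("molecular_function", "GO"),
      c("cellular_component", "GO")
    ),
    function(pt_src) {
      k <- 4
      partner_pool <- switch(pt_src[1],
        "exposure" = ent$exposures,
        "gene/protein" = genes,
        "disease" = dis,
        ent$go[ent$go$namespace == pt_src[1], ]
      )
      picked <- partner_pool[sample(nrow(partner_pool), k, replace = TRUE), ]
      tibble::tibble(
        exposure_id = sample(ent$exposures$id, k, replace = TRUE),
        exposure_name = NA_character_,
        partner_id = picked$id, partner_name = picked$name,
        partner_type = pt_src[1], partner_source = pt_src[2]
      )
    }
  )
  exp_rows <- exp_rows[exp_rows$exposure_id != exp_rows$partner_id, ]
  # chain the exposure terms so none is isolated
  exp_rows <- dplyr::bind_rows(
    exp_rows,
    tibble::tibble(
      exposure_id = ent$exposures$id[-nrow(ent$exposures)],
      exposure_name = NA_character_,
      partner_id = ent$exposures$id[-1],
      partner_name = ent$exposures$name[-1],
      partner_type = "exposure", partner_source = "CTD"
    )
  )
  exp_rows$exposure_name <- ent$exposures$name[match(exp_rows$exposure_id, ent$exposures$id)]
  readr::write_csv(exp_rows, file.path(dir, "exposures.csv"), progress = FALSE)

  # anatomy ontology (hierarchy keeps the anatomy layer connected)
  write_obo(
    file.path(dir, "anatomy.obo"),
    ent$anatomy, tree_edges(ent$anatomy$id)
  )

  # GO ontologies (three namespaces) and gene annotations
  for (ns in unique(ent$go$namespace)) {
    terms <- ent$go[ent$go$namespace == ns, c("id", "name")]
    write_obo(
      file.path(dir, paste0("go_", substr(ns, 1, 2), ".obo")),
      terms, tree_edges(terms$id)
    )
  }
  g2g <- tibble::tibble(
    gene_id = sample(genes$id, 30, replace = TRUE),
    gene_name = NA_character_,
    go_id = sample(ent$go$id, 30, replace = TRUE),
    go_name = NA_character_, go_type = NA_character_
  )
  g2g$gene_name <- genes$name[match(g2g$gene_id, genes$id)]
  g2g$go_name <- ent$go$name[match(g2g$go_id, ent$go$id)]
  g2g$go_type <- ent$go$namespace[match(g2g$go_id, ent$go$id)]
  readr::write_tsv(g2g, file.path(dir, "gene2go.tsv"), progress = FALSE)

  # pathways: hierarchy chain + memberships
  pw_rel <- tibble::tibble(
    child_id = ent$pathways$id[-1], child_name = ent$pathways$name[-1],
    parent_id = ent$pathways$id[-nrow(ent$pathways)],
    parent_name = ent$pathways$name[-nrow(ent$pathways)]
  )
  pw_mem <- tibble::tibble(
    gene_id = sample(genes$id, 20, replace = TRUE),
    gene_name = NA_character_,
    pathway_id = sample(ent$pathways$id, 20, replace = TRUE),
    pathway_name = NA_character_
  )
  pw_mem$gene_name <- genes$name[match(pw_mem$gene_id, genes$id)]
  pw_mem$pathway_name <- ent$pathways$name[match(pw_mem$pathway_id, ent$pathways$id)]
  readr::write_tsv(pw_rel, file.path(dir, "pathway_relations.tsv"), progress = FALSE)
  readr::write_tsv(pw_mem, file.path(dir, "pathway_members.tsv"), progress = FALSE)

  # disease-phenotype annotations; a few negatives; a few overlap phenotypes
  # (dropped later at rewiring, planted count recorded)
  n_dp <- 50
  dp <- tibble::tibble(
    disease_id = sample(dis$id, n_dp, replace = TRUE),
    disease_name = NA_character_,
    phenotype_id = c(
      sample(ov_ids, 6, replace = TRUE),
      sample(plain_phe, n_dp - 6, replace = TRUE)
    ),
    phenotype_name = NA_character_,
    qualifier = sample(c("", "NOT"), n_dp, replace = TRUE, prob = c(0.9, 0.1))
  )
  dp$disease_name <- dis$name[match(dp$disease_id, dis$id)]
  dp$phenotype_name <- phe$name[match(dp$phenotype_id, phe$id)]
  readr::write_tsv(dp, file.path(dir, "disease_phenotypes.tsv"), progress = FALSE)

  # UMLS-style RRF tables: n_umls_disorders planted Disorder-group concepts
  cuis <- sprintf("C%07d", seq_len(spec$n_umls_concepts))
  sty <- tibble::tibble(
    cui = cuis,
    semantic_type = c(
      rep_len(
        c("Disease or Syndrome", "Neoplastic Process", "Congenital Abnormality"),
        spec$n_umls_disorders
      ),
      rep_len(c("Finding", "Laboratory Procedure"), spec$n_umls_concepts - spec$n_umls_disorders)
    )
  )
  conso <- tibble::tibble(
    cui = rep(cuis, each = 2),
    language = rep(c("ENG", "FRE"), spec$n_umls_concepts),
    name = paste0("concept name ", rep(seq_along(cuis), each = 2))
  )
  mrdef <- tibble::tibble(
    cui = cuis, source = "SYNTH", language = "ENG",
    definition = paste0("synthetic concept definition ", seq_along(cuis))
  )
  write_rrf <- function(df, path) {
    readr::write_delim(df, path, delim = "|", progress = FALSE)
  }
  write_rrf(conso, file.path(dir, "concepts.rrf"))
  write_rrf(sty, file.path(dir, "semantic_types.rrf"))
  write_rrf(mrdef, file.path(dir, "definitions.rrf"))
  truth$umls_disorder_concepts <- spec$n_umls_disorders

  # clinical features: drug text/numeric features and pre-scraped synthetic
  # disease feature tables
  drug_feat <- tibble::tibble(
    drug_id = drugs$id,
    description = paste0(
      "Synthetic description of ", drugs$name, " [L", 10000 + seq_len(nrow(drugs)), "]."
    ),
    indication = paste0("Indicated for synthetic condition ", seq_len(nrow(drugs)), "."),
    half_life = rep_len(
      c("2.1-3.5 hours", "No half-life data is available", "12 hours"),
      nrow(drugs)
    ),
    group = rep_len(c("approved", "approved; investigational"), nrow(drugs)),
    state = rep_len(c("solid", "liquid"), nrow(drugs))
  )
  readr::write_csv(drug_feat, file.path(dir, "drug_features.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(
      cas_id = drugs$cas,
      molecular_weight = round(stats::runif(nrow(drugs), 150, 900), 2),
      tpsa = round(stats::runif(nrow(drugs), 20, 200), 2),
      clogp = round(stats::runif(nrow(drugs), -2, 6), 2)
    ),
    file.path(dir, "drugcentral_numeric.csv"),
    progress = FALSE
  )
  mayo_n <- 12
  readr::write_csv(
    tibble::tibble(
      name = dis$name[seq_len(mayo_n)],
      symptoms = paste0(
        "Synthetic symptoms of ", dis$name[seq_len(mayo_n)],
        ". When to see a doctor: if synthetic symptom persists."
      ),
      causes = "Synthetic causes.", risk_factors = "Synthetic risk factors.",
      complications = "Synthetic complications.", prevention = "Synthetic prevention."
    ),
    file.path(dir, "mayo_synthetic.csv"),
    progress = FALSE
  )
  readr::write_csv(
    tibble::tibble(
      orpha_id = sprintf("Orphanet:%04d", seq_len(10)),
      definition = paste0("synthetic rare-disease definition ", seq_len(10)),
      prevalence = "1/200000",
      epidemiology = "synthetic epidemiology",
      clinical_description = "synthetic clinical description",
      management_and_treatment = "synthetic management"
    ),
    file.path(dir, "orphanet_synthetic.csv"),
    progress = FALSE
  )

  truth$expression_pass <- spec$n_expression_pass
  truth$manifest <- list(
    disease_obo = "disease.obo", phenotype_obo = "phenotype.obo",
    anatomy_obo = "anatomy.obo",
    go_obo = c("go_bi.obo", "go_mo.obo", "go_ce.obo"),
    expression = "expression_calls.tsv", gene_disease = "gene_disease.tsv",
    drug_disease = "drug_disease.csv",
    ppi = c("ppi_source1.tsv", "ppi_source2.tsv"),
    side_effects = "side_effects.tsv", drugs_xml = "drugs.xml",
    partners = paste0("partners_", names(partner_tabs), ".csv"),
    exposures = "exposures.csv", gene2go = "gene2go.tsv",
    pathway_relations = "pathway_relations.tsv",
    pathway_members = "pathway_members.tsv",
    disease_phenotypes = "disease_phenotypes.tsv",
    umls = c("concepts.rrf", "semantic_types.rrf", "definitions.rrf"),
    vocab = c(
      uniprot2gene = "vocab_uniprot2gene.tsv", cas2drug = "vocab_cas2drug.tsv",
      stitch2atc = "vocab_stitch2atc.tsv", atc2drug = "vocab_atc2drug.tsv"
    ),
    drug_features = "drug_features.csv",
    drugcentral_numeric = "drugcentral_numeric.csv",
    mayo = "mayo_synthetic.csv", orphanet = "orphanet_synthetic.csv"
  )
  jsonlite::write_json(
    truth[setdiff(names(truth), c("files"))],
    file.path(dir, "planted_truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(truth)
}

#' Verify a fixture bundle against its planted truth
#'
#' Self-audit pass: re-runs the ingest adapters on the generated files and
#' checks every planted survivor count, the planted overlap set, and the
#' planted grouping seeds. Errors on the first mismatch.
#'
#' @param spec The [fixture_spec()] used to generate the bundle.
#' @param dir Bundle directory.
#' @return `TRUE` invisibly on success.
#' @export
verify_fixture_bundle <- function(spec, dir) {
  truth <- make_mock_ontologies(spec, tempfile("audit"))
  expr <- readr::read_tsv(file.path(dir, "expression_calls.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  stopifnot(nrow(filter_expression_calls(expr)) == spec$n_expression_pass)

  mondo <- parse_obo(file.path(dir, "disease.obo"))
  hp <- parse_obo(file.path(dir, "phenotype.obo"))
  P <- compute_overlap_set(hp, mondo)
  stopifnot(setequal(P$phenotype_id, truth$overlap$phenotype_id))

  conso <- readr::read_delim(file.path(dir, "concepts.rrf"),
    delim = "|",
    show_col_types = FALSE, progress = FALSE
  )
  sty <- readr::read_delim(file.path(dir, "semantic_types.rrf"),
    delim = "|",
    show_col_types = FALSE, progress = FALSE
  )
  defs <- readr::read_delim(file.path(dir, "definitions.rrf"),
    delim = "|",
    show_col_types = FALSE, progress = FALSE
  )
  stopifnot(nrow(select_umls_disorders(conso, sty, defs)) == spec$n_umls_disorders)

  se <- readr::read_tsv(file.path(dir, "side_effects.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  s2a <- xref_map(readr::read_tsv(file.path(dir, "vocab_stitch2atc.tsv"),
    show_col_types = FALSE, progress = FALSE
  ))
  a2d <- xref_map(readr::read_tsv(file.path(dir, "vocab_atc2drug.tsv"),
    show_col_types = FALSE, progress = FALSE
  ))
  stopifnot(nrow(filter_side_effects(se, s2a, a2d)) == spec$n_side_effect_pass)
  invisible(TRUE)
}

# --- proximity testbed -------------------------------------------------------

#' Generate a proximity-analysis testbed graph
#'
#' Two planted designs. `"calibration"` builds a caterpillar graph in which
#' every disease sits at a distinct hop distance from the drug, so a uniformly
#' drawn indicated disease is exchangeable with the permutation null.
#' `"power"` plants one indicated disease two hops from the drug against a
#' background of diseases at four or more hops.
#'
#' @param kind `"calibration"` or `"power"`.
#' @param n_diseases Number of disease nodes.
#' @param rng_seed Seed for the construction.
#' @return A list with `kg` (a `kg` object), `pairs` (a one-row or `NULL`
#'   pairs tibble for [proximity_test()]; `NULL` for calibration, where the
#'   caller draws indicated diseases), `truth` (planted structure: the
#'   distance of every disease from the drug).
#' @export
make_proximity_testbed <- function(kind = c("calibration", "power"),
                                   n_diseases = 150, rng_seed = 1) {
  kind <- match.arg(kind)
  set.seed(rng_seed)
  if (kind == "calibration") {
    prot <- paste0("g", seq_len(n_diseases))
    rows <- dplyr::bind_rows(
      tibble::tibble(
        x_id = "DBX0001", x_type = "drug", x_source = "DrugBank",
        relation = "drug_protein",
        y_id = prot[1], y_type = "gene/protein", y_source = "NCBI"
      ),
      tibble::tibble(
        x_id = prot[-length(prot)], x_type = "gene/protein", x_source = "NCBI",
        relation = "protein_protein",
        y_id = prot[-1], y_type = "gene/protein", y_source = "NCBI"
      ),
      tibble::tibble(
        x_id = paste0("MONDO:", 6000000 + seq_len(n_diseases)),
        x_type = "disease", x_source = "MONDO",
        relation = "disease_protein",
        y_id = prot, y_type = "gene/protein", y_source = "NCBI"
      )
    )
    truth <- tibble::tibble(
      disease_id = paste0("MONDO:", 6000000 + seq_len(n_diseases)),
      distance = seq_len(n_diseases) + 1
    )
  } else {
    n_bg <- n_diseases - 1
    rows <- dplyr::bind_rows(
      tibble::tibble(
        x_id = "DBX0001", x_type = "drug", x_source = "DrugBank",
        relation = "drug_protein",
        y_id = "gNear", y_type = "gene/protein", y_source = "NCBI"
      ),
      tibble::tibble(
        x_id = "MONDO:7000000", x_type = "disease", x_source = "MONDO",
        relation = "disease_protein",
        y_id = "gNear", y_type = "gene/protein", y_source = "NCBI"
      ),
      tibble::tibble(
        x_id = c("gNear", "gMid1", "gMid2"), x_type = "gene/protein", x_source = "NCBI",
        relation = "protein_protein",
        y_id = c("gMid1", "gMid2", "gFar"), y_type = "gene/protein", y_source = "NCBI"
      ),
      tibble::tibble(
        x_id = paste0("MONDO:", 7000000 + seq_len(n_bg)),
        x_type = "disease", x_source = "MONDO",
        relation = "disease_protein",
        y_id = "gFar", y_type = "gene/protein", y_source = "NCBI"
      )
    )
    truth <- tibble::tibble(
      disease_id = c("MONDO:7000000", paste0("MONDO:", 7000000 + seq_len(n_bg))),
      distance = c(2, rep(5, n_bg))
    )
  }
  built <- assemble_kg(list(triples_table(rows, resource = "testbed")))
  kg <- built$kg_giant
  pairs <- NULL
  if (kind == "power") {
    pairs <- tibble::tibble(
      drug_index = kg$nodes$node_index[kg$nodes$node_id == "DBX0001"],
      disease_index = kg$nodes$node_index[kg$nodes$node_id == "MONDO:7000000"]
    )
  }
  list(kg = kg, pairs = pairs, truth = truth)
}
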