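#' Remove bracketed citation tokens from text
#'
#' Deletes reference tokens of the form `[<letter><digits>]` (a configurable
#' letter prefix followed by digits inside square brackets, e.g. `[L64839]`),
#' optionally run together (`[A12][L3456]`). All other bracketed material is
#' preserved. Idempotent.
#'
#' @param text Character vector.
#' @param prefixes Regex character class of admissible prefix letters; default
#'   covers the citation prefixes in common use (`A`, `L`, `T`, `F`).
#' @return The cleaned text, with whitespace re-collapsed.
#' @export
#' @examples
#' clean_reference_tokens("binds receptor [L64839] strongly")
clean_reference_tokens <- function(text, prefixes = "[ALTF]") {
  pattern <- paste0("\\[", prefixes, "[0-9]+\\]")
  out <- gsub(pattern, "", text)
  out <- gsub("[ \t]+", " ", out)
  out <- gsub(" ([.,;:])", "\\1", out)
  stringr::str_trim(out)
}

#' Nullify half-life text stating that no data is available
#'
#' @param text Character vector of half-life descriptions.
#' @param trigger_patterns Regexes (case-insensitive) whose match empties the
#'   field.
#' @return `text` with no-data statements replaced by `""`; `NA` also becomes
#'   `""`.
#' @export
#' @examples
#' normalize_half_life("No half-life data is available")
#' normalize_half_life("2.1-3.5 hours")
normalize_half_life <- function(text,
                                trigger_patterns = c(
                                  "no (half-?life )?data (is |are )?available",
                                  "not available", "no information", "unknown"
                                )) {
  out <- ifelse(is.na(text), "", text)
  hit <- Reduce(
    `|`,
    lapply(trigger_patterns, function(p) {
      stringr::str_detect(out, stringr::regex(p, ignore_case = TRUE))
    }),
    init = rep(FALSE, length(out))
  )
  ifelse(hit, "", out)
}

#' Render a numerical drug descriptor as a sentence
#'
#' Fixed templates standardize the numeric descriptors into text:
#' `"The molecular weight is <v>."`,
#' `"<name> has a topological polar surface area of <v>."`,
#' `"The log p value of <name> is <v>."`.
#'
#' @param drug_name Drug display name.
#' @param descriptor One of `"molecular_weight"`, `"tpsa"`, `"clogp"`.
#' @param value Numeric value; a non-finite value yields `""`.
#' @return A sentence, or `""`.
#' @export
#' @examples
#' numeric_to_text("Prednisolone", "molecular_weight", 360.45)
numeric_to_text <- function(drug_name, descriptor = c("molecular_weight", "tpsa", "clogp"),
                            value) {
  descriptor <- match.arg(descriptor)
  if (!is.finite(value)) {
    return("")
  }
  v <- format(value, trim = TRUE)
  switch(descriptor,
    molecular_weight = paste0("The molecular weight is ", v, "."),
    tpsa = paste0(drug_name, " has a topological polar surface area of ", v, "."),
    clogp = paste0("The log p value of ", drug_name, " is ", v, ".")
  )
}

#' Split out the when-to-see-a-doctor section of a symptoms text
#'
#' Splits at the first occurrence of a heading such as "When to see a doctor"
#' (case-insensitive, optional trailing punctuation); when absent, the second
#' element is empty.
#'
#' @param symptoms_text Character scalar.
#' @param heading_pattern Regex matching the heading.
#' @return A list with elements `symptoms` and `when_to_see_doctor`.
#' @export
split_when_to_see_doctor <- function(symptoms_text,
                                     heading_pattern = "when to see (a|the|your) doctor[.:;,]?\\s*") {
  m <- stringr::str_locate(
    symptoms_text,
    stringr::regex(heading_pattern, ignore_case = TRUE)
  )
  if (is.na(m[1, 1])) {
    return(list(symptoms = symptoms_text, when_to_see_doctor = ""))
  }
  list(
    symptoms = stringr::str_trim(substr(symptoms_text, 1, m[1, 1] - 1)),
    when_to_see_doctor = stringr::str_trim(
      substr(symptoms_text, m[1, 2] + 1, nchar(symptoms_text))
    )
  )
}

#' Map clinical-source disease names onto ontology names
#'
#' Stage one auto-accepts exact normalized matches and encapsulating matches
#' (the source name wholly contained in the target name). Stage two embeds the
#' remaining names and proposes matches at or above the similarity cutoff,
#' routed through the same review-file workflow as disease grouping.
#'
#' @param source_names Character vector of names from the clinical source.
#' @param target_names Named or plain character vector of ontology names
#'   (names taken as identifiers; defaults to the names themselves).
#' @param embedder A name embedder for stage two.
#' @param cfg A [grouping_config()]; `similarity_cutoff` gates proposals.
#' @return A list with `mapping` (tibble `source_name`, `target_id`,
#'   `target_name`, `rule`), `proposals` (review tibble for embedding
#'   matches) and `unmatched` (source names with neither match nor proposal).
#' @export
match_disease_names <- function(source_names, target_names,
                                embedder = trigram_embedder(),
                                cfg = grouping_config()) {
  tgt_ids <- if (is.null(names(target_names))) target_names else names(target_names)
  tgt <- tibble::tibble(
    target_id = tgt_ids, target_name = unname(target_names),
    norm = normalize_name(unname(target_names))
  )
  src <- tibble::tibble(
    source_name = unique(source_names),
    norm = normalize_name(unique(source_names))
  )

  exact <- dplyr::inner_join(src, tgt, by = "norm") |>
    dplyr::mutate(rule = "exact")
  rest <- src[!(src$norm %in% exact$norm), ]
  encaps <- purrr::map_dfr(seq_len(nrow(rest)), function(i) {
    hits <- which(stringr::str_detect(
      tgt$norm,
      stringr::fixed(paste0(" ", rest$norm[i], " "))
    ) | startsWith(tgt$norm, paste0(rest$norm[i], " ")) |
      endsWith(tgt$norm, paste0(" ", rest$norm[i])))
    if (length(hits) == 0) {
      return(NULL)
    }
    tibble::tibble(
      source_name = rest$source_name[i], norm = rest$norm[i],
      target_id = tgt$target_id[hits], target_name = tgt$target_name[hits],
      rule = "encapsulating"
    )
  })
  mapping <- dplyr::bind_rows(exact, encaps)[
    , c("source_name", "target_id", "target_name", "rule")
  ]

  remaining <- setdiff(src$source_name, mapping$source_name)
  proposals <- empty_review()
  if (length(remaining) > 0 && nrow(tgt) > 0) {
    es <- embed_names(embedder, normalize_name(remaining))
    et <- embed_names(embedder, tgt$norm)
    sim <- es %*% t(et)
    hits <- which(sim >= cfg$similarity_cutoff, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      proposals <- tibble::tibble(
        proposal_id = seq_len(nrow(hits)),
        group_a = remaining[hits[, 1]],
        group_b = tgt$target_id[hits[, 2]],
        representative_a = remaining[hits[, 1]],
        representative_b = tgt$target_name[hits[, 2]],
        similarity = sim[hits],
        decision = NA_character_,
        assigned_name = NA_character_
      )
    }
  }
  list(
    mapping = mapping,
    proposals = proposals,
    unmatched = setdiff(remaining, proposals$group_a)
  )
}

#' Attach clinical feature records to graph nodes
#'
#' Drug features attach one-to-one by drug node identifier. Disease features
#' are keyed by contributing ontology identifier; grouped disease nodes
#' aggregate the features of all their member identifiers, so one
#' `node_index` may carry several feature rows. Records whose identifier does
#' not resolve to a node are logged, never invented.
#'
#' @param kg A `kg` object.
#' @param drug_records Data frame with `drug_id` plus feature columns; at most
#'   one record per drug.
#' @param disease_records Data frame with `disease_id` (ontology identifier)
#'   plus feature columns.
#' @param grouping Optional `disease_grouping` used to resolve member
#'   identifiers of grouped nodes.
#' @return A list with `drug_features` (keyed by `node_index`),
#'   `disease_features` (keyed by `node_index` and contributing `node_id`) and
#'   `unmapped` (records that did not attach, with a reason).
#' @export
attach_features <- function(kg, drug_records, disease_records, grouping = NULL) {
  nodes <- kg$nodes
  drug_records <- tibble::as_tibble(drug_records)
  disease_records <- tibble::as_tibble(disease_records)
  if (anyDuplicated(drug_records$drug_id) > 0) {
    rlang::abort("at most one feature record per drug_id",
      class = "kgcraft_contract_error"
    )
  }

  drugs <- nodes[nodes$node_type == "drug", ]
  drug_feat <- dplyr::inner_join(
    drugs[, c("node_index", "node_id")], drug_records,
    by = c(node_id = "drug_id")
  )
  drug_unmapped <- drug_records[!(drug_records$drug_id %in% drugs$node_id), ]

  dis <- nodes[nodes$node_type == "disease", ]
  member_map <- tibble::tibble(
    node_index = dis$node_index, node_id = dis$node_id, member_id = dis$node_id
  )
  if (!is.null(grouping)) {
    exp <- grouping$members |>
      tidyr::unnest(cols = "members") |>
      dplyr::rename(member_id = "members", node_id = "group_id")
    exp <- dplyr::inner_join(
      dis[, c("node_index", "node_id")], exp,
      by = "node_id"
    )
    member_map <- dplyr::distinct(dplyr::bind_rows(member_map, exp))
  }
  dis_feat <- dplyr::inner_join(
    member_map, disease_records,
    by = c(member_id = "disease_id")
  )
  dis_unmapped <- disease_records[
    !(disease_records$disease_id %in% member_map$member_id),
  ]

  list(
    drug_features = drug_feat,
    disease_features = dis_feat,
    unmapped = dplyr::bind_rows(
      if (nrow(drug_unmapped)) {
        tibble::tibble(id = drug_unmapped$drug_id, kind = "drug", reason = "no_matching_node")
      },
      if (nrow(dis_unmapped)) {
        tibble::tibble(id = dis_unmapped$disease_id, kind = "disease", reason = "no_matching_node")
      }
    )
  )
}

#' Join multi-valued feature attributes into one text description
#'
#' Multi-valued attributes (groups, ATC levels, pathways) are rendered as one
#' deterministic sentence fragment: values joined with `"; "` and a final
#' `" and "` before the last value.
#'
#' @param values Character vector of attribute values.
#' @return A single string; `""` for no values.
#' @export
#' @examples
#' join_feature_values(c("approved", "vet approved"))
join_feature_values <- function(values) {
  values <- values[!is.na(values) & values != ""]
  n <- length(values)
  if (n == 0) {
    return("")
  }
  if (n == 1) {
    return(values)
  }
  paste0(paste(values[-n], collapse = "; "), " and ", values[n])
}
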