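#' Grouping configuration
#'
#' @param similarity_cutoff Cosine-similarity threshold at or above which two
#'   group representatives are proposed for merging; default 0.98.
#' @param ignored_words Words ignored during bag-of-words comparison; default
#'   `c("type", "(disease)")`.
#' @param max_suffix_len Maximum character length of a short alphanumeric
#'   suffix token (containing a digit, or a single letter) that qualifies a
#'   name for base-phrase extraction; default 2.
#' @param require_review If `TRUE`, only embedding merge proposals marked
#'   `approve` in the review file are merged; if `FALSE` all proposals merge.
#' @return A list of class `grouping_config`.
#' @export
grouping_config <- function(similarity_cutoff = 0.98,
                            ignored_words = c("type", "(disease)"),
                            max_suffix_len = 2,
                            require_review = FALSE) {
  stopifnot(similarity_cutoff >= -1, similarity_cutoff <= 1)
  structure(
    list(
      similarity_cutoff = similarity_cutoff,
      ignored_words = tolower(gsub("[^a-z0-9 ]", "", tolower(ignored_words))),
      max_suffix_len = max_suffix_len,
      require_review = require_review
    ),
    class = "grouping_config"
  )
}

# Lowercase, strip punctuation to spaces, collapse whitespace.
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  stringr::str_squish(x)
}

roman_numerals <- function() {
  tolower(as.character(utils::as.roman(1:20)))
}

# Qualifier token: a number, a roman numeral (i-xx), or a short alphanumeric
# token (length <= max_len containing a digit, or a single letter).
is_qualifier_token <- function(tok, max_len = 2) {
  is_num <- grepl("^[0-9]+$", tok)
  is_roman <- tok %in% roman_numerals()
  short_alnum <- nchar(tok) <= max_len &
    (grepl("[0-9]", tok) | nchar(tok) == 1) &
    grepl("^[a-z0-9]+$", tok)
  is_num | is_roman | short_alnum
}

#' Extract the primary disease phrase from a subtype-qualified name
#'
#' If the normalized name ends with a number, a roman numeral, or a short
#' alphanumeric token, or has `"type"` as its second-last word, the qualifying
#' ending is dropped and the remaining phrase returned; otherwise `NA`.
#'
#' @param name A disease name (scalar or vector).
#' @param cfg A [grouping_config()].
#' @return Character vector of base phrases, `NA` where the name has no
#'   qualifying ending.
#' @export
#' @examples
#' extract_base_phrase("Autism, susceptibility to, 1")
#' extract_base_phrase("mucopolysaccharidosis type II")
#' extract_base_phrase("asthma")
extract_base_phrase <- function(name, cfg = grouping_config()) {
  vapply(name, function(nm) {
    norm <- normalize_name(nm)
    toks <- strsplit(norm, " ", fixed = TRUE)[[1]]
    if (length(toks) < 2) {
      return(NA_character_)
    }
    last <- toks[length(toks)]
    second_last <- toks[length(toks) - 1]
    if (is_qualifier_token(last, cfg$max_suffix_len) || second_last == "type") {
      paste(toks[-length(toks)], collapse = " ")
    } else {
      NA_character_
    }
  }, character(1), USE.NAMES = FALSE)
}

# Word bag used for order-insensitive comparison: tokens of the normalized
# name minus ignored words and qualifier tokens, as a sorted key.
bag_key <- function(norm, cfg) {
  vapply(norm, function(n) {
    toks <- strsplit(n, " ", fixed = TRUE)[[1]]
    toks <- toks[!(toks %in% cfg$ignored_words)]
    toks <- toks[!is_qualifier_token(toks, cfg$max_suffix_len)]
    if (length(toks) == 0) {
      return("")
    }
    paste(sort(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Minimal union-find used for transitive closure of matches.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# Resolve all parents to roots.
uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

#' Group diseases by suffix-driven string matching
#'
#' Stage one of disease entity grouping. Every name with an extractable base
#' phrase seeds a candidate group that collects (a) all names whose normalized
#' form begins with that base phrase and (b) all names whose word bag equals
#' the base phrase's word bag regardless of word order, ignoring the configured
#' words and subtype qualifier tokens. The transitive closure of these matches
#' yields the partition. Names sharing no informative tokens are never merged.
#'
#' @param names A data frame with columns `disease_id`, `name`, or a named
#'   character vector of names keyed by identifier.
#' @param cfg A [grouping_config()].
#' @return An object of class `disease_grouping`: list with `partition`
#'   (tibble `disease_id`, `group_id`), `group_names` (tibble `group_id`,
#'   `group_name`), `members` and `evidence` (tibble of merged pairs with the
#'   rule that joined them).
#' @export
string_match_groups <- function(names, cfg = grouping_config()) {
  if (!is.data.frame(names)) {
    names <- tibble::tibble(disease_id = names(names), name = unname(names))
  }
  names <- tibble::as_tibble(names)
  stopifnot(all(c("disease_id", "name") %in% names(names)))
  n <- nrow(names)
  norm <- normalize_name(names$name)
  base <- extract_base_phrase(names$name, cfg)
  bags <- bag_key(norm, cfg)

  parent <- uf_new(n)
  evidence <- list()
  seeds <- which(!is.na(base))
  for (s in seeds) {
    b <- base[s]
    if (b == "") next
    # (a) initial-phrase rule: normalized name starts with the base phrase
    # on a token boundary
    pref <- which(norm == b | startsWith(norm, paste0(b, " ")))
    # (b) bag rule: equal word bags after dropping ignored/qualifier tokens
    b_bag <- bag_key(b, cfg)
    bagm <- if (b_bag == "") integer(0) else which(bags == b_bag)
    for (m in union(pref, bagm)) {
      if (m == s) next
      # guard: never merge names sharing no normalized tokens
      if (length(intersect(
        strsplit(norm[s], " ")[[1]],
        strsplit(norm[m], " ")[[1]]
      )) == 0) {
        next
      }
      parent <- uf_union(parent, s, m)
      evidence[[length(evidence) + 1]] <- tibble::tibble(
        id_a = names$disease_id[s], id_b = names$disease_id[m],
        rule = if (m %in% pref) "initial-phrase" else "bag-of-words",
        similarity = NA_real_
      )
    }
  }

  roots <- uf_roots(parent)
  build_grouping(names$disease_id, names$name, roots,
    evidence = if (length(evidence)) dplyr::bind_rows(evidence) else NULL
  )
}

# Construct a disease_grouping from ids, names and an integer root labelling.
# Group name: shortest member name (ties by alphabetical order).
# Group id: joined sorted member ids for multi-member groups, the member id
# itself for singletons.
build_grouping <- function(ids, nms, roots, evidence = NULL,
                           group_names = NULL) {
  df <- tibble::tibble(disease_id = ids, name = nms, root = roots)
  grp <- df |>
    dplyr::group_by(.data$root) |>
    dplyr::summarise(
      group_id = if (dplyr::n() == 1) .data$disease_id[1] else {
        paste(sort(.data$disease_id), collapse = "_")
      },
      group_name = .data$name[order(nchar(.data$name), .data$name)][1],
      members = list(sort(.data$disease_id)),
      .groups = "drop"
    )
  if (!is.null(group_names)) {
    idx <- match(grp$group_id, group_names$group_id)
    grp$group_name <- ifelse(is.na(idx), grp$group_name, group_names$group_name[idx])
  }
  partition <- dplyr::left_join(df, grp, by = "root")[, c("disease_id", "group_id")]
  structure(
    list(
      partition = partition,
      group_names = grp[, c("group_id", "group_name")],
      members = grp[, c("group_id", "members")],
      evidence = if (is.null(evidence)) {
        tibble::tibble(
          id_a = character(), id_b = character(),
          rule = character(), similarity = numeric()
        )
      } else {
        evidence
      }
    ),
    class = "disease_grouping"
  )
}

#' @export
print.disease_grouping <- function(x, ...) {
  n_dis <- nrow(x$partition)
  n_grp <- length(unique(x$partition$group_id))
  cat("<disease grouping>", n_dis, "diseases in", n_grp, "groups\n")
  invisible(x)
}

# Representative name used for embedding: the base phrase when the group name
# has one, else the group name itself (stabilizes similarity against suffixes).
group_representatives <- function(grouping, cfg) {
  rep <- extract_base_phrase(grouping$group_names$group_name, cfg)
  ifelse(is.na(rep), normalize_name(grouping$group_names$group_name), rep)
}

#' Refine a grouping with name-embedding similarity
#'
#' Stage two of disease entity grouping. Embeds the representative name of
#' every group, computes pairwise cosine similarity, and emits a merge proposal
#' for every pair at or above the cutoff. Without a review requirement all
#' proposals merge; with `require_review = TRUE` only proposals marked
#' `approve` in the supplied review table are merged, and `assigned_name`
#' overrides the merged group's name.
#'
#' @param grouping A `disease_grouping` from [string_match_groups()].
#' @param embedder A name embedder, e.g. [trigram_embedder()].
#' @param cfg A [grouping_config()].
#' @param review Optional review tibble as written by [write_review_file()]
#'   with a filled `decision` column.
#' @return A list with `grouping` (the refined `disease_grouping`) and
#'   `proposals` (the review tibble: `proposal_id`, `group_a`, `group_b`,
#'   `representative_a`, `representative_b`, `similarity`, `decision`,
#'   `assigned_name`).
#' @export
embedding_refine <- function(grouping, embedder = trigram_embedder(),
                             cfg = grouping_config(), review = NULL) {
  gids <- grouping$group_names$group_id
  reps <- group_representatives(grouping, cfg)
  if (length(gids) < 2) {
    return(list(grouping = grouping, proposals = empty_review()))
  }
  emb <- embed_names(embedder, reps)
  sim <- emb %*% t(emb) # rows are unit vectors -> cosine similarity
  pairs <- which(upper.tri(sim) & sim >= cfg$similarity_cutoff, arr.ind = TRUE)
  proposals <- tibble::tibble(
    proposal_id = seq_len(nrow(pairs)),
    group_a = gids[pairs[, 1]],
    group_b = gids[pairs[, 2]],
    representative_a = reps[pairs[, 1]],
    representative_b = reps[pairs[, 2]],
    similarity = sim[pairs],
    decision = NA_character_,
    assigned_name = NA_character_
  )

  if (!is.null(review)) {
    unknown <- setdiff(
      c(review$group_a, review$group_b),
      grouping$group_names$group_id
    )
    if (length(unknown) > 0) {
      rlang::abort(
        paste0(
          "review file references unknown group id(s): ",
          paste(utils::head(unknown, 5), collapse = ", ")
        ),
        class = "kgcraft_contract_error"
      )
    }
  }

  to_merge <- proposals
  if (cfg$require_review) {
    if (is.null(review)) {
      to_merge <- proposals[0, ]
    } else {
      approved <- review[!is.na(review$decision) & review$decision == "approve", ]
      to_merge <- dplyr::semi_join(
        proposals, approved,
        by = c("group_a", "group_b")
      )
    }
  }

  # merge proposals by union-find over groups, then rebuild over diseases
  parent <- uf_new(length(gids))
  for (k in seq_len(nrow(to_merge))) {
    i <- match(to_merge$group_a[k], gids)
    j <- match(to_merge$group_b[k], gids)
    parent <- uf_union(parent, i, j)
  }
  group_root <- uf_roots(parent)
  dis_group_idx <- match(grouping$partition$group_id, gids)
  dis_root <- group_root[dis_group_idx]

  names_by_id <- grouping$group_names$group_name[dis_group_idx]
  refined <- build_grouping(
    grouping$partition$disease_id, names_by_id, dis_root,
    evidence = dplyr::bind_rows(
      grouping$evidence,
      tibble::tibble(
        id_a = to_merge$group_a, id_b = to_merge$group_b,
        rule = "embedding", similarity = to_merge$similarity
      )
    )
  )

  # names assigned in the review override the shortest-member default; the
  # pre-merge group id is resolved to the refined group through any member
  if (!is.null(review) && any(!is.na(review$assigned_name))) {
    ren <- review[!is.na(review$assigned_name), ]
    for (k in seq_len(nrow(ren))) {
      old <- match(ren$group_a[k], grouping$members$group_id)
      if (is.na(old)) next
      member <- grouping$members$members[[old]][1]
      new_gid <- refined$partition$group_id[
        match(member, refined$partition$disease_id)
      ]
      refined$group_names$group_name[refined$group_names$group_id == new_gid] <-
        ren$assigned_name[k]
    }
  }
  list(grouping = refined, proposals = proposals)
}

empty_review <- function() {
  tibble::tibble(
    proposal_id = integer(), group_a = character(), group_b = character(),
    representative_a = character(), representative_b = character(),
    similarity = numeric(), decision = character(), assigned_name = character()
  )
}

#' Write / read a merge-proposal review file
#'
#' The review file is the machine-readable audit trail replacing interactive
#' approval: proposals are written, decisions (`approve` / `reject`) and
#' optional assigned names are filled in, and the grouping is re-run.
#'
#' @param proposals Proposal tibble from [embedding_refine()].
#' @param path CSV path.
#' @return `write_review_file` returns `path` invisibly; `read_review_file`
#'   returns the review tibble.
#' @export
write_review_file <- function(proposals, path) {
  readr::write_csv(proposals, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_review_file
#' @export
read_review_file <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      proposal_id = readr::col_integer(), similarity = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Full disease-grouping pipeline
#'
#' Runs [string_match_groups()] then [embedding_refine()].
#'
#' @inheritParams string_match_groups
#' @inheritParams embedding_refine
#' @return As [embedding_refine()].
#' @export
group_diseases <- function(names, cfg = grouping_config(),
                           embedder = trigram_embedder(), review = NULL) {
  embedding_refine(string_match_groups(names, cfg), embedder, cfg, review)
}

#' Apply a disease grouping to triples tables
#'
#' Replaces every disease identifier with its group identifier (and the group's
#' display name), deduplicates the resulting edges, and removes (with a log)
#' self-edges created when both endpoints fall into one group.
#'
#' @param kg_tables A triples table.
#' @param grouping A `disease_grouping`; its partition must cover every disease
#'   identifier occurring in the tables.
#' @param grouped_source_suffix Suffix appended to the node source of
#'   multi-member grouped nodes.
#' @return A triples table with a drop log for removed self-edges.
#' @export
apply_grouping <- function(kg_tables, grouping, grouped_source_suffix = "_grouped") {
  t <- kg_tables
  dis_ids <- unique(c(
    t$x_id[t$x_type == "disease"], t$y_id[t$y_type == "disease"]
  ))
  missing_ids <- setdiff(dis_ids, grouping$partition$disease_id)
  if (length(missing_ids) > 0) {
    rlang::abort(
      paste0(
        "disease id(s) missing from partition: ",
        paste(utils::head(missing_ids, 5), collapse = ", ")
      ),
      class = "kgcraft_contract_error"
    )
  }
  gid <- stats::setNames(grouping$partition$group_id, grouping$partition$disease_id)
  gname <- stats::setNames(grouping$group_names$group_name, grouping$group_names$group_id)
  multi <- grouping$members$group_id[
    vapply(grouping$members$members, length, integer(1)) > 1
  ]

  relabel <- function(side) {
    sel <- t[[paste0(side, "_type")]] == "disease"
    old <- t[[paste0(side, "_id")]][sel]
    new <- unname(gid[old])
    t[[paste0(side, "_id")]][sel] <<- new
    t[[paste0(side, "_name")]][sel] <<- unname(gname[new])
    grouped <- sel
    grouped[sel] <- new %in% multi
    src <- t[[paste0(side, "_source")]]
    needs_tag <- grouped & !endsWith(src, grouped_source_suffix)
    t[[paste0(side, "_source")]][needs_tag] <<-
      paste0(src[needs_tag], grouped_source_suffix)
    invisible(NULL)
  }
  relabel("x")
  relabel("y")

  self_loop <- t$x_id == t$y_id & t$x_type == "disease" & t$y_type == "disease"
  loops <- t[self_loop, ]
  t <- t[!self_loop, ]
  out <- dplyr::distinct(
    t, .data$x_id, .data$x_type, .data$relation, .data$y_id, .data$y_type,
    .keep_all = TRUE
  )
  add_drop_log(out, loops, "grouped_self_edge")
}
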