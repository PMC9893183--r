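#' Proximity test configuration
#'
#' @param n_permutations Number of non-indicated diseases sampled for the
#'   permutation null; default 1000.
#' @param alpha Significance level applied to the adjusted p-value; default
#'   0.05.
#' @param ci_level Confidence level for the interval around the null mean;
#'   default 0.95.
#' @param rng_seed Optional integer seed fixing the permutation sampling.
#' @param exclude_direct_pairs Whether pairs already joined by an indication
#'   edge are excluded from testing (reported with their distance but no
#'   p-value); default `TRUE`.
#' @param ci_method `"normal"` (normal-theory interval for the mean,
#'   mean +/- z * sd / sqrt(n)) or `"percentile"` (bootstrap percentile
#'   interval of the sampled mean).
#' @param unreachable How sampled diseases disconnected from the drug enter
#'   the null summary: `"exclude"` (default; excluded from mean/CI, counted
#'   and reported) or a finite numeric sentinel distance.
#' @return A list of class `proximity_config`.
#' @export
proximity_config <- function(n_permutations = 1000, alpha = 0.05,
                             ci_level = 0.95, rng_seed = NULL,
                             exclude_direct_pairs = TRUE,
                             ci_method = c("normal", "percentile"),
                             unreachable = "exclude") {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1)
  structure(
    list(
      n_permutations = as.integer(n_permutations), alpha = alpha,
      ci_level = ci_level, rng_seed = rng_seed,
      exclude_direct_pairs = exclude_direct_pairs,
      ci_method = match.arg(ci_method),
      unreachable = unreachable
    ),
    class = "proximity_config"
  )
}

# Undirected igraph over node indices; vertex names are node_index values.
kg_to_igraph <- function(kg) {
  g <- igraph::graph_from_edgelist(
    cbind(as.character(kg$edges$x_index), as.character(kg$edges$y_index)),
    directed = FALSE
  )
  iso <- setdiff(as.character(kg$nodes$node_index), igraph::V(g)$name)
  if (length(iso) > 0) g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

# BFS hop distances from one node to a set of nodes (or all).
bfs_distances <- function(g, from, to = igraph::V(g)) {
  as.vector(igraph::distances(g, v = as.character(from), to = to, weights = NA))
}

#' Shortest-path hop distance between two nodes
#'
#' Breadth-first hop count on the undirected view of the graph over all
#' relation types; `Inf` when the nodes are in different components, 0 when
#' the nodes coincide.
#'
#' @param kg A `kg` object.
#' @param a,b Node indices.
#' @return A non-negative number, possibly `Inf`.
#' @export
shortest_path_distance <- function(kg, a, b) {
  if (!all(c(a, b) %in% kg$nodes$node_index)) {
    rlang::abort("unknown node index", class = "kgcraft_contract_error")
  }
  g <- kg_to_igraph(kg)
  bfs_distances(g, a, as.character(b))
}

# Candidate diseases for the null: disease nodes without an indication edge
# to the drug, excluding the indicated disease itself.
null_candidates <- function(kg, drug, indicated_disease) {
  diseases <- kg$nodes$node_index[kg$nodes$node_type == "disease"]
  ind_edges <- kg$edges[kg$edges$relation == "indication", ]
  indicated_of_drug <- unique(c(
    ind_edges$y_index[ind_edges$x_index == drug],
    ind_edges$x_index[ind_edges$y_index == drug]
  ))
  setdiff(diseases, c(indicated_of_drug, indicated_disease))
}

#' Sample the permutation null of randomized distances
#'
#' Samples non-indicated diseases for a drug (uniformly without replacement;
#' with replacement only when fewer candidates exist than requested draws) and
#' returns their shortest-path distances to the drug.
#'
#' @param kg A `kg` object.
#' @param drug,indicated_disease Node indices.
#' @param cfg A [proximity_config()].
#' @return Numeric vector of length `n_permutations` (possibly containing
#'   `Inf` for unreachable sampled diseases).
#' @export
permutation_null <- function(kg, drug, indicated_disease,
                             cfg = proximity_config()) {
  candidates <- null_candidates(kg, drug, indicated_disease)
  if (length(candidates) == 0) {
    rlang::abort("no candidate non-indicated diseases",
      class = "kgcraft_contract_error"
    )
  }
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  replace <- length(candidates) < cfg$n_permutations
  sampled <- sample(candidates, cfg$n_permutations, replace = replace)
  g <- kg_to_igraph(kg)
  d_all <- bfs_distances(g, drug, as.character(candidates))
  d_all[match(sampled, candidates)]
}

summarize_null <- function(d_rand, cfg) {
  finite <- if (identical(cfg$unreachable, "exclude")) {
    d_rand[is.finite(d_rand)]
  } else {
    ifelse(is.finite(d_rand), d_rand, as.numeric(cfg$unreachable))
  }
  n <- length(finite)
  m <- mean(finite)
  if (cfg$ci_method == "normal") {
    z <- stats::qnorm(1 - (1 - cfg$ci_level) / 2)
    half <- z * stats::sd(finite) / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    boots <- replicate(1000, mean(sample(finite, n, replace = TRUE)))
    ci <- stats::quantile(boots, c((1 - cfg$ci_level) / 2, 1 - (1 - cfg$ci_level) / 2),
      names = FALSE
    )
  }
  list(mean = m, ci_low = ci[1], ci_high = ci[2], n_unreachable = sum(!is.finite(d_rand)))
}

#' Network-proximity permutation test for drug-disease pairs
#'
#' For each pair, computes the observed shortest-path distance, a permutation
#' null over sampled non-indicated diseases, the null mean with its confidence
#' interval, the add-one-smoothed empirical p-value
#' `p_raw = (1 + #\{d_rand <= d_obs\}) / (n_permutations + 1)`, and a
#' Bonferroni-adjusted p over the pairs actually tested. Pairs already joined
#' by a direct indication edge are flagged and (by default) excluded from
#' testing and from the multiplicity count, mirroring the dash convention for
#' such pairs in reported tables.
#'
#' @param kg A `kg` object.
#' @param pairs Data frame with columns `drug_index` and `disease_index`
#'   (node indices), optionally `drug` and `disease` display names.
#' @param cfg A [proximity_config()].
#' @return A tibble of class `proximity_result` with one row per pair:
#'   `drug`, `disease`, `has_indication_edge`, `d_observed`, `null_mean`,
#'   `ci_low`, `ci_high`, `n_unreachable`, `p_raw`, `p_adjusted`,
#'   `significant`, `n_tested_pairs`.
#' @export
proximity_test <- function(kg, pairs, cfg = proximity_config()) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("drug_index", "disease_index") %in% names(pairs)))
  all_idx <- c(pairs$drug_index, pairs$disease_index)
  if (!all(all_idx %in% kg$nodes$node_index)) {
    rlang::abort("pair references unknown node index",
      class = "kgcraft_contract_error"
    )
  }
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  g <- kg_to_igraph(kg)
  ind_edges <- kg$edges[kg$edges$relation == "indication", ]
  name_of <- stats::setNames(kg$nodes$node_name, kg$nodes$node_index)

  rows <- purrr::pmap(pairs, function(drug_index, disease_index, ...) {
    extra <- list(...)
    direct <- any(
      (ind_edges$x_index == drug_index & ind_edges$y_index == disease_index) |
        (ind_edges$x_index == disease_index & ind_edges$y_index == drug_index)
    )
    d_obs <- bfs_distances(g, drug_index, as.character(disease_index))
    base <- tibble::tibble(
      drug = extra$drug %||% unname(name_of[as.character(drug_index)]),
      disease = extra$disease %||% unname(name_of[as.character(disease_index)]),
      drug_index = drug_index, disease_index = disease_index,
      has_indication_edge = direct, d_observed = d_obs
    )
    if (direct && cfg$exclude_direct_pairs) {
      return(dplyr::mutate(base,
        null_mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_unreachable = NA_integer_, p_raw = NA_real_
      ))
    }
    candidates <- null_candidates(kg, drug_index, disease_index)
    if (length(candidates) == 0) {
      rlang::abort("no candidate non-indicated diseases",
        class = "kgcraft_contract_error"
      )
    }
    replace <- length(candidates) < cfg$n_permutations
    sampled <- sample(candidates, cfg$n_permutations, replace = replace)
    d_cand <- bfs_distances(g, drug_index, as.character(candidates))
    d_rand <- d_cand[match(sampled, candidates)]
    s <- summarize_null(d_rand, cfg)
    dplyr::mutate(base,
      null_mean = s$mean, ci_low = s$ci_low, ci_high = s$ci_high,
      n_unreachable = as.integer(s$n_unreachable),
      p_raw = (1 + sum(d_rand <= d_obs)) / (cfg$n_permutations + 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  m <- sum(!is.na(out$p_raw))
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= cfg$alpha
  out$n_tested_pairs <- m
  attr(out, "config") <- cfg
  class(out) <- c("proximity_result", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a proximity result
#'
#' @param x A `proximity_result`.
#' @param ... Unused.
#' @return The result as a plain tibble, one row per drug-disease pair.
#' @method tidy proximity_result
#' @export
tidy.proximity_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "proximity_result")
  attr(out, "config") <- NULL
  out
}

#' One-row summary of a proximity analysis
#'
#' @param x A `proximity_result`.
#' @param ... Unused.
#' @return A one-row tibble: pairs tested, pairs with direct indication edges,
#'   pairs significant after Bonferroni adjustment, permutations, alpha.
#' @method glance proximity_result
#' @export
glance.proximity_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_pairs = nrow(x),
    n_direct = sum(x$has_indication_edge),
    n_tested = x$n_tested_pairs[1] %||% 0L,
    n_significant = sum(x$significant, na.rm = TRUE),
    n_permutations = cfg$n_permutations,
    alpha = cfg$alpha
  )
}

#' Plot observed distances against the permutation null
#'
#' One row per drug-disease pair: the observed shortest-path distance (point)
#' against the null mean with its confidence interval (bar); significant pairs
#' after Bonferroni adjustment are highlighted.
#'
#' @param object A `proximity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot proximity_result
#' @export
autoplot.proximity_result <- function(object, ...) {
  df <- tidy(object)
  df$pair <- paste(df$drug, "—", df$disease)
  df$pair <- stats::reorder(df$pair, df$d_observed)
  df$status <- dplyr::case_when(
    df$has_indication_edge ~ "direct indication",
    df$significant ~ "significant",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$pair)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.25, colour = "grey50", na.rm = TRUE
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$null_mean),
      shape = 3, colour = "grey40", na.rm = TRUE
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$d_observed, colour = .data$status),
      size = 2.5
    ) +
    ggplot2::labs(
      x = "shortest-path distance (hops)", y = NULL, colour = NULL,
      title = "Observed drug–disease distance vs permutation null"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
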