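# All permutations of 1..n as an (n! x n) integer matrix. Exact Spearman
# inference only calls this for n <= 9.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

#' Spearman rank correlation with exact small-sample inference
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' exact — computed over all n! permutations of one variable — for
#' `n <= 9`, and uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, neither constant.
#' @return List with `rho`, `p`, `n`, and `method` ("exact" or
#'   "t-approximation").
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; rank correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    s <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    mu <- n * mean(rx) * mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_all <- (s - mu) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Keep documents with enough ratings
#'
#' @param documents Character vector of document ids, or a data frame
#'   with an `id` column.
#' @param ratings Data frame with columns `id`, `rating`, `n_ratings`.
#' @param min_ratings Minimum rating count, inclusive (default 5).
#' @return The subset of `documents` whose id has
#'   `n_ratings >= min_ratings`.
#' @export
filter_rated <- function(documents, ratings, min_ratings = 5L) {
  stopifnot(all(c("id", "rating", "n_ratings") %in% names(ratings)))
  ok_ids <- ratings$id[ratings$n_ratings >= min_ratings]
  if (is.data.frame(documents)) {
    documents[documents$id %in% ok_ids, , drop = FALSE]
  } else {
    documents[documents %in% ok_ids]
  }
}

#' Percentile of an empirical value within a null ensemble
#'
#' Fraction of ensemble values strictly below the empirical value, with a
#' midpoint correction for ties, times 100.
#'
#' @param value Empirical scalar.
#' @param ensemble Numeric vector of null values (non-empty).
#' @return Percentile in `[0, 100]`.
#' @export
null_percentile <- function(value, ensemble) {
  if (length(ensemble) == 0L) stop("empty ensemble")
  100 * (sum(ensemble < value) + 0.5 * sum(ensemble == value)) /
    length(ensemble)
}

#' Analyse one document end to end
#'
#' From a tokenized document and its concept index, builds the total
#' network and both filtrations, detects core-periphery and periphery
#' community structure, measures the core/periphery introduction-curve
#' area, and computes persistent homology summaries (interval counts and
#' normalized average cycle lifetimes) for the sentence and one-at-a-time
#' filtrations. Optionally attaches null-ensemble percentiles for the
#' main metrics.
#'
#' @param doc A `tokenized_document`.
#' @param index An `index_set` or character vector of phrases.
#' @param seed Integer seed governing every stochastic step.
#' @param gamma_C,gamma_M Resolutions for core-ness and modularity.
#' @param restarts,runs Optimizer restarts for core-ness and modularity.
#' @param null_size Instantiations per null ensemble (0 disables null
#'   comparisons, the default; 100 is the conventional full-scale
#'   ensemble size).
#' @param stop_list Stop words, required when `null_size > 0` (for the
#'   random index null).
#' @return A `document_summary` list; see [summary_to_json()].
#' @export
analyze_document <- function(doc, index, seed = 1L, gamma_C = 1,
                             gamma_M = 1, restarts = 10L, runs = 10L,
                             null_size = 0L, stop_list = NULL) {
  g <- build_total_network(doc, index)
  fs <- build_sentence_filtration(doc, index)
  fo <- build_oaat_filtration(doc, index)
  cp <- coreness_partition(g, gamma = gamma_C, restarts = restarts,
                           seed = seed)
  pm <- if (length(cp$periphery) >= 1L &&
            igraph::ecount(igraph::induced_subgraph(g, cp$periphery)) >= 1L) {
    periphery_modularity(g, cp, gamma = gamma_M, runs = runs,
                         seed = seed + 1L)
  } else {
    NULL
  }
  area <- if (length(cp$core) >= 1L && length(cp$periphery) >= 1L) {
    curve_area_difference(
      introduction_curves(fs, intersect(cp$core, names(fs$node_birth))),
      introduction_curves(fs, intersect(cp$periphery,
                                        names(fs$node_birth))))
  } else {
    NA_real_
  }
  bc_s <- persistent_homology(fs)
  bc_o <- persistent_homology(fo)
  life_s <- normalized_cycle_lifetime(bc_s)
  life_o <- normalized_cycle_lifetime(bc_o)
  out <- list(
    source_id = doc$source_id,
    n_sentences = doc$n_sentences,
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = if (igraph::vcount(g) >= 2L) {
      igraph::edge_density(g)
    } else {
      NA_real_
    },
    coreness = cp$coreness,
    core_size = length(cp$core),
    periphery_modularity = if (is.null(pm)) NA_real_ else pm$modularity,
    n_periphery_communities = if (is.null(pm)) NA_integer_
                              else pm$n_communities,
    core_periphery_area = area,
    sentence = list(m = as.list(life_s$m), D = as.list(life_s$D),
                    D_mean = life_s$mean, n_steps = life_s$n_steps),
    oaat = list(m = as.list(life_o$m), D = as.list(life_o$D),
                D_mean = life_o$mean, n_steps = life_o$n_steps),
    seed = seed
  )
  if (null_size > 0L) {
    if (is.null(stop_list)) {
      stop("stop_list is required when null ensembles are requested")
    }
    d1_total <- function(f) {
      unname(interval_counts(persistent_homology(f))["m_1"])
    }
    d0_life <- function(f) {
      unname(normalized_cycle_lifetime(persistent_homology(f))$D["D_0"])
    }
    ens_edge <- build_ensemble(
      "random_edge", list(g = g),
      metrics = list(m_1 = d1_total, D_0 = d0_life),
      size = null_size, master_seed = seed * 1000L
    )
    ens_sent <- build_ensemble(
      "random_sentence", list(doc = doc, index = index),
      metrics = list(D_0 = d0_life),
      size = null_size, master_seed = seed * 1000L + null_size
    )
    emp_m1 <- unname(interval_counts(bc_s)["m_1"])
    emp_d0 <- unname(life_s$D["D_0"])
    out$null_percentiles <- list(
      m_1_vs_random_edge = null_percentile(emp_m1, ens_edge$metrics$m_1),
      D_0_vs_random_edge = null_percentile(emp_d0, ens_edge$metrics$D_0),
      D_0_vs_random_sentence = null_percentile(emp_d0,
                                               ens_sent$metrics$D_0)
    )
  }
  class(out) <- "document_summary"
  out
}

#' Serialize a document summary to canonical JSON
#'
#' Deterministic: two analyses run with identical inputs and seeds
#' serialize byte-identically.
#'
#' @param x A `document_summary` (or any list of scalars/lists).
#' @param path Optional output path; when supplied the JSON is written
#'   there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
summary_to_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Correlate a per-document metric with user-supplied ratings
#'
#' Joins a metric table with a ratings table (documents with fewer than
#' `min_ratings` ratings are dropped) and reports the Spearman rank
#' correlation.
#'
#' @param metrics Data frame with columns `id` and `value`.
#' @param ratings Data frame with columns `id`, `rating`, `n_ratings`.
#' @param min_ratings Minimum rating count (default 5).
#' @return List with `rho`, `p`, `n`, `method`, and the joined data in
#'   `data`.
#' @export
rating_correlation <- function(metrics, ratings, min_ratings = 5L) {
  kept <- filter_rated(ratings, ratings, min_ratings)
  joined <- merge(metrics, kept, by = "id")
  if (nrow(joined) < 3L) {
    stop("fewer than 3 rated documents after filtering")
  }
  res <- spearman(joined$value, joined$rating)
  res$data <- joined
  res
}
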