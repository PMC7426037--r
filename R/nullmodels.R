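# Eligible word types for the random index null: any token that is not a
# stop word and not one of the placeholders.
eligible_word_types <- function(doc, stop_list) {
  toks <- unique(unlist(doc$sentences, use.names = FALSE))
  sort(setdiff(toks, c(stop_list, "#", "VAR")))
}

#' Random index null model
#'
#' Bypasses keyphrase extraction: samples `n` distinct eligible word types
#' (not stop words, not placeholders) uniformly at random to serve as the
#' index set, then builds the total network and expositional filtration
#' exactly as for the empirical index. Acts as a null for both the total
#' network and the filtration.
#'
#' @param doc A `tokenized_document`.
#' @param n Number of word types to sample.
#' @param stop_list Character vector of stop words.
#' @param seed Integer seed, or `NULL`.
#' @return List with `network` (weighted `igraph`), `filtration` (kind
#'   `"random_index"`), and `index` (the sampled word types).
#' @export
random_index_filtration <- function(doc, n, stop_list, seed = NULL) {
  pool <- eligible_word_types(doc, stop_list)
  if (n < 1L) stop("index size n must be >= 1")
  if (length(pool) < n) {
    stop(sprintf("only %d eligible word types available (%d requested)",
                 length(pool), n))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  idx <- sort(sample(pool, n))
  f <- build_sentence_filtration(doc, idx)
  f$kind <- "random_index"
  list(network = build_total_network(doc, idx), filtration = f,
       index = idx)
}

#' Random sentence-order null model
#'
#' Rebuilds the sentence filtration after a uniform random permutation of
#' sentence order, keeping sub-sentence structure intact. The total
#' weighted network is invariant under this permutation; only introduction
#' times change.
#'
#' @param doc A `tokenized_document`.
#' @param index An `index_set` or character vector of phrases.
#' @param seed Integer seed, or `NULL`.
#' @return A `filtration` with `kind = "random_sentence"`.
#' @export
random_sentence_filtration <- function(doc, index, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  perm <- sample.int(doc$n_sentences)
  shuffled <- structure(
    list(sentences = doc$sentences[perm], n_sentences = doc$n_sentences,
         source_id = doc$source_id),
    class = "tokenized_document"
  )
  f <- build_sentence_filtration(shuffled, index)
  f$kind <- "random_sentence"
  f
}

#' Continuous configuration null model
#'
#' Rewires the network with degree-preserving double-edge swaps (10 |E|
#' attempted swaps; swaps creating self-loops or multi-edges are rejected)
#' and then reassigns the original weight multiset to the rewired edges so
#' as to approximate the original node strengths: edges are sorted by the
#' sum of their endpoints' target strengths and the largest weights are
#' assigned first. The degree sequence and the weight multiset are
#' preserved exactly; strengths approximately.
#'
#' @param g Weighted `igraph` graph with `|E| >= 2`.
#' @param seed Integer seed, or `NULL`.
#' @return A weighted `igraph` graph; attribute `n_swaps` records the
#'   number of successful swaps (a warning is issued when none were
#'   possible).
#' @export
continuous_configuration <- function(g, seed = NULL) {
  m <- igraph::ecount(g)
  if (m < 2L) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, m)
  edge_set <- new.env(parent = emptyenv(), size = 2L * m)
  for (i in seq_len(m)) {
    edge_set[[paste(min(el[i, ]), max(el[i, ]))]] <- TRUE
  }
  n_swaps <- 0L
  for (attempt in seq_len(10L * m)) {
    ij <- sample.int(m, 2L)
    a <- el[ij[1L], ]; b <- el[ij[2L], ]
    # orientation: swap partners (a1-b2, b1-a2); flip b half the time
    if (stats::runif(1) < 0.5) b <- rev(b)
    new1 <- c(a[1L], b[2L]); new2 <- c(b[1L], a[2L])
    if (new1[1L] == new1[2L] || new2[1L] == new2[2L]) next
    k1 <- paste(min(new1), max(new1)); k2 <- paste(min(new2), max(new2))
    if (!is.null(edge_set[[k1]]) || !is.null(edge_set[[k2]]) || k1 == k2) next
    rm(list = c(paste(min(a), max(a)), paste(min(b), max(b))),
       envir = edge_set)
    edge_set[[k1]] <- TRUE
    edge_set[[k2]] <- TRUE
    el[ij[1L], ] <- new1
    el[ij[2L], ] <- new2
    n_swaps <- n_swaps + 1L
  }
  if (n_swaps == 0L) {
    warning("no degree-preserving swap was possible; returning a copy")
  }
  # strength-targeted weight reassignment: heaviest weights to the edges
  # whose endpoints have the largest combined target strength
  target_s <- igraph::strength(g, weights = w)
  pair_target <- target_s[el[, 1L]] + target_s[el[, 2L]]
  ord_edges <- order(-pair_target, el[, 1L], el[, 2L])
  new_w <- w
  new_w[ord_edges] <- sort(w, decreasing = TRUE)
  out <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(out)$name <- nodes
  out <- igraph::add_edges(out, t(el), attr = list(weight = new_w))
  attr(out, "n_swaps") <- n_swaps
  out
}

#' Random edge-order null model
#'
#' Reorders the introduction of the empirical edges uniformly at random:
#' edge i of the permutation is born at step i, each node is born with its
#' first incident edge, and `N = |E|`. Mimics totally random exposition of
#' the final network.
#'
#' @param g Binary undirected `igraph` graph, `|E| >= 1` (weights, if
#'   present, are ignored).
#' @param seed Integer seed, or `NULL`.
#' @return A `filtration` with `kind = "random_edge"`. Isolated vertices
#'   of `g` are dropped (they have no incident edge to be born with).
#' @export
random_edge_filtration <- function(g, seed = NULL) {
  m <- igraph::ecount(g)
  if (m < 1L) stop("need at least 1 edge")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  el <- igraph::as_edgelist(g)
  perm <- sample.int(m)
  el <- el[perm, , drop = FALSE]
  births <- seq_len(m)
  node_first <- tapply(rep(births, 2L), c(el[, 1L], el[, 2L]), min)
  nb <- as.integer(node_first)
  names(nb) <- names(node_first)
  new_filtration(nb,
                 data.frame(u = el[, 1L], v = el[, 2L], birth = births,
                            stringsAsFactors = FALSE),
                 n_steps = m, kind = "random_edge")
}

#' Node-ordered null model
#'
#' Adds nodes one per step in the given order; when a node arrives, every
#' edge from it to already-present nodes arrives at the same step. Mimics
#' an exposition that immediately connects each new concept to everything
#' previously related. `N = |V|`.
#'
#' @param g Binary undirected `igraph` graph.
#' @param node_order Character vector: a permutation of the vertex names
#'   of `g` (e.g. by first mention in the exposition).
#' @return A `filtration` with `kind = "node_ordered"`.
#' @export
node_ordered_filtration <- function(g, node_order) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (length(node_order) != length(nodes) ||
      !setequal(node_order, nodes) || anyDuplicated(node_order)) {
    stop("node_order must be a permutation of the vertex set")
  }
  pos <- seq_along(node_order)
  names(pos) <- node_order
  el <- igraph::as_edgelist(g)
  nb <- pos[nodes]
  if (nrow(el)) {
    eb <- data.frame(u = el[, 1L], v = el[, 2L],
                     birth = pmax(pos[el[, 1L]], pos[el[, 2L]]),
                     stringsAsFactors = FALSE)
  } else {
    eb <- data.frame(u = character(0), v = character(0),
                     birth = integer(0))
  }
  new_filtration(nb, eb, n_steps = length(nodes), kind = "node_ordered")
}

#' Build a null-model ensemble
#'
#' Runs `size` seeded instantiations of a null model and evaluates a set
#' of metric functions on each, collecting per-instance values and
#' distribution summaries. Per-instance seeds are `master_seed + i` for
#' instance i, so reruns with the same master seed are identical.
#'
#' @param model One of `"random_index"`, `"random_sentence"`,
#'   `"continuous_configuration"`, `"random_edge"`, `"node_ordered"`.
#'   (The node-ordered model is deterministic given the exposition; its
#'   ensemble has a single effective instance repeated.)
#' @param inputs Named list of base inputs for the model: `doc`,
#'   `stop_list`, `n` (random_index); `doc`, `index` (random_sentence);
#'   `g` (continuous_configuration, random_edge); `g`, `node_order`
#'   (node_ordered).
#' @param metrics Named list of pure functions, each taking the model
#'   output (a `filtration`, or an `igraph` for
#'   continuous_configuration) and returning a single number.
#' @param size Ensemble size (default 100).
#' @param master_seed Integer master seed (default 1).
#' @return A `null_ensemble`: list with `model`, `size`, `seeds`,
#'   `metrics` (data frame instance x metric), and `summary` (mean, sd,
#'   quantiles per metric).
#' @export
build_ensemble <- function(model = c("random_index", "random_sentence",
                                     "continuous_configuration",
                                     "random_edge", "node_ordered"),
                           inputs, metrics, size = 100L,
                           master_seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(metrics) >= 1L, !is.null(names(metrics)))
  seeds <- master_seed + seq_len(size)
  draw <- switch(
    model,
    random_index = function(s) {
      random_index_filtration(inputs$doc, inputs$n, inputs$stop_list,
                              seed = s)$filtration
    },
    random_sentence = function(s) {
      random_sentence_filtration(inputs$doc, inputs$index, seed = s)
    },
    continuous_configuration = function(s) {
      continuous_configuration(inputs$g, seed = s)
    },
    random_edge = function(s) random_edge_filtration(inputs$g, seed = s),
    node_ordered = function(s) {
      node_ordered_filtration(inputs$g, inputs$node_order)
    }
  )
  vals <- matrix(NA_real_, nrow = size, ncol = length(metrics),
                 dimnames = list(NULL, names(metrics)))
  for (i in seq_len(size)) {
    inst <- tryCatch(draw(seeds[i]), error = function(e) {
      stop(sprintf("null-model instance failed (model %s, seed %d): %s",
                   model, seeds[i], conditionMessage(e)))
    })
    for (mn in names(metrics)) {
      vals[i, mn] <- as.numeric(metrics[[mn]](inst))
    }
  }
  metr <- as.data.frame(vals)
  summ <- lapply(metr, function(x) {
    c(mean = mean(x), sd = stats::sd(x),
      stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  })
  structure(list(model = model, size = size, seeds = seeds,
                 metrics = metr, summary = summ),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble '%s': %d instances, metrics: %s>\n",
              x$model, x$size, paste(names(x$metrics), collapse = ", ")))
  invisible(x)
}
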