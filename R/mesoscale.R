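weight_matrix <- function(g) {
  if (igraph::ecount(g) > 0 && !is.null(igraph::E(g)$weight)) {
    igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  } else {
    igraph::as_adjacency_matrix(g, sparse = FALSE)
  }
}

#' Core-ness quality of a core/periphery assignment
#'
#' Evaluates the quality function
#' `Q_C = (1/v_C) (sum_{i,j in core} (w_ij - gamma*wbar)
#'               - sum_{i,j in periphery} (w_ij - gamma*wbar))`,
#' with sums over ordered off-diagonal pairs, `wbar` the mean weight over
#' all ordered off-diagonal node pairs (absent edges count as weight 0),
#' and `v_C = sum_{i != j} |w_ij - gamma*wbar|` so that `|Q_C| <= 1`.
#' Because the normalization is convention-dependent, absolute values are
#' implementation-relative; comparisons across partitions or against null
#' ensembles within one implementation are the meaningful quantities.
#'
#' @param g Weighted `igraph` graph.
#' @param core Character vector (vertex names) or logical/integer vector
#'   marking the core.
#' @param gamma Resolution controlling core size (default 1).
#' @return The scalar Q_C.
#' @export
coreness_quality <- function(g, core, gamma = 1) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("graph must have at least 2 nodes")
  if (igraph::ecount(g) == 0L) return(0)
  W <- weight_matrix(g)
  if (is.character(core)) core <- rownames(W) %in% core
  core <- as.logical(core)
  B <- W - gamma * sum(W) / (n * (n - 1))
  diag(B) <- 0
  v <- sum(abs(B))
  if (v == 0) return(0)
  cc <- sum(B[core, core])
  pp <- sum(B[!core, !core])
  (cc - pp) / v
}

#' Detect core-periphery structure by quality maximization
#'
#' Maximizes [coreness_quality()] with seeded greedy label switching from
#' `restarts` random initial assignments: at each step the single
#' core/periphery flip with the largest quality gain is applied until no
#' flip improves. (For this pairwise quality the objective is linear in
#' the core indicator, so the greedy reaches the global optimum — the
#' strength-threshold rule — from any start; the exhaustive-search tests
#' confirm this.)
#'
#' @param g Weighted `igraph` graph, `|V| >= 2`.
#' @param gamma Resolution (default 1); larger values shrink the core.
#' @param restarts Number of random initializations (default 10).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A `core_periphery` object: list with `core` and `periphery`
#'   (vertex name vectors), `coreness` (Q_C), `gamma`, `v_C`, `wbar`.
#' @export
coreness_partition <- function(g, gamma = 1, restarts = 10L, seed = NULL) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("graph must have at least 2 nodes")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (igraph::ecount(g) == 0L) {
    return(structure(list(core = character(0), periphery = nodes,
                          coreness = 0, gamma = gamma, v_C = 0, wbar = 0),
                     class = "core_periphery"))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  W <- weight_matrix(g)
  wbar <- sum(W) / (n * (n - 1))
  B <- W - gamma * wbar
  diag(B) <- 0
  v <- sum(abs(B))
  if (v == 0) {
    # uniform complete graph: every partition scores 0; all-core by
    # convention (the densest admissible core)
    return(structure(list(core = nodes, periphery = character(0),
                          coreness = 0, gamma = gamma, v_C = 0,
                          wbar = wbar),
                     class = "core_periphery"))
  }
  best_q <- -Inf
  best_core <- logical(n)
  for (r in seq_len(restarts)) {
    cvec <- stats::runif(n) < 0.5
    repeat {
      row_c <- as.vector(B %*% cvec)
      row_p <- as.vector(B %*% (!cvec))
      delta <- ifelse(cvec, -2 * (row_c + row_p), 2 * (row_c + row_p))
      i <- which.max(delta)
      if (delta[i] <= 1e-12) break
      cvec[i] <- !cvec[i]
    }
    q <- (sum(B[cvec, cvec]) - sum(B[!cvec, !cvec])) / v
    if (q > best_q + 1e-15) {
      best_q <- q
      best_core <- cvec
    }
  }
  structure(list(core = nodes[best_core], periphery = nodes[!best_core],
                 coreness = best_q, gamma = gamma, v_C = v, wbar = wbar),
            class = "core_periphery")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.core_periphery <- function(x, ...) {
  cat(sprintf("<core_periphery: %d core, %d periphery, Q_C = %.4f (gamma = %g)>\n",
              length(x$core), length(x$periphery), x$coreness, x$gamma))
  invisible(x)
}

#' Modularity of a community assignment
#'
#' Evaluates
#' `Q_M = (1/v_M) sum_{i != j, same community} (w_ij - gamma*s_i*s_j/v_M)`
#' with `v_M = 2m`, the total weight over ordered pairs (the Newman
#' convention), and `s_i` the node strengths. Diagonal terms are excluded
#' (the graphs carry no self-loops); this shifts Q by a partition-independent
#' constant relative to conventions that include them, so optima coincide.
#'
#' @param g Weighted `igraph` graph.
#' @param membership Named vector (vertex name -> community id) or vector
#'   in vertex order.
#' @param gamma Resolution (default 1).
#' @return The scalar Q_M.
#' @export
modularity_quality <- function(g, membership, gamma = 1) {
  if (igraph::ecount(g) == 0L) return(0)
  nodes <- igraph::V(g)$name
  if (!is.null(names(membership))) membership <- membership[nodes]
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  v <- 2 * sum(w)
  s <- igraph::strength(g, weights = w)
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- membership[el[, 1L]] == membership[el[, 2L]]
  internal <- 2 * sum(w[same])
  q <- internal / v
  for (comm in unique(membership)) {
    sc <- s[membership == comm]
    q <- q - gamma * (sum(sc)^2 - sum(sc^2)) / v^2
  }
  unname(q)
}

# Greedy single-node refinement: move nodes (including to fresh singleton
# communities) while any move raises Q_M. Polishes the Louvain result out
# of shallow local optima; cheap relative to the main pass.
refine_membership <- function(g, memb, gamma) {
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  el <- igraph::as_edgelist(g, names = FALSE)
  s <- as.numeric(igraph::strength(g, weights = w))
  v <- 2 * sum(w)
  nbr <- vector("list", n)
  for (e in seq_along(w)) {
    i <- el[e, 1L]; j <- el[e, 2L]
    nbr[[i]] <- rbind(nbr[[i]], c(j, w[e]))
    nbr[[j]] <- rbind(nbr[[j]], c(i, w[e]))
  }
  memb <- as.integer(factor(memb))
  S <- tapply(s, memb, sum)
  comm_ids <- as.integer(names(S))
  Svec <- rep(0, max(memb) + n)
  Svec[comm_ids] <- S
  next_free <- max(memb) + 1L
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- memb[i]
      ws <- nbr[[i]]
      w_to <- if (is.null(ws)) numeric(0) else {
        tapply(ws[, 2L], memb[ws[, 1L]], sum)
      }
      w_ia <- if (as.character(a) %in% names(w_to)) {
        w_to[[as.character(a)]]
      } else 0
      base <- -2 * w_ia + gamma * 2 * s[i] * (Svec[a] - s[i]) / v
      cand <- setdiff(as.integer(names(w_to)), a)
      gains <- vapply(cand, function(b) {
        base + 2 * w_to[[as.character(b)]] -
          gamma * 2 * s[i] * Svec[b] / v
      }, numeric(1))
      # fresh singleton community
      cand <- c(cand, next_free)
      gains <- c(gains, base)
      k <- which.max(gains)
      if (gains[k] > 1e-12) {
        b <- cand[k]
        Svec[a] <- Svec[a] - s[i]
        Svec[b] <- Svec[b] + s[i]
        memb[i] <- b
        if (b == next_free) next_free <- next_free + 1L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

#' Detect community structure by seeded multi-run greedy optimization
#'
#' Runs a Louvain-family locally greedy modularity optimizer (igraph's
#' Leiden implementation with the modularity objective) `runs` times under
#' random vertex permutations, polishes each result with greedy
#' single-node moves, and returns the partition with the highest
#' [modularity_quality()] at resolution `gamma`.
#'
#' @param g Weighted `igraph` graph with at least one edge (an edgeless
#'   graph returns singleton communities with Q_M = 0).
#' @param gamma Resolution (default 1); larger values yield smaller
#'   communities.
#' @param runs Number of randomized runs (default 10).
#' @param seed Integer seed, or `NULL`.
#' @return A `community_partition` object: list with `membership` (named
#'   integer vector), `modularity` (Q_M), `gamma`, `n_communities`.
#' @export
modularity_partition <- function(g, gamma = 1, runs = 10L, seed = NULL) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(n))
    igraph::V(g)$name <- nodes
  }
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(n)
    names(memb) <- nodes
    return(structure(list(membership = memb, modularity = 0, gamma = gamma,
                          n_communities = n),
                     class = "community_partition"))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  w <- igraph::E(g)$weight
  if (is.null(w)) {
    w <- rep(1, igraph::ecount(g))
    igraph::E(g)$weight <- w
  }
  best_q <- -Inf
  best_memb <- NULL
  for (r in seq_len(runs)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_leiden(gp, objective_function = "modularity",
                                 weights = igraph::E(gp)$weight,
                                 resolution = gamma, n_iterations = 10L)
    memb <- igraph::membership(cl)[nodes]
    memb <- stats::setNames(refine_membership(g, memb, gamma), nodes)
    q <- modularity_quality(g, memb, gamma)
    if (q > best_q + 1e-15) {
      best_q <- q
      best_memb <- memb
    }
  }
  memb <- as.integer(factor(best_memb, levels = unique(best_memb)))
  names(memb) <- nodes
  structure(list(membership = memb, modularity = best_q, gamma = gamma,
                 n_communities = length(unique(memb))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: %d communities, Q_M = %.4f (gamma = %g)>\n",
              x$n_communities, x$modularity, x$gamma))
  invisible(x)
}

#' Community structure of the periphery subnetwork
#'
#' Applies [modularity_partition()] to the subgraph induced by the
#' periphery of a core-periphery partition (edges with both endpoints in
#' the periphery, weights retained).
#'
#' @param g Weighted `igraph` graph.
#' @param cp A `core_periphery` partition of `g`.
#' @inheritParams modularity_partition
#' @return A `community_partition` on the periphery nodes.
#' @export
periphery_modularity <- function(g, cp, gamma = 1, runs = 10L,
                                 seed = NULL) {
  stopifnot(inherits(cp, "core_periphery"))
  if (length(cp$periphery) == 0L) {
    stop("periphery is empty; no subnetwork to partition")
  }
  sub <- igraph::induced_subgraph(g, cp$periphery)
  modularity_partition(sub, gamma = gamma, runs = runs, seed = seed)
}

#' Introduction curve of a node or edge group
#'
#' The fraction of the group introduced by each filtration step, as a
#' piecewise-constant nondecreasing curve on the normalized step grid
#' `t = k/N`.
#'
#' @param f A `filtration`.
#' @param group For `element = "node"`, a character vector of concepts in
#'   `f`; for `element = "edge"`, an integer vector of row indices into
#'   `f$edge_birth` or a data frame with columns `u`, `v`.
#' @param element `"node"` (default) or `"edge"`.
#' @return An `introduction_curve`: data frame with columns `step`
#'   (0..N), `t` (step/N) and `fraction`, plus attributes `n_steps` and
#'   `group_size`.
#' @export
introduction_curves <- function(f, group, element = c("node", "edge")) {
  element <- match.arg(element)
  stopifnot(inherits(f, "filtration"))
  if (element == "node") {
    if (length(group) == 0L) stop("empty group")
    if (!all(group %in% names(f$node_birth))) {
      stop("group contains concepts absent from the filtration")
    }
    births <- unname(f$node_birth[group])
  } else {
    if (is.data.frame(group)) {
      keys <- sorted_pair_keys(group$u, group$v)
      idx <- match(keys, sorted_pair_keys(f$edge_birth$u, f$edge_birth$v))
      if (anyNA(idx)) stop("group contains edges absent from the filtration")
    } else {
      idx <- as.integer(group)
    }
    if (length(idx) == 0L) stop("empty group")
    births <- f$edge_birth$birth[idx]
  }
  N <- f$n_steps
  counts <- cumsum(tabulate(births, nbins = N))
  curve <- data.frame(step = 0:N, t = (0:N) / N,
                      fraction = c(0, counts / length(births)))
  attr(curve, "n_steps") <- N
  attr(curve, "group_size") <- length(births)
  class(curve) <- c("introduction_curve", "data.frame")
  curve
}

#' Area between two introduction curves
#'
#' Step-function integral over normalized time of (first minus second):
#' `(1/N) * sum_k (curve1(k) - curve2(k))`. Positive when the first group
#' (typically the core) is introduced earlier than the second.
#'
#' @param curve1,curve2 `introduction_curve` objects on the same step
#'   grid.
#' @return Signed area, a real in `[-1, 1]`.
#' @export
curve_area_difference <- function(curve1, curve2) {
  n1 <- attr(curve1, "n_steps")
  n2 <- attr(curve2, "n_steps")
  if (is.null(n1) || is.null(n2) || n1 != n2) {
    stop("curves are not on the same step grid")
  }
  keep <- curve1$step >= 1L
  mean(curve1$fraction[keep] - curve2$fraction[keep])
}

#' Edge-class introduction curves
#'
#' Classifies every filtration edge by the meso-scale roles of its
#' endpoints — core-core, core-periphery, within a single periphery
#' community, or between periphery communities — and returns the
#' introduction curve of each non-empty class.
#'
#' @param f A `filtration`.
#' @param cp A `core_periphery` partition covering the nodes of `f`.
#' @param comm A `community_partition` of the periphery.
#' @return Named list of `introduction_curve`s, with names among
#'   `"core-core"`, `"core-periphery"`, `"periphery-within"`,
#'   `"periphery-between"`; empty classes are omitted (with a message).
#' @export
edge_group_curves <- function(f, cp, comm) {
  stopifnot(inherits(cp, "core_periphery"),
            inherits(comm, "community_partition"))
  eb <- f$edge_birth
  if (nrow(eb) == 0L) stop("filtration has no edges")
  u_core <- eb$u %in% cp$core
  v_core <- eb$v %in% cp$core
  cls <- character(nrow(eb))
  cls[u_core & v_core] <- "core-core"
  cls[xor(u_core, v_core)] <- "core-periphery"
  both_p <- !u_core & !v_core
  if (any(both_p)) {
    mu <- comm$membership[eb$u[both_p]]
    mv <- comm$membership[eb$v[both_p]]
    cls[both_p] <- ifelse(!is.na(mu) & !is.na(mv) & mu == mv,
                          "periphery-within", "periphery-between")
  }
  out <- list()
  for (class_name in c("core-core", "core-periphery",
                       "periphery-within", "periphery-between")) {
    idx <- which(cls == class_name)
    if (length(idx) == 0L) {
      message("edge class '", class_name, "' is empty; omitted")
      next
    }
    out[[class_name]] <- introduction_curves(f, idx, element = "edge")
  }
  out
}

#' One-sample t-test against mean zero
#'
#' Standard two-sided one-sample t-test of the hypothesis that the values
#' are drawn from a distribution with mean 0.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @return List with elements `t`, `p`, `df`, `mean`.
#' @export
one_sample_ttest <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance; t statistic undefined")
  ht <- stats::t.test(values, mu = 0, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = unname(ht$estimate))
}
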