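# Internal: enumerate cliques of the final graph of a filtration and stamp
# each simplex with the step at which all of its vertices and edges exist.
# Returns list(verts = list of sorted integer vertex ids (1-based),
# filt = numeric, dim = integer, nodes = vertex names).
filtration_simplices <- function(f, max_dim = 3L) {
  nodes <- names(f$node_birth)
  n <- length(nodes)
  g <- filtration_graph(f)
  eb <- f$edge_birth
  ui <- match(eb$u, nodes)
  vi <- match(eb$v, nodes)
  ekey <- paste(pmin(ui, vi), pmax(ui, vi))
  ebirth <- as.numeric(eb$birth)
  names(ebirth) <- ekey

  verts <- as.list(seq_len(n))
  filt <- as.numeric(f$node_birth)
  dims <- rep(0L, n)

  if (nrow(eb)) {
    verts <- c(verts, lapply(seq_len(nrow(eb)), function(i) {
      sort(c(ui[i], vi[i]))
    }))
    filt <- c(filt, ebirth)
    dims <- c(dims, rep(1L, nrow(eb)))
    for (size in seq(3L, max_dim + 1L)) {
      if (size > n) break
      cl <- igraph::cliques(g, min = size, max = size)
      if (length(cl) == 0L) next
      mat <- vapply(cl, function(x) sort(as.integer(x)), integer(size))
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = size)
      pair_idx <- utils::combn(size, 2L)
      cf <- rep(0, ncol(mat))
      for (p in seq_len(ncol(pair_idx))) {
        a <- mat[pair_idx[1L, p], ]
        b <- mat[pair_idx[2L, p], ]
        cf <- pmax(cf, ebirth[paste(pmin(a, b), pmax(a, b))])
      }
      verts <- c(verts, lapply(seq_len(ncol(mat)), function(i) mat[, i]))
      filt <- c(filt, cf)
      dims <- c(dims, rep(size - 1L, ncol(mat)))
    }
  }
  list(verts = verts, filt = filt, dim = dims, nodes = nodes)
}

#' Clique complex of a binary graph
#'
#' Assigns a k-simplex to every (k+1)-clique of the graph, for cliques up
#' to size `max_dim + 1`. When node and edge births are supplied each
#' simplex is stamped with the maximum birth over its constituent vertices
#' and edges (the step at which the clique is complete); otherwise all
#' stamps are 1.
#'
#' @param g Undirected `igraph` graph without self-loops.
#' @param max_dim Maximum simplex dimension (default 3, the dimension
#'   needed for homology through dimension 2).
#' @param node_birth,edge_birth Optional births as in a [new_filtration()].
#' @return Data frame with columns `dim`, `filt`, and `vertices` (a
#'   comma-separated vertex-name string per simplex).
#' @export
clique_complex <- function(g, max_dim = 3L, node_birth = NULL,
                           edge_birth = NULL) {
  stopifnot(max_dim <= 3L)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (is.null(node_birth)) {
    node_birth <- rep(1L, length(nodes))
    names(node_birth) <- nodes
  }
  if (is.null(edge_birth)) {
    el <- igraph::as_edgelist(g)
    edge_birth <- data.frame(u = el[, 1L], v = el[, 2L],
                             birth = rep(1L, nrow(el)),
                             stringsAsFactors = FALSE)
  }
  f <- new_filtration(node_birth, edge_birth,
                      n_steps = max(1L, node_birth, edge_birth$birth),
                      kind = "static")
  sx <- filtration_simplices(f, max_dim = max_dim)
  data.frame(
    dim = sx$dim,
    filt = sx$filt,
    vertices = vapply(sx$verts, function(v) {
      paste(sx$nodes[v], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Persistent homology of the clique-complex filtration
#'
#' Computes the barcode (dimensions 0 through `max_hom_dim`) of the
#' sequence of clique complexes of a growing graph, over Z/2 coefficients.
#' Each simplex enters at the step at which its last vertex or edge is
#' introduced. Interval deaths use the half-open convention `[b, d)`: the
#' cavity exists at step `d - 1` and is filled at `d`. Cavities still open
#' in the final graph have death `Inf`. Zero-length intervals (`b == d`)
#' represent no lived cavity and are dropped by default.
#'
#' @param f A `filtration`.
#' @param max_hom_dim Highest homology dimension (default 2; cliques up to
#'   size `max_hom_dim + 2` are enumerated).
#' @param drop_zero Drop zero-length intervals (default TRUE).
#' @return A `barcode`: data frame with columns `dim`, `birth`, `death`
#'   (possibly `Inf`), attribute `n_steps`, sorted by (dim, birth, death).
#' @export
persistent_homology <- function(f, max_hom_dim = 2L, drop_zero = TRUE) {
  validate_filtration(f)
  stopifnot(max_hom_dim >= 0L, max_hom_dim <= 2L)
  sx <- filtration_simplices(f, max_dim = max_hom_dim + 1L)
  ord <- order(sx$filt, sx$dim,
               vapply(sx$verts, function(v) {
                 sum(v * 65536^(rev(seq_along(v)) - 1))
               }, numeric(1)))
  verts0 <- lapply(sx$verts[ord], function(v) v - 1L)
  lens <- lengths(verts0)
  offsets <- c(0L, cumsum(lens))
  res <- .reduce_filtration(as.integer(unlist(verts0)),
                            as.integer(offsets),
                            as.numeric(sx$filt[ord]),
                            as.integer(max_hom_dim),
                            isTRUE(drop_zero))
  bc <- data.frame(dim = as.integer(res[, 1L]), birth = res[, 2L],
                   death = res[, 3L])
  bc <- bc[order(bc$dim, bc$birth, bc$death), , drop = FALSE]
  rownames(bc) <- NULL
  attr(bc, "n_steps") <- f$n_steps
  class(bc) <- c("barcode", "data.frame")
  bc
}

#' Interval counts per dimension of a barcode
#'
#' @param bc A `barcode`.
#' @param dims Dimensions to report (default 0:2).
#' @return Named integer vector `m_0`, `m_1`, ...
#' @export
interval_counts <- function(bc, dims = 0:2) {
  m <- vapply(dims, function(d) sum(bc$dim == d), integer(1))
  names(m) <- paste0("m_", dims)
  m
}

#' Betti curves of a barcode
#'
#' `beta_n(t)` counts the intervals of dimension n alive at step t (born
#' at or before t, not yet dead under the half-open convention).
#'
#' @param bc A `barcode` with attribute `n_steps`.
#' @param dims Dimensions to include (default 0:2).
#' @return Data frame with column `step` (1..N) and one `beta<d>` column
#'   per dimension.
#' @export
betti_curves <- function(bc, dims = 0:2) {
  N <- attr(bc, "n_steps")
  if (is.null(N)) stop("barcode lacks the n_steps attribute")
  out <- data.frame(step = seq_len(N))
  for (d in dims) {
    b <- bc$birth[bc$dim == d]
    dd <- bc$death[bc$dim == d]
    born <- cumsum(tabulate(b, nbins = N))
    dead <- cumsum(tabulate(dd[is.finite(dd)], nbins = N))
    out[[paste0("beta", d)]] <- as.integer(born - dead)
  }
  out
}

#' Normalized average cycle lifetime
#'
#' For each dimension k, `D_k = (1/(m_k * N)) * sum_i (d_i - b_i)` over the
#' m_k intervals of that dimension, with infinite deaths replaced by
#' `N + 1` (distinguishing still-open cavities from those dying at the last
#' step). `D_k = 0` when no interval exists. Summarizes how persistent the
#' knowledge gaps of each dimension are, comparably across documents of
#' different lengths.
#'
#' @param bc A `barcode` with attribute `n_steps`.
#' @param dims Dimensions to summarize (default 0:2).
#' @return List with `D` (named vector `D_0`, `D_1`, ...), `mean` (mean of
#'   those values), `m` (interval counts), and `n_steps`.
#' @export
normalized_cycle_lifetime <- function(bc, dims = 0:2) {
  N <- attr(bc, "n_steps")
  if (is.null(N)) stop("barcode lacks the n_steps attribute")
  D <- vapply(dims, function(d) {
    sel <- bc$dim == d
    m <- sum(sel)
    if (m == 0L) return(0)
    death <- pmin(bc$death[sel], N + 1)
    sum(death - bc$birth[sel]) / (m * N)
  }, numeric(1))
  names(D) <- paste0("D_", dims)
  list(D = D, mean = mean(D), m = interval_counts(bc, dims), n_steps = N)
}

#' @export
print.barcode <- function(x, ...) {
  m <- interval_counts(x, dims = sort(unique(x$dim)))
  cat(sprintf("<barcode: N = %d; %s>\n", attr(x, "n_steps"),
              paste(names(m), m, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Write a barcode as CSV (death written as "inf" for open intervals)
#'
#' @param bc A `barcode`.
#' @param path Output path.
#' @export
write_barcode <- function(bc, path) {
  out <- data.frame(dim = bc$dim, birth = bc$birth,
                    death = ifelse(is.finite(bc$death),
                                   as.character(bc$death), "inf"))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
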