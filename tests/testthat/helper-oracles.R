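# Independent oracles used to validate the package implementations.
# Each is deliberately written with different mechanics from the code it
# checks (dense matrices, exhaustive enumeration, direct formulas).

# --- persistent homology: plain left-to-right column reduction over GF(2),
# no clearing, list-of-rows columns built from a dense face search --------

ph_oracle <- function(f, max_hom_dim = 2L, drop_zero = TRUE) {
  sx <- exposnet:::filtration_simplices(f, max_dim = max_hom_dim + 1L)
  ord <- order(sx$filt, sx$dim)
  verts <- sx$verts[ord]
  filt <- sx$filt[ord]
  dims <- sx$dim[ord]
  n <- length(verts)
  key <- vapply(verts, paste, character(1), collapse = "-")
  idx <- seq_len(n)
  names(idx) <- key
  cols <- lapply(seq_len(n), function(j) {
    if (dims[j] == 0L) return(integer(0))
    v <- verts[[j]]
    faces <- vapply(seq_along(v), function(d) {
      paste(v[-d], collapse = "-")
    }, character(1))
    sort(unname(idx[faces]))
  })
  pivots <- integer(n)
  for (j in seq_len(n)) {
    repeat {
      if (length(cols[[j]]) == 0L) break
      l <- max(cols[[j]])
      k <- pivots[l]
      if (k == 0L) {
        pivots[l] <- j
        break
      }
      a <- cols[[j]]; b <- cols[[k]]
      cols[[j]] <- sort(c(setdiff(a, b), setdiff(b, a)))
    }
  }
  res <- list()
  pivot_rows <- which(pivots != 0L)
  for (r in pivot_rows) {
    j <- pivots[r]
    if (dims[r] <= max_hom_dim && (!drop_zero || filt[j] > filt[r])) {
      res[[length(res) + 1L]] <- c(dims[r], filt[r], filt[j])
    }
  }
  zero_cols <- which(vapply(cols, length, integer(1)) == 0L)
  for (j in setdiff(zero_cols, pivot_rows)) {
    if (dims[j] <= max_hom_dim) {
      res[[length(res) + 1L]] <- c(dims[j], filt[j], Inf)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(dim = integer(0), birth = numeric(0),
                      death = numeric(0)))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("dim", "birth", "death")
  out[order(out$dim, out$birth, out$death), , drop = FALSE]
}

barcode_key <- function(bc) {
  bc <- bc[order(bc$dim, bc$birth, bc$death), , drop = FALSE]
  paste(bc$dim, bc$birth, bc$death, sep = ":", collapse = ";")
}

# --- RAKE: incidence-matrix statistics and direct-formula scores ---------

rake_oracle <- function(candidates, ref_counts = numeric(0)) {
  words_per <- strsplit(candidates, " ", fixed = TRUE)
  vocab <- sort(unique(unlist(words_per)))
  B <- t(vapply(words_per, function(ws) as.integer(vocab %in% ws),
                integer(length(vocab))))
  lens <- lengths(words_per)
  freq <- colSums(B)
  deg <- as.vector(t(B) %*% lens)
  names(freq) <- names(deg) <- vocab
  phrases <- unique(candidates)
  rake <- vapply(strsplit(phrases, " ", fixed = TRUE), function(ws) {
    sum(deg[ws] / freq[ws])
  }, numeric(1))
  rc <- ifelse(phrases %in% names(ref_counts), ref_counts[phrases], 0)
  data.frame(phrase = phrases, rake_score = rake,
             final_score = rake / (1 + rc),
             stringsAsFactors = FALSE)
}

# --- meso-scale: exhaustive searches on tiny graphs ----------------------

exhaustive_coreness <- function(g, gamma = 1) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  best <- -Inf
  best_core <- character(0)
  for (mask in 0:(2^n - 1)) {
    core <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    q <- coreness_quality(g, core, gamma)
    if (q > best) {
      best <- q
      best_core <- core
    }
  }
  list(q = best, core = best_core)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1L)) {
      recurse(c(prefix, b), max(maxblock, b))
    }
  }
  recurse(integer(0), 0L)
  out
}

exhaustive_modularity <- function(g, gamma = 1) {
  n <- igraph::vcount(g)
  best <- -Inf
  best_memb <- NULL
  for (memb in all_set_partitions(n)) {
    names(memb) <- igraph::V(g)$name
    q <- modularity_quality(g, memb, gamma)
    if (q > best) {
      best <- q
      best_memb <- memb
    }
  }
  list(q = best, membership = best_memb)
}

# --- Spearman: brute-force permutation p on small n ----------------------

spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- exposnet:::all_permutations(n)
  rhos <- apply(perms, 1L, function(p) stats::cor(rank(x), rank(y)[p]))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# --- label-agreement helpers ---------------------------------------------

core_label_accuracy <- function(detected_core, labels) {
  truth_core <- labels$phrase[labels$role == "core"]
  truth_periph <- labels$phrase[labels$role == "periphery"]
  (sum(truth_core %in% detected_core) +
     sum(!truth_periph %in% detected_core)) / nrow(labels)
}

pairwise_agreement <- function(memb_a, memb_b) {
  common <- intersect(names(memb_a), names(memb_b))
  stopifnot(length(common) >= 2L)
  pairs <- utils::combn(common, 2L)
  same_a <- memb_a[pairs[1L, ]] == memb_a[pairs[2L, ]]
  same_b <- memb_b[pairs[1L, ]] == memb_b[pairs[2L, ]]
  mean(same_a == same_b)
}
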