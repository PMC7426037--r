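fixture_doc <- function() {
  make_doc(list(c("alpha", "beta", "the", "gamma"),
                c("delta", "of", "alpha"),
                c("beta", "gamma", "epsilon"),
                c("zeta", "alpha", "delta"),
                c("epsilon", "zeta")))
}

test_that("random index sampling respects eligibility and seeds", {
  doc <- fixture_doc()
  sl <- c("the", "of")
  pool <- exposnet:::eligible_word_types(doc, sl)
  expect_setequal(pool, c("alpha", "beta", "gamma", "delta", "epsilon",
                          "zeta"))
  # sampling the whole pool is deterministic regardless of seed
  r1 <- random_index_filtration(doc, length(pool), sl, seed = 1)
  r2 <- random_index_filtration(doc, length(pool), sl, seed = 99)
  expect_identical(r1$index, r2$index)
  expect_error(random_index_filtration(doc, 0, sl), "n must be")
  expect_error(random_index_filtration(doc, 50, sl), "only 6 eligible")
  # placeholders are never eligible
  doc2 <- make_doc(list(c("alpha", "#", "VAR")))
  expect_setequal(exposnet:::eligible_word_types(doc2, sl), "alpha")
  # different seeds give different subsets with high probability
  s1 <- random_index_filtration(doc, 3, sl, seed = 4)$index
  s2 <- random_index_filtration(doc, 3, sl, seed = 5)$index
  s3 <- random_index_filtration(doc, 3, sl, seed = 6)$index
  expect_true(!identical(s1, s2) || !identical(s2, s3))
  expect_s3_class(r1$filtration, "filtration")
  expect_equal(r1$filtration$kind, "random_index")
})

test_that("sentence shuffling preserves the total network", {
  doc <- fixture_doc()
  idx <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  g <- build_total_network(doc, idx)
  f <- random_sentence_filtration(doc, idx, seed = 8)
  expect_silent(validate_filtration(f))
  gN <- filtration_graph(f)
  key <- function(gr) sort(apply(igraph::as_edgelist(gr), 1, function(e) {
    paste(sort(e), collapse = "|")
  }))
  expect_identical(key(gN), key(g))
  # one-sentence documents are unchanged
  doc1 <- make_doc(list(c("alpha", "beta")))
  f1 <- random_sentence_filtration(doc1, idx, seed = 9)
  expect_equal(f1$n_steps, 1L)
  expect_equal(unname(f1$node_birth), c(1L, 1L))
})

test_that("shuffled edge births equal first-occurrence ranks under the permutation", {
  doc <- fixture_doc()
  idx <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  seed <- 21
  f <- random_sentence_filtration(doc, idx, seed = seed)
  # reproduce the permutation the function drew and recompute births by
  # scanning sentences in permuted order
  set.seed(seed)
  perm <- sample.int(doc$n_sentences)
  matched <- lapply(doc$sentences[perm], match_concepts, index = idx)
  expected <- list()
  for (k in seq_along(matched)) {
    s <- matched[[k]]
    if (length(s) >= 2L) {
      for (pair in utils::combn(sort(s), 2L, simplify = FALSE)) {
        kk <- paste(pair, collapse = "|")
        if (is.null(expected[[kk]])) expected[[kk]] <- k
      }
    }
  }
  got <- stats::setNames(f$edge_birth$birth,
                         paste(f$edge_birth$u, f$edge_birth$v, sep = "|"))
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(unname(got[names(expected)]), unname(unlist(expected)))
})

test_that("configuration rewiring preserves degrees and weights exactly", {
  for (s in 1:5) {
    g <- random_weighted_graph(12, 0.4, seed = 900 + s)
    if (igraph::ecount(g) < 2) next
    cc <- continuous_configuration(g, seed = s)
    expect_identical(sort(igraph::degree(cc)[igraph::V(g)$name]),
                     sort(igraph::degree(g)))
    expect_identical(sort(igraph::E(cc)$weight),
                     sort(igraph::E(g)$weight))
    expect_equal(igraph::count_multiple(cc),
                 rep(1, igraph::ecount(cc)))
    expect_false(any(igraph::which_loop(cc)))
  }
  # stars admit no swap
  star <- unit_graph(cbind(rep("hub", 4), paste0("leaf", 1:4)))
  expect_warning(cc_star <- continuous_configuration(star, seed = 1),
                 "no degree-preserving swap")
  expect_identical(sort(igraph::degree(cc_star)), sort(igraph::degree(star)))
})

test_that("rewired strengths stay close to their targets", {
  rel_err <- vapply(1:20, function(s) {
    g <- random_weighted_graph(50, 0.15, seed = 1000 + s, max_w = 6L)
    cc <- continuous_configuration(g, seed = s)
    s_in <- igraph::strength(g)
    s_out <- igraph::strength(cc)[names(s_in)]
    stats::median(abs(s_out - s_in) / pmax(s_in, 1))
  }, numeric(1))
  expect_lte(stats::median(rel_err), 0.25)
})

test_that("random edge ordering reproduces the final graph", {
  g <- random_weighted_graph(10, 0.4, seed = 1100)
  f <- random_edge_filtration(g, seed = 3)
  expect_silent(validate_filtration(f))
  expect_equal(f$n_steps, igraph::ecount(g))
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  el <- igraph::as_edgelist(g)
  expect_setequal(key(f$edge_birth$u, f$edge_birth$v),
                  key(el[, 1], el[, 2]))
  expect_equal(sort(f$edge_birth$birth), seq_len(igraph::ecount(g)))
  # single-edge graphs are the same for every seed
  e1 <- unit_graph(cbind("a", "b"))
  f1 <- random_edge_filtration(e1, seed = 1)
  f2 <- random_edge_filtration(e1, seed = 2)
  expect_identical(f1$edge_birth, f2$edge_birth)
})

test_that("node-ordered filtrations add each node with its back-edges", {
  g <- random_weighted_graph(8, 0.5, seed = 1200)
  ord <- sample(igraph::V(g)$name)
  f <- node_ordered_filtration(g, ord)
  pos <- stats::setNames(seq_along(ord), ord)
  expect_equal(f$edge_birth$birth,
               unname(pmax(pos[f$edge_birth$u], pos[f$edge_birth$v])))
  expect_equal(f$n_steps, igraph::vcount(g))
  expect_error(node_ordered_filtration(g, ord[-1]), "permutation")
  # on a complete graph every later node connects instantly: a single
  # reported dim-0 bar
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  fk <- node_ordered_filtration(k5, letters[1:5])
  bck <- persistent_homology(fk)
  expect_equal(sum(bck$dim == 0), 1L)
  expect_false(is.finite(bck$death[bck$dim == 0]))
})

test_that("ensembles are seeded, deterministic, and summarized", {
  g <- random_weighted_graph(10, 0.4, seed = 1300)
  metrics <- list(
    n_steps = function(f) f$n_steps,
    last_birth = function(f) max(f$edge_birth$birth))
  e1 <- build_ensemble("random_edge", list(g = g), metrics, size = 5,
                       master_seed = 7)
  e2 <- build_ensemble("random_edge", list(g = g), metrics, size = 5,
                       master_seed = 7)
  expect_identical(e1$metrics, e2$metrics)
  expect_equal(e1$size, 5L)
  expect_equal(length(unique(e1$seeds)), 5L)
  # constant metrics summarize to the constant
  expect_true(all(e1$metrics$n_steps == igraph::ecount(g)))
  expect_equal(e1$summary$n_steps[["mean"]], igraph::ecount(g))
  expect_equal(e1$summary$n_steps[["sd"]], 0)
  e3 <- build_ensemble("random_edge", list(g = g), metrics, size = 1,
                       master_seed = 9)
  expect_equal(nrow(e3$metrics), 1L)
})
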