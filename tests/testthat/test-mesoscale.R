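test_that("core-ness optimizer recovers a planted clique core", {
  g <- unit_graph(rbind(t(utils::combn(paste0("c", 1:4), 2)),
                        cbind(paste0("c", 1:4), paste0("p", 1:4))))
  cp <- coreness_partition(g, seed = 1)
  expect_setequal(cp$core, paste0("c", 1:4))
  ex <- exhaustive_coreness(g)
  expect_equal(cp$coreness, ex$q, tolerance = 1e-12)
  # stored Q re-evaluates exactly
  expect_equal(coreness_quality(g, cp$core), cp$coreness,
               tolerance = 1e-12)
})

test_that("complete uniform graphs score zero with an all-core optimum", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$weight <- 1
  expect_equal(coreness_quality(k5, letters[1:5]), 0)
  cp <- coreness_partition(k5, seed = 2)
  expect_equal(cp$coreness, 0)
  expect_setequal(cp$core, letters[1:5])
})

test_that("edgeless graphs yield the all-periphery zero convention", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  cp <- coreness_partition(g, seed = 3)
  expect_equal(cp$coreness, 0)
  expect_length(cp$core, 0)
  mp <- modularity_partition(g, seed = 3)
  expect_equal(mp$modularity, 0)
  expect_equal(mp$n_communities, 3L)
})

test_that("core-ness optimizer matches exhaustive search on random graphs", {
  for (s in 1:8) {
    g <- random_weighted_graph(sample(4:7, 1), 0.5, seed = 100 + s)
    if (igraph::ecount(g) == 0) next
    cp <- coreness_partition(g, restarts = 5, seed = s)
    ex <- exhaustive_coreness(g)
    expect_equal(cp$coreness, ex$q, tolerance = 1e-10)
  }
})

test_that("modularity optimizer separates two triangles and matches search", {
  g <- unit_graph(cbind(c("a", "b", "a", "d", "e", "d", "c"),
                        c("b", "c", "c", "e", "f", "f", "d")))
  mp <- modularity_partition(g, seed = 4)
  expect_equal(mp$n_communities, 2L)
  expect_equal(length(unique(mp$membership[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(mp$membership[c("d", "e", "f")])), 1L)
  ex <- exhaustive_modularity(g)
  expect_equal(mp$modularity, ex$q, tolerance = 1e-12)
  expect_equal(modularity_quality(g, mp$membership), mp$modularity,
               tolerance = 1e-12)
  # a lone triangle is one community
  tri <- unit_graph(cbind(c("a", "b", "a"), c("b", "c", "c")))
  expect_equal(modularity_partition(tri, seed = 5)$n_communities, 1L)
})

test_that("all-in-one modularity equals the direct formula", {
  for (s in 1:5) {
    g <- random_weighted_graph(6, 0.5, seed = 200 + s)
    if (igraph::ecount(g) == 0) next
    memb <- stats::setNames(rep(1L, 6), igraph::V(g)$name)
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    v <- sum(W)
    s_i <- rowSums(W)
    direct <- (sum(W) - sum(outer(s_i, s_i))/v + sum(s_i^2)/v) / v
    expect_equal(modularity_quality(g, memb), direct, tolerance = 1e-12)
  }
})

test_that("periphery modularity works on the induced subgraph", {
  # core pair plus two disconnected periphery triangles
  edges <- rbind(cbind(c("x", "x", "y"), c("y", "a", "d")),
                 cbind(c("a", "b", "a"), c("b", "c", "c")),
                 cbind(c("d", "e", "d"), c("e", "f", "f")))
  g <- unit_graph(edges)
  cp <- structure(list(core = c("x", "y"),
                       periphery = c("a", "b", "c", "d", "e", "f"),
                       coreness = NA, gamma = 1, v_C = NA, wbar = NA),
                  class = "core_periphery")
  pm <- periphery_modularity(g, cp, seed = 6)
  expect_equal(pm$n_communities, 2L)
  expect_setequal(names(pm$membership), cp$periphery)
  # induced weights are the original weights
  sub <- igraph::induced_subgraph(g, cp$periphery)
  expect_true(all(igraph::E(sub)$weight == 1))
  # empty periphery errors
  cp_bad <- structure(list(core = igraph::V(g)$name,
                           periphery = character(0)),
                      class = "core_periphery")
  expect_error(periphery_modularity(g, cp_bad), "empty")
  # periphery with no internal edges: zero modularity convention
  cp2 <- structure(list(core = c("x", "y", "a", "c", "d", "f"),
                        periphery = c("b", "e")),
                   class = "core_periphery")
  pm2 <- periphery_modularity(g, cp2, seed = 7)
  expect_equal(pm2$modularity, 0)
  expect_equal(pm2$n_communities, 2L)
})

test_that("modularity optimizer matches exhaustive search on random graphs", {
  for (s in 1:6) {
    g <- random_weighted_graph(sample(4:6, 1), 0.6, seed = 300 + s)
    if (igraph::ecount(g) == 0) next
    mp <- modularity_partition(g, runs = 8, seed = s)
    ex <- exhaustive_modularity(g)
    expect_equal(mp$modularity, ex$q, tolerance = 1e-10)
  }
})

test_that("introduction curves step at birth times", {
  f <- new_filtration(c(a = 1L, b = 10L),
                      data.frame(u = "a", v = "b", birth = 10L),
                      10L, "fix")
  cv <- introduction_curves(f, c("a", "b"))
  expect_equal(cv$fraction[cv$step == 0], 0)
  expect_equal(cv$fraction[cv$step == 1], 0.5)
  expect_equal(cv$fraction[cv$step == 9], 0.5)
  expect_equal(cv$fraction[cv$step == 10], 1)
  # all born at step 1
  f2 <- new_filtration(c(a = 1L, b = 1L),
                       data.frame(u = character(0), v = character(0),
                                  birth = integer(0)), 5L, "fix")
  cv2 <- introduction_curves(f2, c("a", "b"))
  expect_true(all(cv2$fraction[cv2$step >= 1] == 1))
  expect_error(introduction_curves(f, character(0)), "empty")
  expect_error(introduction_curves(f, c("a", "zz")), "absent")
  # nondecreasing on random fixtures
  for (s in 1:5) {
    fr <- random_filtration(8, 0.5, seed = 400 + s)
    cvr <- introduction_curves(fr, names(fr$node_birth))
    expect_true(all(diff(cvr$fraction) >= 0))
    expect_equal(cvr$fraction[length(cvr$fraction)], 1)
  }
})

test_that("curve areas behave like signed step-function integrals", {
  N <- 50L
  nodes_a <- sprintf("a%02d", 1:5)
  nodes_b <- sprintf("b%02d", 1:N)
  nb <- c(stats::setNames(rep(1L, 5), nodes_a),
          stats::setNames(1:N, nodes_b))
  f <- new_filtration(nb, data.frame(u = character(0), v = character(0),
                                     birth = integer(0)), N, "fix")
  core <- introduction_curves(f, nodes_a)     # all present from step 1
  peri <- introduction_curves(f, nodes_b)     # uniform introduction
  expect_equal(curve_area_difference(core, core), 0)
  a <- curve_area_difference(core, peri)
  expect_equal(curve_area_difference(peri, core), -a)
  # discrete analogue of int (1 - t) dt = 1/2
  expect_equal(a, 0.5 - 1 / (2 * N), tolerance = 1e-12)
  expect_error(
    curve_area_difference(core, introduction_curves(
      new_filtration(nb, data.frame(u = character(0), v = character(0),
                                    birth = integer(0)), N + 1L, "fix"),
      nodes_a)),
    "same step grid")
})

test_that("curve areas are invariant under uniform step stretching", {
  set.seed(17)
  for (rep in 1:5) {
    N <- 20L
    g1 <- sprintf("x%02d", 1:6)
    g2 <- sprintf("y%02d", 1:6)
    nb <- c(stats::setNames(sample.int(N, 6, TRUE), g1),
            stats::setNames(sample.int(N, 6, TRUE), g2))
    f1 <- new_filtration(nb, data.frame(u = character(0),
                                        v = character(0),
                                        birth = integer(0)), N, "fix")
    stretch <- 3L
    f2 <- new_filtration(nb * stretch,
                         data.frame(u = character(0), v = character(0),
                                    birth = integer(0)),
                         N * stretch, "fix")
    a1 <- curve_area_difference(introduction_curves(f1, g1),
                                introduction_curves(f1, g2))
    a2 <- curve_area_difference(introduction_curves(f2, g1),
                                introduction_curves(f2, g2))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("edge classes partition the filtration edges", {
  # one edge of each class
  nb <- c(c1 = 1L, c2 = 2L, p1 = 3L, p2 = 4L, p3 = 5L)
  eb <- data.frame(u = c("c1", "c1", "p1", "p1"),
                   v = c("c2", "p1", "p2", "p3"),
                   birth = c(2L, 3L, 4L, 5L))
  f <- new_filtration(nb, eb, 5L, "fix")
  cp <- structure(list(core = c("c1", "c2"),
                       periphery = c("p1", "p2", "p3")),
                  class = "core_periphery")
  comm <- structure(list(membership = c(p1 = 1L, p2 = 1L, p3 = 2L),
                         modularity = NA, gamma = 1, n_communities = 2L),
                    class = "community_partition")
  curves <- edge_group_curves(f, cp, comm)
  expect_setequal(names(curves),
                  c("core-core", "core-periphery", "periphery-within",
                    "periphery-between"))
  sizes <- vapply(curves, attr, numeric(1), "group_size")
  expect_equal(sum(sizes), nrow(eb))
  # each curve jumps exactly once
  for (cv in curves) {
    expect_equal(sum(diff(cv$fraction) > 0), 1L)
  }
})

test_that("one-sample t-test matches the textbook formula", {
  res <- one_sample_ttest(c(-1, 1))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(one_sample_ttest(c(1, 1, 1, 1)), "variance")
  expect_error(one_sample_ttest(3), "at least 2")
  set.seed(23)
  x <- rnorm(12, mean = 0.4)
  res2 <- one_sample_ttest(x)
  t_direct <- mean(x) / (sd(x) / sqrt(length(x)))
  expect_equal(res2$t, t_direct, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(t_direct), df = 11), tolerance = 1e-12)
})
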