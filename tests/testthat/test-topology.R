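cycle4 <- function() {
  new_filtration(c(a = 1L, b = 1L, c = 1L, d = 1L),
                 data.frame(u = c("a", "b", "c", "a"),
                            v = c("b", "c", "d", "d"), birth = 1:4),
                 4L, "fix")
}

test_that("clique complexes enumerate the right simplices", {
  tri <- unit_graph(cbind(c("a", "b", "a"), c("b", "c", "c")))
  cx <- clique_complex(tri)
  expect_equal(sum(cx$dim == 0), 3L)
  expect_equal(sum(cx$dim == 1), 3L)
  expect_equal(sum(cx$dim == 2), 1L)
  sq <- unit_graph(cbind(c("a", "b", "c", "a"), c("b", "c", "d", "d")))
  expect_equal(sum(clique_complex(sq)$dim == 2), 0L)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  cx4 <- clique_complex(k4)
  expect_equal(sum(cx4$dim == 2), 4L)
  expect_equal(sum(cx4$dim == 3), 1L)
  # simplex stamps are the latest constituent birth
  f <- cycle4()
  sx <- exposnet:::filtration_simplices(f, max_dim = 2L)
  expect_equal(max(sx$filt[sx$dim == 1]), 4)
})

test_that("persistence detects the known homology of standard fixtures", {
  bc <- persistent_homology(cycle4())
  d1 <- bc[bc$dim == 1, ]
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$birth, 4)
  expect_false(is.finite(d1$death))
  # a triangle is filled immediately by its 2-simplex
  tri <- new_filtration(c(a = 1L, b = 1L, c = 1L),
                        data.frame(u = c("a", "b", "a"),
                                   v = c("b", "c", "c"), birth = 1:3),
                        3L, "fix")
  expect_equal(sum(persistent_homology(tri)$dim == 1), 0L)
  # octahedron boundary is a 2-sphere
  oct <- igraph::make_graph("Octahedral")
  igraph::V(oct)$name <- letters[1:6]
  el <- igraph::as_edgelist(oct)
  foct <- new_filtration(stats::setNames(rep(1L, 6), letters[1:6]),
                         data.frame(u = el[, 1], v = el[, 2], birth = 1L),
                         1L, "fix")
  bo <- persistent_homology(foct)
  expect_equal(sum(bo$dim == 2), 1L)
  expect_equal(sum(bo$dim == 1), 0L)
  expect_equal(sum(bo$dim == 0), 1L)
  # merging two components kills a dim-0 class at the merge step
  fm <- new_filtration(c(a = 1L, b = 1L, c = 2L, d = 2L),
                       data.frame(u = c("a", "c", "a"),
                                  v = c("b", "d", "c"),
                                  birth = c(1L, 2L, 5L)),
                       5L, "fix")
  bm <- persistent_homology(fm)
  expect_equal(bm$death[bm$dim == 0 & is.finite(bm$death)], 5)
})

test_that("barcodes match the independent reduction oracle", {
  for (s in 1:25) {
    f <- random_filtration(sample(6:10, 1), stats::runif(1, 0.3, 0.7),
                           seed = 500 + s)
    mine <- persistent_homology(f)
    orac <- ph_oracle(f)
    expect_identical(barcode_key(as.data.frame(mine)), barcode_key(orac))
  }
})

test_that("infinite dim-0 bars count the components of the final graph", {
  for (s in 1:10) {
    f <- random_filtration(sample(5:10, 1), stats::runif(1, 0.1, 0.5),
                           seed = 600 + s)
    bc <- persistent_homology(f)
    n_inf0 <- sum(bc$dim == 0 & !is.finite(bc$death))
    expect_equal(n_inf0, igraph::count_components(filtration_graph(f)))
  }
})

test_that("Euler characteristic is consistent at every step on small fixtures", {
  check_chi <- function(f) {
    sx <- exposnet:::filtration_simplices(f, max_dim = 3L)
    bc <- persistent_homology(f, drop_zero = FALSE)
    for (t in unique(sx$filt)) {
      chi_simplices <- sum((-1)^sx$dim[sx$filt <= t])
      alive <- bc$birth <= t & (!is.finite(bc$death) | bc$death > t)
      chi_betti <- sum((-1)^bc$dim[alive])
      expect_equal(chi_simplices, chi_betti)
    }
  }
  # octahedron: chi = 6 - 12 + 8 = 2 = beta0 + beta2
  oct <- igraph::make_graph("Octahedral")
  el <- igraph::as_edgelist(oct)
  check_chi(new_filtration(
    stats::setNames(rep(1L, 6), as.character(1:6)),
    data.frame(u = as.character(el[, 1]), v = as.character(el[, 2]),
               birth = 1L),
    1L, "fix"))
  # random filtrations whose complexes stop at dimension 2 (no 4-clique),
  # so chi = beta0 - beta1 + beta2 holds exactly
  tested <- 0L
  for (s in 1:12) {
    f <- random_filtration(7, 0.35, seed = 700 + s)
    if (igraph::clique_num(filtration_graph(f)) > 3) next
    check_chi(f)
    tested <- tested + 1L
  }
  expect_gte(tested, 3L)
})

test_that("Betti curves use the half-open death convention", {
  bc <- structure(data.frame(dim = 1L, birth = 2, death = 5),
                  n_steps = 6L, class = c("barcode", "data.frame"))
  curves <- betti_curves(bc, dims = 1)
  expect_equal(curves$beta1, c(0L, 1L, 1L, 1L, 0L, 0L))
  empty <- structure(data.frame(dim = integer(0), birth = numeric(0),
                                death = numeric(0)),
                     n_steps = 3L, class = c("barcode", "data.frame"))
  expect_true(all(betti_curves(empty)$beta1 == 0L))
})

test_that("summed Betti mass double-counts interval lifetimes", {
  for (s in 1:5) {
    f <- random_filtration(8, 0.5, seed = 800 + s)
    bc <- persistent_homology(f)
    curves <- betti_curves(bc)
    N <- attr(bc, "n_steps")
    for (d in 0:2) {
      sel <- bc$dim == d
      expect_equal(sum(curves[[paste0("beta", d)]]),
                   sum(pmin(bc$death[sel], N + 1) - bc$birth[sel]))
    }
  }
})

test_that("normalized cycle lifetimes follow the formula exactly", {
  mk <- function(df, N) {
    structure(df, n_steps = N, class = c("barcode", "data.frame"))
  }
  one <- mk(data.frame(dim = 1L, birth = 2, death = 5), 10L)
  expect_equal(normalized_cycle_lifetime(one)$D[["D_1"]], 0.3)
  open <- mk(data.frame(dim = 1L, birth = 2, death = Inf), 10L)
  expect_equal(normalized_cycle_lifetime(open)$D[["D_1"]], 0.9)
  two <- mk(data.frame(dim = c(1L, 1L), birth = c(1, 1), death = c(2, 3)),
            4L)
  life <- normalized_cycle_lifetime(two)
  expect_equal(life$D[["D_1"]], 0.375)
  expect_equal(life$D[["D_0"]], 0)
  expect_equal(life$mean, mean(c(0, 0.375, 0)))
  expect_equal(unname(life$m), c(0L, 2L, 0L))
})

test_that("OAAT and sentence filtrations agree on every infinite bar", {
  set.seed(31)
  concepts <- letters[1:8]
  for (rep in 1:5) {
    sentences <- replicate(10, sample(concepts, sample(1:4, 1)),
                           simplify = FALSE)
    doc <- make_doc(sentences)
    bs <- persistent_homology(build_sentence_filtration(doc, concepts))
    bo <- persistent_homology(build_oaat_filtration(doc, concepts))
    for (d in 0:2) {
      expect_equal(sum(bo$dim == d & !is.finite(bo$death)),
                   sum(bs$dim == d & !is.finite(bs$death)))
    }
  }
})

test_that("barcode CSV writes open deaths as 'inf'", {
  bc <- persistent_homology(cycle4())
  path <- withr::local_tempfile(fileext = ".csv")
  write_barcode(bc, path)
  lines <- readLines(path)
  expect_true(any(grepl(",inf$", lines)))
  expect_equal(length(lines) - 1L, nrow(bc))
})
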