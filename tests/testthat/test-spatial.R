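# brute-force two-point correlation oracle for tiny maps (non-periodic)
brute_corr <- function(grid, r_max) {
  mu <- mean(grid); dev <- grid - mu; s2 <- mean(dev^2)
  n_r <- nrow(grid); n_c <- ncol(grid)
  sums <- list(); cnts <- list()
  for (i1 in 1:n_r) for (j1 in 1:n_c) for (i2 in 1:n_r) for (j2 in 1:n_c) {
    r2 <- (i2 - i1)^2 + (j2 - j1)^2
    if (r2 > r_max^2) next
    key <- as.character(r2)
    sums[[key]] <- c(sums[[key]], dev[i1, j1] * dev[i2, j2])
    cnts[[key]] <- TRUE
  }
  r2v <- sort(as.numeric(names(sums)))
  data.frame(r = sqrt(r2v),
             value = vapply(as.character(r2v),
                            function(k) mean(sums[[k]]) / s2, numeric(1)))
}

test_that("two-point correlation is 1 at r = 0 and matches the brute-force oracle", {
  set.seed(60)
  for (i in 1:4) {
    g <- matrix(rbinom(36, 1, 0.4), 6, 6)
    if (stats::var(as.vector(g)) == 0) next
    cc <- two_point_correlation(structure(g, class = "nk_binary_map",
                                          provenance = "image"),
                                r_max = 4, periodic = FALSE)
    expect_equal(cc$value[cc$r == 0], 1)
    oracle <- brute_corr(g, 4)
    expect_equal(cc$r, oracle$r)
    expect_equal(cc$value, oracle$value, tolerance = 1e-12)
  }
})

test_that("a checkerboard anticorrelates perfectly at unit distance", {
  g <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  cc <- two_point_correlation(structure(g, class = "nk_binary_map",
                                        provenance = "image"),
                              r_max = 2, periodic = FALSE)
  expect_equal(cc$value[cc$r == 1], -1)
  expect_error(two_point_correlation(matrix(1L, 4, 4)), "variance")
})

test_that("an i.i.d. random map decorrelates beyond r = 0", {
  set.seed(61)
  g <- matrix(rbinom(8281, 1, 0.3), 91, 91)
  cc <- two_point_correlation(structure(g, class = "nk_binary_map",
                                        provenance = "synthetic"),
                              r_max = 10)
  expect_lt(max(abs(cc$value[cc$r > 0])), 0.05)
})

test_that("cluster randomization preserves the size histogram exactly", {
  m <- generate_cluster_map(50, seed = 70)
  r <- randomize_clusters(m, seed = 71)
  expect_equal(sum(r), sum(m))
  # the placed multiset of shapes equals the original's connected components
  # (re-labelling the output can merge clusters that happen to touch)
  placed_sizes <- sort(vapply(attr(r, "clusters"), length, 1L))
  orig_sizes <- sort(tabulate(nkrsig:::label_components(unclass(m),
                                                        periodic = TRUE)))
  expect_equal(placed_sizes, orig_sizes)
  # single-cluster map: one identically shaped cluster somewhere
  m1 <- generate_cluster_map(1, seed = 72)
  r1 <- randomize_clusters(m1, seed = 73)
  expect_equal(sum(r1), sum(m1))
  expect_equal(max(nkrsig:::label_components(unclass(r1), TRUE)), 1L)
})

test_that("randomized uniform maps stay statistically indistinguishable", {
  m <- generate_cluster_map(60, seed = 80)
  c0 <- two_point_correlation(m, r_max = 12)
  rand_curves <- vapply(1:15, function(i)
    two_point_correlation(randomize_clusters(m, seed = 800 + i),
                          r_max = 12)$value,
    numeric(nrow(c0)))
  mean_curve <- c0
  mean_curve$value <- rowMeans(rand_curves)
  band <- pmax(3 * apply(rand_curves, 1, stats::sd), 0.02)
  ov <- curve_overlap(c0, mean_curve, band)
  expect_gt(ov$overlap, 0.85)
  # identical curves overlap fully; an everywhere-negated curve not at all
  expect_equal(curve_overlap(c0, c0, 1e-9)$overlap, 1)
  flat <- data.frame(r = 0:5, value = 0.5)
  neg <- data.frame(r = 0:5, value = -0.5)
  expect_equal(curve_overlap(flat, neg, 0.1)$overlap, 0)
  bad <- c0[-1, ]
  expect_error(curve_overlap(c0, bad, 0.1), "different r grids")
})
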