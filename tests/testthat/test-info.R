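test_that("mutual information matches direct summation and its entropy identity", {
  # identity channel over 4 equiprobable inputs: MI = H(s) = 2 bits
  expect_equal(mutual_information(diag(4)), 2)
  # indistinguishable inputs carry no information
  P_same <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(mutual_information(P_same), 0)
  # joint P = [[0.4, 0.1], [0.1, 0.4]]: brute-force double sum
  joint <- rbind(c(0.4, 0.1), c(0.1, 0.4))
  Q <- rowSums(joint); R <- colSums(joint)
  oracle <- sum(joint * log2(joint / outer(Q, R)))
  expect_equal(mutual_information(joint / Q, Q = Q), oracle)
  expect_equal(oracle, 0.278072, tolerance = 1e-5)

  # MI = H(s) - H(s|o) on random channels
  set.seed(90)
  for (i in 1:10) {
    P <- matrix(stats::rgamma(12, 1), 3, 4)
    P <- P / rowSums(P)
    Q <- rep(1 / 3, 3)
    joint <- Q * P
    post <- t(t(joint) / colSums(joint))    # P(s|o)
    hs <- -sum(Q * log2(Q))
    hso <- -sum(joint * log2(post))
    expect_equal(mutual_information(P), hs - hso, tolerance = 1e-10)
  }
  expect_error(mutual_information(rbind(c(0.5, 0.6), c(0.5, 0.5))), "sum to 1")
})

test_that("Blahut-Arimoto recovers closed-form capacities with monotone objective", {
  # binary symmetric channel, crossover 0.1: CC = 1 - H2(0.1)
  bsc <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  res <- blahut_arimoto(bsc, tol = 1e-10)
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(res$cc, 1 - h2(0.1), tolerance = 1e-7)
  expect_equal(res$Q_star, c(0.5, 0.5), tolerance = 1e-4)
  expect_true(all(diff(res$trace) > -1e-12))  # non-decreasing objective

  # noiseless channel: 1 bit; constant output: 0 bits
  expect_equal(blahut_arimoto(diag(2))$cc, 1, tolerance = 1e-9)
  expect_equal(blahut_arimoto(rbind(c(1, 0), c(1, 0)))$cc, 0,
               tolerance = 1e-9)

  # capacity dominates MI at uniform input for arbitrary channels
  set.seed(91)
  for (i in 1:15) {
    P <- matrix(stats::rgamma(20, 0.8), 4, 5)
    P <- P / rowSums(P)
    expect_gte(blahut_arimoto(P)$cc + 1e-9, mutual_information(P))
  }
  expect_error(blahut_arimoto(bsc, tol = 0, max_iter = 3L), "converge")
})

test_that("Gamma fitting recovers parameters and scales equivariantly", {
  set.seed(92)
  x <- stats::rgamma(1e5, shape = 3, scale = 2)
  fit <- fit_gamma(x)
  expect_equal(fit$shape, 3, tolerance = 0.05)
  expect_equal(fit$scale, 2, tolerance = 0.05)
  expect_equal(fit$offset, 0)
  # scaling samples scales the scale parameter, not the shape
  fit3 <- fit_gamma(3 * x)
  expect_equal(fit3$shape, fit$shape, tolerance = 0.02)
  expect_equal(fit3$scale, 3 * fit$scale, tolerance = 0.02)
  # zero-containing counts are offset before fitting
  fit0 <- fit_gamma(c(0, stats::rpois(50, 4)))
  expect_equal(fit0$offset, 0.5)
  expect_error(fit_gamma(rep(2, 50)), "zero variance")
  expect_error(fit_gamma(1:5), "at least 10")
})

test_that("Gamma-Gamma KL divergence matches numerical quadrature", {
  fp <- list(shape = 2, scale = 1)
  fq <- list(shape = 3, scale = 1)
  expect_equal(kl_gamma(fp, fp), 0)
  quad <- stats::integrate(function(x)
    stats::dgamma(x, 2, scale = 1) *
      (stats::dgamma(x, 2, scale = 1, log = TRUE) -
       stats::dgamma(x, 3, scale = 1, log = TRUE)),
    0, Inf, rel.tol = 1e-10)$value
  expect_equal(kl_gamma(fp, fq, base = "nats"), quad, tolerance = 1e-7)
  expect_equal(kl_gamma(fp, fq), quad / log(2), tolerance = 1e-7)
  # asymmetry
  expect_false(isTRUE(all.equal(kl_gamma(fp, fq), kl_gamma(fq, fp))))
  expect_gt(kl_gamma(list(shape = 5, scale = 2), fq), 0)
  expect_error(kl_gamma(list(shape = -1, scale = 1), fq), "invalid")
})

test_that("channels built from responses behave at the edges", {
  # perfectly separable doses: 1 bit at uniform input
  rs <- list(`20` = rep(c(1, 2), 15), `400` = rep(c(40, 41), 15))
  ch <- build_channel(rs)
  expect_equal(mutual_information(ch), 1)
  expect_equal(rowSums(ch$P), c(`20` = 1, `400` = 1))
  expect_error(build_channel(rs["20"]), "two doses")
  expect_warning(build_channel(list(`1` = 1:5, `2` = 6:10)), "fewer than 20")

  # more replicates shrink the bootstrap SE and keep MI stable
  set.seed(93)
  gen <- function(n) list(`20` = stats::rpois(n, 2), `400` = stats::rpois(n, 25))
  small <- mi_bootstrap(gen(30), n_boot = 60)
  large <- mi_bootstrap(gen(120), n_boot = 60)
  expect_lt(abs(large$mi - small$mi), 3 * (small$se + large$se) + 0.1)
  expect_lt(large$se, small$se + 0.02)
})
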