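test_that("single-pair binding equilibrium matches the two-state closed form", {
  g <- geometry_params(n_side = 1)
  sp <- free_species_df(c("X", "Y", "B"), D = 0)
  kb <- 2; ku <- 1
  net <- test_network(sp, list(
    list(reactants = c("X", "Y"), products = "B", propensity = kb),
    list(reactants = "B", products = c("X", "Y"), propensity = ku)), g)
  cfg <- test_config(net, matrix(c(1L, 1L, 0L), nrow = 1))
  tr <- simulate_trajectory(cfg, net, t_end = 2000,
                            sample_times = seq(0, 2000, by = 0.5), seed = 8)
  bound <- mean(tr$totals[, "B"])
  expect_equal(bound, kb / (kb + ku), tolerance = 0.06)
})

test_that("free diffusion reproduces lattice random-walk mean-square displacement", {
  g <- geometry_params()
  sp <- free_species_df("W", D = 0.01)  # total hop rate D/l0^2 = 6.25/s
  net <- test_network(sp, list(), g)
  cm <- matrix(0L, g$n_chambers, 1)
  centre <- 46L + 45L * 91L
  cm[centre, 1] <- 400L
  cfg <- test_config(net, cm)
  t_end <- 2
  tr <- simulate_trajectory(cfg, net, t_end = t_end,
                            sample_times = c(0, t_end), seed = 9)
  idx <- which(tr$final_counts[, 1] > 0)
  n <- tr$final_counts[idx, 1]
  dr <- (idx - 1L) %% 91L - 45L
  dc <- (idx - 1L) %/% 91L - 45L
  msd <- sum(n * (dr^2 + dc^2)) / sum(n)
  # total hop rate Gamma = D/l0^2 => MSD = Gamma * t chamber^2 (= D*t)
  expect_equal(msd, (0.01 / 0.04^2) * t_end, tolerance = 0.2)
})

test_that("mask-confined species never cross the cluster boundary", {
  g <- geometry_params(n_side = 21)
  sp <- data.frame(name = c("C", "F"), compartment = "NK-membrane",
                   D = 0.5, confinement = c("nkg2d", "none"),
                   phospho_vav = FALSE, stringsAsFactors = FALSE)
  net <- test_network(sp, list(), g)
  mask <- integer(g$n_chambers)
  block <- as.vector(outer(10:12, (9:11) * 21L, `+`))
  mask[block] <- 1L
  cm <- matrix(0L, g$n_chambers, 2)
  cm[block[1], 1] <- 40L   # confined
  cm[block[1], 2] <- 40L   # free
  cfg <- test_config(net, cm, mask_a = mask)
  tr <- simulate_trajectory(cfg, net, t_end = 10, seed = 10)
  expect_equal(sum(tr$final_counts[-block, 1]), 0L)
  expect_gt(sum(tr$final_counts[-block, 2]), 0L)  # free species escaped
})

test_that("SSA ensemble mean converges to the mass-action ODE solution", {
  g <- geometry_params(n_side = 1)
  sp <- free_species_df(c("X", "Y", "B", "P"), D = 0)
  rx <- list(
    list(reactants = c("X", "Y"), products = "B", propensity = 0.05),
    list(reactants = "B", products = c("X", "Y"), propensity = 1),
    list(reactants = "B", products = c("B", "P"), propensity = 0.5),
    list(reactants = "P", products = character(0), propensity = 0.2))
  net <- test_network(sp, rx, g)
  times <- seq(0, 10, by = 1)
  cfg <- test_config(net, matrix(c(200L, 200L, 0L, 0L), nrow = 1))
  set.seed(14)
  sims <- replicate(25, simulate_trajectory(cfg, net, t_end = 10,
                                            sample_times = times)$totals[, "P"])
  rhs <- nkrsig:::network_ode_rhs(net$stoich, net$reactant_idx,
                                  net$reactions$propensity, 1)
  ode <- deSolve::lsoda(c(X = 200, Y = 200, B = 0, P = 0), times, rhs, NULL)
  expect_equal(rowMeans(sims)[-1], unname(ode[-1, "P"]), tolerance = 0.05)
})

test_that("trajectories conserve every moiety and need both ligands to signal", {
  net <- default_net()
  cc <- cell_counts(nkg2dl = 100, hlac = "low", network = net)
  cfg <- make_config("homogeneous", cc, network = net, seed = 21)
  tr <- simulate_trajectory(cfg, net, t_end = 5, seed = 22)
  mt <- moiety_totals(tr, net)
  expect_true(all(apply(mt, 2, function(x) diff(range(x))) == 0))
  expect_gt(tr$pvav1[length(tr$pvav1)] + sum(tr$totals[, "RL"]), -1)  # ran

  # no NKG2DL and no HLA-C -> no trigger, pVav1 identically zero
  cc0 <- cell_counts(nkg2dl = 0, hlac = 0, network = net)
  cfg0 <- make_config("homogeneous", cc0, network = net, seed = 23)
  tr0 <- simulate_trajectory(cfg0, net, t_end = 3, seed = 24)
  expect_true(all(tr0$pvav1 == 0))
})

test_that("trajectories are reproducible from their seed", {
  g <- geometry_params(n_side = 11)
  sp <- free_species_df(c("X", "Y", "B"), D = 0.2)
  net <- test_network(sp, list(
    list(reactants = c("X", "Y"), products = "B", propensity = 1),
    list(reactants = "B", products = c("X", "Y"), propensity = 1)), g)
  cm <- matrix(0L, g$n_chambers, 3)
  cm[, 1] <- 2L; cm[, 2] <- 2L
  cfg <- test_config(net, cm)
  t1 <- simulate_trajectory(cfg, net, t_end = 5, seed = 31)
  t2 <- simulate_trajectory(cfg, net, t_end = 5, seed = 31)
  expect_identical(t1$totals, t2$totals)
  expect_identical(t1$final_counts, t2$final_counts)
})

test_that("ensembles demand replication and mean response rises with dose", {
  net <- default_net()
  expect_error(run_ensemble(net, "disjoint", 20, n_reps = 1), "at least 2")
  expect_error(run_ensemble(net, "disjoint", numeric(0)), "dose")
  ens <- run_ensemble(net, "disjoint", c(20, 400), hlac = "low", n_reps = 4,
                      t_end = 10, seed = 33)
  s <- summary(ens)
  m20 <- s$mean[s$dose == 20 & s$time == 10]
  m400 <- s$mean[s$dose == 400 & s$time == 10]
  expect_gt(m400, m20)
  expect_error(responses_at(ens, 99), "not recorded")
  expect_length(responses_at(ens, 10)[["400"]], 4L)
})
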