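test_that("lattice geometry bookkeeping is exact", {
  g <- geometry_params()
  expect_identical(g$n_chambers, 8281L)
  expect_equal(g$box_area_um2, 13.2496)
  expect_error(geometry_params(n_side = 0))
  expect_error(geometry_params(l0 = -1))
})

test_that("rate-to-propensity conversion matches the hand unit-conversion oracle", {
  g <- geometry_params()
  # k_on = 2.387e-2 uM^-1 s^-1 over nu = 40 x 40 x 2 nm^3 = 3.2e-21 L:
  # 2.387e4 M^-1 s^-1 / (N_A * nu) = 12.39 s^-1 per pair
  oracle <- 2.387e-2 * 1e6 / (6.02214076e23 * 3.2e-21)
  expect_equal(rate_to_propensity(2.387e-2, "uM-1s-1", "recep-lig", g),
               oracle, tolerance = 1e-12)
  expect_equal(oracle, 12.39, tolerance = 1e-3)
  # zero rate -> zero propensity
  expect_equal(rate_to_propensity(0, "uM-1s-1", "cytosol-recep", g), 0)
  # volume-class ratio: cytosol-recep vs recep-lig = d_contact / z = 2/1000
  expect_equal(rate_to_propensity(1, "uM-1s-1", "cytosol-recep", g) /
                 rate_to_propensity(1, "uM-1s-1", "recep-lig", g),
               2 / 1000, tolerance = 1e-12)
  # doubling the reaction volume halves the propensity
  g2 <- geometry_params(d_contact = 4)
  expect_equal(rate_to_propensity(1, "uM-1s-1", "recep-lig", g2),
               rate_to_propensity(1, "uM-1s-1", "recep-lig", g) / 2)
  # unimolecular rates must not carry a volume class
  expect_error(rate_to_propensity(1, "s-1", "recep-lig", g), "unimolecular")
  expect_error(rate_to_propensity(1, "uM-1s-1", NULL, g), "volume class")
})

test_that("density-to-count conversion pins the printed copy numbers", {
  g <- geometry_params()
  expect_identical(counts_from_density(4, g), 53L)
  expect_identical(counts_from_density(882, g), 11686L)
  expect_identical(counts_from_density(1.5, g), 20L)
  expect_identical(counts_from_density(30, g), 400L)
  expect_identical(counts_from_density(0, g), 0L)
  expect_identical(counts_from_density(10, g), as.integer(round(10 * g$box_area_um2)))
  expect_error(counts_from_density(-1, g))
})

test_that("network builds with KP flags and conserves every moiety", {
  net <- default_net()
  expect_equal(nrow(net$species), 28L)
  expect_gte(sum(net$reactions$kp == "activating"), 1L)
  expect_gte(sum(net$reactions$kp == "inhibitory"), 1L)
  expect_identical(moiety_violation(net), 0L)

  # KP ablation removes the flagged reactions and nothing else
  for (flags in list(c(FALSE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))) {
    sub <- build_network(flags[1], flags[2])
    expect_lt(nrow(sub$reactions), nrow(net$reactions))
    if (!flags[1]) expect_equal(sum(sub$reactions$kp == "activating"), 0L)
    if (!flags[2]) expect_equal(sum(sub$reactions$kp == "inhibitory"), 0L)
    kept <- net$reactions$reaction %in% sub$reactions$reaction
    expect_equal(net$reactions$propensity[kept], sub$reactions$propensity)
    expect_identical(moiety_violation(sub), 0L)
  }
  no_kp <- build_network(FALSE, FALSE)
  expect_equal(sum(no_kp$reactions$kp != "none"), 0L)
})

test_that("a parameter file referencing unknown species is rejected", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "counts: {}",
    "species:",
    "  - {name: A, compartment: cytosol, D: 1, confinement: none, moieties: {A: 1}}",
    "rates:",
    "  k1: {value: 1.0, unit: s-1}",
    "reactions:",
    "  - {reaction: 'A -> B', rate: k1, kp: none, sector: act, bond: local}"
  ), bad)
  expect_error(build_network(file = bad), "unknown species")
})

test_that("cell counts carry the printed copy numbers and respect doses", {
  net <- default_net()
  cc <- cell_counts(nkg2dl = 400, hlac = "low", network = net)
  expect_identical(unname(cc["NKG2D"]), 53L)
  expect_identical(unname(cc["KIR2DL1"]), 11686L)
  expect_identical(unname(cc["HLAC"]), 4213L)
  expect_identical(unname(cc["NKG2DL"]), 400L)
  cc_hi <- cell_counts(hlac = "high", network = net)
  expect_identical(unname(cc_hi["HLAC"]), 11686L)
  expect_error(cell_counts(nkg2dl = -5, network = net))
})
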