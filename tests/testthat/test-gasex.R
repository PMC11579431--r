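test_that("observed discrimination matches the mass-balance form", {
  # direct high-precision evaluation: xi = 6, 6120/987.88
  expect_equal(observed_discrimination(300, 250, -7.02, -6.00),
               6120 / 987.88, tolerance = 1e-12)
  expect_equal(observed_discrimination(310, 290, -7, -7), 0)
  # invariance under common rescaling of the CO2 mole fractions
  expect_equal(observed_discrimination(300, 250, -7.02, -6.00),
               observed_discrimination(600, 500, -7.02, -6.00))
  expect_error(observed_discrimination(300, 300, -7, -6), "drawdown")
})

test_that("discrimination inversion is the exact inverse", {
  for (delta in c(0.5, 3.2, 6.1)) {
    dout <- c4dehyd:::invert_discrimination(300, 260, -7.02, delta)
    expect_equal(observed_discrimination(300, 260, -7.02, dout), delta,
                 tolerance = 1e-12)
  }
})

test_that("ternary factor has the right units and scalings", {
  expect_equal(ternary_factor(0, 0.1), 0)
  expect_equal(ternary_factor(2, 0.1, a_s = 0), 0.01)
  expect_equal(ternary_factor(2, 0.2, a_s = 0),
               ternary_factor(2, 0.1, a_s = 0) / 2)
  expect_error(ternary_factor(2, 0), "g_sc")
})

test_that("cuticle-corrected C_i reduces to classical and shifts down", {
  # g_cw -> 0 limit equals the classical calculation
  expect_equal(cuticle_corrected_ci(20, 3, 0.3, 280, g_cw = 0, beta = 0),
               classical_ci(20, 3, 0.3, 280), tolerance = 1e-12)
  # transpiring, assimilating leaf: cuticular pathway lowers C_i
  ci_cut <- cuticle_corrected_ci(20, 3, 0.3, 280, g_cw = 2, beta = 0.025)
  expect_lt(ci_cut, classical_ci(20, 3, 0.3, 280))
  # monotone in beta at fixed positive A
  ci_b2 <- cuticle_corrected_ci(20, 3, 0.3, 280, g_cw = 2, beta = 0.05)
  expect_lt(ci_cut, ci_b2)  # larger beta -> more CO2 leaks in -> higher C_i
  # A = 0, E = 0 gives C_i = C_a
  expect_equal(cuticle_corrected_ci(0, 0, 0.3, 280), 280)
})

test_that("ATP production scales with gross assimilation and yield ratio", {
  expect_equal(j_atp(19, 0.3, 0.3, R_LIGHT = 1), 5.4 * 20)
  expect_equal(j_atp(20, 0.27, 0.3, R_LIGHT = 1.19), 5.4 * 21.19 * 0.9)
  expect_equal(j_atp(10, 0, 0.3, R_LIGHT = 1), 0)
  # linear in (A_low + R_LIGHT) and in Y_II
  expect_equal(j_atp(2 * 10 + 1, 0.3, 0.3, R_LIGHT = 1),
               2 * j_atp(10, 0.3, 0.3, R_LIGHT = 1))
  expect_equal(j_atp(10, 0.6, 0.3, R_LIGHT = 1),
               2 * j_atp(10, 0.3, 0.3, R_LIGHT = 1))
  expect_error(j_atp(10, 0.3, 0, 1), "Y_II_low")
})

test_that("mesophyll conductance follows the supply function", {
  expect_equal(mesophyll_conductance(5, 150, 100), 0.1)
  expect_equal(mesophyll_conductance(0, 150, 100), 0)
  expect_warning(mesophyll_conductance(5, 100, 150), "drawdown")
  expect_error(mesophyll_conductance(5, 100, 100), "undefined")
})

test_that("ATP-cost calibration returns the generating cost on clean data", {
  cost <- calibrate_atp_cost(sim_noiseless$replicates, params_maize,
                             grid = seq(3, 8, by = 0.05))
  expect_lte(cost, 5.4)
  expect_gte(cost, 3)
  # a singleton grid either passes at 5.4 or errors
  expect_equal(calibrate_atp_cost(sim_noiseless$replicates, params_maize,
                                  grid = 5.4), 5.4)
  # an impossible grid reports the offending steps
  expect_error(calibrate_atp_cost(sim_noiseless$replicates, params_maize,
                                  g_BS = 0.03, grid = 3),
               "positive bundle-sheath")
})
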