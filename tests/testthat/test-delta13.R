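test_that("fractionation corrections vanish with their driving fluxes", {
  p <- params_maize
  fr <- fractionation_params(25, V_C = 20, V_O = 0, V_P = 25, p)
  # no photorespiration: b3 reduced only by the respiratory term
  e_prime <- p$d13_growth - p$d13_measurement
  expect_equal(e_prime, -0.98)
  expect_equal(fr$b3, 29 - e_prime * p$R_LIGHT / 20)
  p0 <- c4_params("maize", R_LIGHT = 0)
  fr0 <- fractionation_params(25, 20, 5, 25, p0)
  expect_equal(fr0$b3, 29 - 11.6 * 2.5 / 20)  # only the f-term remains
  expect_equal(fr0$b4, p$b4_offset - p$b4_slope_K / 298.15)
})

test_that("default liquid-phase and PEPC fractionations at 25 C are standard", {
  fr <- fractionation_params(25, 20, 1, 25, params_maize)
  expect_equal(fr$a_m, 1.18 - 0.0041 * 25 + 0.7)     # about 1.78 permil
  b4p <- 26.19 - 9483 / 298.15                        # about -5.62 permil
  expect_lt(abs(b4p + 5.62), 0.01)
  expect_gt(fr$b3, fr$b4)                             # b3 > b4 always
})

test_that("modelled discrimination collapses to b4 in the no-gradient limit", {
  fr <- list(a_s = 4.4, a_m = 1.8, b3 = 29, b4 = -5.6, s = 1.8)
  expect_equal(modelled_discrimination(0, 280, 280, 280, 2000, 0, fr),
               fr$b4)
  # C_M = C_i: the a_m term collapses, leaving diffusion + C4 terms
  d <- modelled_discrimination(0, 280, 180, 180, 2000, 0.2, fr)
  leak <- fr$b3 * 2000 / (2000 - 180) - fr$s * (1 + 0.2 * 180 / (2000 - 180))
  expect_equal(d, 4.4 * 100 / 280 + (fr$b4 + 0.2 * leak) * 180 / 280)
  expect_error(modelled_discrimination(1, 280, 180, 150, 2000, 0.2, fr), "t")
  expect_error(modelled_discrimination(0, 280, 180, 150, 150, 0.2, fr),
               "singular")
})

test_that("randomized inputs match an independent assembly of the model", {
  set.seed(21)
  for (i in 1:100) {
    t <- runif(1, 0, 0.05); Ca <- runif(1, 250, 350)
    Ci <- Ca * runif(1, 0.4, 0.8); Cm <- Ci * runif(1, 0.5, 0.9)
    Cbs <- runif(1, 800, 4000); phi <- runif(1, 0, 0.5)
    fr <- list(a_s = 4.4, a_m = runif(1, 1, 3), b3 = runif(1, 25, 30),
               b4 = runif(1, -7, -4), s = runif(1, 1, 3))
    got <- modelled_discrimination(t, Ca, Ci, Cm, Cbs, phi, fr)
    # assembled term by term, different order of operations
    term_s <- fr$a_s * (Ca - Ci) / (Ca * (1 - t))
    term_m <- fr$a_m * (Ci - Cm) / Ca
    ratio <- Cbs / (Cbs - Cm)
    b_eff <- fr$b4 + phi * (fr$b3 * ratio -
                              fr$s - fr$s * phi * Cm / (Cbs - Cm))
    want <- term_s + (1 + t) / (1 - t) * (term_m + b_eff * Cm / Ca)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("discrimination rises with leakiness at physiological values", {
  fr <- list(a_s = 4.4, a_m = 1.8, b3 = 28, b4 = -5.6, s = 1.8)
  phis <- seq(0.05, 0.6, by = 0.05)
  d <- vapply(phis, function(phi)
    modelled_discrimination(0.01, 300, 180, 140, 2000, phi, fr), numeric(1))
  expect_true(all(diff(d) > 0))
})
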