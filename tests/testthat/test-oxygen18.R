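test_that("PDB to SMOW conversion is the exact affine map", {
  expect_equal(pdb_to_smow(0), 30.92)
  expect_equal(pdb_to_smow(-30.92 / 1.03092), 0)
  # linearity
  expect_equal(pdb_to_smow(3) - pdb_to_smow(1), 2 * 1.03092)
})

test_that("Craig-Gordon enrichment has the right limits", {
  # dry air, no fractionation: evaporative site = source
  expect_equal(evaporative_site_water(-15, w_a = 1e-12, w_i = 30, 25,
                                      source_water = -5, eps_k = 0),
               -5 + c4dehyd:::equilibrium_vapour_fractionation(25),
               tolerance = 1e-10)
  # saturated air with vapour in equilibrium: source + eps_plus recovered
  eps_p <- c4dehyd:::equilibrium_vapour_fractionation(25)
  d_eq_vap <- -5 - eps_p
  expect_equal(evaporative_site_water(d_eq_vap, w_a = 30, w_i = 30 + 1e-9,
                                      25, source_water = -5, eps_k = 28),
               d_eq_vap + eps_p, tolerance = 1e-6)
  # defaults at 25 C enrich above source for sub-saturated air
  expect_gt(evaporative_site_water(-15, 21.4, 31.3, 25, -5), -5)
  expect_error(evaporative_site_water(-15, 32, 31.3, 25, -5), "condensation")
})

test_that("equilibrium CO2-water fractionation follows 17604/T - 17.93", {
  expect_equal(d18_equilibrated_co2(0, 25), 17604 / 298.15 - 17.93)
  # decreases with temperature, shifts 1:1 with water delta
  expect_gt(d18_equilibrated_co2(0, 20), d18_equilibrated_co2(0, 30))
  expect_equal(d18_equilibrated_co2(5, 25) - d18_equilibrated_co2(0, 25), 5)
})

test_that("assimilated CO2 delta is the flux-weighted mass balance", {
  expect_equal(d18_assimilated(300, 250, 30, 30), 30)
  expect_equal(d18_assimilated(300, 1e-9, 30, 45), 30, tolerance = 1e-9)
  # worked case against the ratio expression
  expect_equal(d18_assimilated(310, 270, 28, 31),
               (310 * 28 - 270 * 31) / 40)
  expect_error(d18_assimilated(300, 300, 30, 31), "undefined")
})

test_that("intercellular CO2 delta satisfies its limits", {
  expect_equal(d18_intercellular(35, 20, 280, 280, 0.01), 35)
  # t = 0 reduces to the simple two-membrane balance
  abar <- 8.8
  dstep <- 20 + abar * (1 + 20 / 1000)
  expect_equal(d18_intercellular(35, 20, 280, 180, 0),
               (280 * 35 - 100 * dstep) / 180)
  expect_warning(d18_intercellular(35, 20, 280, 290, 0), "non-physical")
})

test_that("C_M from the 18O chain is exact and degree-1 homogeneous", {
  # symmetric limit: identical deltas collapse the ratio to 1
  expect_equal(mesophyll_co2(150, 40, 20, 40), 150)
  # randomized inputs match an independent evaluation of the ratio
  set.seed(7)
  for (i in 1:50) {
    Ci <- runif(1, 80, 250); di <- runif(1, 30, 50)
    dA <- runif(1, 10, 30); dce <- runif(1, 35, 55)
    aw <- 0.8; alpha <- 1 + aw / 1000
    expected <- Ci * (di - alpha * dA - aw) / (dce - alpha * dA - aw)
    expect_equal(mesophyll_co2(Ci, di, dA, dce), expected, tolerance = 1e-12)
    expect_equal(mesophyll_co2(2 * Ci, di, dA, dce), 2 * expected,
                 tolerance = 1e-12)
  }
  # vanishing denominator is an unresolvable step
  aw <- 0.8
  expect_error(mesophyll_co2(150, 40, 20, (1 + aw / 1000) * 20 + aw),
               "unresolvable")
})

test_that("noiseless synthetic steps recover the latent C_M below 0.1", {
  p <- params_maize
  for (r in sim_noiseless$replicates) {
    d <- derive_steps(r, p)
    tr <- sim_noiseless$truth[sim_noiseless$truth$day_id == r$day_id, ]
    expect_lt(max(abs(d$C_M - tr$C_M)), 0.1)
    # physiological ordering along the diffusion path
    expect_true(all(d$C_M > 0 & d$C_M < d$C_i))
  }
})
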