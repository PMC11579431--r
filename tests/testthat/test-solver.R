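test_that("bundle-sheath O2 follows the diffusion balance", {
  p <- params_maize
  expect_equal(o_bs(30, 0.002, c4_params("maize", alpha = 0)), p$O_M)
  expect_equal(o_bs(0, 0.002, p), p$O_M)
  expect_equal(o_bs(30, 0.002, p), p$O_M + 0.15 * 30 / (0.047 * 0.002))
  expect_error(o_bs(30, 0, p), "g_BS")
})

test_that("gamma* = 0 collapses to the closed-form allocation", {
  p0 <- c4_params("maize", gamma_star = 1e-300)  # effectively zero
  sol <- solve_fluxes(A = 20, J_ATP = 120, C_M = 100, g_BS = 0.002, p0)
  expect_true(sol$feasible)
  expect_equal(sol$V_O, 0, tolerance = 1e-10)
  expect_equal(sol$V_C, 21.19, tolerance = 1e-9)
  expect_equal(sol$V_P, (120 - 3 * 21.19) / 2, tolerance = 1e-8)
})

test_that("all five governing equations hold to 1e-9 on feasible returns", {
  inp <- random_solver_inputs(400, seed = 31)
  sol <- solve_fluxes(inp$A, inp$J_ATP, inp$C_M, inp$g_BS, params_maize)
  ok <- sol$feasible
  expect_gt(mean(ok), 0.5)
  res <- c4dehyd:::flux_residuals(sol[ok, ], inp$A[ok], inp$J_ATP[ok],
                                  inp$C_M[ok], inp$g_BS[ok], params_maize)
  expect_lt(max(abs(res)), 1e-9)
})

test_that("closed form matches the independent bisection oracle", {
  inp <- random_solver_inputs(300, seed = 57)
  sol <- solve_fluxes(inp$A, inp$J_ATP, inp$C_M, inp$g_BS, params_maize)
  n_checked <- 0
  for (i in seq_len(nrow(inp))) {
    orc <- oracle_solve(inp$A[i], inp$J_ATP[i], inp$C_M[i], inp$g_BS[i],
                        params_maize)
    expect_equal(is.null(orc), !sol$feasible[i])
    if (is.null(orc)) next
    n_checked <- n_checked + 1
    for (v in c("V_O", "V_C", "V_P", "C_BS"))
      expect_equal(sol[[v]][i], orc[[v]], tolerance = 1e-8)
  }
  expect_gt(n_checked, 100)
})

test_that("a multidimensional root-finder confirms returned states", {
  skip_if_not_installed("pracma")
  p <- params_maize
  inp <- random_solver_inputs(25, seed = 4)
  sol <- solve_fluxes(inp$A, inp$J_ATP, inp$C_M, inp$g_BS, p)
  for (i in which(sol$feasible)) {
    fn <- function(x) {  # x = (V_C, V_P, V_O, C_BS, O_BS)
      c(x[1] - 0.5 * x[3] - p$R_LIGHT - inp$A[i],
        x[3] - 2 * p$gamma_star * x[5] * x[1] / x[4],
        x[4] - inp$C_M[i] - (x[2] - 0.5 * p$R_LIGHT - inp$A[i]) / inp$g_BS[i],
        x[5] - p$O_M - p$alpha * inp$A[i] / (0.047 * inp$g_BS[i]),
        3 * x[1] + 3.5 * x[3] + 2 * x[2] - inp$J_ATP[i])
    }
    x0 <- unlist(sol[i, c("V_C", "V_P", "V_O", "C_BS", "O_BS")]) *
      (1 + 0.02)  # perturbed start
    out <- pracma::fsolve(fn, x0, tol = 1e-12)
    expect_equal(unname(out$x),
                 unname(unlist(sol[i, c("V_C", "V_P", "V_O", "C_BS", "O_BS")])),
                 tolerance = 1e-6)
  }
})

test_that("leakiness identities hold", {
  p <- params_maize
  RM <- 0.5 * p$R_LIGHT
  expect_equal(leakiness(20 + RM, 20, p), 0)
  expect_equal(leakiness(30, 20, c4_params("maize", R_LIGHT = 1)), 9.5 / 30)
  expect_error(leakiness(0, 20, p), "V_P")
  # two-form identity on solved states: (V_P - R_M - A)/V_P = g(C_BS - C_M)/V_P
  inp <- random_solver_inputs(200, seed = 8)
  sol <- solve_fluxes(inp$A, inp$J_ATP, inp$C_M, inp$g_BS, p)
  ok <- sol$feasible
  expect_equal(sol$phi[ok],
               inp$g_BS[ok] * (sol$C_BS[ok] - inp$C_M[ok]) / sol$V_P[ok],
               tolerance = 1e-9)
})

test_that("oxygenation-to-carboxylation ratio has a sane magnitude", {
  # ratio law V_O/V_C = 2 gamma* O_BS / C_BS at textbook concentrations
  expect_equal(2 * 0.000233 * 210000 / 2000, 0.04893)
  inp <- random_solver_inputs(100, seed = 12)
  sol <- solve_fluxes(inp$A, inp$J_ATP, inp$C_M, inp$g_BS, params_maize)
  ok <- sol$feasible
  expect_equal(sol$V_O[ok] / sol$V_C[ok],
               2 * params_maize$gamma_star * sol$O_BS[ok] / sol$C_BS[ok],
               tolerance = 1e-9)
})

test_that("fold projection returns a continuous near-feasible state", {
  p <- params_maize
  # push J just below the feasible minimum at fixed other inputs
  base <- list(A = 20, C_M = 120, g = 0.002)
  feas <- function(J) solve_fluxes(base$A, J, base$C_M, base$g, p)$feasible
  Jlo <- 100; Jhi <- 140
  while (Jhi - Jlo > 1e-6) {
    mid <- (Jlo + Jhi) / 2
    if (feas(mid)) Jhi <- mid else Jlo <- mid
  }
  just_out <- solve_fluxes(base$A, Jlo - 0.05, base$C_M, base$g, p,
                           project = TRUE)
  just_in <- solve_fluxes(base$A, Jhi + 0.05, base$C_M, base$g, p)
  expect_false(just_out$feasible)
  expect_gt(just_out$violation, 0)
  expect_false(is.na(just_out$V_C))
  # states on either side of the fold are close
  expect_equal(just_out$V_C, just_in$V_C, tolerance = 0.05)
  expect_equal(just_out$C_BS, just_in$C_BS, tolerance = 0.15)
})
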