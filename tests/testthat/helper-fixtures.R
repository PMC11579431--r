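# Shared fixtures, built once per test run. All synthetic; seeds fixed.

params_maize <- c4_params("maize")
params_sorghum <- c4_params("sorghum")

# noiseless two-replicate maize dataset: exact forward/inverse anchor
sim_noiseless <- simulate_dataset(
  sim_config("maize", n_replicates = 2,
             noise_d13 = 0, noise_d18 = 0, noise_A = 0, seed = 101))

# small noisy maize dataset at default (study-condition) noise
sim_noisy <- simulate_dataset(sim_config("maize", n_replicates = 2, seed = 202))

# random physiological inputs for solver property tests
random_solver_inputs <- function(n, seed) {
  set.seed(seed)
  A <- runif(n, 5, 35)
  R <- params_maize$R_LIGHT
  # J must exceed the ATP demand of carboxylation + the C4 pump at zero
  # leak for a feasible state to exist; sample around that scale
  J <- (3 * (A + R) + 2 * (A + 0.5 * R)) * runif(n, 1.01, 1.25)
  data.frame(A = A, J_ATP = J,
             C_M = runif(n, 60, 200),
             g_BS = 10^runif(n, -3.3, -2.3))
}

# independent scalar-bisection oracle for the flux system: solves
# h(V_O) = V_O * C_BS(V_O) - 2 gamma* O_BS V_C(V_O) = 0 by bracketed
# bisection on a fine grid (no quadratic formula), then applies the same
# physical qualification as the solver
oracle_solve <- function(A, J, C_M, g, p) {
  R <- p$R_LIGHT; RM <- p$R_M_fraction * R
  OBS <- p$O_M + p$alpha * A / (p$diff_sol_ratio * g)
  D <- C_M + (J / 2 - 1.5 * (A + R) - RM - A) / g
  h <- function(vo) {
    cbs <- D - 2.5 * vo / g
    vc <- A + R + 0.5 * vo
    vo * cbs - 2 * p$gamma_star * OBS * vc
  }
  vo_max <- (J - 3 * (A + R)) / 5
  if (vo_max <= 0) return(NULL)
  grid <- seq(0, vo_max, length.out = 4000)
  hv <- vapply(grid, h, numeric(1))
  roots <- list()
  for (j in which(diff(sign(hv)) != 0)) {
    vo <- uniroot(h, grid[c(j, j + 1)], tol = 1e-14)$root
    cbs <- D - 2.5 * vo / g
    vp <- (J - 3 * (A + R) - 5 * vo) / 2
    vc <- A + R + 0.5 * vo
    if (vo >= 0 && vc > 0 && vp > 0 && cbs > 0 && cbs >= C_M - 1e-9)
      roots[[length(roots) + 1]] <- c(V_O = vo, V_C = vc, V_P = vp,
                                      C_BS = cbs, O_BS = OBS)
  }
  if (!length(roots)) return(NULL)
  roots[[which.min(vapply(roots, `[[`, numeric(1), "C_BS"))]]
}
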