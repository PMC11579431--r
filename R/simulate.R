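#' Configuration of the forward dehydration simulator
#'
#' Defines the conditions of a simulated fast-dehydration experiment with
#' known ground truth. The forward closure uses the legacy fixed
#' ATP-partitioning assumption (`x_partition`, fraction of J_ATP consumed
#' by PEP regeneration, V_P = x J_ATP / 2); this is the one place that
#' assumption appears, because the inference side deliberately avoids it.
#'
#' The default water-potential trajectory runs from -0.3 MPa downward in
#' steps drawn uniformly from 0.1-0.15 MPa and stops at `psi_end`; the end
#' point is set so the true conductance line g_BS0 + k psi stays positive
#' throughout (with the study-scale truth values the line crosses zero near
#' -1 MPa, which caps the usable dehydration range).
#'
#' @param species `"maize"` or `"sorghum"`; sets the truth defaults
#'   (`true_gbs0`, `true_k`) to the study-condition species values
#'   (0.00209, 0.00218) and (0.00200, 0.00154) respectively.
#' @param n_replicates number of simulated days (default 6 maize,
#'   7 sorghum).
#' @param psi_start,psi_end,psi_step_range trajectory of leaf water
#'   potential (MPa).
#' @param true_gbs0,true_k ground truth of the conductance line.
#' @param x_partition fraction of J_ATP to PEP regeneration, 0.4.
#' @param g_M mesophyll conductance, held constant across the trajectory
#'   (mol m-2 s-1).
#' @param J0,eta_J ATP production at -0.3 MPa (umol m-2 s-1) and its
#'   power-law exponent in (-psi/0.3).
#' @param Y0,eta_Y PSII yield at -0.3 MPa and its power-law exponent.
#' @param yield_ratio Y(II) ambient / Y(II) low-O2, constant.
#' @param ci_min,ci_max,ci_mid,ci_scale logistic decline of intercellular
#'   CO2 with psi (umol mol-1; midpoint and scale in MPa).
#' @param C_in reference CO2 entering the cuvette (umol mol-1).
#' @param draw_factor cuvette drawdown per unit flux (leaf area / molar
#'   flow, (umol mol-1)/(umol m-2 s-1)); 1.22 corresponds to 6 cm2 at
#'   490 umol s-1.
#' @param T_leaf leaf temperature (C).
#' @param w_i,w_a leaf-internal and cuvette vapour mole fractions
#'   (mmol mol-1); defaults give a vapour pressure deficit of about 1 kPa
#'   at 25 C.
#' @param d13_in delta13C of reference CO2 (permil V-PDB).
#' @param d18C_in delta18O of reference CO2 (permil V-SMOW).
#' @param d18W_in delta18O of reference water vapour (permil V-SMOW).
#' @param noise_d13 SD of Gaussian noise on Delta13C (permil), 0.2.
#' @param noise_d18 SD of Gaussian noise on the delta18O observables
#'   (permil), 0.2.
#' @param noise_A SD of Gaussian noise on assimilation (umol m-2 s-1).
#' @param seed integer seed.
#' @return object of class `"sim_config"` (named list).
#' @export
sim_config <- function(species = c("maize", "sorghum"),
                       n_replicates = NULL,
                       psi_start = -0.3, psi_end = -0.9,
                       psi_step_range = c(0.1, 0.15),
                       true_gbs0 = NULL, true_k = NULL,
                       x_partition = 0.4, g_M = 0.6,
                       J0 = 110, eta_J = -0.21,
                       Y0 = 0.32, eta_Y = -0.19, yield_ratio = 0.95,
                       ci_min = 80, ci_max = 200, ci_mid = -0.6,
                       ci_scale = 0.18,
                       C_in = 300, draw_factor = 1.22,
                       T_leaf = 25, w_i = 31.3, w_a = 21.4,
                       d13_in = -7.02, d18C_in = 30, d18W_in = -15,
                       noise_d13 = 0.2, noise_d18 = 0.2, noise_A = 0.3,
                       seed = 1L) {
  species <- match.arg(species)
  if (is.null(true_gbs0)) true_gbs0 <- if (species == "maize") 0.00209 else 0.00200
  if (is.null(true_k))    true_k    <- if (species == "maize") 0.00218 else 0.00154
  if (is.null(n_replicates)) n_replicates <- if (species == "maize") 6L else 7L
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (cfg$true_gbs0 + cfg$true_k * cfg$psi_end <= 0)
    stop("true conductance line non-positive at psi_end; shorten the trajectory")
  if (cfg$x_partition <= 0 || cfg$x_partition >= 1)
    stop("x_partition must be in (0, 1)")
  if (any(c(cfg$noise_d13, cfg$noise_d18, cfg$noise_A) < 0))
    stop("noise SDs must be non-negative")
  cfg
}

# prescribed intercellular CO2 trajectory (logistic decline with psi)
ci_trajectory <- function(psi, cfg) {
  cfg$ci_min + (cfg$ci_max - cfg$ci_min) /
    (1 + exp(-(psi - cfg$ci_mid) / cfg$ci_scale))
}

#' One noiseless forward step with its latent truth
#'
#' Given a water potential, composes the C4 flux system forward: the true
#' conductance line sets g_BS; prescribed C_i(psi) and J_ATP(psi) plus the
#' legacy closure V_P = x J_ATP/2 and the mesophyll supply
#' C_M = C_i - A/g_M close the system, which is solved for A by
#' root-finding on the ATP balance. Observables (gas exchange, cuvette CO2
#' and water isotopologues, fluorescence) are then synthesised by inverting
#' the same measurement equations the inference chain uses, so the
#' noiseless pipeline recovers the latent truth exactly.
#'
#' @param psi_L leaf water potential (MPa).
#' @param cfg a [sim_config()].
#' @param params a [c4_params()] object.
#' @return list with `step` (one-row data.frame of observables, no noise)
#'   and `truth` (one-row data.frame of latent values).
#' @export
forward_step <- function(psi_L, cfg, params) {
  gbs <- cfg$true_gbs0 + cfg$true_k * psi_L
  if (gbs <= 0) stop("infeasible trajectory point: g_BS <= 0 at psi_L = ", psi_L)
  C_i <- ci_trajectory(psi_L, cfg)
  J   <- cfg$J0 * ((-psi_L) / 0.3)^cfg$eta_J
  V_P <- cfg$x_partition * J / 2
  R   <- params$R_LIGHT
  RM  <- r_mesophyll(params)
  gs  <- params$gamma_star

  # ATP balance residual as a function of A
  fA <- function(A) {
    OBS <- o_bs(A, gbs, params)
    C_M <- C_i - A / cfg$g_M
    CBS <- C_M + (V_P - RM - A) / gbs
    den <- 1 - gs * OBS / CBS
    if (CBS <= 0 || den <= 0) return(NA_real_)
    V_C <- (A + R) / den
    V_O <- 2 * (V_C - (A + R))
    3 * V_C + 3.5 * V_O + 2 * V_P - J
  }
  grid <- seq(0.5, V_P - RM + C_i * gbs - 0.5, length.out = 200)
  fv <- vapply(grid, fA, numeric(1))
  okv <- which(is.finite(fv))
  sgn <- which(diff(sign(fv[okv])) != 0)
  if (!length(sgn))
    stop("infeasible trajectory point: no ATP-balance root at psi_L = ", psi_L)
  lo <- grid[okv[sgn[1]]]; hi <- grid[okv[sgn[1] + 1]]
  A <- stats::uniroot(fA, c(lo, hi), tol = 1e-13)$root

  # the x-closure above fixes realistic (A, J, C_M) combinations; the
  # latent truth emitted is the flux solver's own solution at those
  # inputs, so the noiseless inference chain recovers it exactly
  C_M <- C_i - A / cfg$g_M
  sol <- solve_fluxes(A, J, C_M, gbs, params)
  if (!sol$feasible)
    stop("infeasible trajectory point: flux system unsolvable at psi_L = ",
         psi_L)
  OBS <- sol$O_BS; CBS <- sol$C_BS
  V_C <- sol$V_C; V_O <- sol$V_O; V_P <- sol$V_P; phi <- sol$phi

  # gas exchange consistent with the latent C_i via the two-pathway balance
  gcw <- params$g_cw / 1000
  r_w <- ((cfg$w_i - cfg$w_a) / 1000) / (1 - (cfg$w_i + cfg$w_a) / 2000)
  drawdown <- A * cfg$draw_factor
  C_out <- cfg$C_in - drawdown
  C_a <- C_out                              # well-mixed cuvette
  den_g <- (C_a - C_i) / 1.6 - r_w * (C_a + C_i) / 2
  g_sw_true <- (A - gcw * (params$beta_cuticle * (C_a - C_i) -
                             r_w * (C_a + C_i) / 2)) / den_g
  if (g_sw_true <= 0) stop("infeasible trajectory point: g_sw <= 0 at psi_L = ", psi_L)
  g_tw <- g_sw_true + gcw
  E <- g_tw * r_w * 1000                    # mmol m-2 s-1
  g_sc <- g_sw_true / 1.6
  t <- ternary_factor(E, g_sc, params$a_s)

  # fluorescence consistent with the ATP production equation
  Y_II <- cfg$Y0 * ((-psi_L) / 0.3)^cfg$eta_Y
  Y_II_low <- Y_II / cfg$yield_ratio
  A_low <- J * Y_II_low / (params$atp_cost * Y_II) - R

  # 13C: modelled discrimination, inverted to an outlet delta
  fr <- fractionation_params(cfg$T_leaf, V_C, V_O, V_P, params)
  dmod <- modelled_discrimination(t, C_a, C_i, C_M, CBS, phi, fr)
  d13_out <- invert_discrimination(cfg$C_in, C_out, cfg$d13_in, dmod)

  # 18O: cuvette vapour from the transpiration mass balance, then the CO2
  # outlet delta that makes the 18O chain return the latent C_M
  w_in <- cfg$w_a - E * cfg$draw_factor
  if (w_in <= 0) stop("cuvette vapour balance infeasible at psi_L = ", psi_L)
  d18W_out <- (w_in * cfg$d18W_in +
                 (cfg$w_a - w_in) * params$d18_source_water) / cfg$w_a
  d_es <- evaporative_site_water(d18W_out, cfg$w_a, cfg$w_i, cfg$T_leaf,
                                 params$d18_source_water,
                                 eps_k = params$eps_k18,
                                 peclet_mixing = params$peclet_mixing)
  d_ce <- d18_equilibrated_co2(d_es, cfg$T_leaf)
  f18 <- function(y) {
    d_A <- d18_assimilated(cfg$C_in, C_out, cfg$d18C_in, y)
    d_i <- d18_intercellular(y, d_A, C_a, C_i, t, params$a_s18)
    mesophyll_co2(C_i, d_i, d_A, d_ce, params$a_w18) - C_M
  }
  ygrid <- seq(d_ce - 40, d_ce + 40, length.out = 800)
  yv <- suppressWarnings(vapply(ygrid, function(y)
    tryCatch(f18(y), error = function(e) NA_real_), numeric(1)))
  d18C_out <- NA_real_
  # sign changes may be roots or poles of the C_M expression; verify each
  for (j in which(diff(sign(yv)) != 0 & is.finite(yv[-length(yv)]) &
                    is.finite(yv[-1]))) {
    root <- tryCatch(stats::uniroot(f18, ygrid[c(j, j + 1)], tol = 1e-12),
                     error = function(e) NULL)
    if (!is.null(root) && abs(root$f.root) < 1e-6) {
      d18C_out <- root$root
      break
    }
  }
  if (!is.finite(d18C_out))
    stop("18O inversion failed at psi_L = ", psi_L)

  step <- data.frame(psi_L = psi_L, A = A, E = E, g_sw = g_tw, C_a = C_a,
                     T_leaf = cfg$T_leaf, w_i = cfg$w_i, w_a = cfg$w_a,
                     C_in = cfg$C_in, C_out = C_out,
                     d13_in = cfg$d13_in, d13_out = d13_out,
                     d18C_in = cfg$d18C_in, d18C_out = d18C_out,
                     d18W_in = cfg$d18W_in, d18W_out = d18W_out,
                     Y_II = Y_II, Y_II_low = Y_II_low, A_low = A_low)
  truth <- data.frame(psi_L = psi_L, g_BS = gbs, A = A, V_C = V_C,
                      V_P = V_P, V_O = V_O, C_BS = CBS, O_BS = OBS,
                      C_M = C_M, C_i = C_i, J_ATP = J, phi = phi,
                      delta13_mod = dmod)
  list(step = step, truth = truth)
}

#' Simulate a full dehydration dataset with known ground truth
#'
#' Generates `n_replicates` independent dehydration days for the configured
#' species: each day steps psi_L down from `psi_start` in uniform random
#' decrements of `psi_step_range`, runs the noiseless forward model at each
#' step, then applies Gaussian measurement noise (on Delta13C via the
#' outlet delta, on the 18O observables, and on assimilation).
#'
#' @param cfg a [sim_config()].
#' @param params a [c4_params()] object; defaults to the species defaults.
#' @return object of class `"c4_simulation"`: `replicates` (list of
#'   `c4_replicate`), `truth` (per-step latent table with `day_id`),
#'   `config`.
#' @examples
#' sim <- simulate_dataset(sim_config("maize", n_replicates = 2, seed = 7))
#' length(sim$replicates)
#' @export
simulate_dataset <- function(cfg, params = NULL) {
  if (is.null(params)) params <- c4_params(cfg$species)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  reps <- vector("list", cfg$n_replicates)
  truths <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    psi <- cfg$psi_start
    psis <- numeric(0)
    while (psi >= cfg$psi_end - 1e-12) {
      psis <- c(psis, psi)
      psi <- psi - stats::runif(1, cfg$psi_step_range[1], cfg$psi_step_range[2])
    }
    fw <- lapply(psis, forward_step, cfg = cfg, params = params)
    steps <- do.call(rbind, lapply(fw, `[[`, "step"))
    truth <- do.call(rbind, lapply(fw, `[[`, "truth"))
    n <- nrow(steps)
    if (cfg$noise_d13 > 0) {
      dnoisy <- truth$delta13_mod + stats::rnorm(n, 0, cfg$noise_d13)
      steps$d13_out <- invert_discrimination(steps$C_in, steps$C_out,
                                             steps$d13_in, dnoisy)
    }
    if (cfg$noise_d18 > 0) {
      steps$d18C_out <- steps$d18C_out + stats::rnorm(n, 0, cfg$noise_d18)
      steps$d18W_out <- steps$d18W_out + stats::rnorm(n, 0, cfg$noise_d18)
    }
    if (cfg$noise_A > 0)
      steps$A <- steps$A + stats::rnorm(n, 0, cfg$noise_A)
    day_id <- sprintf("%s_%02d", substr(cfg$species, 1, 2), r)
    reps[[r]] <- replicate_series(cfg$species, day_id, steps)
    truth$day_id <- day_id
    truths[[r]] <- truth
  }
  structure(list(replicates = reps, truth = do.call(rbind, truths),
                 config = cfg), class = "c4_simulation")
}

#' @export
print.c4_simulation <- function(x, ...) {
  cat(sprintf("Simulated %s dataset: %d replicates, %d steps total, truth (g_BS0, k) = (%.5f, %.5f)\n",
              x$config$species, length(x$replicates), nrow(x$truth),
              x$config$true_gbs0, x$config$true_k))
  invisible(x)
}
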