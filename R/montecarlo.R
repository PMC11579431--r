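#' Default parameter uncertainty distributions for Monte-Carlo propagation
#'
#' Independent normal distributions for the assumed (non-measured) model
#' parameters. Means are the [c4_params()] defaults; standard deviations
#' are plausible literature-spread values chosen once for this package
#' (roughly 10-30\% relative, tighter for well-constrained fractionation
#' factors), since the parameters are assumptions rather than measurements.
#'
#' @param params a [c4_params()] object supplying the means.
#' @return named list of `c(mean, sd)` pairs.
#' @export
mc_default_distributions <- function(params) {
  list(
    gamma_star = c(params$gamma_star, 0.2 * params$gamma_star),
    alpha      = c(params$alpha,      0.2 * params$alpha),
    R_LIGHT    = c(params$R_LIGHT,    0.2 * params$R_LIGHT),
    atp_cost   = c(params$atp_cost,   0.1 * params$atp_cost),
    a_s        = c(params$a_s,        0.2),
    a_liq      = c(params$a_liq,      0.2),
    b3_prime   = c(params$b3_prime,   1),
    s          = c(params$s,          0.5),
    f          = c(params$f,          1),
    a_w18      = c(params$a_w18,      0.2),
    g_cw       = c(params$g_cw,       0.5)
  )
}

#' Monte-Carlo error propagation for the conductance fit
#'
#' Draws `n` random parameter combinations from independent normal
#' distributions, refits `(g_BS0, k)` for each draw with the deterministic
#' fitting machinery, and summarises the spread of the fitted parameters.
#' Parameter uncertainty and natural variability are not distinguished;
#' measured input variables are not perturbed.
#'
#' @param rep a `c4_replicate`.
#' @param params a [c4_params()] object (central values).
#' @param distributions named list of `c(mean, sd)`; defaults to
#'   [mc_default_distributions()].
#' @param n number of draws, default 200.
#' @param seed integer seed.
#' @param control optimizer control passed to [fit_gbs()]; the default uses
#'   a reduced search budget appropriate for repeated refits.
#' @return an object of class `"gbs_mc"`: `draws` (data.frame of sampled
#'   parameters and fitted `g_BS0`, `k`, `sse`, `converged`),
#'   `sd_gbs0_rel`, `sd_k_rel` (relative SDs, \%), `p_k_negative`
#'   (fraction of draws with fitted k < 0), `n`, `seed`.
#' @export
monte_carlo <- function(rep, params = NULL, distributions = NULL,
                        n = 200, seed = 1L,
                        control = list(np = 24, maxiter = 40)) {
  stopifnot(n >= 2)
  if (is.null(params)) params <- c4_params(rep$species)
  if (is.null(distributions)) distributions <- mc_default_distributions(params)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pars <- names(distributions)
  draws <- sapply(pars, function(p)
    stats::rnorm(n, distributions[[p]][1], distributions[[p]][2]))
  draws <- as.data.frame(draws)
  # clamp draws to the physical domain of each parameter
  if ("gamma_star" %in% pars) draws$gamma_star <- pmax(draws$gamma_star, 1e-6)
  if ("alpha" %in% pars) draws$alpha <- pmin(pmax(draws$alpha, 0), 1)
  if ("R_LIGHT" %in% pars) draws$R_LIGHT <- pmax(draws$R_LIGHT, 0)
  if ("atp_cost" %in% pars) draws$atp_cost <- pmax(draws$atp_cost, 3)
  if ("g_cw" %in% pars) draws$g_cw <- pmax(draws$g_cw, 0)
  # one shared optimizer seed: each refit is then a deterministic function
  # of the drawn parameters alone (zero-variance draws give zero spread)
  fit_seed <- sample.int(2^30, 1)

  res <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("g_BS0", "k", "sse")))
  conv <- logical(n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i[pars] <- as.list(draws[i, pars])
    f <- try(fit_gbs(rep, p_i, seed = fit_seed, control = control),
             silent = TRUE)
    if (!inherits(f, "try-error")) {
      res[i, ] <- c(f$coefficients, f$sse)
      conv[i] <- f$converged
    }
  }
  if (mean(conv) < 0.5)
    warning("more than half of the Monte-Carlo draws failed to converge; ",
            "propagated uncertainties are unreliable")
  ok <- conv
  sd_rel <- function(v) 100 * stats::sd(v[ok]) / abs(mean(v[ok]))
  structure(list(draws = cbind(draws, as.data.frame(res), converged = conv),
                 sd_gbs0_rel = sd_rel(res[, "g_BS0"]),
                 sd_k_rel = sd_rel(res[, "k"]),
                 p_k_negative = mean(res[ok, "k"] < 0),
                 n = n, seed = seed, day_id = rep$day_id),
            class = "gbs_mc")
}

#' @export
print.gbs_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo propagation (day %s, %d draws, %d converged)\n",
              x$day_id, x$n, sum(x$draws$converged)))
  cat(sprintf("  relative SD: g_BS0 %.0f%%, k %.0f%%\n",
              x$sd_gbs0_rel, x$sd_k_rel))
  cat(sprintf("  P(k < 0) over draws: %.3f\n", x$p_k_negative))
  invisible(x)
}
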