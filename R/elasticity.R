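#' Elasticity to dehydration of a positive variable
#'
#' The dimensionless relative sensitivity of a variable to leaf water
#' potential, estimated as the slope of ln(value) on ln(-psi_L) in a
#' repeated-measurement linear mixed model (REML) with day as a random
#' intercept. A variable that declines as the leaf dehydrates (psi_L more
#' negative, -psi_L larger) has a negative elasticity.
#'
#' @param values per-step variable values, strictly positive (log domain).
#' @param psi per-step leaf water potential (MPa, negative).
#' @param day per-step replicate/day grouping factor (>= 2 levels).
#' @return list with `eta` (slope), `se`, `p` (P of eta = 0 from the
#'   mixed model, Satterthwaite df), `day_slopes` (named per-day OLS
#'   slopes, used for paired comparisons), `n`.
#' @examples
#' psi <- rep(seq(-0.3, -1.8, by = -0.15), 2)
#' day <- rep(c("d1", "d2"), each = 11)
#' elasticity(5 * (-psi)^(-0.5), psi, day)$eta  # -0.5
#' @export
elasticity <- function(values, psi, day) {
  bad <- which(!(values > 0))
  if (length(bad))
    stop("non-positive values at step(s) ", paste(bad, collapse = ","),
         ": elasticity is defined on the log scale")
  if (any(psi >= 0)) stop("psi_L must be negative")
  day <- factor(day)
  if (nlevels(day) < 2) stop("need >= 2 days for the mixed model")
  d <- data.frame(ly = log(values), lp = log(-psi), day = day)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(ly ~ lp + (1 | day), data = d, REML = TRUE)))
  co <- summary(fit)$coefficients
  day_slopes <- vapply(split(d, d$day), function(g)
    unname(stats::coef(stats::lm(ly ~ lp, data = g))[2]), numeric(1))
  list(eta = unname(co["lp", "Estimate"]),
       se = unname(co["lp", "Std. Error"]),
       p = unname(co["lp", "Pr(>|t|)"]),
       day_slopes = day_slopes, n = nrow(d))
}

#' Standard error of the paired per-day difference of elasticities
#'
#' Pairs the per-day log-log slopes of a variable with those of a reference
#' variable (assimilation, in the standard report) and returns the standard
#' error of the mean per-day difference.
#'
#' @param var_slopes,ref_slopes named per-day slopes (from
#'   [elasticity()]`$day_slopes`); matched by name.
#' @return scalar SED.
#' @export
paired_sed <- function(var_slopes, ref_slopes) {
  days <- intersect(names(var_slopes), names(ref_slopes))
  if (length(days) < 2) stop("need >= 2 paired days")
  d <- var_slopes[days] - ref_slopes[days]
  stats::sd(d) / sqrt(length(d))
}

#' One-sided t-test of k not greater than zero
#'
#' Single-sample t-test of the per-replicate fitted slopes `k` against the
#' null hypothesis that the mean is not greater than zero.
#'
#' @param k_values per-replicate fitted `k`.
#' @return list with `t`, `df`, `p` (one-sided), `mean`, `se`.
#' @export
one_sided_t_k <- function(k_values) {
  n <- length(k_values)
  if (n < 2) stop("need >= 2 replicates")
  if (stats::sd(k_values) == 0) {
    if (mean(k_values) == 0)
      stop("all k equal to zero: t-test undefined (zero variance, zero mean)")
    return(list(t = sign(mean(k_values)) * Inf, df = n - 1,
                p = if (mean(k_values) > 0) 0 else 1,
                mean = mean(k_values), se = 0))
  }
  tt <- stats::t.test(k_values, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(k_values),
       se = stats::sd(k_values) / sqrt(n))
}

#' Elasticity table across species
#'
#' The machine twin of the study-style elasticity report: for each variable
#' of a per-step diagnostics table, computes the elasticity per species
#' (species-separate mixed-model fits), their average, the SED of the
#' paired per-day comparison with assimilation, the mixed-model P of
#' eta = 0, and the rank by signed average elasticity (rank 1 = most
#' negative, i.e. the quantity declining most steeply with dehydration).
#'
#' @param steps per-step table with columns `psi_L`, `species`, `day_id`
#'   and the variables in `variables`.
#' @param variables character vector of column names to analyse; defaults
#'   to the 13 standard quantities when present.
#' @param reference variable for the paired SED, default `"A"`.
#' @return data.frame with one row per variable: `variable`, `eta_maize`,
#'   `eta_sorghum`, `eta_avg`, `sed_vs_A`, `p_maize`, `p_sorghum`, `rank`.
#' @export
elasticity_table <- function(steps, variables = NULL, reference = "A") {
  std <- c("A", "C_BS", "C_i", "C_M", "g_BS", "J_ATP", "V_C", "VO_VC",
           "V_P", "Y_II", "delta13_obs", "delta18_obs", "phi")
  if (is.null(variables)) variables <- intersect(std, names(steps))
  species_present <- intersect(c("maize", "sorghum"), unique(steps$species))
  est <- function(v, sp) {
    sub <- steps[steps$species == sp, ]
    elasticity(sub[[v]], sub$psi_L, sub$day_id)
  }
  ref_fit <- lapply(species_present, function(sp) est(reference, sp))
  names(ref_fit) <- species_present
  rows <- lapply(variables, function(v) {
    fits <- lapply(species_present, function(sp) est(v, sp))
    names(fits) <- species_present
    etas <- vapply(fits, `[[`, numeric(1), "eta")
    sed <- if (v == reference) NA_real_ else
      mean(vapply(species_present, function(sp)
        paired_sed(fits[[sp]]$day_slopes, ref_fit[[sp]]$day_slopes),
        numeric(1)))
    data.frame(variable = v,
               eta_maize = if ("maize" %in% species_present) etas[["maize"]] else NA,
               eta_sorghum = if ("sorghum" %in% species_present) etas[["sorghum"]] else NA,
               eta_avg = mean(etas),
               sed_vs_A = sed,
               p_maize = if ("maize" %in% species_present) fits[["maize"]]$p else NA,
               p_sorghum = if ("sorghum" %in% species_present) fits[["sorghum"]]$p else NA)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$eta_avg, ties.method = "first")
  out[order(out$variable), ]
}

#' Fixed-effects ANOVA for tail-exclusion robustness
#'
#' Tests whether excluding the last one or two dehydration steps changes
#' the fitted parameters: a fixed-effects ANOVA of the fitted values with
#' method (all steps, drop last, drop last two), species and quantity
#' (g_BS0, k) as factors.
#'
#' @param fits_table data.frame with columns `method`, `species`,
#'   `quantity`, `value`.
#' @return the [stats::aov()] fit.
#' @export
robustness_anova <- function(fits_table) {
  stats::aov(value ~ method + species + quantity, data = fits_table)
}
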