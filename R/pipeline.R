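#' Run the end-to-end analysis pipeline
#'
#' Chains all stages over a list of replicates: per-step derivation
#' (discrimination, C_i, J_ATP, 18O chain, C_M), the per-replicate
#' conductance fit, optional Monte-Carlo propagation, the cross-species
#' elasticity table, and species-level summaries of `g_BS0` and `k` with
#' the one-sided test of k > 0. Failure of one replicate is isolated: its
#' fit is recorded as NA and excluded from summaries.
#'
#' @param series list of `c4_replicate` (one or both species).
#' @param params named list of [c4_params()] per species, or `NULL` for
#'   defaults.
#' @param seed integer seed; per-replicate fit seeds are derived from it.
#' @param exclude_tail 0, 1 or 2 final steps dropped before fitting.
#' @param mc `FALSE` (default), or the number of Monte-Carlo draws to run
#'   per replicate.
#' @param control optimizer control passed to [fit_gbs()].
#' @return object of class `"c4_pipeline"`: `steps` (per-step diagnostics
#'   incl. fitted g_BS, fluxes, leakiness, both discriminations), `fits`
#'   (per-replicate table: species, day, g_BS0, k, sse, n, converged),
#'   `fit_objects`, `mc` (list of [monte_carlo()] results or NULL),
#'   `elasticity` (13-variable table), `summary` (per species: mean, SE,
#'   n, one-sided P for k).
#' @export
run_pipeline <- function(series, params = NULL, seed = 1L,
                         exclude_tail = 0L, mc = FALSE,
                         control = list()) {
  if (inherits(series, "c4_replicate")) series <- list(series)
  if (is.null(params))
    params <- list(maize = c4_params("maize"), sorghum = c4_params("sorghum"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit_seeds <- sample.int(2^30, length(series))

  fits <- vector("list", length(series))
  steps <- vector("list", length(series))
  mcs <- if (isFALSE(mc)) NULL else vector("list", length(series))
  rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    rep <- series[[i]]
    p <- params[[rep$species]]
    f <- try(fit_gbs(rep, p, seed = fit_seeds[i],
                     exclude_tail = exclude_tail, control = control),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("replicate '", rep$day_id, "' failed: ",
              attr(f, "condition")$message)
      rows[[i]] <- data.frame(species = rep$species, day_id = rep$day_id,
                              g_BS0 = NA_real_, k = NA_real_,
                              sse = NA_real_, n_steps = NA_integer_,
                              converged = FALSE)
      next
    }
    fits[[i]] <- f
    st <- f$steps
    st$species <- rep$species
    st$day_id <- rep$day_id
    st$VO_VC <- st$V_O / st$V_C
    steps[[i]] <- st
    rows[[i]] <- data.frame(species = rep$species, day_id = rep$day_id,
                            g_BS0 = f$coefficients[["g_BS0"]],
                            k = f$coefficients[["k"]], sse = f$sse,
                            n_steps = f$n_steps_used,
                            converged = f$converged)
    if (!isFALSE(mc))
      mcs[[i]] <- monte_carlo(rep, p, n = mc, seed = fit_seeds[i])
  }
  fit_tab <- do.call(rbind, rows)
  step_tab <- do.call(rbind, steps)

  elas <- if (!is.null(step_tab) &&
              length(unique(step_tab$day_id)) >= 2)
    elasticity_table(step_tab) else NULL

  summ <- lapply(split(fit_tab[fit_tab$converged & !is.na(fit_tab$k), ],
                       fit_tab$species[fit_tab$converged & !is.na(fit_tab$k)]),
                 function(g) {
    if (!nrow(g)) return(NULL)
    kt <- if (nrow(g) >= 2) one_sided_t_k(g$k) else
      list(p = NA_real_, t = NA_real_)
    data.frame(species = g$species[1], n = nrow(g),
               g_BS0_mean = mean(g$g_BS0),
               g_BS0_se = stats::sd(g$g_BS0) / sqrt(nrow(g)),
               k_mean = mean(g$k),
               k_se = stats::sd(g$k) / sqrt(nrow(g)),
               p_k = kt$p)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  structure(list(steps = step_tab, fits = fit_tab, fit_objects = fits,
                 mc = mcs, elasticity = elas, summary = summ,
                 seed = seed, exclude_tail = exclude_tail),
            class = "c4_pipeline")
}

#' @export
print.c4_pipeline <- function(x, ...) {
  cat("C4 dehydration pipeline result\n")
  cat(sprintf("  %d replicates (%d converged), %d steps\n",
              nrow(x$fits), sum(x$fits$converged),
              if (is.null(x$steps)) 0L else nrow(x$steps)))
  if (!is.null(x$summary)) {
    cat("  species summary (mean +/- SE, one-sided P for k > 0):\n")
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("    %-7s (n=%d): g_BS0 = %.5f +/- %.5f, k = %.5f +/- %.5f, P(t) = %.4g\n",
                  s$species, s$n, s$g_BS0_mean, s$g_BS0_se,
                  s$k_mean, s$k_se, s$p_k))
    }
  }
  if (!is.null(x$elasticity)) {
    cat("  elasticity table: ", nrow(x$elasticity), " variables\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline results to CSV/JSON files
#'
#' Emits `steps.csv`, `fits.csv`, `elasticity.csv` and (if jsonlite is
#' installed) `summary.json` under `dir`.
#'
#' @param x a `c4_pipeline` result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  utils::write.csv(x$fits, file.path(dir, "fits.csv"), row.names = FALSE)
  if (!is.null(x$elasticity))
    utils::write.csv(x$elasticity, file.path(dir, "elasticity.csv"),
                     row.names = FALSE)
  if (!is.null(x$summary) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(x$summary, file.path(dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
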