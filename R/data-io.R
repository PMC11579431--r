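#' Construct a dehydration replicate series
#'
#' One replicate ("day") of a fast-dehydration experiment: an ordered set of
#' dehydration steps, each bundling leaf water potential, ambient-O2 gas
#' exchange, CO2 and water isotopologue records, and fluorescence (ambient
#' and 2\% O2).
#'
#' @param species `"maize"` or `"sorghum"`.
#' @param day_id replicate label.
#' @param steps data.frame with one row per dehydration step and columns:
#'   `psi_L` (MPa, negative), `A`, `E`, `g_sw` (apparent total conductance
#'   to water, mol m-2 s-1), `C_a`, `T_leaf`, `w_i`, `w_a` (mmol mol-1),
#'   `C_in`, `C_out`, `d13_in`, `d13_out`, `d18C_in`, `d18C_out`,
#'   `d18W_in`, `d18W_out`, `Y_II`, `Y_II_low`, `A_low`.
#' @param psi_tol tolerance (MPa) for the requirement that psi_L be
#'   non-increasing along the series.
#' @return an object of class `"c4_replicate"`.
#' @export
replicate_series <- function(species, day_id, steps, psi_tol = 0.05) {
  species <- match.arg(species, c("maize", "sorghum"))
  req <- c("psi_L", "A", "E", "g_sw", "C_a", "T_leaf", "w_i", "w_a",
           "C_in", "C_out", "d13_in", "d13_out", "d18C_in", "d18C_out",
           "d18W_in", "d18W_out", "Y_II", "Y_II_low", "A_low")
  miss <- setdiff(req, names(steps))
  if (length(miss)) stop("missing step column(s): ", paste(miss, collapse = ", "))
  steps <- as.data.frame(steps)[, req]
  x <- structure(list(species = species, day_id = as.character(day_id),
                      steps = steps, psi_tol = psi_tol),
                 class = "c4_replicate")
  validate_replicate(x)
  x
}

#' @keywords internal
validate_replicate <- function(x) {
  s <- x$steps
  n <- nrow(s)
  if (n < 3) stop("replicate '", x$day_id,
                  "' has fewer than 3 steps; cannot fit two parameters")
  problems <- character(0)
  chk <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad))
      problems <<- c(problems, paste0(msg, " (row ", paste(bad, collapse = ","), ")"))
  }
  chk(s$psi_L < 0, "psi_L must be negative")
  chk(is.finite(s$A), "A must be finite")
  chk(s$E > 0, "E must be positive")
  chk(s$g_sw > 0, "g_sw must be positive")
  chk(s$C_a > 0, "C_a must be positive")
  chk(s$w_a >= 0 & s$w_a <= s$w_i, "need 0 <= w_a <= w_i")
  chk(s$C_in > s$C_out & s$C_out > 0, "need C_in > C_out > 0 for an assimilating leaf")
  chk(s$Y_II > 0 & s$Y_II <= 1, "Y_II must be in (0, 1]")
  chk(s$Y_II_low > 0 & s$Y_II_low <= 1, "Y_II_low must be in (0, 1]")
  dd <- c("d13_in", "d13_out", "d18C_in", "d18C_out", "d18W_in", "d18W_out")
  chk(rowSums(!is.finite(as.matrix(s[, dd]))) == 0, "all delta values must be finite")
  if (n > 1) chk(c(TRUE, diff(s$psi_L) <= x$psi_tol),
                 "psi_L must be non-increasing along the series")
  if (length(problems))
    stop("invalid replicate '", x$day_id, "': ",
         paste(problems, collapse = "; "))
  invisible(x)
}

#' @export
print.c4_replicate <- function(x, ...) {
  cat(sprintf("C4 dehydration replicate '%s' (%s): %d steps, psi_L %.2f to %.2f MPa\n",
              x$day_id, x$species, nrow(x$steps),
              max(x$steps$psi_L), min(x$steps$psi_L)))
  invisible(x)
}

# canonical long-format column order (one row per step x O2 level)
.csv_cols <- c("species", "day_id", "step", "o2_level", "psi_L", "A", "E",
               "g_sw", "C_a", "T_leaf", "w_i", "w_a", "C_in", "C_out",
               "d13_in", "d13_out", "d18C_in", "d18C_out", "d18W_in",
               "d18W_out", "Y_II")

#' Write replicate series to the canonical long-format CSV
#'
#' One row per dehydration step per O2 level: ambient rows carry the full
#' gas-exchange and isotope record, low-O2 rows carry the 2\% O2
#' assimilation and PSII yield. Column order is fixed, so write/read is a
#' bit-stable round trip.
#'
#' @param series a `c4_replicate` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(series, path) {
  if (inherits(series, "c4_replicate")) series <- list(series)
  rows <- lapply(series, function(r) {
    s <- r$steps
    n <- nrow(s)
    amb <- data.frame(species = r$species, day_id = r$day_id,
                      step = seq_len(n), o2_level = "ambient",
                      psi_L = s$psi_L, A = s$A, E = s$E, g_sw = s$g_sw,
                      C_a = s$C_a, T_leaf = s$T_leaf, w_i = s$w_i,
                      w_a = s$w_a, C_in = s$C_in, C_out = s$C_out,
                      d13_in = s$d13_in, d13_out = s$d13_out,
                      d18C_in = s$d18C_in, d18C_out = s$d18C_out,
                      d18W_in = s$d18W_in, d18W_out = s$d18W_out,
                      Y_II = s$Y_II)
    low <- data.frame(species = r$species, day_id = r$day_id,
                      step = seq_len(n), o2_level = "low",
                      psi_L = s$psi_L, A = s$A_low, E = NA_real_,
                      g_sw = NA_real_, C_a = NA_real_, T_leaf = NA_real_,
                      w_i = NA_real_, w_a = NA_real_, C_in = NA_real_,
                      C_out = NA_real_, d13_in = NA_real_,
                      d13_out = NA_real_, d18C_in = NA_real_,
                      d18C_out = NA_real_, d18W_in = NA_real_,
                      d18W_out = NA_real_, Y_II = s$Y_II_low)
    out <- rbind(amb, low)
    out[order(out$step, out$o2_level), ]
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(.csv_cols)), .csv_cols))
  tab <- tab[, .csv_cols]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read replicate series from the canonical long-format CSV
#'
#' Ambient and low-O2 rows sharing a `step` index are merged into one
#' dehydration step. Rows failing the domain invariants abort with a
#' message naming the offending rows.
#'
#' @param path CSV file written by [write_replicates()] or following the
#'   same schema.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in a foreign file,
#'   e.g. `c(psi_L = "WaterPot")`.
#' @return list of `c4_replicate` objects.
#' @export
read_replicates <- function(path, col_map = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(tab))
        stop("mapped column '", col_map[[canon]], "' not found in file")
      names(tab)[names(tab) == col_map[[canon]]] <- canon
    }
  }
  miss <- setdiff(.csv_cols, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  keys <- unique(tab[, c("species", "day_id")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- tab[tab$species == keys$species[i] & tab$day_id == keys$day_id[i], ]
    amb <- sub[sub$o2_level == "ambient", ]
    low <- sub[sub$o2_level == "low", ]
    amb <- amb[order(amb$step), ]
    unpaired <- setdiff(low$step, amb$step)
    if (length(unpaired))
      stop("unpaired low-O2 row(s) at step(s) ",
           paste(unpaired, collapse = ","), " in replicate '",
           keys$day_id[i], "'")
    if (!setequal(amb$step, low$step))
      stop("ambient step(s) without low-O2 pair in replicate '",
           keys$day_id[i], "'")
    m <- match(amb$step, low$step)
    steps <- amb[, c("psi_L", "A", "E", "g_sw", "C_a", "T_leaf", "w_i",
                     "w_a", "C_in", "C_out", "d13_in", "d13_out",
                     "d18C_in", "d18C_out", "d18W_in", "d18W_out", "Y_II")]
    steps$Y_II_low <- low$Y_II[m]
    steps$A_low <- low$A[m]
    rownames(steps) <- NULL
    out[[i]] <- replicate_series(keys$species[i], keys$day_id[i], steps)
  }
  out
}
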