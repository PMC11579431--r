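#' Observed isotope discrimination from cuvette inlet-outlet mass balance
#'
#' Discrimination against the heavy isotopologue (13CO2 or C18OO) computed
#' from the CO2 mole fraction and isotopic composition of the air entering
#' and leaving the leaf cuvette,
#' \deqn{\Delta_{obs} = \frac{1000\,\xi(\delta_{out}-\delta_{in})}
#'   {1000 + \delta_{out} - \xi(\delta_{out}-\delta_{in})},\qquad
#'   \xi = \frac{C_{in}}{C_{in}-C_{out}}.}
#'
#' @param C_in,C_out 12CO2 mole fraction in dry air entering/leaving the
#'   chamber (umol mol-1).
#' @param d_in,d_out delta value (13C or 18O of CO2) of air in/out (permil).
#' @return discrimination in permil. Vectorized over all arguments.
#' @examples
#' observed_discrimination(300, 250, -7.02, -6.00) # about 6.195 permil
#' @export
observed_discrimination <- function(C_in, C_out, d_in, d_out) {
  if (any(C_in == C_out))
    stop("C_in equals C_out: CO2 drawdown is zero, discrimination undefined")
  xi <- C_in / (C_in - C_out)
  num <- 1000 * xi * (d_out - d_in)
  den <- 1000 + d_out - xi * (d_out - d_in)
  if (any(den <= 0)) stop("non-positive denominator: inputs outside the physical domain")
  num / den
}

# inverse of observed_discrimination for d_out, used by the forward simulator
invert_discrimination <- function(C_in, C_out, d_in, delta) {
  xi <- C_in / (C_in - C_out)
  (1000 * delta + xi * d_in * (1000 + delta)) / (1000 * xi + delta * xi - delta)
}

#' Ternary correction factor
#'
#' Correction for the interaction of the transpiration stream with CO2
#' diffusion through stomata, \eqn{t = (1 + a_s/1000)\,E / (2 g_{sc})} with
#' `E` converted from mmol to mol m-2 s-1.
#'
#' @param E transpiration (mmol m-2 s-1).
#' @param g_sc stomatal conductance to CO2 (mol m-2 s-1).
#' @param a_s diffusion fractionation in air (permil), default 4.4.
#' @return dimensionless ternary factor, small (order 0.01) for realistic
#'   leaves.
#' @export
ternary_factor <- function(E, g_sc, a_s = 4.4) {
  if (any(g_sc <= 0)) stop("g_sc must be positive")
  (1 + a_s / 1000) * (E / 1000) / (2 * g_sc)
}

#' Intercellular CO2 corrected for cuticular fluxes
#'
#' Recomputes the intercellular CO2 mole fraction from gas-exchange data
#' splitting water loss and CO2 uptake between a stomatal and a cuticular
#' pathway. The measured total conductance to water
#' \eqn{g_{tw} = E(1-\bar w)/(w_i-w_a)} is decomposed as
#' \eqn{g_{tw} = g_{sw} + g_{cw}}; CO2 crosses with
#' \eqn{g_{sc} = g_{sw}/1.6} and \eqn{g_{cc} = \beta\,g_{cw}}, and
#' \deqn{C_i = \frac{(g_{sc}+g_{cc}-E/2)\,C_a - A}{g_{sc}+g_{cc}+E/2}}
#' (E in mol m-2 s-1). With `g_cw = 0` this is the classical
#' von Caemmerer-Farquhar C_i.
#'
#' @param A net assimilation (umol m-2 s-1).
#' @param E transpiration (mmol m-2 s-1).
#' @param g_tw total conductance to water vapour (mol m-2 s-1), i.e. the
#'   apparent stomatal conductance reported by a gas-exchange system when
#'   the cuticular pathway is ignored.
#' @param C_a cuvette CO2 mole fraction (umol mol-1).
#' @param g_cw cuticular conductance to water (mmol m-2 s-1), default 2.
#' @param beta ratio of cuticular CO2 to water conductance, default 0.025.
#' @return corrected C_i (umol mol-1); negative values are flagged with a
#'   warning (non-physical, typically a sign of inconsistent inputs).
#' @export
cuticle_corrected_ci <- function(A, E, g_tw, C_a, g_cw = 2, beta = 0.025) {
  g_cw <- g_cw / 1000                      # mmol -> mol
  g_sw <- g_tw - g_cw
  if (any(g_sw <= 0)) stop("cuticular conductance exceeds total water conductance")
  g_co2 <- g_sw / 1.6 + beta * g_cw
  E_mol <- E / 1000
  ci <- ((g_co2 - E_mol / 2) * C_a - A) / (g_co2 + E_mol / 2)
  if (any(ci < 0)) warning("non-physical C_i < 0 computed; check inputs")
  ci
}

#' @rdname cuticle_corrected_ci
#' @export
classical_ci <- function(A, E, g_tw, C_a) {
  cuticle_corrected_ci(A, E, g_tw, C_a, g_cw = 0, beta = 0)
}

# total conductance to water implied by E and the vapour gradient, with the
# ternary correction for the net outflow of water; w_i, w_a in mmol mol-1
total_water_conductance <- function(E, w_i, w_a) {
  wbar <- (w_i + w_a) / 2 / 1000
  (E / 1000) * (1 - wbar) / ((w_i - w_a) / 1000)
}

#' Total ATP production rate from fluorescence and low-O2 gas exchange
#'
#' Scales gross assimilation measured under 2\% O2 by the ratio of PSII
#' yields under ambient and low O2:
#' \eqn{J_{ATP} = c\,(A_{low} + R_{LIGHT})\,Y(II)/Y(II)_{low}}, where `c`
#' is the ATP cost of gross assimilation under low O2 (default 5.4).
#'
#' @param A_low net assimilation under 2\% O2 (umol m-2 s-1).
#' @param Y_II,Y_II_low PSII yield under ambient and low O2.
#' @param R_LIGHT day respiration (umol m-2 s-1).
#' @param atp_cost ATP per gross assimilation under low O2, default 5.4.
#' @return J_ATP (umol m-2 s-1).
#' @examples
#' j_atp(19, 0.3, 0.3, R_LIGHT = 1) # 5.4 * 20 = 108
#' @export
j_atp <- function(A_low, Y_II, Y_II_low, R_LIGHT, atp_cost = 5.4) {
  if (any(Y_II_low <= 0)) stop("Y_II_low must be positive")
  atp_cost * (A_low + R_LIGHT) * Y_II / Y_II_low
}

#' Mesophyll conductance from the supply function
#'
#' \eqn{g_M = A/(C_i - C_M)}.
#'
#' @param A net assimilation (umol m-2 s-1).
#' @param C_i intercellular CO2 (umol mol-1).
#' @param C_M mesophyll CO2 (umol mol-1).
#' @return g_M (mol m-2 s-1). A negative drawdown (C_M > C_i at positive A)
#'   is flagged with a warning.
#' @export
mesophyll_conductance <- function(A, C_i, C_M) {
  if (any(C_i == C_M)) stop("C_i equals C_M: g_M undefined")
  gm <- A / (C_i - C_M)
  if (any(gm < 0 & A > 0)) warning("negative CO2 drawdown into the mesophyll")
  gm
}

#' Calibrate the ATP cost of gross assimilation
#'
#' Finds the smallest ATP cost on a grid from 3 upward for which every step
#' of every replicate yields a feasible flux solution with positive
#' bundle-sheath CO2. Feasibility is a step function of the cost, so a grid
#' scan (not a root-finder) is appropriate.
#'
#' @param series list of replicate series (see [read_replicates()]).
#' @param params a [c4_params()] object.
#' @param g_BS bundle-sheath conductance used for the feasibility scan
#'   (mol m-2 s-1). The default probes at the low end of the physiological
#'   range, where the flux system is feasible whenever the ATP supply can
#'   cover the fluxes at all.
#' @param grid candidate costs, default `seq(3, 8, by = 0.05)`.
#' @return the smallest feasible cost; 5.4 is returned when it is feasible
#'   and no smaller grid value is.
#' @export
calibrate_atp_cost <- function(series, params, g_BS = 3e-4,
                               grid = seq(3, 8, by = 0.05)) {
  if (inherits(series, "c4_replicate")) series <- list(series)
  feas_at <- function(cost) {
    p <- params
    p$atp_cost <- cost
    ok <- TRUE
    for (rep in series) {
      d <- derive_steps(rep, p)
      sol <- solve_fluxes(d$A, d$J_ATP, d$C_M, g_BS, p)
      if (!all(sol$feasible & sol$C_BS > 0)) { ok <- FALSE; break }
    }
    ok
  }
  for (cost in sort(grid)) if (feas_at(cost)) return(cost)
  bad <- list()
  p <- params; p$atp_cost <- max(grid)
  for (rep in series) {
    d <- derive_steps(rep, p)
    sol <- solve_fluxes(d$A, d$J_ATP, d$C_M, g_BS, p)
    i <- which(!(sol$feasible & sol$C_BS > 0))
    if (length(i)) bad[[rep$day_id]] <- d$psi_L[i]
  }
  stop("no ATP cost in the grid yields positive bundle-sheath CO2 at all steps; ",
       "offending steps (psi_L by day): ",
       paste(vapply(names(bad), function(n)
         paste0(n, ": ", paste(signif(bad[[n]], 3), collapse = ",")), ""),
         collapse = "; "))
}
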