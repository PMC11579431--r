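#' Effective fractionation factors for the 13C discrimination model
#'
#' Assembles the per-step fractionation set entering the modelled
#' discrimination: the liquid-phase fractionation `a_m(T)` (dissolution +
#' aqueous diffusion), and the effective Rubisco and PEPC fractionations
#' `b3`, `b4` corrected for day respiration, photorespiration and the
#' offset between growth and measurement air:
#' \deqn{b_3 = b_3' - e'\,R_{LIGHT}/V_C - f\,(V_O/2)/V_C}
#' \deqn{b_4 = b_4'(T) - e'\,R_M/V_P}
#' with \eqn{e' = \delta^{13}C_{growth} - \delta^{13}C_{measurement}}
#' (respired carbon carries the growth-air signature while the cuvette runs
#' on measurement air). Corrections are flux-ratio weighted and vanish when
#' the corresponding flux does.
#'
#' @param T_leaf leaf temperature (C).
#' @param V_C,V_O,V_P per-step fluxes (umol m-2 s-1).
#' @param params a [c4_params()] object.
#' @return list with components `a_s`, `a_m`, `b3`, `b4`, `s`.
#' @export
fractionation_params <- function(T_leaf, V_C, V_O, V_P, params) {
  e_prime <- params$d13_growth - params$d13_measurement
  a_m <- params$a_m_offset + params$a_m_slope * T_leaf + params$a_liq
  TK <- T_leaf + 273.15
  b4p <- params$b4_offset - params$b4_slope_K / TK
  RM <- r_mesophyll(params)
  b3 <- params$b3_prime - e_prime * params$R_LIGHT / V_C -
    params$f * (V_O / 2) / V_C
  b4 <- b4p - e_prime * RM / V_P
  list(a_s = params$a_s, a_m = a_m, b3 = b3, b4 = b4, s = params$s)
}

#' Modelled 13C discrimination of C4 photosynthesis
#'
#' Farquhar-Cernusak-type discrimination for a two-compartment C4 leaf,
#' boundary layer disregarded:
#' \deqn{\Delta_{MOD} = \frac{1}{1-t} a_s \frac{C_a - C_i}{C_a} +
#'   \frac{1+t}{1-t}\left[a_m \frac{C_i - C_M}{C_a} +
#'   \left(b_4 + \Phi\left(b_3\frac{C_{BS}}{C_{BS}-C_M} -
#'   s\left(1 + \Phi\frac{C_M}{C_{BS}-C_M}\right)\right)\right)
#'   \frac{C_M}{C_a}\right]}
#'
#' @param t ternary factor, in [0, 1).
#' @param C_a,C_i,C_M,C_BS CO2 mole fractions along the diffusion path
#'   (umol mol-1); requires `C_BS != C_M`.
#' @param phi leakiness.
#' @param fr fractionation set from [fractionation_params()].
#' @return modelled discrimination (permil). Vectorized over steps.
#' @export
modelled_discrimination <- function(t, C_a, C_i, C_M, C_BS, phi, fr) {
  if (any(t >= 1)) stop("ternary factor t must be < 1")
  if (any(C_BS == C_M)) stop("C_BS equals C_M: leak term singular")
  leak <- fr$b3 * C_BS / (C_BS - C_M) -
    fr$s * (1 + phi * C_M / (C_BS - C_M))
  1 / (1 - t) * fr$a_s * (C_a - C_i) / C_a +
    (1 + t) / (1 - t) *
      (fr$a_m * (C_i - C_M) / C_a + (fr$b4 + phi * leak) * C_M / C_a)
}

# Delta_MOD for a set of derived steps at candidate g_BS values (vectorized);
# with project = TRUE, near-infeasible steps are evaluated at their
# fold-projected state; NA where no admissible state exists.
delta_mod_steps <- function(derived, g_BS, params, project = FALSE) {
  sol <- solve_fluxes(derived$A, derived$J_ATP, derived$C_M, g_BS, params,
                      project = project)
  dmod <- rep(NA_real_, nrow(derived))
  ok <- !is.na(sol$V_C) & !is.na(sol$phi)
  if (any(ok)) {
    fr <- fractionation_params(derived$T_leaf[ok], sol$V_C[ok], sol$V_O[ok],
                               sol$V_P[ok], params)
    dmod[ok] <- modelled_discrimination(derived$t[ok], derived$C_a[ok],
                                        derived$C_i[ok], derived$C_M[ok],
                                        sol$C_BS[ok], sol$phi[ok], fr)
  }
  list(delta_mod = dmod, sol = sol)
}
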