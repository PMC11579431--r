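#' Convert delta18O from the V-PDB to the V-SMOW scale
#'
#' Exact affine map: delta18O(V-SMOW) = 1.03092 * delta18O(V-PDB) + 30.92.
#'
#' @param d18_pdb delta18O on the V-PDB scale (permil).
#' @return delta18O on the V-SMOW scale (permil).
#' @export
pdb_to_smow <- function(d18_pdb) 1.03092 * d18_pdb + 30.92

# Majoube-type liquid-vapour 18O equilibrium fractionation, permil, T in C
equilibrium_vapour_fractionation <- function(T_leaf) {
  TK <- T_leaf + 273.15
  (exp(1137 / TK^2 - 0.4156 / TK - 0.0020667) - 1) * 1000
}

#' Steady-state 18O enrichment of evaporative-site (cytosol) water
#'
#' Craig-Gordon steady-state model:
#' \deqn{\delta_{es} = \delta_{src} + \varepsilon^+ + \varepsilon_k +
#'   (\delta_{vap} - \delta_{src} - \varepsilon_k)\,e_a/e_i}
#' with \eqn{\varepsilon^+(T)} the liquid-vapour equilibrium fractionation
#' (Majoube form) and \eqn{\varepsilon_k} the kinetic fractionation of the
#' stomatal pathway. The vapour-pressure ratio is taken as `w_a / w_i`.
#' Cytosol water is equated to evaporative-site water scaled by
#' `peclet_mixing` (1 = no mixing).
#'
#' @param d18_vapour delta18O of cuvette water vapour (permil V-SMOW).
#' @param w_a,w_i cuvette and leaf-internal water vapour mole fractions
#'   (mmol mol-1); requires `w_a < w_i` (a transpiring leaf).
#' @param T_leaf leaf temperature (C).
#' @param source_water delta18O of source (xylem) water (permil V-SMOW).
#' @param eps_k kinetic fractionation (permil), default 28.
#' @param peclet_mixing fraction of the enrichment above source water seen
#'   by cytosol water, default 1.
#' @return delta18O of cytosol water (permil V-SMOW).
#' @export
evaporative_site_water <- function(d18_vapour, w_a, w_i, T_leaf,
                                   source_water, eps_k = 28,
                                   peclet_mixing = 1) {
  if (any(w_a >= w_i)) stop("w_a >= w_i: condensation, Craig-Gordon model undefined")
  eps_plus <- equilibrium_vapour_fractionation(T_leaf)
  d_es <- source_water + eps_plus + eps_k +
    (d18_vapour - source_water - eps_k) * (w_a / w_i)
  source_water + peclet_mixing * (d_es - source_water)
}

#' delta18O of CO2 in isotopic equilibrium with cytosol water
#'
#' Full CO2-water equilibration is assumed (high carbonic-anhydrase
#' activity in the C4 mesophyll): \eqn{\delta_{ce} = \delta_{water} +
#' \varepsilon_w(T)} with \eqn{\varepsilon_w = 17604/T_K - 17.93} permil.
#'
#' @param d18_water_es cytosol water delta18O (permil V-SMOW).
#' @param T_leaf leaf temperature (C).
#' @return delta18O of equilibrated CO2 (permil V-SMOW).
#' @export
d18_equilibrated_co2 <- function(d18_water_es, T_leaf) {
  d18_water_es + 17604 / (T_leaf + 273.15) - 17.93
}

#' delta18O of net-assimilated CO2
#'
#' Flux-weighted cuvette mass balance
#' \eqn{\delta_A = (C_{in}\delta_{in} - C_{out}\delta_{out})/(C_{in}-C_{out})}.
#'
#' @param C_in,C_out CO2 mole fractions in/out (umol mol-1).
#' @param d_in,d_out delta18O of CO2 in/out (permil V-SMOW).
#' @return delta18O of the CO2 taken up (permil V-SMOW).
#' @export
d18_assimilated <- function(C_in, C_out, d_in, d_out) {
  if (any(C_in == C_out)) stop("C_in equals C_out: delta_A undefined")
  (C_in * d_in - C_out * d_out) / (C_in - C_out)
}

#' delta18O of CO2 in the intercellular airspaces
#'
#' Two-membrane mass balance across the stomata: the heavy-isotopologue
#' flux continuity \eqn{C_a R_a - C_i R_i = \alpha_s R_A (C_a - C_i)} gives
#' \deqn{\delta_i = \frac{C_a\delta_a - (C_a - C_i)
#'   \left[\delta_A + \bar a(1 + \delta_A/1000)\right]}{C_i}}
#' with the diffusion fractionation inflated by the ternary factor,
#' \eqn{\bar a = a_{s18}/(1-t)}. Satisfies \eqn{\delta_i \to \delta_a} as
#' \eqn{C_i \to C_a}, and reduces to the simple diffusion form at t = 0.
#'
#' @param d18_a delta18O of cuvette CO2 (permil V-SMOW).
#' @param d18_A delta18O of assimilated CO2 (permil V-SMOW).
#' @param C_a,C_i cuvette and intercellular CO2 (umol mol-1).
#' @param t ternary factor.
#' @param a_s18 18O diffusion fractionation in air (permil), default 8.8.
#' @return delta18O of intercellular CO2 (permil V-SMOW).
#' @export
d18_intercellular <- function(d18_a, d18_A, C_a, C_i, t, a_s18 = 8.8) {
  if (any(C_i <= 0)) stop("C_i must be positive")
  if (any(C_i > C_a)) warning("C_i > C_a without negative assimilation is non-physical")
  abar <- a_s18 / (1 - t)
  d_step <- d18_A + abar * (1 + d18_A / 1000)
  (C_a * d18_a - (C_a - C_i) * d_step) / C_i
}

#' Mesophyll CO2 concentration from C18OO discrimination
#'
#' \deqn{C_M = C_i\,\frac{\delta_i^{18} - \alpha_{w18}\delta_A^{18} - a_{w18}}
#'   {\delta_{ce}^{18} - \alpha_{w18}\delta_A^{18} - a_{w18}}}
#' with \eqn{\alpha_{w18} = 1 + a_{w18}/1000}. When
#' \eqn{\delta_i^{18} = \delta_{ce}^{18}} the ratio is 1 and \eqn{C_M = C_i}
#' regardless of grouping.
#'
#' @param C_i intercellular CO2 (umol mol-1).
#' @param d18_i,d18_A,d18_ce delta18O of intercellular, assimilated and
#'   water-equilibrated CO2 (permil V-SMOW).
#' @param a_w18 summed liquid-phase diffusion + dissolution discrimination
#'   (permil), default 0.8.
#' @param tol denominator magnitude below which the step is declared
#'   unresolvable.
#' @return C_M (umol mol-1).
#' @export
mesophyll_co2 <- function(C_i, d18_i, d18_A, d18_ce, a_w18 = 0.8,
                          tol = 1e-10) {
  alpha_w18 <- 1 + a_w18 / 1000
  num <- d18_i  - alpha_w18 * d18_A - a_w18
  den <- d18_ce - alpha_w18 * d18_A - a_w18
  if (any(abs(den) < tol))
    stop("unresolvable C_M: 18O signal denominator vanishes")
  C_i * num / den
}

# Full per-step 18O chain: observables -> C_M. Returns the intermediate
# state alongside C_M for diagnostics.
oxygen18_chain <- function(step, C_i, t, params) {
  d_es <- evaporative_site_water(step$d18W_out, step$w_a, step$w_i,
                                 step$T_leaf, params$d18_source_water,
                                 eps_k = params$eps_k18,
                                 peclet_mixing = params$peclet_mixing)
  d_ce <- d18_equilibrated_co2(d_es, step$T_leaf)
  d_A  <- d18_assimilated(step$C_in, step$C_out, step$d18C_in, step$d18C_out)
  d_a  <- step$d18C_out   # well-mixed cuvette: air around the leaf = outlet
  d_i  <- d18_intercellular(d_a, d_A, step$C_a, C_i, t, params$a_s18)
  C_M  <- mesophyll_co2(C_i, d_i, d_A, d_ce, params$a_w18)
  list(d18_water_es = d_es, d18_ce = d_ce, d18_A = d_A, d18_a = d_a,
       d18_i = d_i, C_M = C_M)
}
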