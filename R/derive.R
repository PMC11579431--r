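#' Per-step derived quantities for one replicate
#'
#' Runs the measurement-side inference chain on every dehydration step:
#' observed 13C and 18O discrimination (inlet-outlet mass balance),
#' cuticle-corrected intercellular CO2, ternary factor, fluorescence-derived
#' ATP production, the 18O chain yielding mesophyll CO2, and mesophyll
#' conductance. These are the model-independent inputs to the flux solver
#' and the conductance fit.
#'
#' @param rep a `c4_replicate`.
#' @param params a [c4_params()] object.
#' @return data.frame with one row per step: `psi_L`, `A`, `E`, `C_a`,
#'   `T_leaf`, `delta13_obs`, `delta18_obs`, `C_i`, `C_i_classical`, `t`,
#'   `J_ATP`, `C_M`, `g_M`, `Y_II`, and the 18O intermediates
#'   (`d18_water_es`, `d18_ce`, `d18_A`, `d18_i`).
#' @export
derive_steps <- function(rep, params) {
  s <- rep$steps
  d13 <- observed_discrimination(s$C_in, s$C_out, s$d13_in, s$d13_out)
  d18 <- observed_discrimination(s$C_in, s$C_out, s$d18C_in, s$d18C_out)
  C_i <- cuticle_corrected_ci(s$A, s$E, s$g_sw, s$C_a,
                              g_cw = params$g_cw, beta = params$beta_cuticle)
  C_i_cl <- classical_ci(s$A, s$E, s$g_sw, s$C_a)
  g_sc <- (s$g_sw - params$g_cw / 1000) / 1.6
  t <- ternary_factor(s$E, g_sc, params$a_s)
  J <- j_atp(s$A_low, s$Y_II, s$Y_II_low, params$R_LIGHT, params$atp_cost)
  o18 <- oxygen18_chain(s, C_i, t, params)
  # noise can produce occasional negative drawdowns; flagged downstream,
  # not per-call
  g_M <- suppressWarnings(mesophyll_conductance(s$A, C_i, o18$C_M))
  data.frame(psi_L = s$psi_L, A = s$A, E = s$E, C_a = s$C_a,
             T_leaf = s$T_leaf, delta13_obs = d13, delta18_obs = d18,
             C_i = C_i, C_i_classical = C_i_cl, t = t, J_ATP = J,
             C_M = o18$C_M, g_M = g_M, Y_II = s$Y_II,
             d18_water_es = o18$d18_water_es, d18_ce = o18$d18_ce,
             d18_A = o18$d18_A, d18_i = o18$d18_i)
}
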