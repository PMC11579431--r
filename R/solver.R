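#' Bundle-sheath O2 concentration
#'
#' \eqn{O_{BS} = O_M + \alpha A / (0.047\, g_{BS})}: photosynthetic O2
#' evolved in the bundle sheath leaves against a diffusive gradient, with
#' 0.047 scaling O2 to CO2 diffusivity and solubility.
#'
#' @param A net assimilation (umol m-2 s-1).
#' @param g_BS bundle-sheath conductance to CO2 (mol m-2 s-1).
#' @param params a [c4_params()] object (uses `alpha`, `O_M`,
#'   `diff_sol_ratio`).
#' @return O_BS (umol mol-1).
#' @export
o_bs <- function(A, g_BS, params) {
  if (any(g_BS <= 0)) stop("g_BS must be positive")
  params$O_M + params$alpha * A / (params$diff_sol_ratio * g_BS)
}

#' Solve the five-equation C4 biochemical system
#'
#' Given measured net assimilation, total ATP production and mesophyll CO2,
#' plus a candidate bundle-sheath conductance, solves exactly for the five
#' unknowns (V_C, V_P, V_O, C_BS, O_BS) of the system
#' \deqn{A = V_C - 0.5 V_O - R_{LIGHT}}
#' \deqn{V_O = 2\gamma^* O_{BS} V_C / C_{BS}}
#' \deqn{C_{BS} = C_M + (V_P - R_M - A)/g_{BS}}
#' \deqn{O_{BS} = O_M + \alpha A/(0.047 g_{BS})}
#' \deqn{J_{ATP} = 3 V_C + 3.5 V_O + 2 V_P.}
#' O_BS is closed-form; eliminating V_C and V_P reduces the system to a
#' quadratic in V_O. Both roots can solve the system; a root qualifies as
#' physical when V_O >= 0, V_P > 0 and C_BS >= C_M > 0 (non-negative leak,
#' the operating regime of a CO2-concentrating C4 leaf), and among
#' qualifying roots the one with the smaller C_BS (larger oxygenation) is
#' selected — the branch a consistent forward model of this system
#' occupies under physiological conditions. In the \eqn{\gamma^* = 0}
#' limit the competing root collapses to C_BS = 0 and is disqualified, so
#' the closed form V_O = 0, V_C = A + R_LIGHT is returned exactly.
#'
#' Infeasibility (no real root, or no root with positive C_BS and V_P) is a
#' reported state (`feasible = FALSE`), not an error, because the ATP-cost
#' calibration scans feasibility across whole datasets.
#'
#' @param A net assimilation (umol m-2 s-1).
#' @param J_ATP total ATP production (umol m-2 s-1).
#' @param C_M mesophyll CO2 (umol mol-1).
#' @param g_BS bundle-sheath conductance (mol m-2 s-1), scalar or vector.
#' @param params a [c4_params()] object.
#' @param project if `TRUE`, inputs just outside the feasible set (no real
#'   root, a consequence of measurement noise on A, J_ATP or C_M) are
#'   projected onto the feasibility boundary (the repeated root of the
#'   quadratic), yielding a continuous, approximately-consistent state;
#'   such steps keep `feasible = FALSE` and carry a positive `violation`.
#' @return a data.frame with columns `V_C`, `V_P`, `V_O`, `C_BS`, `O_BS`,
#'   `phi` (leakiness), `feasible` and `violation` (0 when feasible, a
#'   distance-to-feasibility measure otherwise). Vectorized over steps.
#' @examples
#' p <- c4_params("maize")
#' solve_fluxes(A = 20, J_ATP = 120, C_M = 100, g_BS = 0.002, p)
#' @export
solve_fluxes <- function(A, J_ATP, C_M, g_BS, params, project = FALSE) {
  n <- max(length(A), length(J_ATP), length(C_M), length(g_BS))
  A <- rep_len(A, n); J_ATP <- rep_len(J_ATP, n)
  C_M <- rep_len(C_M, n); g_BS <- rep_len(g_BS, n)
  if (any(g_BS <= 0)) stop("g_BS must be positive")
  R  <- params$R_LIGHT
  RM <- r_mesophyll(params)
  gs <- params$gamma_star
  OBS <- o_bs(A, g_BS, params)

  # C_BS = D - 2.5 V_O / g_BS after substituting V_P(V_O)
  D <- C_M + (J_ATP / 2 - 1.5 * (A + R) - RM - A) / g_BS
  qa <- 2.5 / g_BS
  qb <- gs * OBS - D
  qc <- 2 * gs * OBS * (A + R)

  disc <- qb^2 - 4 * qa * qc
  V_O <- V_C <- V_P <- C_BS <- rep(NA_real_, n)
  feasible <- rep(FALSE, n)
  # distance-to-feasibility diagnostic (0 when feasible): drives penalty-
  # based optimization toward the feasible set instead of a flat cliff
  violation <- sqrt(pmax(-disc, 0)) / (2 * qa)
  ok <- disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    roots <- cbind((-qb[ok] - sq) / (2 * qa[ok]),
                   (-qb[ok] + sq) / (2 * qa[ok]))
    pick <- function(i, r) {
      vo <- roots[i, r]
      vc <- A[ok][i] + R + 0.5 * vo
      vp <- (J_ATP[ok][i] - 3 * (A[ok][i] + R) - 5 * vo) / 2
      cbs <- D[ok][i] - 2.5 * vo / g_BS[ok][i]
      # tolerance on C_BS >= C_M admits the exact zero-leak boundary
      c(vo, vc, vp, cbs,
        vo >= 0 && vc > 0 && vp > 0 && cbs > 0 &&
          cbs >= C_M[ok][i] - 1e-9)
    }
    for (j in seq_len(sum(ok))) {
      cand <- rbind(pick(j, 1), pick(j, 2))
      phys <- which(cand[, 5] == 1)
      i <- which(ok)[j]
      if (length(phys)) {
        sel <- phys[which.min(cand[phys, 4])]   # smaller C_BS
        V_O[i] <- cand[sel, 1]; V_C[i] <- cand[sel, 2]
        V_P[i] <- cand[sel, 3]; C_BS[i] <- cand[sel, 4]
        feasible[i] <- TRUE
      } else {
        violation[i] <- min(pmax(0, -cand[, 1]) + pmax(0, -cand[, 3]) +
                              pmax(0, (C_M[i] - cand[, 4]) / 100))
      }
    }
  }
  if (project) {
    # fold projection: repeated root V_O = -qb/(2 qa), admissible only if
    # the projected state still satisfies the physical sign constraints
    pr <- which(!feasible & disc < 0)
    for (i in pr) {
      vo <- max(0, -qb[i] / (2 * qa[i]))
      vc <- A[i] + R + 0.5 * vo
      vp <- (J_ATP[i] - 3 * (A[i] + R) - 5 * vo) / 2
      cbs <- D[i] - 2.5 * vo / g_BS[i]
      if (vc > 0 && vp > 0 && cbs > 0 && cbs >= C_M[i]) {
        V_O[i] <- vo; V_C[i] <- vc; V_P[i] <- vp; C_BS[i] <- cbs
      }
    }
  }
  phi <- ifelse(!is.na(V_P) & V_P > 0, (V_P - RM - A) / V_P, NA_real_)
  data.frame(V_C = V_C, V_P = V_P, V_O = V_O, C_BS = C_BS, O_BS = OBS,
             phi = phi, feasible = feasible, violation = violation)
}

#' Leakiness of the bundle sheath
#'
#' The rate of CO2 retrodiffusing from the bundle sheath to the mesophyll
#' relative to PEPC carboxylation:
#' \eqn{\Phi = (V_P - R_M - A)/V_P}, identically equal to
#' \eqn{g_{BS}(C_{BS}-C_M)/V_P} through the bundle-sheath supply function.
#'
#' @param V_P PEPC carboxylation (umol m-2 s-1), must be positive.
#' @param A net assimilation (umol m-2 s-1).
#' @param params a [c4_params()] object (uses `R_LIGHT`, `R_M_fraction`).
#' @return leakiness (dimensionless).
#' @export
leakiness <- function(V_P, A, params) {
  if (any(V_P <= 0)) stop("V_P must be positive")
  (V_P - r_mesophyll(params) - A) / V_P
}

# residuals of the five governing equations, for validation
flux_residuals <- function(sol, A, J_ATP, C_M, g_BS, params) {
  R <- params$R_LIGHT; RM <- r_mesophyll(params)
  cbind(
    assim = sol$V_C - 0.5 * sol$V_O - R - A,
    vo    = sol$V_O - 2 * params$gamma_star * sol$O_BS * sol$V_C / sol$C_BS,
    cbs   = sol$C_BS - C_M - (sol$V_P - RM - A) / g_BS,
    obs   = sol$O_BS - params$O_M -
            params$alpha * A / (params$diff_sol_ratio * g_BS),
    jatp  = 3 * sol$V_C + 3.5 * sol$V_O + 2 * sol$V_P - J_ATP
  )
}
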