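#' Physical constants and assumed parameters of the C4 flux model
#'
#' Builds the full parameter set used throughout the inference chain:
#' biochemical constants of the C4 model, isotopic fractionation factors for
#' the 13C discrimination model and the 18O chain, cuticle-pathway
#' conductances, and the isotopic composition of the measurement and growth
#' air. All defaults are the values used in the fast-dehydration study design
#' this package implements; any can be overridden by name.
#'
#' Units follow leaf gas-exchange convention: fluxes in umol m-2 s-1 (water
#' in mmol m-2 s-1), conductances in mol m-2 s-1, mole fractions in
#' umol mol-1 (water vapour in mmol mol-1), fractionations in permil,
#' temperatures in degrees Celsius, water potential in MPa.
#'
#' @param species `"maize"` or `"sorghum"`; selects the species default for
#'   day respiration `R_LIGHT` (1.19 and 0.92 umol m-2 s-1 respectively).
#' @param ... named overrides for any parameter listed below.
#' @param file optional path to a YAML file of named overrides; values in
#'   `...` take precedence over the file.
#'
#' @details Parameters and defaults:
#' \describe{
#'   \item{gamma_star}{half the reciprocal Rubisco CO2/O2 specificity,
#'     0.000233 (dimensionless).}
#'   \item{alpha}{fraction of photosynthetic O2 evolution occurring in the
#'     bundle sheath, 0.15.}
#'   \item{O_M}{mesophyll O2 mole fraction, 210000 umol mol-1 (ambient).}
#'   \item{diff_sol_ratio}{0.047, scales O2 to CO2 diffusivity and
#'     solubility across the bundle-sheath interface.}
#'   \item{R_LIGHT}{day respiration, species default (umol m-2 s-1).}
#'   \item{R_M_fraction}{mesophyll share of day respiration, 0.5.}
#'   \item{atp_cost}{ATP cost of gross assimilation under low O2, 5.4.}
#'   \item{a_s}{13C fractionation for CO2 diffusion in air, 4.4 permil.}
#'   \item{a_s18}{18O fractionation for C18OO diffusion in air, 8.8 permil.}
#'   \item{a_m_offset, a_m_slope}{dissolution fractionation e_s(T) =
#'     a_m_offset + a_m_slope * T_leaf (permil); a_m = e_s(T) + a_liq.}
#'   \item{a_liq}{13C fractionation for liquid-phase diffusion, 0.7 permil.}
#'   \item{b3_prime}{raw Rubisco fractionation, 29 permil.}
#'   \item{b4_offset, b4_slope_K}{raw CA+PEPC fractionation
#'     b4'(T) = b4_offset - b4_slope_K / T_K (permil), about -5.6 at 25 C.}
#'   \item{s}{fractionation during CO2 leakage out of the bundle sheath,
#'     1.8 permil.}
#'   \item{f}{photorespiratory fractionation, 11.6 permil.}
#'   \item{a_w18}{summed 18O discrimination during liquid-phase diffusion
#'     and dissolution of CO2, 0.8 permil.}
#'   \item{eps_k18}{kinetic 18O fractionation of water vapour diffusion
#'     through stomata, 28 permil (boundary layer disregarded).}
#'   \item{g_cw}{cuticular conductance to water vapour, 2 mmol m-2 s-1.}
#'   \item{beta_cuticle}{ratio of cuticular CO2 to water conductance, 0.025.}
#'   \item{d13_measurement}{delta13C of the measurement CO2, -7.02 permil.}
#'   \item{d13_growth}{delta13C of the growth-chamber CO2, -8 permil.}
#'   \item{d18_source_water}{delta18O of the plant source water, -5 permil
#'     V-SMOW (typical irrigation water).}
#'   \item{peclet_mixing}{fraction of evaporative-site enrichment seen by
#'     cytosol water, 1 (no Peclet mixing).}
#' }
#'
#' @return an object of class `"c4_params"` (a named list).
#' @examples
#' p <- c4_params("maize")
#' p$gamma_star
#' c4_params("sorghum", alpha = 0)$alpha
#' @export
c4_params <- function(species = c("maize", "sorghum"), ..., file = NULL) {
  species <- match.arg(species)
  p <- list(
    species         = species,
    gamma_star      = 0.000233,
    alpha           = 0.15,
    O_M             = 210000,
    diff_sol_ratio  = 0.047,
    R_LIGHT         = if (species == "maize") 1.19 else 0.92,
    R_M_fraction    = 0.5,
    atp_cost        = 5.4,
    a_s             = 4.4,
    a_s18           = 8.8,
    a_m_offset      = 1.18,
    a_m_slope       = -0.0041,
    a_liq           = 0.7,
    b3_prime        = 29,
    b4_offset       = 26.19,
    b4_slope_K      = 9483,
    s               = 1.8,
    f               = 11.6,
    a_w18           = 0.8,
    eps_k18         = 28,
    g_cw            = 2,
    beta_cuticle    = 0.025,
    d13_measurement = -7.02,
    d13_growth      = -8,
    d18_source_water = -5,
    peclet_mixing   = 1
  )
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    p[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "c4_params")
  validate_params(p)
  p
}

#' @keywords internal
validate_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.finite(p$gamma_star) || p$gamma_star <= 0)
    stop("gamma_star must be positive")
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must be in [0, 1]")
  if (p$O_M <= 0) stop("O_M must be positive")
  if (p$atp_cost < 3)
    stop("atp_cost below 3 cannot cover the ATP demand of Rubisco carboxylation")
  if (p$R_LIGHT < 0) stop("R_LIGHT must be non-negative")
  if (p$g_cw < 0 || p$beta_cuticle < 0) stop("cuticle parameters must be non-negative")
  frac <- unlist(p[c("a_s", "a_s18", "a_liq", "b3_prime", "s", "f",
                     "a_w18", "eps_k18")])
  if (!all(is.finite(frac))) stop("all fractionation factors must be finite")
  invisible(p)
}

#' @export
print.c4_params <- function(x, ...) {
  cat("C4 model parameters (", x$species, ")\n", sep = "")
  nm <- setdiff(names(x), "species")
  for (n in nm) cat(sprintf("  %-16s %s\n", n, format(x[[n]])))
  invisible(x)
}

# mesophyll respiration, half of day respiration by default
r_mesophyll <- function(params) params$R_M_fraction * params$R_LIGHT
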