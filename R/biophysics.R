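#' Diffusive conductance of a spiracle (Fick's law)
#'
#' Capacity of a barrier of given cross-sectional area and depth to pass
#' oxygen by diffusion: `G_diff = (area / depth) * K`, with Krogh's constant
#' `K = D * beta_cap`.
#'
#' @param area opening area, cm^2. Vectorized.
#' @param depth barrier depth, cm. Vectorized.
#' @param constants a [physical_constants()] object.
#' @return Diffusive conductance, nmol s^-1 kPa^-1.
#' @examples
#' diffusive_conductance(1, 1)  # 0.178 * 404 = 71.912
#' @export
diffusive_conductance <- function(area, depth, constants = physical_constants()) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("diffusive_conductance: 'area' must be finite and > 0")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("diffusive_conductance: 'depth' must be finite and > 0")
  (area / depth) * constants$D * constants$beta_cap
}

#' Diffusive oxygen flux across an exchanger
#'
#' `J_diff = G_diff * dPO2`; the sign follows the partial-pressure gradient.
#'
#' @param g_diff diffusive conductance, nmol s^-1 kPa^-1 (>= 0).
#' @param dpo2 O2 partial-pressure gradient across the exchanger, kPa.
#' @return Oxygen flux, nmol s^-1.
#' @export
diffusive_flux <- function(g_diff, dpo2) {
  if (any(g_diff < 0)) stop("diffusive_flux: 'g_diff' must be >= 0")
  g_diff * dpo2
}

#' Advective conductance of a spiracle (Poiseuille's law)
#'
#' Capacity of a channel to carry bulk flow per unit pressure:
#' `G_adv = area^2 / (8 * mu * length)`. SI geometry in, so that the
#' conductance comes out in m^3 s^-1 kPa^-1 with the viscosity in kPa s.
#'
#' @param area channel cross-sectional area, m^2. Vectorized.
#' @param length channel length, m. Vectorized.
#' @param constants a [physical_constants()] object.
#' @return Advective conductance, m^3 s^-1 kPa^-1.
#' @examples
#' advective_conductance(1e-4, 0.01)  # 1 cm^2 opening, 1 cm deep
#' @export
advective_conductance <- function(area, length, constants = physical_constants()) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("advective_conductance: 'area' must be finite and > 0")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("advective_conductance: 'length' must be finite and > 0")
  area^2 / (8 * constants$mu * length)
}

#' Advective oxygen flux through a channel
#'
#' `J_adv = G_adv * [O2] * dHP`.
#'
#' @param g_adv advective conductance, m^3 s^-1 kPa^-1 (>= 0).
#' @param o2_conc O2 concentration in the fluid, mol m^-3 (>= 0).
#' @param dhp hydrostatic pressure gradient, kPa.
#' @return Oxygen flux, mol s^-1.
#' @export
advective_flux <- function(g_adv, o2_conc, dhp) {
  if (any(g_adv < 0)) stop("advective_flux: 'g_adv' must be >= 0")
  if (any(o2_conc < 0)) stop("advective_flux: 'o2_conc' must be >= 0")
  g_adv * o2_conc * dhp
}

#' Resting metabolic rate of an insect from body mass
#'
#' Evaluates the allometric model
#' `log10(metabolic rate, uW) = mr_intercept + mr_exponent * log10(mass, g)`
#' (defaults 3.2 and 0.75, for a quiescent insect at 25 C).
#'
#' @param mass body mass, g. Vectorized.
#' @param constants a [physical_constants()] object.
#' @return Metabolic rate, uW.
#' @examples
#' resting_metabolic_rate(1)    # 10^3.2 ~ 1585 uW
#' resting_metabolic_rate(0.1)
#' @export
resting_metabolic_rate <- function(mass, constants = physical_constants()) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("resting_metabolic_rate: 'mass' must be finite and > 0")
  10^(constants$mr_intercept + constants$mr_exponent * log10(mass))
}

#' Convert an aerobic metabolic rate to an oxygen consumption rate
#'
#' Chains uW -> uJ s^-1 -> nL O2 s^-1 (via the energy equivalent of oxygen,
#' 20.7 uJ/nL at RQ 0.85) -> nmol O2 s^-1 (via the molar volume, 24.5 nL/nmol
#' at 25 C).
#'
#' @param mr metabolic rate, uW (>= 0). Vectorized.
#' @param constants a [physical_constants()] object.
#' @return Oxygen consumption, nmol s^-1.
#' @export
o2_consumption <- function(mr, constants = physical_constants()) {
  if (any(mr < 0)) stop("o2_consumption: 'mr' must be >= 0")
  mr / constants$e_per_nl / constants$nl_per_nmol
}

#' Metabolic scenario: aerobic scope and metabolic scaling exponent
#'
#' @param aerobic_scope multiple of resting metabolic rate for a 1 g animal
#'   (1 = rest; 90 = the median maximal flight scope reported for beetles).
#' @param exponent mass-scaling exponent of metabolic rate in this state.
#'   Flight exponents of 0.67 (large insects) and 1.19 (small insects) bracket
#'   the literature; 0.75 is the canonical resting value.
#' @param name optional label.
#' @return A `metabolic_scenario` object.
#' @examples
#' metabolic_scenario(1, 0.75, "rest")
#' metabolic_scenario(90, 0.67, "flight_large")
#' @export
metabolic_scenario <- function(aerobic_scope = 1, exponent = 0.75, name = NULL) {
  if (!is.numeric(aerobic_scope) || aerobic_scope < 1)
    stop("metabolic_scenario: 'aerobic_scope' must be >= 1")
  if (!is.numeric(exponent) || exponent <= 0)
    stop("metabolic_scenario: 'exponent' must be > 0")
  if (is.null(name))
    name <- sprintf("AS%g_EXP%g", aerobic_scope, exponent)
  structure(list(aerobic_scope = aerobic_scope, exponent = exponent, name = name),
            class = "metabolic_scenario")
}

#' Default metabolic scenarios: rest and the two flight-exponent brackets
#'
#' @return A list of three [metabolic_scenario()] objects: rest
#'   (AS = 1, EXP = 0.75) and flight at 90x aerobic scope with EXP 0.67 and 1.19.
#' @export
default_scenarios <- function() {
  list(metabolic_scenario(1, 0.75, "rest"),
       metabolic_scenario(90, 0.67, "flight_exp0.67"),
       metabolic_scenario(90, 1.19, "flight_exp1.19"))
}

#' PO2 gradient required to supply metabolism by diffusion across the spiracles
#'
#' Rearranges Fick's law: the oxygen demand
#' `10^(log10(AS) + mr_intercept + EXP * log10(mass))` uW is converted to
#' nmol s^-1 and divided by the summed spiracular diffusive conductance.
#' At 1 g the aerobic scope factors out exactly, so the flight/rest ratio
#' equals AS and the exponent is inert.
#'
#' @param mass body mass, g. Vectorized (recycled against `total_g_diff`).
#' @param total_g_diff total spiracular diffusive conductance,
#'   nmol s^-1 kPa^-1 (> 0).
#' @param scenario a [metabolic_scenario()].
#' @param constants a [physical_constants()] object.
#' @return Required O2 partial-pressure gradient, kPa.
#' @examples
#' required_dpo2(1, 100)                                  # rest
#' required_dpo2(1, 100, metabolic_scenario(90, 0.67))    # 90x larger
#' @export
required_dpo2 <- function(mass, total_g_diff,
                          scenario = metabolic_scenario(1, 0.75),
                          constants = physical_constants()) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("required_dpo2: 'mass' must be finite and > 0")
  if (any(!is.finite(total_g_diff)) || any(total_g_diff <= 0))
    stop("required_dpo2: 'total_g_diff' must be finite and > 0")
  mr <- 10^(log10(scenario$aerobic_scope) + constants$mr_intercept +
              scenario$exponent * log10(mass))
  o2_consumption(mr, constants) / total_g_diff
}

#' Does a required PO2 gradient exceed the atmospheric oxygen level?
#'
#' Air can supply at most ~21 kPa of oxygen partial pressure at sea level,
#' so a required gradient above 21 kPa cannot be realised by diffusion.
#'
#' @param dpo2 required gradient(s), kPa (>= 0).
#' @param ceiling atmospheric PO2, kPa.
#' @return Logical: strictly above the ceiling.
#' @export
exceeds_atmosphere <- function(dpo2, ceiling = 21) {
  if (any(dpo2 < 0)) stop("exceeds_atmosphere: 'dpo2' must be >= 0")
  dpo2 > ceiling
}
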