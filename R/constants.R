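#' Physical constants for tracheal gas-exchange calculations
#'
#' Bundle of the physical constants used throughout the package, frozen at
#' 25 degrees C. Defaults are the standard literature values for oxygen in
#' air; any of them can be overridden, e.g. for sensitivity analyses.
#'
#' @param D O2 diffusivity in air, cm^2 s^-1.
#' @param beta_cap O2 capacitance coefficient in air, nmol cm^-3 kPa^-1.
#'   Krogh's diffusion constant is `D * beta_cap`.
#' @param mu dynamic viscosity of air, kPa s.
#' @param e_per_nl energy equivalent of oxygen, uJ per nL O2 (RQ 0.85).
#' @param nl_per_nmol molar volume of an ideal gas at 25 C, nL per nmol
#'   (equivalently L per mol).
#' @param mr_intercept log10 resting metabolic rate (uW) of a 1 g insect.
#' @param mr_exponent mass-scaling exponent of resting metabolic rate.
#' @param temperature reference temperature, degrees C. Informational only:
#'   no temperature correction is applied.
#'
#' @return An immutable object of class `physical_constants`.
#' @examples
#' cc <- physical_constants()
#' cc$D * cc$beta_cap  # Krogh's constant, nmol cm^-1 s^-1 kPa^-1
#' @export
physical_constants <- function(D = 0.178,
                               beta_cap = 404,
                               mu = 1.86e-8,
                               e_per_nl = 20.7,
                               nl_per_nmol = 24.5,
                               mr_intercept = 3.2,
                               mr_exponent = 0.75,
                               temperature = 25) {
  vals <- list(D = D, beta_cap = beta_cap, mu = mu,
               e_per_nl = e_per_nl, nl_per_nmol = nl_per_nmol,
               mr_intercept = mr_intercept, mr_exponent = mr_exponent,
               temperature = temperature)
  num <- vapply(vals, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num))
    stop("all physical constants must be finite numeric scalars: ",
         paste(names(vals)[!num], collapse = ", "))
  pos <- setdiff(names(vals), "temperature")
  bad <- pos[vapply(vals[pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("physical constants must be strictly positive: ",
         paste(bad, collapse = ", "))
  structure(vals, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (", x$temperature, " C):\n", sep = "")
  cat(sprintf("  D        = %g cm^2 s^-1 (O2 diffusivity in air)\n", x$D))
  cat(sprintf("  beta_cap = %g nmol cm^-3 kPa^-1 (O2 capacitance)\n", x$beta_cap))
  cat(sprintf("  mu       = %g kPa s (air viscosity)\n", x$mu))
  cat(sprintf("  O2 energy: %g uJ/nL, molar volume %g nL/nmol\n",
              x$e_per_nl, x$nl_per_nmol))
  cat(sprintf("  resting MR: log10(uW) = %g + %g log10(mass g)\n",
              x$mr_intercept, x$mr_exponent))
  invisible(x)
}

# Disallow silent mutation: constants are constructed once.
#' @export
`$<-.physical_constants` <- function(x, name, value) {
  stop("physical_constants are immutable; construct a new set with physical_constants()")
}
#' @export
`[[<-.physical_constants` <- function(x, i, value) {
  stop("physical_constants are immutable; construct a new set with physical_constants()")
}

#' Mass-scaling exponent of a tube's gas conductance from its dimension exponents
#'
#' Pure exponent algebra for conductances of a cylindrical exchanger. If the
#' cross-sectional area of the tube scales with mass^a and its depth (length)
#' with mass^d, the diffusive conductance area/depth scales with mass^(a - d)
#' and the Poiseuille advective conductance area^2/depth with mass^(2a - d).
#' When the radius exponent r is supplied instead, area scales as mass^(2r),
#' giving 2r - d (diffusive) and 4r - d (advective). This reproduces the
#' classic mammalian aorta and bronchial-tree arithmetic.
#'
#' @param kind `"diffusive"` or `"advective"`.
#' @param depth_exp mass exponent of depth/length.
#' @param area_exp mass exponent of cross-sectional area (exclusive with
#'   `radius_exp`).
#' @param radius_exp mass exponent of radius.
#' @return The mass-scaling exponent of the conductance.
#' @examples
#' conductance_exponent("advective", depth_exp = 0.25, radius_exp = 0.375) # aorta: 1.25
#' conductance_exponent("advective", depth_exp = 0.27, radius_exp = 0.39)  # bronchi: 1.29
#' conductance_exponent("diffusive", depth_exp = 0.25, radius_exp = 0.375) # 0.5
#' @export
conductance_exponent <- function(kind = c("diffusive", "advective"),
                                 depth_exp, area_exp = NULL, radius_exp = NULL) {
  kind <- match.arg(kind)
  if (is.null(area_exp) == is.null(radius_exp))
    stop("supply exactly one of area_exp or radius_exp")
  a <- if (is.null(area_exp)) 2 * radius_exp else area_exp
  k <- switch(kind, diffusive = 1, advective = 2)
  k * a - depth_exp
}

#' Area exponent required to keep the diffusive PO2 gradient size-invariant
#'
#' If metabolic rate scales with mass^EXP and barrier depth with mass^d, the
#' required partial-pressure gradient across the exchanger is constant across
#' body sizes only when area scales with mass^(EXP + d): the conductance
#' exponent (area - depth) then equals the metabolic exponent. With the
#' usual resting exponent 0.75 and isometric depth 0.33 this gives 1.08.
#'
#' @param metabolic_exp mass exponent of metabolic rate.
#' @param depth_exp mass exponent of barrier depth.
#' @return Required mass exponent for exchanger area.
#' @export
area_exponent_for_constant_dpo2 <- function(metabolic_exp = 0.75,
                                            depth_exp = 0.33) {
  metabolic_exp + depth_exp
}
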