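#' Blood (fluid) properties
#'
#' Container for the fluid constants used throughout the package. All internal
#' computations are in CGS units (cm, g, s); pressures in dyn/cm^2, flows in
#' mL/s. Defaults are the standard blood values for pulmonary-artery
#' simulation: density 1.06 g/cm^3 and dynamic viscosity 0.04 g/(cm s)
#' (0.04 poise = 4 cP).
#'
#' @param density Blood density rho, g/cm^3.
#' @param viscosity Dynamic viscosity mu, g/(cm s).
#' @return An object of class `fluid_properties` with fields `density`,
#'   `viscosity` and the derived kinematic viscosity `nu = mu / rho` (cm^2/s).
#' @examples
#' fl <- fluid_properties()
#' fl$nu  # 0.04 / 1.06
#' @export
fluid_properties <- function(density = 1.06, viscosity = 0.04) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("`density` must be a single positive number (g/cm^3)")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (g/(cm s))")
  }
  structure(
    list(density = density, viscosity = viscosity, nu = viscosity / density),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties (CGS):\n")
  cat(sprintf("  density   rho = %g g/cm^3\n", x$density))
  cat(sprintf("  viscosity mu  = %g g/(cm s)\n", x$viscosity))
  cat(sprintf("  kinematic nu  = %g cm^2/s\n", x$nu))
  invisible(x)
}

# conversion factor: 1 mmHg in dyn/cm^2
MMHG_TO_DYN_CM2 <- 1333.22

#' Unit conversions at the I/O boundary
#'
#' The package works in CGS internally; clinical inputs are usually in mmHg
#' and L/min. `mmhg_to_dyn_cm2()` uses 1 mmHg = 1333.22 dyn/cm^2.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
mmhg_to_dyn_cm2 <- function(x) x * MMHG_TO_DYN_CM2

#' @rdname unit_conversions
#' @export
dyn_cm2_to_mmhg <- function(x) x / MMHG_TO_DYN_CM2

#' @rdname unit_conversions
#' @export
lmin_to_ml_s <- function(x) x * 1000 / 60

#' @rdname unit_conversions
#' @export
ml_s_to_lmin <- function(x) x * 60 / 1000
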