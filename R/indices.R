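#' Reynolds number
#'
#' `Re = rho * V * L / mu`, with `V` a representative sectional mean speed
#' (cm/s) and `L` the vessel diameter (cm).
#'
#' @param fluid A [fluid_properties()].
#' @param mean_velocity Representative velocity, cm/s (>= 0).
#' @param diameter Vessel diameter, cm (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, mean_velocity, diameter) {
  if (any(diameter <= 0)) stop("`diameter` must be positive")
  if (any(mean_velocity < 0)) stop("`mean_velocity` must be >= 0")
  fluid$density * mean_velocity * diameter / fluid$viscosity
}

#' Womersley number
#'
#' `Wo = r * sqrt(2 * pi / (nu * T))` with `r` the vessel radius (cm), `nu`
#' the kinematic viscosity (cm^2/s) and `T` the cardiac-cycle length (s).
#' Healthy pulmonary arteries typically sit between 14 and 21.
#'
#' @param radius Vessel radius, cm (> 0).
#' @param fluid A [fluid_properties()].
#' @param period Cardiac cycle length T, s (> 0).
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(radius, fluid, period) {
  if (any(radius <= 0)) stop("`radius` must be positive")
  if (period <= 0) stop("`period` must be positive")
  radius * sqrt(2 * pi / (fluid$nu * period))
}

#' Cross-sectional vorticity index
#'
#' Computes the magnitude of the curl of the in-segment velocity field on the
#' measurement cross-section, area-averaged over the disc and time-averaged
#' over the cycle. For an axisymmetric field with axial component `u(s, t)`
#' and optional azimuthal (swirl) component `w(s, t)`, the curl has azimuthal
#' part `-du/ds` and axial part `(1/s) d(s w)/ds`; radial derivatives are
#' evaluated by second-order finite differences.
#'
#' For steady Poiseuille flow with sectional mean velocity `V` and radius `R`
#' the index equals `8 V / (3 R)`; for rigid-body swirl at angular rate
#' `Omega` it equals `2 Omega`.
#'
#' @param field A `velocity_field` (see [womersley_profile()]). A `swirl`
#'   matrix of the same shape as `field$u` may be attached as `field$swirl`.
#' @param site Optional [measurement_site()]; when supplied, its segment
#'   radius must match the field's radius.
#' @return Time-averaged, area-weighted mean |curl|, 1/s.
#' @export
vorticity_index <- function(field, site = NULL) {
  if (!inherits(field, "velocity_field")) stop("`field` must be a velocity_field")
  if (!is.null(site) &&
      abs(site$radius - field$radius) > 1e-9 * field$radius) {
    stop("measurement site radius does not match the velocity field's segment")
  }
  s <- field$s
  dus <- apply(field$u, 2, fd_gradient, s)
  om_az <- -dus
  if (!is.null(field$swirl)) {
    sw <- field$swirl * s
    dsw <- apply(sw, 2, fd_gradient, s)
    om_ax <- dsw / ifelse(s == 0, NA, s)
    # axis value by limit: (1/s) d(sw)/ds -> 2 dw/ds at s = 0
    dw <- apply(field$swirl, 2, fd_gradient, s)
    om_ax[1, ] <- 2 * dw[1, ]
    om_mag <- sqrt(om_az^2 + om_ax^2)
  } else {
    om_mag <- abs(om_az)
  }
  w_q <- s * trapz_weights(s)
  area <- field$radius^2 / 2            # int s ds
  sect <- as.vector(crossprod(om_mag, w_q)) / area
  mean(sect)                            # uniform grid over one period
}

# second-order finite-difference gradient (one-sided second order at ends)
fd_gradient <- function(y, x) {
  n <- length(y)
  h <- x[2] - x[1]
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  g
}

#' Energy dissipation of the PA bed
#'
#' Cycle-averaged total-pressure energy flux entering the MPA minus the flux
#' leaving all outlet caps:
#' `ED = <(P + rho V^2 / 2) A V>_MPA - sum_outlets <(P + rho V^2 / 2) A V>`,
#' with `V = Q / A` the sectional mean velocity and pressures sampled at the
#' model inlet and at the outlet caps (upstream of the Windkessel proximal
#' resistance). The instantaneous flux is averaged over the last cycle; a
#' literal variant that multiplies the cycle-averaged pressure by the
#' instantaneous velocity flux is available via
#' `time_treatment = "averaged_pressure"` (the two coincide for steady flow).
#' Result converted from erg/s to mW (1 mW = 1e4 erg/s).
#'
#' @param sol A `network_solution` (see [solve_network()]).
#' @param tree The [pa_tree()] the solution was computed on (provides the
#'   inlet and outlet cap areas).
#' @param fluid A [fluid_properties()].
#' @param time_treatment `"instantaneous"` (default) or
#'   `"averaged_pressure"`.
#' @return Energy dissipation, mW.
#' @export
energy_dissipation <- function(sol, tree, fluid = fluid_properties(),
                               time_treatment = c("instantaneous",
                                                  "averaged_pressure")) {
  time_treatment <- match.arg(time_treatment)
  lc <- last_cycle(sol)
  seg <- tree$segments
  a_in <- seg$area[is.na(seg$parent)]
  outs <- sol$outlet_ids
  if (!all(as.character(outs) %in% colnames(lc$outlet_flow))) {
    stop("missing outlet trace in solution")
  }
  a_out <- seg$area[match(outs, seg$id)]
  T <- sol$period
  rho <- fluid$density
  tt <- lc$time

  flux <- function(P, Q, A) {
    V <- Q / A
    if (time_treatment == "averaged_pressure") {
      Pbar <- trapz_rows(P, tt) / T
      (Pbar + 0.5 * rho * V^2) * Q
    } else {
      (P + 0.5 * rho * V^2) * Q
    }
  }
  e_in <- trapz_rows(flux(lc$inlet_pressure, lc$inlet_flow, a_in), tt) / T
  e_out <- sum(vapply(seq_along(outs), function(i) {
    trapz_rows(flux(lc$outlet_pressure[, i], lc$outlet_flow[, i], a_out[i]),
               tt) / T
  }, numeric(1)))
  (e_in - e_out) / 1e4                  # erg/s -> mW
}

#' Decompose a flow waveform into forward and backward parts
#'
#' Splits one cycle of a flow waveform into its forward (`Q > 0`) and
#' backward (`Q < 0`) phases: per-cycle forward and backward volumes
#' (trapezoid rule with periodic wrap), phase-mean sectional velocities
#' (`Q / area`, the backward one reported as a magnitude), and the
#' regurgitation fraction `PR% = 100 * backward / forward`.
#'
#' @param waveform A [flow_waveform()].
#' @param area Cross-sectional area, cm^2 (> 0).
#' @return List: `forward_volume`, `backward_volume` (mL), `forward_velocity`,
#'   `backward_velocity` (cm/s), `pr_percent`.
#' @export
flow_decomposition <- function(waveform, area) {
  if (area <= 0) stop("`area` must be positive")
  t <- waveform$time; q <- waveform$flow; T <- waveform$period
  fwd <- cycle_integral(t, pmax(q, 0), T)
  bwd <- cycle_integral(t, pmax(-q, 0), T)
  if (fwd <= 0 && bwd > 0) {
    stop("PR% undefined: zero forward volume with nonzero backward flow")
  }
  pr <- if (fwd > 0) 100 * bwd / fwd else 0
  pos <- q > 0; neg <- q < 0
  vf <- if (any(pos)) mean(q[pos]) / area else 0
  vb <- if (any(neg)) mean(-q[neg]) / area else 0
  list(forward_volume = fwd, backward_volume = bwd,
       forward_velocity = vf, backward_velocity = vb,
       pr_percent = pr)
}

#' Summarize per-patient index tables as mean and sample SD
#'
#' Column-wise arithmetic mean and sample standard deviation (n - 1
#' denominator) over patients, with a display copy rounded half-up to one
#' decimal to mirror the conventional table layout.
#'
#' @param indices `data.frame` of per-patient indices; non-numeric columns
#'   (e.g. patient id) are carried through untouched.
#' @return List with `mean`, `sd` (named numeric vectors over the numeric
#'   columns) and `display` (`data.frame` with `Mean` and `SD` rows rounded
#'   to one decimal).
#' @export
summarize_indices <- function(indices) {
  num <- vapply(indices, is.numeric, logical(1))
  if (nrow(indices) < 2L) stop("need at least 2 patients (sample SD undefined)")
  x <- indices[, num, drop = FALSE]
  m <- colMeans(x)
  s <- vapply(x, stats::sd, numeric(1))
  disp <- rbind(Mean = round_half_up(m, 1), SD = round_half_up(s, 1))
  list(mean = m, sd = s, display = as.data.frame(disp))
}

# round half away from zero (display convention for printed tables)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
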