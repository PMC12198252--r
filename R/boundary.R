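#' Three-element Windkessel (RCR) outlet model
#'
#' Lumped model of the vascular bed distal to one outlet: proximal resistance
#' `Rp`, compliance `C` and distal resistance `Rd` in the usual RCR
#' arrangement, referenced to a distal pressure `Pd`.
#'
#' @param Rp Proximal resistance, dyn s/cm^5 (>= 0).
#' @param C Compliance, cm^5/dyn (> 0).
#' @param Rd Distal resistance, dyn s/cm^5 (> 0).
#' @param Pd Distal reference pressure, dyn/cm^2.
#' @return Object of class `windkessel_rcr`.
#' @export
windkessel_rcr <- function(Rp, C, Rd, Pd = 0) {
  if (Rp < 0) stop("`Rp` must be >= 0")
  if (Rd <= 0) stop("`Rd` must be > 0")
  if (C <= 0) stop("`C` must be > 0")
  structure(list(Rp = Rp, C = C, Rd = Rd, Pd = Pd), class = "windkessel_rcr")
}

#' @export
print.windkessel_rcr <- function(x, ...) {
  cat(sprintf("RCR outlet: Rp = %.4g, Rd = %.4g dyn s/cm^5, C = %.4g cm^5/dyn, Pd = %.4g dyn/cm^2\n",
              x$Rp, x$Rd, x$C, x$Pd))
  invisible(x)
}

#' Total pulmonary resistance from mean pressure and flow
#'
#' `R = (mean_pressure - distal_pressure) / mean_flow`, returned in
#' dyn s/cm^5. Clinical units are accepted at the boundary and converted
#' (1 mmHg = 1333.22 dyn/cm^2).
#'
#' @param mean_pressure Cycle-mean PA pressure.
#' @param mean_flow Cycle-mean PA flow (> 0).
#' @param distal_pressure Distal reference pressure (same unit as
#'   `mean_pressure`).
#' @param pressure_unit `"dyn_cm2"` or `"mmHg"`.
#' @param flow_unit `"ml_s"` or `"l_min"`.
#' @return Resistance in dyn s/cm^5.
#' @examples
#' total_pa_resistance(10, 5, pressure_unit = "mmHg", flow_unit = "l_min")
#' @export
total_pa_resistance <- function(mean_pressure, mean_flow, distal_pressure = 0,
                                pressure_unit = c("dyn_cm2", "mmHg"),
                                flow_unit = c("ml_s", "l_min")) {
  pressure_unit <- match.arg(pressure_unit)
  flow_unit <- match.arg(flow_unit)
  if (pressure_unit == "mmHg") {
    mean_pressure <- mmhg_to_dyn_cm2(mean_pressure)
    distal_pressure <- mmhg_to_dyn_cm2(distal_pressure)
  }
  if (flow_unit == "l_min") mean_flow <- lmin_to_ml_s(mean_flow)
  if (mean_flow <= 0) stop("`mean_flow` must be positive")
  if (mean_pressure <= distal_pressure) {
    stop("`mean_pressure` must exceed `distal_pressure` (zero or negative driving pressure)")
  }
  (mean_pressure - distal_pressure) / mean_flow
}

#' Split the total resistance between the two lungs
#'
#' The measured flow distribution sets the split: a side receiving flow
#' fraction `f` gets resistance `R_total / f`, so the two sides in parallel
#' reconstruct `R_total` exactly.
#'
#' @param R_total Total PA resistance, dyn s/cm^5.
#' @param rpa_flow_fraction RPA share of total flow, strictly inside (0, 1).
#' @return Named numeric `c(RPA = ..., LPA = ...)`.
#' @export
side_resistances <- function(R_total, rpa_flow_fraction) {
  f <- rpa_flow_fraction
  if (!is.finite(f) || f < 1e-6 || f > 1 - 1e-6) {
    stop("`rpa_flow_fraction` must lie strictly inside (0, 1)")
  }
  if (R_total <= 0) stop("`R_total` must be positive")
  c(RPA = R_total / f, LPA = R_total / (1 - f))
}

#' Murray's-law flow fractions for a set of outlet caps
#'
#' Each outlet cap of area `A_i` is assigned an effective radius
#' `r_i = sqrt(A_i / pi)` and a flow share proportional to `r_i^exponent`.
#' The pulmonary-specific exponent 2.3 (Q proportional to r^2.3) is the
#' default; exponent 2 reduces to an area-proportional split.
#'
#' @param outlet_areas Cap areas, cm^2 (all > 0).
#' @param exponent Murray exponent (> 0), default 2.3.
#' @return Fractions summing to 1.
#' @examples
#' murray_fractions(pi * c(1, 2)^2)  # radii 1 and 2 cm
#' @export
murray_fractions <- function(outlet_areas, exponent = 2.3) {
  if (length(outlet_areas) == 0L) stop("`outlet_areas` must be non-empty")
  if (any(outlet_areas <= 0)) stop("all outlet areas must be positive")
  if (exponent <= 0) stop("`exponent` must be positive")
  r <- sqrt(outlet_areas / pi)
  w <- r^exponent
  w / sum(w)
}

#' Assemble an RCR outlet from its total resistance
#'
#' Splits one outlet's resistance into proximal and distal parts
#' (`Rp = proximal_fraction * R`, `Rd = (1 - proximal_fraction) * R`) and
#' sets the compliance from the exponential decay time constant
#' `tau = Rd * C`.
#'
#' @param outlet_resistance Total outlet resistance `R`, dyn s/cm^5.
#' @param proximal_fraction Fraction of `R` placed proximally, in [0, 1).
#' @param tau Windkessel time constant `Rd * C`, s (> 0); 1.0 s is a typical
#'   pulmonary value.
#' @param distal_pressure Distal reference pressure `Pd`, dyn/cm^2.
#' @return A [windkessel_rcr()].
#' @export
assemble_rcr <- function(outlet_resistance, proximal_fraction = 0.1,
                         tau = 1.0, distal_pressure = 0) {
  if (proximal_fraction < 0 || proximal_fraction >= 1) {
    stop("`proximal_fraction` must lie in [0, 1): Rd must stay positive")
  }
  if (tau <= 0) stop("`tau` must be positive")
  if (outlet_resistance <= 0) stop("`outlet_resistance` must be positive")
  Rp <- proximal_fraction * outlet_resistance
  Rd <- (1 - proximal_fraction) * outlet_resistance
  windkessel_rcr(Rp = Rp, C = tau / Rd, Rd = Rd, Pd = distal_pressure)
}

#' Distribute the total resistance over the outlets of a tree
#'
#' Builds the resistance budget: the total resistance is split between the
#' RPA and LPA sides by the measured flow distribution
#' ([side_resistances()]), and each side's resistance is distributed over its
#' outlet caps by Murray's law ([murray_fractions()]). Per-outlet resistance
#' is `R_side / f_outlet`, so all outlets in parallel reconstruct `R_total`.
#'
#' @param tree A [pa_tree()].
#' @param R_total Total PA resistance, dyn s/cm^5.
#' @param rpa_flow_fraction RPA share of total flow.
#' @param exponent Murray exponent, default 2.3.
#' @return Object of class `resistance_budget`: fields `R_total`,
#'   `side_fractions`, `outlet_ids`, `outlet_side`, `outlet_fractions`
#'   (within side), `outlet_resistances`.
#' @export
resistance_budget <- function(tree, R_total, rpa_flow_fraction,
                              exponent = 2.3) {
  rs <- side_resistances(R_total, rpa_flow_fraction)
  ids <- sides <- frac <- res <- NULL
  for (s in c("RPA", "LPA")) {
    oid <- outlet_ids(tree, s)
    f <- murray_fractions(outlet_areas(tree, s), exponent)
    ids <- c(ids, oid)
    sides <- c(sides, rep(s, length(oid)))
    frac <- c(frac, f)
    res <- c(res, rs[[s]] / f)
  }
  b <- structure(list(
    R_total = R_total,
    side_fractions = c(RPA = rpa_flow_fraction, LPA = 1 - rpa_flow_fraction),
    outlet_ids = ids, outlet_side = sides,
    outlet_fractions = frac, outlet_resistances = res,
    exponent = exponent
  ), class = "resistance_budget")
  validate_budget(b)
  b
}

validate_budget <- function(b) {
  stopifnot(abs(sum(b$side_fractions) - 1) < 1e-12)
  for (s in c("RPA", "LPA")) {
    fs <- b$outlet_fractions[b$outlet_side == s]
    if (abs(sum(fs) - 1) > 1e-12) stop("per-side outlet fractions must sum to 1")
  }
  recon <- 1 / sum(1 / b$outlet_resistances)
  if (abs(recon - b$R_total) > 1e-9 * b$R_total) {
    stop("parallel combination of outlet resistances does not reproduce R_total")
  }
  invisible(b)
}

#' @export
print.resistance_budget <- function(x, ...) {
  cat(sprintf(
    "Resistance budget: R_total = %.4g dyn s/cm^5, RPA fraction %.3f, %d outlets (Murray exponent %g)\n",
    x$R_total, x$side_fractions[["RPA"]], length(x$outlet_ids), x$exponent))
  invisible(x)
}

#' Build the per-outlet RCR set from a resistance budget
#'
#' Applies [assemble_rcr()] to every outlet resistance in the budget,
#' returning the named list of Windkessel models that [solve_network()]
#' expects.
#'
#' @param budget A [resistance_budget()].
#' @param proximal_fraction,tau,distal_pressure See [assemble_rcr()].
#' @return Named list of [windkessel_rcr()], keyed by outlet segment id.
#' @export
budget_to_rcr <- function(budget, proximal_fraction = 0.1, tau = 1.0,
                          distal_pressure = 0) {
  rcr <- lapply(budget$outlet_resistances, assemble_rcr,
                proximal_fraction = proximal_fraction, tau = tau,
                distal_pressure = distal_pressure)
  names(rcr) <- as.character(budget$outlet_ids)
  rcr
}

#' Calibrate outlet resistances until the simulated flow split matches
#'
#' The achieved RPA flow fraction of the simulated last cycle generally
#' deviates from its target because tree-segment resistances sit in series
#' with the outlet Windkessels. This loop multiplicatively rescales the two
#' side conductance blocks by `target / achieved` (and the complement), then
#' renormalizes so the total parallel resistance is preserved, re-solving the
#' network each iteration; it stops when the relative split error
#' `|achieved - target| / target` is at or below `tolerance` (the protocol
#' criterion is 10 percent, read as a relative per-side bound).
#'
#' @param tree A [pa_tree()].
#' @param budget A [resistance_budget()].
#' @param inflow A [flow_waveform()].
#' @param target_rpa_fraction Target RPA share of cycle-mean flow.
#' @param tolerance Relative error tolerance (default 0.10).
#' @param max_iter Maximum calibration iterations.
#' @param fluid A [fluid_properties()].
#' @param proximal_fraction,tau,distal_pressure RCR assembly settings, see
#'   [assemble_rcr()].
#' @param n_cycles,steps_per_cycle,rtol,atol Solver settings, see
#'   [solve_network()].
#' @return List with elements `budget` (calibrated [resistance_budget()]) and
#'   `report` (class `calibration_report`: `iterations`, `achieved` trace,
#'   `relative_error`, `converged`).
#' @export
calibrate_flow_split <- function(tree, budget, inflow, target_rpa_fraction,
                                 tolerance = 0.10, max_iter = 20L,
                                 fluid = fluid_properties(),
                                 proximal_fraction = 0.1, tau = 1.0,
                                 distal_pressure = 0,
                                 n_cycles = 6L, steps_per_cycle = 128L,
                                 rtol = 1e-8, atol = 1e-10) {
  if (target_rpa_fraction <= 0 || target_rpa_fraction >= 1) {
    stop("`target_rpa_fraction` must lie strictly inside (0, 1)")
  }
  achieved_trace <- numeric(0)
  b <- budget
  converged <- FALSE
  err <- NA_real_
  for (it in 0:max_iter) {
    rcr <- budget_to_rcr(b, proximal_fraction, tau, distal_pressure)
    sol <- solve_network(tree, rcr, inflow, fluid,
                         n_cycles = n_cycles,
                         steps_per_cycle = steps_per_cycle,
                         rtol = rtol, atol = atol)
    achieved <- achieved_rpa_fraction(tree, sol)
    achieved_trace <- c(achieved_trace, achieved)
    err <- abs(achieved - target_rpa_fraction) / target_rpa_fraction
    if (err <= tolerance) {
      converged <- TRUE
      break
    }
    if (it == max_iter) break
    b <- rescale_budget_sides(b, achieved, target_rpa_fraction)
  }
  report <- structure(list(
    iterations = length(achieved_trace) - 1L,
    achieved = achieved_trace,
    target = target_rpa_fraction,
    relative_error = err,
    converged = converged,
    tolerance = tolerance
  ), class = "calibration_report")
  list(budget = b, report = report)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "Flow-split calibration: %s after %d iteration(s); achieved %.4f vs target %.4f (rel. error %.2f%%, tol %.0f%%)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$achieved[length(x$achieved)], x$target,
    100 * x$relative_error, 100 * x$tolerance))
  invisible(x)
}

# cycle-mean RPA flow share of the last simulated cycle
achieved_rpa_fraction <- function(tree, sol) {
  q_rpa <- segment_cycle_volume(sol, principal_id(tree, "RPA"))
  q_lpa <- segment_cycle_volume(sol, principal_id(tree, "LPA"))
  q_rpa / (q_rpa + q_lpa)
}

# multiplicative conductance update, preserving total parallel resistance
rescale_budget_sides <- function(b, achieved, target) {
  g <- 1 / b$outlet_resistances
  is_r <- b$outlet_side == "RPA"
  g_r <- sum(g[is_r]); g_l <- sum(g[!is_r])
  g_tot <- g_r + g_l
  ratio_r <- target / max(achieved, 1e-9)
  ratio_l <- (1 - target) / max(1 - achieved, 1e-9)
  g[is_r] <- g[is_r] * ratio_r
  g[!is_r] <- g[!is_r] * ratio_l
  g <- g * g_tot / sum(g)               # renormalize total conductance
  b$outlet_resistances <- 1 / g
  b$side_fractions <- c(RPA = sum(g[is_r]) / g_tot,
                        LPA = sum(g[!is_r]) / g_tot)
  b
}
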