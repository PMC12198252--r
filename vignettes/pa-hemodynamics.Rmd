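---
title: "Reduced-order pulmonary-artery hemodynamics: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order pulmonary-artery hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahemo)
```

# What this package models

`pahemo` re-creates, at desk scale, the hemodynamic analysis chain used to
compare pulmonary-artery (PA) flow before and after percutaneous pulmonary
valve implantation (PPVI): boundary-condition construction and calibration,
a pulsatile flow solution over six cardiac cycles, the standard index set
(Reynolds number, Womersley number, cross-sectional vorticity, energy
dissipation, regurgitation fraction, forward/backward volumes and
velocities), and the small-sample statistics applied to the results.

The one deliberate, central substitution: clinical studies of this kind run
a patient-specific 3-D finite-element Navier–Stokes solve on MRI-derived
anatomy. Those geometries are not public, and the 3-D solve is not a
desk-scale object. `pahemo` replaces it with

1. a **lumped-parameter (0-D) network**: each vessel segment contributes its
   Poiseuille resistance $R_\mathrm{seg} = 8\mu L/(\pi r^4)$, junctions are
   pressure-continuous and loss-free, walls are rigid, and each outlet
   terminates in a three-element Windkessel (RCR) model; and
2. **analytic in-segment velocity profiles**: each segment's flow waveform is
   decomposed into Fourier harmonics, harmonic 0 mapping to the Poiseuille
   parabola and harmonics $k \ge 1$ to the oscillatory Womersley solution of
   the radial momentum equation.

Every published formula downstream (Re, Wo, Vo, ED, PR%) is then computed
from these fields exactly as it would be from 3-D fields. The package's
validation therefore rests on closed-form oracles — Hagen–Poiseuille energy
balances, Bessel-profile solutions, complex-impedance transfer functions —
rather than on reproducing patient-level 3-D values, which it explicitly
does not claim (see *Limitations*).

# The model, stage by stage

## Synthetic anatomy and inflow

`generate_pa_tree()` builds the two-lung topology the clinical models
reconstruct: one MPA segment, RPA and LPA principal branches, and about ten
outlet branches per side. Principal radii follow a Murray-type taper
$r_p = r_\mathrm{MPA}\,2^{-1/2.3}$ so the MPA radius bounds the principal
radii. Outlet radii are log-normal around a common base (dispersion
`radius_dispersion`, default 0.3) and rescaled so the summed outlet area per
side is `outlet_area_ratio` (default 1.5) times the principal-branch area —
the peripheral bed widens, keeping outlet velocities physiological. With one
outlet per side the principals themselves are the outlets (the minimal
three-segment tree).

`generate_inflow_waveform()` is the canonical synthetic inflow: a forward
half-sine lobe carrying the stroke volume in systole, and a backward
half-sine carrying `pr_target × stroke_volume` in diastole. The shape is
smooth, integrable in closed form, and makes the regurgitant fraction
exactly controllable — `flow_decomposition()` recovers `pr_target` to
quadrature error only. Clinical waveform morphology (ejection upstroke
asymmetry, dicrotic features) is *not* reproduced; the half-sine pair is an
assumption, not a reconstruction, and the systolic fraction (default 0.35 of
the cycle, a typical resting value) is likewise an assumption the source
protocol does not pin down.

## Boundary conditions

Total PA resistance comes from the cycle-mean pressure and flow,
$R = (\bar P - P_d)/\bar Q$, with clinical units (mmHg, L/min) converted at
the boundary (1 mmHg = 1333.22 dyn/cm²). The RPA/LPA split is
flow-proportional: a side carrying fraction $f$ of the flow receives
resistance $R/f$, so the two sides in parallel reconstruct $R$ exactly.
Within a side, outlet caps of area $A_i$ get effective radii
$r_i = \sqrt{A_i/\pi}$ and flow shares $\propto r_i^{2.3}$ — Murray's law
with the pulmonary-specific exponent 2.3. (Caps are measured by area but
Murray weights radii, hence the explicit conversion.)

Each outlet's resistance is split into a proximal part
`Rp = proximal_fraction × R` (default 0.1) and a distal part, with
compliance set by the decay time constant `tau = Rd·C` (default 1.0 s, a
typical pulmonary Windkessel value). Neither the Rp:Rd ratio nor the
compliance is specified by the clinical protocol; both are exposed in the
configuration. The distal reference pressure defaults to 0 and can emulate
left-atrial pressure.

`calibrate_flow_split()` then closes the loop: because segment resistances
sit in series with the Windkessels, the achieved cycle-mean RPA flow share
deviates from target. The loop multiplicatively rescales the two side
conductance blocks by achieved-vs-target ratios, renormalizes so the total
parallel resistance is preserved (verified to 1e-6 relative across
iterations), and re-solves. The protocol's acceptance bound — flow splits
matched "within 10%" — is read as a *relative, per-side* criterion
$|f_\mathrm{achieved}-f_\mathrm{target}|/f_\mathrm{target} \le 0.10$; the
update rule itself is this package's choice, since only the achieved
tolerance is documented clinically. In practice the Murray budget already
lands within a fraction of a percent of target on generated trees and the
loop converges immediately; its value is robustness on strongly asymmetric
trees and an auditable iteration trace.

## The pulsatile network solve

The Windkessel capacitor pressures are the only state variables:

$$C_i \frac{dP_{c,i}}{dt} = Q_i - \frac{P_{c,i} - P_{d,i}}{R_{d,i}},$$

with the outlet flows recovered algebraically at every instant from the
resistive network and the prescribed total inflow. The shared-path
resistance matrix is small (one row per outlet), so its inverse is
precomputed and each right-hand-side evaluation is a dense matrix-vector
product. Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and
absolute tolerance 1e-10 on a fixed output grid (`steps_per_cycle`, default
256 for standalone solves, 128 inside the cohort pipeline); the inflow is
interpolated with a periodic spline. The initial condition is the steady
state under the cycle-mean inflow, and six cycles are simulated with
last-cycle extraction, matching the clinical protocol; the cycle-to-cycle
periodicity defect of outlet volumes is reported (typically below 1e-6 with
the steady-state initialization) so non-settled configurations are visible.

Mass conservation closes over a period: last-cycle inlet volume equals the
summed outlet volumes to well below 0.5% (capacitor storage integrates to
zero over a period).

## Velocity profiles and the flow-matching closure

Each harmonic's radial profile solves
$i\omega\rho\,\hat u = G + \mu(\hat u'' + \hat u'/s)$ with no-slip at the
wall and symmetry at the axis — the classical Womersley problem whose
closed form is a complex Bessel ratio. The package solves it by a
second-order finite-difference scheme (complex tridiagonal, Thomas
algorithm, default 128 radial intervals) rather than by evaluating Bessel
functions: the FD route is numerically robust at every Womersley number
(the Bessel power series suffers catastrophic cancellation beyond
$\alpha \approx 15$, and high harmonics of a large PA reach $\alpha > 50$),
and it is cross-checked in the tests against an independent complex-series
Bessel oracle at moderate $\alpha$, against the quasi-static parabola as
$\alpha \to 0$, and for core flattening at $\alpha = 20$.

Each harmonic profile is scaled so its *discrete* sectional flow
$2\pi\int u\,s\,ds$ (trapezoid rule) equals that harmonic's Fourier
coefficient. Waveforms with derivative kinks (the half-sine pair has them at
the lobe junctions) have slowly decaying Fourier tails, so a truncated
harmonic sum alone misses the prescribed flow by a few percent at 8
harmonics. The remainder is therefore carried as a **quasi-static parabolic
correction**: the unresolved part of $Q(t)$ — a few percent in L2 — is
distributed with the Poiseuille shape, making the reconstructed sectional
flow match $Q(t)$ exactly at every sample. The high-frequency remainder is
physically plug-like rather than parabolic, but its amplitude is small and
the alternative (raising the harmonic count until truncation is negligible)
buys accuracy the 0-D substitution does not support anyway. Set
`residual = "none"` for the pure truncated-harmonic field.

For non-circular inlet sections, `map_inlet_velocity()` distributes an
instantaneous flow rate with a parabolic shape in the normalized
centroid-to-boundary distance and rescales so the discrete surface integral
reproduces the flow exactly — the flow-preserving parabolic mapping used at
model inlets.

## Indices

- **Measurement sites.** Branch indices are evaluated one MPA radius distal
  to the bifurcation along the centerline, walking across segment
  boundaries if needed (descending into the largest-radius child — the
  continuation of the named artery). The protocol defines branch sites
  only; the MPA site is placed at the MPA mid-length cross-section
  (documented, configurable by constructing a site directly).
- **Re** uses the cycle-mean sectional speed $\overline{|Q|}/A$ and diameter
  $2r$; a forward-phase mean is available through `flow_decomposition()`.
- **Vo**: the pointwise curl of the axisymmetric field reduces to
  $-\partial u/\partial s$ (plus an axial component if a swirl field is
  attached); its magnitude is area-averaged over the site disc and
  time-averaged over the last cycle. How a 3-D curl field is collapsed to
  one number per artery is not documented clinically; this area-and-time
  average is this package's choice, and only order-of-magnitude and trend
  agreement with published values is claimed. The closed-form oracle:
  steady Poiseuille gives $8\bar V/(3R)$, matched within 0.5% at any radial
  resolution of 64 or more.
- **ED** cycle-averages the instantaneous total-pressure flux
  $(P + \tfrac12\rho V^2)\,A V$ at the inlet minus all outlet caps, sampled
  upstream of the Windkessel proximal resistance (the 0-D analogue of the
  anatomical outlet face), and converts erg/s to mW. The published formula
  lists a cycle-averaged pressure without fixing the velocity's time
  treatment; the default here averages the simultaneous product (which
  reduces to the printed formula for steady flow), and the literal
  "averaged pressure × instantaneous velocity flux" reading is available
  via `time_treatment = "averaged_pressure"`. For a steady tube, ED equals
  the Hagen–Poiseuille balance $\Delta P\,Q$ exactly.
- **PR%** integrates the clipped waveform with the trapezoid rule and
  periodic wrap: $100\times$ backward over forward volume.

## Statistics

Small clinical series of this design name the "Wilcoxon rank-sum test" but
compare paired pre/post values; the package implements both tests and uses
the signed-rank test for paired comparisons and the rank-sum test for
between-artery comparisons. Conventions, all documented in the function
help: zero differences dropped, mid-ranks for ties, two-sided p as twice
the smaller tail (capped at 1).

Exact enumeration is the default at the study's sample size: the signed-rank
null distribution is built by generating-function convolution on the
doubled-rank grid (equivalent to enumerating all $2^n$ sign patterns, and
tested to be bitwise equal to brute-force enumeration); the rank-sum
distribution enumerates all group assignments up to $n_a + n_b = 20$. The
tie-corrected normal approximation (no continuity correction by default) is
provided because it is what clinical software typically reports: nine
all-positive differences give exact $2/512 = 0.0039$ but a normal
approximation of 0.0077 ≈ 0.008 — the method-variant discrepancy to keep in
mind when comparing against printed p-values. No multiple-testing
correction is applied, matching the clinical analysis.

`screened_regression()` implements the univariable-screening protocol:
per-variable simple regressions, variables with $p < 0.05$ entering a joint
OLS fit, factors screened by their overall F-test, categorical recodings
accepted alongside their continuous originals, and rank-deficient screened
designs rejected by name. Screening is monotone in the threshold and
recovers noiseless coefficients to 1e-10.

# The synthetic cohort: what it does and does not emulate

`generate_cohort()` reproduces the *statistical structure* the analysis
assumes: per-patient trees and waveform pairs whose regurgitant fractions
are drawn around the reported population means (pre 0.442, post 0.145, each
patient's pre strictly exceeding its post), plausible clinical covariates
(ages, mean PA pressure around 13 mmHg, stroke volume around 75 mL, cycle
length around 0.9 s, RPA flow fractions around 0.614 pre / 0.594 post), and
an optional regression bench with known coefficients. It is fully
deterministic given its seed.

It does **not** emulate: real anatomic variation (stenoses, aneurysmal
outflow tracts, non-planar bifurcations), waveform morphology beyond the
half-sine pair, correlations between covariates and hemodynamics beyond the
configured linear effects, or measurement noise. Consequently, passing the
cohort-level tests demonstrates that the pipeline's plumbing, calibration
and statistics behave correctly under the stated distributions — not that
the package predicts any individual patient's hemodynamics.

# Numerical choices and degenerate inputs

- Time grids are uniform and half-open $[0, T)$; all cycle integrals use
  the trapezoid rule with periodic wrap.
- Units are CGS internally; mmHg and L/min are converted at the I/O
  boundary only.
- Waveforms need at least 64 samples per cycle; quadrature errors in the
  PR% round trip are below 0.005 absolute at 128 samples.
- Trees are validated at construction (positive radii and lengths, single
  root, two principal children labelled RPA/LPA, MPA radius bounding the
  principal radii); degenerate geometry never reaches the solver.
- Radial gradients use second-order differences, one-sided second order at
  the axis and wall (exact for the quadratic Poiseuille profile).
- The measurement-site walk breaks ties toward the largest-radius child;
  a branch shorter than one MPA radius raises an error naming the branch.
- Calibration with tolerance 0 cannot converge in finite iterations and is
  reported as non-converged rather than raising.
- The display rounding in `summarize_indices()` is half-away-from-zero to
  one decimal, matching the printed-table convention; the unrounded values
  are always returned alongside.

# Problem sizes

The shipped tests and the acceptance script run: trees of 10 outlets per
side (23 segments, 20 Windkessels); six cycles at 128–256 output steps per
cycle per solve (about 0.1 s each); 20-tree calibration studies (about 2 s);
cohort pipelines of 3–9 patients; 10⁴-replicate null calibration of the
exact test; and 100-seed screening-rate studies at n = 200. These sizes were
chosen so the full chain is interactive on a single CPU while keeping every
tolerance meaningful.

# Limitations

- The 0-D network carries no convective acceleration, secondary flow,
  junction losses or flow separation. Vorticity here is shear-layer
  vorticity of an axisymmetric profile; 3-D vortical structures — the main
  driver of the large published pre-to-post drops in Vo and ED — are absent.
  The package therefore reproduces published *formulas, protocols and
  summary statistics*, and the directional behaviour of its own synthetic
  cohort, but not patient-level 3-D index values; pre/post contrasts in ED
  are much smaller in the 0-D model than in the 3-D study it emulates.
- Rigid walls throughout (as in the emulated protocol); compliance lives
  only in the RCR outlets.
- The Windkessel Rp:Rd split and compliance are assumptions (0.1 and
  τ = 1.0 s), not fitted values.
- The exact-vs-approximate Wilcoxon discrepancy means printed clinical
  p-values are reproduced by the `normal_approx` method, not the exact one;
  both are reported deliberately.
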