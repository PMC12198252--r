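# pahemo

Reduced-order pulmonary-artery (PA) hemodynamics around percutaneous
pulmonary valve implantation (PPVI).

## The problem

Repaired Tetralogy of Fallot commonly leaves pulmonary regurgitation (PR):
during diastole, blood flows backwards from the pulmonary arteries into the
right ventricle. Catheter-based valve implantation (PPVI) restores valve
competence, and the hemodynamic benefit shows up not only in right-ventricular
volumes but in the flow state of the pulmonary arteries themselves — less
backward flow, less rotational (vortical) flow, less energy wasted driving
blood through the PA bed. Patient-specific CFD studies quantify this with a
small set of indices evaluated at standard cross-sections of the main (MPA),
right (RPA) and left (LPA) pulmonary arteries:

- Reynolds number `Re = ρVL/μ` (V the sectional mean speed, L the diameter),
- Womersley number `Wo = r·√(2π/(νT))` (r the radius, ν = μ/ρ, T the cardiac
  cycle; healthy PAs sit around 14–21),
- vorticity `Vo = |∇×V|`, area- and time-averaged over the measurement
  cross-section,
- energy dissipation
  `ED = ⟨(P + ½ρV²)·A·V⟩_MPA − Σ_outlets ⟨(P + ½ρV²)·A·V⟩` over one cycle,
- regurgitation fraction `PR% = 100 × backward volume / forward volume`.

`pahemo` rebuilds that analysis chain at desk scale, for method development
and statistical work where the original MRI geometries are unavailable. The
deliberate, central substitution: the 3-D finite-element Navier–Stokes solve
is replaced by a lumped-parameter (0-D) network — Poiseuille segment
resistances `8μL/(πr⁴)`, rigid walls, loss-free junctions, three-element
Windkessel (RCR) outlets — plus analytic Womersley/Poiseuille velocity
profiles reconstructed inside each segment. Everything around that
substitution follows the clinical protocol: total PA resistance from mean
pressure and flow, an RPA/LPA split by measured flow distribution, per-outlet
distribution by Murray's law with the pulmonary exponent 2.3 (Q ∝ r^2.3),
flow-split calibration to within 10%, six simulated cardiac cycles with
last-cycle extraction, blood density 1.06 g/cm³ and viscosity 0.04 g/(cm·s).

The package also ships the published nine-patient per-patient index table
(`load_reference_indices()`) for summary reproduction and small-sample
statistics, a synthetic cohort generator, and the study's statistical layer:
exact and normal-approximation Wilcoxon signed-rank/rank-sum tests and
univariable-screened multivariable linear regression.

## Worked example

```r
library(pahemo)

# synthetic PA tree and a severely regurgitant inflow (PR fraction 0.442)
tree   <- generate_pa_tree(10, mpa_radius = 1.3, radius_dispersion = 0.3, seed = 1)
inflow <- generate_inflow_waveform(75, period = 0.9, pr_target = 0.442)

# boundary conditions: 13 mmHg mean PA pressure, RPA takes 61.4% of flow
R_total <- total_pa_resistance(13, cycle_mean(inflow$time, inflow$flow, 0.9),
                               pressure_unit = "mmHg")   # 372.7 dyn s/cm^5
budget  <- resistance_budget(tree, R_total, rpa_flow_fraction = 0.614)
cal     <- calibrate_flow_split(tree, budget, inflow, 0.614)
cal$report
#> Flow-split calibration: converged after 0 iteration(s); achieved 0.6137
#> vs target 0.6140 (rel. error 0.05%, tol 10%)

# six-cycle pulsatile solve and indices from the last cycle
sol <- solve_network(tree, budget_to_rcr(cal$budget), inflow)
hemodynamic_indices(tree, sol)[, c("mpa_re", "mpa_wo", "mpa_vo", "mpa_pr", "ed_mw")]
#>     mpa_re   mpa_wo  mpa_vo mpa_pr   ed_mw
#> 1  1559.4    17.68    59.9   44.2   11.16
```

`mpa_pr = 44.2` recovers the prescribed regurgitant fraction; `mpa_wo = 17.7`
sits in the healthy 14–21 band; Re, Vo and ED are the 0-D/analytic
counterparts of the published indices (right order of magnitude, but the 0-D
model does not claim their patient-level 3-D values).

Reproducing the published summary rows and a paired test:

```r
ref <- load_reference_indices()
summarize_indices(ref[ref$state == "pre", -(1:2)])$display
#>      mpa_re mpa_wo mpa_vo rpa_re rpa_wo rpa_vo lpa_re lpa_wo lpa_vo ed_mw
#> Mean  825.2   18.5  116.7  814.0   11.4  388.9  469.3   12.4  331.8  93.8
#> SD    248.6    2.2   21.6  266.8    1.4  144.1  129.0    2.3  120.3  67.7

pre <- ref[ref$state == "pre", ]; post <- ref[ref$state == "post", ]
wilcoxon_paired(pre$mpa_vo, post$mpa_vo)$p_value                             # 0.0039 (exact, 2/512)
wilcoxon_paired(pre$mpa_vo, post$mpa_vo, method = "normal_approx")$p_value   # 0.0077
```

The full cohort pipeline (`run_pipeline(pipeline_config(...))`) chains
cohort generation → calibration → solve → indices → summaries → paired tests
deterministically from one seed.

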