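# branchflow

Desk-scale computational hemodynamics of renal branch stents after
fenestrated/branched endovascular aneurysm repair (F/B EVAR).

After F/B EVAR, the covered stent feeding a renal artery protrudes into
the aortic stent-graft lumen. Whether the branch receives forward flow
(*outflow*) or is sucked backward (*reflux*) — and hence its occlusion
risk — depends on the stent's tilt angle θ (measured from the proximal
aortic axis; θ > 90° points with the flow), its entry depth L into the
aortic lumen, and its width D2. `branchflow` implements the full
computational study of this question for vascular-biomechanics
researchers:

* **Geometry** — parametric planar model of the aorta + protruding branch
  stent, rasterized onto a Cartesian mask, including the beveled-tip
  variant (`make_geometry()`, `bevel_cut()`, `rasterize()`).
* **Flow** — steady incompressible Newtonian solve with a staggered-grid
  finite-volume SIMPLE scheme (`solve_steady()`), run at a reduced
  laminar Reynolds number (`scale_reynolds()`, default Re = 200), with a
  direct sparse Stokes solve (`stokes_solve()`) as an independent
  low-Re oracle.
* **Observables** — signed branch mass flux and reflux/outflow
  classification, wall-shear-stress profiles, recirculation area
  (`branch_flow_result()`, `wall_shear_stress()`,
  `recirculation_metrics()`).
* **Experiments** — the four sweeps: no-stent angle sweep, angle × depth,
  branch diameter, and the beveled-tip comparison, plus bisection for the
  reflux→outflow transition angle (`run_*_sweep()`, `compare_bevel()`,
  `find_transition_angle()`).
* **Clinical statistics** — median flow split, exact small-sample
  Mann–Whitney U (p from the full null distribution,
  `exact_mann_whitney()`), KS/Lilliefors normality gating, pooled-t,
  Cohen's d with bootstrap CI, and a grouped report (`compare_groups()`)
  over per-artery case records (`load_patient_cases()`).
* **Synthetic cohorts** — a generator emulating the case-series structure
  (`generate_cohort()`) and a reduced-order flow surrogate calibrated on
  the sweeps (`fit_surrogate()`, `surrogate_flow()`).

## Worked example

Reflux at a right-angle, deep-entry branch stent, and the beveled-tip
rescue:

```r
library(branchflow)

pair <- compare_bevel(theta = 90, depth = 15, D2 = 8)
pair[, c("bevel", "mass_flux", "normalized_flux", "classification",
         "wss_mean", "vortex_area")]
#>   bevel mass_flux normalized_flux classification wss_mean vortex_area
#> 1 FALSE -1.399469     -0.05527150         reflux 20.29774         404
#> 2  TRUE  4.043484      0.15969131        outflow 36.60055         202
```

With the square-cut tip the branch is in reflux (negative flux, about
−5.5% of the inlet mass flow per unit depth); cutting the protruding tip
parallel to the aortic wall so the lumen opens toward the oncoming flow
flips it to outflow at about +16% of the inlet flux, with roughly half
the ostium vortex area. The statistics stage on the packaged case table:

```r
rec <- load_patient_cases()
grp <- reconstruct_table4_membership(rec)
median(grp$high$tilt_angle)   # 126.9 degrees
median(grp$low$tilt_angle)    # 86.5 degrees
exact_mann_whitney(grp$low$tilt_angle, grp$high$tilt_angle)
#> U = 1, exact two-sided p = 0.004329 (prints as 0.004)
```

The tilt angle separates the high- and low-flow groups (p < 0.05); entry
depth and branch diameter do not. A command-line wrapper for the sweeps,
statistics, fixture export and cohort generation lives at
`inst/cli/branchflow.R`.

## Method notes

The flow model is a deliberate planar (2D) reduction at reduced Reynolds
number: absolute magnitudes are not comparable with 3D patient-scale
CFD, and all conclusions are drawn from signs, classifications and
monotone trends. See the methods vignette
(`vignettes/branch-stent-hemodynamics.Rmd`) for the model, numerics,
validation oracles, and exactly which full-scale features do and do not
transfer to the reduction.
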