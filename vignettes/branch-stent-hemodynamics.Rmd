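---
title: "Branch-stent hemodynamics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-stent hemodynamics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After fenestrated or branched endovascular aneurysm repair (F/B EVAR), the
covered stent that feeds a renal artery usually protrudes some distance
into the aortic stent-graft lumen. Clinically, some of these renal
branches occlude during follow-up. The working hypothesis this package
investigates is hemodynamic: the protruding tube obstructs the aortic
stream, and depending on its **tilt angle** $\theta$ (measured from the
proximal aortic axis to the outward branch axis, so $\theta<90^\circ$
points against the flow), its **entry depth** $L$ and its **width**
$D_2$, the branch either receives forward flow (*outflow*) or is sucked
backward (*reflux*). Chronic low flow and low wall shear stress (WSS) are
established precursors of thrombosis and occlusion.

`branchflow` implements a desk-scale version of this study end to end:

1. parametric geometry of an aortic conduit with a protruding branch stent
   (`make_geometry()`, `rasterize()`), including a beveled-tip variant
   (`bevel_cut()`);
2. a steady incompressible Newtonian flow solver (`solve_steady()`):
   finite volumes on a staggered grid with SIMPLE pressure–velocity
   coupling;
3. observables (`boundary_flux()`, `classify_branch_flow()`,
   `wall_shear_stress()`, `recirculation_metrics()`);
4. the four sweep experiments (`run_no_stent_angle_sweep()`,
   `run_angle_depth_sweep()`, `run_diameter_sweep()`, `compare_bevel()`,
   `find_transition_angle()`);
5. the clinical statistics stage (`median_split()`,
   `exact_mann_whitney()`, `students_t()`, `ks_normality()`,
   `cohens_d()`, `compare_groups()`) on per-artery case records;
6. a synthetic cohort generator (`generate_cohort()`) and a
   reduced-order flow surrogate (`fit_surrogate()`, `surrogate_flow()`)
   so the statistics stage is testable end to end.

# The planar reduction

The reference setting is a 3D tube junction solved in commercial CFD
software at the physiological Reynolds number
$\mathrm{Re} = \rho V D_1/\mu \approx 7200$ ($\rho = 1055$ kg/m³,
$\mu = 0.0035$ kg/(m·s), $V_{\mathrm{inlet}} = 0.8$ m/s,
$D_1 = 30$ mm), which is transitional — and no turbulence closure is
specified in that setting. This package deliberately solves a different,
fully specified problem: the **symmetry plane** of the junction (channel
widths stand in for diameters) at a **reduced, laminar Reynolds number**
(default `target_Re = 200`, set by rescaling the viscosity with
`scale_reynolds()`; the nominal Re is recorded in the run log). The
in-plane mechanisms the study turns on — tip obstruction, the vortex below
the tip, direction-dependent reflux, the ram effect of a with-flow tilted
opening — are all present in this reduction. Absolute flow magnitudes are
*not* comparable with the 3D values and are never used as targets;
conclusions are drawn from signs, classifications and monotone trends.

Geometry defaults follow the study scene: $D_1 = 30$ mm, $D_2 = 8$ mm,
$L_1 = 200$ mm, $L_2 = 100$ mm (the printed values; the "ten diameters"
rule that motivates them is inconsistent with these numbers and is
treated as motivation only), stent wall thickness 0.5 mm (typical covered
stent graft), branch anchored at the middle of the far aortic wall.
`entry_depth` is measured along the branch axis from the inner surface of
the near wall to the tip plane. The beveled variant removes the
protruding wall material on the upstream side of the branch axis,
truncated at the aortic wall plane (a cut parallel to the aortic axis),
so the tip lumen opens toward the oncoming flow while the downstream wall
keeps its full depth.

# Discretization and solver

* Uniform Cartesian grid; cells classified by point-in-region predicates
  at cell centres (no cut cells). Slanted stent walls are rendered at
  least one cell thick (`max(wall_thickness, 1.05 h)`) which keeps them
  watertight under face-connected flow.
* Staggered storage: `u` on vertical faces, `v` on horizontal faces,
  pressure at cell centres. Convective fluxes use Patankar's hybrid
  scheme by default (`convection_scheme = "upwind"` available).
* Walls (domain edges and immersed solid cells) are no-slip: normal
  velocities on solid-adjacent faces are fixed at zero and tangential
  diffusion to a flat wall uses the half-cell distance; staircase corners
  fall back to first order.
* Boundary conditions: plug inlet velocity; both outlets share one fixed
  gauge pressure (the physiological 13,300 Pa offset is added back when
  reporting, since only differences matter), so the branch/aorta flow
  split is an emergent result of the solve — this split is the quantity
  of interest.
* SIMPLE loop: momentum under-relaxation 0.7, pressure 0.3, normalized
  residual tolerance $10^{-5}$ (mass and momentum), at most 20,000 outer
  iterations, deterministic iteration order. A run that stops early on a
  residual blow-up ($>10^3\times$ the initial mass residual) raises an
  error naming the iteration; a run that reaches the cap returns its
  field with a warning flag.
* After the outer loop a final exact pressure projection (SOR to a
  $10^{-9}$ relative mass target) enforces discrete continuity, so
  converged runs conserve mass globally to well below $10^{-6}$ relative
  — the level the test suite asserts.
* Validation oracles: developed plane Poiseuille flow (profile,
  max/mean = 1.5, wall shear $6\mu U/w$) on a 30-cell channel at
  Re = 25 — chosen so the $\approx 0.044\,\mathrm{Re}_{D_h} D_h$ entry
  length fits inside the 200 mm conduit; pressure-gauge invariance;
  bit-identical determinism; and a direct sparse-LU **Stokes** solve
  (`stokes_solve()`, same discretization without convection, assembled
  once) that the SIMPLE solution must match within 1% in branch flux at
  Re = 1.

# Observables

Branch mass flow is the signed flux through the branch outlet
(per unit depth in 2D, kg/(m·s); positive = outflow). Classification
uses a dead band of $10^{-3}$ of the inlet flux — sign alone is not
meaningful in a discrete solution. WSS is the first-order one-sided
estimate $\mu |u_t| / (h/2)$ at each wall face; the per-artery summary is
the **mean over the branch wall** (the reference reports per-artery WSS
without defining the summary; the mean is this package's choice).
Recirculation is measured as the area of fluid cells whose axial velocity
opposes the local bulk direction inside a window of $\pm 2 D_2$ around
the ostium plus the first $2 D_2$ of the branch lumen.

# Grid profiles and problem sizes

Sweeps default to the fast profile, $h = D_2/8$ (the coarsest the mask
validator accepts — 8 cells across the branch), about 26,000 cells for
the default scene; the finer profile uses $D_2/12$. The Poiseuille and
Stokes validations run on 6,000–9,600-cell grids. Classification
stability under refinement is spot-checked on a representative reflux and
outflow pair (a $D_2 = 12$ mm scene at $h$ and $h/2$) rather than on
every sweep configuration, which would multiply the suite cost roughly
tenfold without changing the conclusion.

# What transfers from the reference setting — and what does not

Running the sweeps at the reduced Reynolds number reproduces the
qualitative program: no-stent branches are always in outflow; a
protruding stent tilted against or across the flow
($\theta \le 90^\circ$) puts the branch in reflux, with deeper entry
giving stronger reflux; tilting with the flow restores outflow; wider
branch stents at $\theta = 90^\circ$, 15 mm entry reflux harder and
carry a larger ostium vortex; beveling the tip flips the canonical
reflux case to outflow with a large flux gain; and reflux cases have
lower mean branch-wall WSS than matched outflow cases.

A few details do **not** transfer exactly, and the package reports them
as they come out rather than forcing them:

* The reflux-to-outflow **transition angle** sits near
  $105^\circ$–$115^\circ$ for 10–15 mm entry depths in the planar
  reduced-Re model, slightly above the $\approx 100^\circ$ of the 3D
  full-Re setting. At $\theta = 105^\circ$ the deep-entry cells are
  therefore still in reflux (or stagnant) here. `find_transition_angle()`
  locates the band by bisection; the band location is reported but not
  treated as a blocking check.
* The **no-stent vortex-vs-angle** ordering (vortex shrinking as the
  angle grows) is a full-Re inertial feature; at Re = 200 in 2D the
  no-stent ostium recirculation is a few cells in every direction. The
  stented cases do show the contrast (the $45^\circ$ vortex is about
  twice the $135^\circ$ one at 10 mm entry).
* The **no-stent flux** is monotone in angle for $\theta > 90^\circ$,
  but the $90^\circ$ case itself sits a percent or two above its
  neighbours: the axis-aligned branch channel has no staircase wall
  friction, an $O(h)$ rasterization effect that shrinks under
  refinement.
* The reflux-side **depth monotonicity** ($|q|$ growing with $L$ at
  $\theta \le 90^\circ$) holds cleanly for $\theta = 75, 90^\circ$ and
  for every 5→10 mm step; at the fast grid the 10→15 mm step at
  $\theta = 45, 60^\circ$ dips by 1–4%, and the finer ($D_2/12$) grid
  restores it. The same trade-off appears with the fully upwind scheme
  (it fixes these dips but degrades the no-stent trend through extra
  numerical wall friction), so the hybrid scheme is kept throughout.

A small number of deep-protrusion configurations (e.g.
$\theta = 60^\circ$, $L = 15$ mm; the narrowest width of the diameter
sweep) approach unsteadiness at Re = 200: their residuals plateau above
the steady tolerance at any under-relaxation tried, and the fields are
returned with an explicit non-convergence flag. Sweep runs therefore cap
the outer iterations at 6000 (the solver default remains 20,000), which
bounds the cost of these runs without altering any converged result.

# The case table and the flow grouping

The packaged table (`load_patient_cases()`) holds the twelve renal-artery
records of the six-patient series: tilt angle, entry depth, branch and
aortic stent diameters, and follow-up patency (patient D bilateral
occlusion; E and F left occlusion). Per-artery flows are **not** printed
in the source tables, so the package fills them computationally:
`fit_surrogate()` interpolates the solver's angle-by-depth flux table
bilinearly (exact at the calibration nodes, linear extrapolation at the
edges) and `reconstruct_case_flows()` evaluates it at each artery's
angle and depth. The branch width is deliberately **not** part of the
surrogate: the sweep calibrates only angle and depth at one width, a
width rescale would extrapolate into the uncalibrated outflow regime,
and the case series itself shows no diameter effect between flow groups
(p = 0.873, d = 0.05). The median split of the surrogate flows then
feeds `compare_groups()`.

Because the published Table-4-style summary prints only group
statistics, the exact group membership is not recoverable from the
tables alone — and its printed quartiles and medians are not mutually
consistent with any single membership. `reconstruct_table4_membership()`
therefore solves a small constraint problem: occluded (reflux) arteries
are in the low-flow group, and the two patent arteries completing it are
chosen so the tilt-angle group medians and the exact Mann–Whitney
p-value reproduce the published summary; the search over all
$\binom{8}{2}$ completions shows this membership is unique. The
surrogate-based split agrees with it on the four occluded arteries and
on the high end of the ranking, but ranks the deep-entry $105.6^\circ$
patent artery below the transition (a direct consequence of the
transition-angle shift above), so the pipeline's own exact-MW statistic
comes out at $U = 2$ ($p = 8/924 \approx 0.009$) rather than the
published $U = 1$ ($p = 4/924 \approx 0.004$); both numbers are
reported.

# Statistics

* `exact_mann_whitney()` builds the full null distribution of
  $U = \#\{x_i > y_j\}$ by the standard counting recursion and returns
  the exact two-sided $p = \min(1, 2P(U \le \min(U, n_1 n_2 - U)))$ for
  $n_1+n_2 \le 25$; ties switch (on request) to the tie-corrected
  normal approximation with continuity correction. The test suite checks
  it against full enumeration of all $\binom{n_1+n_2}{n_1}$ label
  arrangements and against `stats::wilcox.test`.
* `ks_normality()` is the Lilliefors variant (parameters estimated from
  the sample), with the null distribution of $D$ simulated once per
  sample size under a fixed seed and cached; the statistic is affine
  invariant.
* `compare_groups()` gates each variable on normality of both groups at
  $\alpha = 0.05$: Student's pooled t if both pass, exact Mann–Whitney
  otherwise. At $n = 6$ per group the Lilliefors test almost never
  rejects, so the gate picks the t test for the case table, while the
  published analysis reports Mann–Whitney p-values; the
  `force_test = "mann_whitney_exact"` setting reproduces that choice.
  The significance pattern (angle significant, depth and diameter not)
  is identical under either test.
* Quartiles use the type-6 convention, which reproduces the published
  low-group lower quartile (79.8); other printed quartiles are not
  consistent with any single convention, so quartiles are reported but
  not asserted.
* Cohen's d uses the pooled-SD definition with an $n-1$ denominator and
  a fixed-seed percentile bootstrap CI. The published tilt-angle effect
  size of 1.32 is not reproducible from any standard formula on any
  reconstructible membership (pooled-SD d is about 2.9); d is reported,
  not asserted.

# The synthetic cohort

`cohort_spec()` encodes the study-shaped cohort: twelve arteries, two
tilt-angle groups centred at 90° and 125° (common SD 12°, anchored to
the case series), entry depth 7 ± 2 mm, branch width 5 ± 0.7 mm, flow =
a strictly angle-monotone response (sign change near 97.5°, magnitude
growing with depth and width, kg/s scale with median outflow near
0.005) plus Gaussian noise (SD 0.001 kg/s), occlusion iff flow < 0.
What it emulates: group structure, effect size, monotone
geometry-to-flow coupling, the patency rule. What it does not: real
anatomical correlation between angle, depth and width; measurement
error in CT-derived angles; 3D secondary flow. Passing the pipeline
tests on this cohort therefore demonstrates the statistics stage's
operating characteristics (type-I error near $\alpha$, power at the
observed effect size), not clinical validity.

# Known limitations

Steady flow only (no pulsatility, no oscillatory shear index); rigid
walls; 2D planar geometry; first-order immersed walls (staircase
friction penalizes strongly tilted channels at the fast grid); reduced
Reynolds number with laminar closure; the branch conduit is straight and
truncated by a horizontal outlet plane. All of these are deliberate
desk-scale reductions; they bound what the trend results can say about
patient-specific 3D flows.
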