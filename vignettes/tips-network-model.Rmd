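---
title: "A reduced-order network model of portal hemodynamics after TIPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order network model of portal hemodynamics after TIPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalflow)
```

## The clinical question

A transjugular intrahepatic portosystemic shunt (TIPS) decompresses a
hypertensive portal venous system by routing part of the portal flow through
an 8 mm stent directly into the inferior vena cava (IVC). Two modelling
questions matter to the planning of the procedure:

1. **Shunt position.** The stent can enter the left, main, or right portal
   vein (LPV, MPV, RPV). How does the choice affect the postoperative portal
   pressure gradient (PPG), the shunt velocity, and the wall-shear
   environment?
2. **Geometric simplification.** Simulation models of the portal system
   truncate the splenic vein (SV) and superior mesenteric vein (SMV)
   tributaries to save computation: relatively intact (Type A), short stubs
   (Type B), or absent with a combined inflow at the MPV inlet (Type C).
   Which results survive the truncation?

`portalflow` answers both with a reduced-order (0D) surrogate: vessels
become lossy edges between pressure nodes and the study design — two
reference patients x three shunt positions x three simplification types,
18 cases — is enumerated, solved and tabulated in seconds.

## Boundary conditions from routine measurements

All boundary data derive from quantities a clinical workup provides.

* **Preoperative MPV flow** is the velocity–area product
  $Q^{pre}_{MPV} = V^{pre}_{MPV}\,\pi D_{MPV}^2/4$
  (`preop_mpv_flow()`).
* **Postoperative MPV flow** is taken as twice the preoperative flow
  (`postop_mpv_flow()`): the low-resistance shunt recruits splanchnic flow,
  and the doubling rule matches reported clinical measurements.
* **Inflow split.** The SV and SMV inflows partition the postoperative flow
  by Murray's law, in proportion to the cubes of the nominal diameters
  (`murray_split()`). The two flows sum to the total to within one unit in
  the last place (a compensated complement).
* **Outlet resistances.** The intrahepatic LPV and RPV outlets terminate in
  lumped resistances closed so that the *preoperative* flow, split by
  Murray's law, sustains the preoperative portal pressure $P_{pv}$ against
  the zero-pressure IVC:
  $R_i = P_{pv} / \bigl(Q^{pre}_{MPV}\, D_i^3/(D_1^3+D_2^3)\bigr)$
  (`outlet_resistances()`). When no invasive measurement exists, $P_{pv}$
  defaults to 25 mmHg, the population average for portal hypertensive
  patients. The mmHg–Pa conversion is fixed once at 133.322 Pa/mmHg; with
  it, one published resistance cell (first patient, LPV) reproduces to 0.5%
  rather than exactly, which is the expected footprint of an unstated
  rounding or conversion constant in the source table.

Constant (non-pulsatile) inflows and pure resistances are deliberate: portal
venous flow has insignificant pulsation, and compliant (Windkessel) outlets
would add parameters nothing in the data constrains.

## The network and its loss laws

`build_network()` translates a case into a directed graph: SV/SMV inflow
stubs (absent in Type C), an MPV trunk split at its midpoint by the
`mpv_mid` probe node, the portal bifurcation, LPV/RPV branches ending in
their outlet resistances, and the shunt, which tees off the host vessel
10 mm from the bifurcation and discharges straight into the IVC sink.
Segment lengths default to plausible adult anatomy (MPV trunk 40 mm,
branches 30 mm, SV/SMV 80/100 mm in Type A and 30/40 mm in Type B). Because
the tributary inflows are prescribed, everything downstream of the
confluence is exactly insensitive to the upstream lengths — the 0D
sharpening of the study's empirical finding that simplification hardly
influences the MPV pressure.

Each edge carries a strictly increasing, odd pressure-loss law with three
terms (all in `R/hydraulics.R`):

* **Darcy–Weisbach friction** $f\,(L/D)\,\rho V^2/2$ with $f = 64/Re$ up to
  $Re = 2300$ and the Blasius correlation $f = 0.316\,Re^{-1/4}$ above. The
  laminar branch reduces exactly to the Poiseuille closed form. The shunt
  runs at $Re \approx 2900$, in the laminar–turbulent transition; the
  surrogate uses the turbulent correlation there with **no blending**,
  mirroring the choice of a turbulence model for the transitional shunt
  flow in 3D practice. The price of the clean switch is a jump in the loss
  law at the threshold, which the solver must (and does) tolerate.
* **Minor losses** $K\rho V^2/2$ at the shunt entrance: a sudden-contraction
  coefficient $K_c = 0.45$ (portal vein into the 8 mm stent) and a bend
  coefficient $K_b = 0.25$ (curved intrahepatic tract) — standard handbook
  values, not fitted. There is no exit-recovery term: the shunt jet's
  kinetic energy is dissipated in the IVC.
* **Bernoulli static-pressure accounting**
  $\tfrac{\rho}{2}(V_{down}^2 - V_{up}^2)$ at every calibre transition
  (branch entries carry the MPV diameter as `d_upstream`, the shunt carries
  its host vessel). Applying the correction at *every* transition makes the
  kinetic-energy terms telescope along the MPV-to-shunt path, so the
  comparison between shunt positions is decided by path friction — the
  physically meaningful part — rather than by which host vessel happens to
  feed the stent. Applying it only at the shunt entry would invert the
  position ranking, because a narrower host implies a smaller velocity
  jump into the stent.

Blood is Newtonian with $\rho = 1060$ kg/m³ and $\mu = 0.0035$ Pa s.
Reported pressures are static, matching what CFD pressure contours show.
The parabolic inlet profiles of a 3D model have no 0D analogue; only mean
flows enter the network.

## Solving the network

`solve_network()` runs damped Newton on the interior nodal pressures,
initialized from the all-laminar linear solution. Edge flows are recovered
from pressure differences through the generalized inverse of the loss law
(flat across the laminar/turbulent jump, so flows stay continuous in the
pressures); the Jacobian uses the analytic slope of the attained branch.
The damping schedule first halves the step and then, if no damped step
helps, expands it — a Newton step sized on one branch's slope can be too
short to carry an edge across the friction jump. If Newton still stalls
(it can when an edge's equilibrium sits essentially on the jump), the
solver falls back to nested bisection on the single unknown shunt flow:
flows are then parameterized directly, mass is conserved by construction,
and the bifurcation split and the leak past the tee are inner monotone
scalar solves. The two reference patients solve by Newton alone; a few
extreme synthetic draws use the fallback.

Convergence demands a maximal nodal mass imbalance below $10^{-12}$ m³/s
(about $10^{-8}$ of the total inflow), checked independently by
`residual_report()`. Zero total inflow short-circuits to the zero solution.
Losses are odd in signed flow, so reversed flow is representable even
though it does not occur in these topologies. Solutions are deterministic:
no randomness enters the solver.

A one-dimensional nested-bisection oracle, written independently of the
package's hydraulics and solver code, lives in the test suite and agrees
with the general solver to better than $10^{-10}$ relative on all 18 cases.

## Metrics and what the surrogate can honestly claim

`case_metrics()` reports, per case: PPG (MPV-midsection pressure minus the
zero IVC pressure, in mmHg), area-averaged shunt velocity and Reynolds
number, shunt flow fraction, the pressures at the shunt inlet plane (10 mm
into the stent, i.e. 50 mm from the outlet) and outlet, and the
segment-mean wall shear stress $(f/8)\rho V^2$ of every segment with a
low/normal/high classification (low below 6 Pa on venous walls, 10 Pa on
the shunt wall; high above 15 Pa — thresholds exposed in
`wss_thresholds()`). `relative_error()` is the percentage comparator
$(x - x_{A})/x_{A}\times 100$ used for Types B/C against Type A, and is
equally applicable to published low-WSS areas, which this package cannot
compute itself: areas of low/high wall shear stress are genuinely 3D
quantities, so the 0D deliverable is segment-mean stress plus
classification, no more.

For the two reference patients the surrogate reproduces the study's
headline numbers: PPG 11.4 mmHg (first patient, shunt at MPV, inside the
published 10–12 mmHg), shunt velocities 1.21–1.30 m/s (published 1.2–1.3),
shunt Reynolds number ≈ 2930 (the published transition argument uses
≈ 2900), a ≈ 10 mmHg drop between the MPV midsection and the shunt inlet
and ≈ 1.6 mmHg along the shunt (published "about 10" and "about 2"), and
the position ranking — the MPV position decompresses most, with LPV and
RPV nearly tied ≈ 0.8–1.3 mmHg higher. Spatial fields (pressure contours,
streamlines, swirling flow, WSS maps) and mesh-convergence figures are 3D
results outside this model's scope, as are the published ALWSS/AHWSS
magnitudes.

## Synthetic cohorts and the plausibility envelope

`generate_cohort()` draws patient records uniformly from closed boxes
bracketing the reference anatomy (MPV 14–18 mm, SV 8–15, SMV 10–17,
LPV 9–13, RPV 8–10 mm, preoperative velocity 0.1–0.3 m/s, portal pressure
20–30 mmHg). Uniform boxes make bound assertions exact; nothing in the
data motivates a distributional shape. One integer seed governs a cohort,
with per-record substreams derived by stable indexing, so records are
order-independent and the caller's RNG state is untouched.
`perturb_patient()` gives multiplicative sensitivity perturbations.

What envelope should cohort results satisfy? Because the outlet closure
makes the parallel hepatic resistance exactly $P_{pv}/Q^{pre}$, the
surrogate obeys $PPG = 2(1-\phi)P_{pv}$ with $\phi$ the shunt flow
fraction. Solving the loss balance at the corners of the sampling box
gives $\phi \approx 0.59$ (largest flows, $PPG \approx 24.5$ mmHg at
$P_{pv}=30$) and $\phi \approx 0.956$ (smallest flows,
$PPG \approx 2.6$ mmHg). The test suite therefore asserts, on a fixed-seed
25-patient cohort across all three positions: 100% convergence, shunt flow
fraction in (0.5, 0.95), and PPG in (2, 26) mmHg. The narrower clinical
band of 5–20 mmHg holds for records near the centre of the box — the two
reference patients sit at 11.4 and 13.0 mmHg — but not at the corners,
where doubling a large portal flow through a fixed 8 mm stent is simply
expensive. Synthetic cohorts emulate the scalar parameter vector the
pipeline consumes, not real anatomy: passing cohort tests demonstrates
numerical robustness over the physiological parameter range, not clinical
validity for any individual.

## Numerical choices, in one place

* mmHg conversion: 133.322 Pa/mmHg, declared once.
* Diameters stay in mm inside `patient_record` (as clinical tables print
  them) and convert to SI at network build.
* Laminar/turbulent threshold $Re = 2300$; Blasius above, no blending.
* Solver tolerance $10^{-12}$ m³/s mass imbalance, 200 Newton iterations,
  bisections run to floating-point interval collapse.
* Murray split returns a compensated complement: the pair sums to the
  total within one ulp.
* Ties at WSS thresholds classify as `normal` (strict inequalities on both
  sides).
* Problem sizes in the shipped tests: the full 18-case study (runs in a
  few seconds), a 25-patient cohort at 3 positions, and 200-draw bound
  checks for the generator.

## Limitations

The model resolves no geometry beyond diameters and lengths: curvature,
tapering, the real confluence shape and jet impingement at the shunt inlet
are absorbed into two handbook coefficients. The transition treatment is a
correlation, not turbulence physics. Simplification-type comparisons are
exact by construction here (prescribed inflows), so the interesting 3D
finding — that simplification distorts *local* fields near the bifurcation
while leaving MPV pressure and shunt flow nearly unchanged — appears in
this package only through its surviving scalar half.
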