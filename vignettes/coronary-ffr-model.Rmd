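---
title: "A reduced-order model of coronary pressure, virtual stenting, and non-invasive FFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of coronary pressure, virtual stenting, and non-invasive FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The problem

Fractional flow reserve (FFR) — the ratio of distal coronary pressure to
aortic pressure under maximal hyperemia — is the reference standard for
deciding whether a coronary stenosis causes ischemia (FFR ≤ 0.80) and for
judging whether a stent has relieved it. Measuring FFR requires a pressure
wire and adenosine. `coroflow` computes a simulated FFR from anatomy
alone: a coronary tree represented as centerlines with lumen-radius
profiles, a patient's cuff blood pressure, and their left-ventricular
mass. Because the geometry can be edited, the same machinery predicts the
hemodynamic effect of a stent *before* it is placed: the stenotic segment
is replaced by a virtual stent and the simulation is repeated.

## The flow model

Blood is treated as an incompressible Newtonian fluid (density
$\rho = 1050\ \mathrm{kg/m^3}$, viscosity $\mu = 3.5\ \mathrm{mPa\,s}$) in
steady flow through a rooted tree of vessels with circular cross-section
$A(s) = \pi r(s)^2$. Two loss mechanisms set the pressure drop along a
vessel carrying flow $Q$:

* a viscous (Poiseuille) term integrated over the radius profile,
  $\Delta P_\mathrm{visc} = \int \frac{8\mu}{\pi r(s)^4} Q \, ds$,
  evaluated with the trapezoidal rule on the centerline samples, and
* a Borda–Carnot (Bernoulli) expansion loss at each maximal area-expansion
  event,
  $\Delta P_\mathrm{exp} = \frac{\rho}{2} Q^2
  \left(\frac{1}{A_\mathrm{min}} - \frac{1}{A_\mathrm{down}}\right)^2$,
  where $A_\mathrm{min}$ is the area at the start and $A_\mathrm{down}$
  the area at the end of a maximal non-decreasing run of $A(s)$.

The expansion term is what makes a focal stenosis expensive at hyperemic
flow: it grows with $Q^2$ and with the square of the reciprocal throat
area. Contractions are treated as loss-free, the standard assumption in
one-dimensional arterial modelling; expansion events are detected within
a branch only, so a daughter narrower than its parent does not generate a
junction loss. Flow reversal and collateral loops are unsupported — the
topology is a tree and all flows are non-negative.

## Boundary conditions

The physiological closure works as follows.

* **Inlet.** The inlet static pressure is the patient's mean blood
  pressure, $\mathrm{MBP} = \mathrm{DBP} + (\mathrm{SBP} -
  \mathrm{DBP})/3$, minus a fixed 6.8 mmHg offset accounting for the
  systemic effect of adenosine.
* **Resting flow.** Total resting coronary flow scales with myocardial
  mass, $Q_\mathrm{rest} = c \cdot m^{0.75}$ mL/min. The coefficient
  $c = 2.6\ \mathrm{mL\,min^{-1}\,g^{-0.75}}$ is chosen so a 114 g left
  ventricle receives about 0.8 mL/min/g at rest, a standard resting
  perfusion; it is configurable in `hemo_params()`.
* **Hyperemia.** Microvascular resistance under adenosine falls to 0.21
  of its resting value, so the hyperemic inflow target is
  $Q_\mathrm{rest}/0.21$.
* **Outlets.** Each outlet $i$ carries a resistance $R_i$ to a common
  reference pressure $P_0$ (default 0 mmHg, a venous reference). Flow is
  apportioned among outlets by Murray-type weights $w_i = d_i^k / \sum_j
  d_j^k$ on the local outlet diameters (default $k = 3$); the initial
  resistances are $R_i = (P_\mathrm{in} - P_0) / (w_i
  Q_\mathrm{target})$.

The $d^k$ allocation is this package's concrete reading of "resistance
proportional to vessel size": it is the allocation implied by Murray's law
when wall shear is uniform, and the exponent is configurable.

## Solving and calibrating

Given outlet flows, pressure drops along every root-to-outlet path are
cheap to evaluate: the viscous part is a constant outlet-by-outlet
coupling matrix (assembled once per geometry) and each expansion event
contributes a quadratic term. The inner problem — find flows such that
$P_\mathrm{in} - \Delta P_i(Q) = P_0 + R_i Q_i$ on every path — has a
symmetric positive-definite Jacobian (the losses are convex and
increasing in $Q$), so it has a unique solution; `solve_flow()` finds it
with a damped Newton iteration, backtracking to keep flows positive, to a
relative residual of $10^{-8}$ (configurable).

The resistances are then *calibrated*: all $R_i$ are rescaled by a common
factor $\beta$, updated with an under-relaxation scheme
$\beta \leftarrow \beta \,(\sum_i Q_i / Q_\mathrm{target})^{\alpha}$
(default $\alpha = 0.5$), until total outflow matches the hyperemic
inflow target within 0.1 %. Calibration is performed on the as-imaged
(stenosed) anatomy, and post-stent runs recalibrate on the stented
anatomy by the same protocol, so each simulation is self-contained; a
study that preferred fixed boundary conditions across phases could reuse
the pre-stent `bcs`, which the API permits. The calibrated operating
point is a property of the physics, not of the iteration: the fixed point
is unique because total outflow is strictly decreasing in $\beta$, and
the relaxation factor only affects the approach path. If the anatomy
physically cannot carry the target flow at the available pressure (for
example a subtotal stenosis of the sole supplying vessel), the
calibration detects the saturation and raises a convergence error rather
than silently under-delivering.

FFR at a measurement site is the local pressure, linearly interpolated
between centerline samples, divided by the inlet pressure — i.e. the
simulated hyperemic aortic pressure is the denominator. Values at or
below 0.80 (inclusive) are classed as ischemic.

## Virtual stenting

A stent is described by its landing points $P^*$ and $D^*$ on the branch,
and its diameter $D$. Deployment replaces the radius profile on
$[P^*, D^*]$ with a cubic spline through circular sections of radius
$D/2$ spaced every 3 mm strictly inside the span (a section falling
exactly on $D^*$ is excluded), blended into the *original* lumen radii at
the two landing points so the new segment joins the untouched vessel
smoothly. Geometry outside the span is never modified, and deploying a
stent at the local healthy diameter reproduces the healthy profile to
within spline tolerance. Multiple stents are deployed
proximal-to-distal. Strut mechanics, recoil, and compliance-induced
curvature changes are out of scope.

Automatic sizing inverts this: on the lumen-area curve $A(s)$, the throat
$S$ is the area minimum in the search window, and the shoulders $P$ and
$D$ are the points of maximal absolute change of slope on either side of
$S$. Discretely, "change of slope" is the second difference of $A$ on the
sample grid; because the curvature magnitude jumps at a lesion shoulder,
the marker is placed at the outermost sample still at half of the local
curvature maximum, then refined to sub-sample accuracy by interpolating
the half-prominence crossing. The search for each shoulder is confined to
the lesion's own flank (the walk stops where the area stops rising), so
with tandem disease the sizer brackets only the dip containing the
window's global minimum. Stent length is $D - P$ and stent diameter the
mean of the lumen diameters at $P$ and $D$. Percent diameter stenosis is
graded against a reference diameter interpolated between the shoulders.

Lesion classes follow the usual clinical definitions: *ostial* within 3 mm
of the vessel origin (the margin is configurable; no standard value
exists), *bifurcation* when the extent spans a daughter take-off,
*tandem* when two or more lesions of ≥ 50 %DS share a root-to-outlet
path, *focal* otherwise, with precedence ostial > bifurcation > tandem >
focal (the definitions themselves do not order overlapping cases, so the
precedence is declared).

## The synthetic cohort

No patient geometries ship with the package; the generator stands in for
them. `generate_tree()` builds epicardial trees whose bifurcations close
Murray's law ($d_p^\gamma = \sum d_c^\gamma$, $\gamma = 3$) exactly, with
a seeded daughter-asymmetry ratio in $[0.6, 1]$, branch lengths of 15–40
mm, a 4 mm root, and truncation when a daughter would fall below 1.5 mm
diameter — mirroring the usual lower limit of lumen segmentation.
`generate_validation_cohort()` draws patients (SBP 113–141, DBP 63–85
mmHg, LV mass 82–146 g, uniform), places one cosine-taper lesion of
30–90 %DS on the largest first-generation vessel (an LAD-like position; a
root lesion would force the entire hyperemic inflow through one throat,
which is not the condition being emulated), computes FFR distal to the
lesion before and after stenting at the reference diameter, and simulates
an "invasive" FFR as the model value minus a bias (default 0.024) plus
Gaussian noise (default SD 0.065), truncated to (0, 1]. With this sign
convention the Bland–Altman mean difference of model minus invasive
recovers the configured bias.

What the synthetic cohort does *not* emulate: real lumen irregularity and
eccentric plaque, diffuse disease, myocardial territory heterogeneity,
curvature-related losses, or the error structure of a real
invasive/simulated comparison. Passing the parameter-recovery tests
therefore demonstrates that the statistics pipeline is faithful and the
simulator internally consistent — not that the model reproduces clinical
accuracy on real anatomies. One visible artifact: post-stent synthetic
FFR values sit close to 1, so the (0, 1] truncation of the noisy
"invasive" values can inflate the apparent post-stent bias at small
sample sizes.

## Agreement statistics

`pearson_r()`, `bland_altman()` (limits of agreement at bias ± 1.96 SD of
the differences) and `diagnostic_metrics()` (2×2 counts with sensitivity,
specificity, PPV, NPV and accuracy, held at full precision and rounded
only for display) follow their textbook definitions.
`reproducibility_stats()` reports the two-way mixed-effects,
absolute-agreement, single-measure ICC with its F-based 95 % confidence
interval — the variant appropriate for fixed observers re-reading the
same cases — and a coefficient of variation defined as the SD of the
paired differences over the grand mean of all measurements, with a seeded
bootstrap interval (2000 resamples). "ICC" and "COV" are reported without
a formula more often than not in the clinical literature; the definitions
used here are declared so results are reproducible.

## Numerical choices and sizes

* Centerline sampling: generated trees use ~0.5 mm spacing; stenosis
  tapers should span several samples. Lesion-recovery accuracy is one
  sample spacing in position and 2 % in diameter.
* Inner Newton tolerance $10^{-8}$ (relative), calibration tolerance
  $10^{-3}$, calibration cap 200 outer iterations, inner cap 500.
* Degenerate inputs: zero-variance vectors, lesion-free vessels, trees
  whose outlets cannot carry the hyperemic target, and unconverged
  solutions all raise typed conditions (`coroflow_*_error`) rather than
  returning quietly wrong numbers.
* The test suite exercises 50 random calibrations, 100 stent
  monotonicity cases and a 200-patient statistics-recovery cohort; the
  shipped validation script runs a 25-patient cohort, the size typical
  of a prospective FFR sub-study.

## Worked example

```{r example, eval = FALSE}
tr <- generate_tree(seed = 42, generations = 2)
dis <- apply_stenosis(tr, stenosis_spec("b2", s_center = 16, length = 12,
                                        severity = 70))
pat <- patient_record(sbp = 127, dbp = 74, lv_mass = 114)
site <- measurement_site("b2", 25)

stent <- auto_size_stent(dis, "b2")
cfg <- case_config(dis, pat, list(site), stents = list(stent))
rep <- run_case(cfg)
rep$pre$ffrb   # pre-stent FFR at the site
rep$post$ffrb  # predicted post-stent FFR
```

## Limitations

The 1-D loss model ignores curvature, eccentricity, and junction losses;
it represents lumens as circular. Boundary conditions assume a healthy
microcirculation (no microvascular disease) and a fixed hyperemic
resistance ratio. The simulated cohort shares the generator's
assumptions, so agreement statistics on it validate the software, not the
clinical model. Transient phenomena and side-branch wire artifacts are
out of scope by design: the model is steady-state.
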