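---
title: "Methods: pulmonary-artery hemodynamics from 4D flow velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulmonary-artery hemodynamics from 4D flow velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pa4dflow)
```

## The problem

Time-resolved three-directional phase-contrast CMR ("4D flow") measures the
blood velocity vector on a regular voxel grid throughout the cardiac cycle.
In pulmonary hypertension — and in particular in chronic thromboembolic
disease before and after endarterectomy — the clinically interesting
quantities are not the raw velocities but integrated descriptors of the
main, left and right pulmonary artery (MPA, LPA, RPA): branch volumes and
cross-sectional areas, wall stiffness surrogates, flow-rate waveforms and
velocity profiles, and secondary-flow descriptors built from the vorticity
field (helicity density, the balance of clockwise vs counterclockwise
rotation, and the helical flow index). `pa4dflow` implements the
post-processing chain from (velocity grid, vessel mesh, centerlines) to a
long-format per-branch metric table, plus the longitudinal statistics used
to relate metric changes to hemodynamic and right-ventricular recovery.

Image segmentation, registration that produces node-corresponded keyframe
meshes, and centerline extraction are upstream concerns: the package
*consumes* a tetrahedral vessel mesh (or two corresponded keyframes) and
ordered branch centerlines.

## Data model and units

All internal lengths are cm, velocities cm/s, times s, pressures mmHg;
flow is reported in cm^3/s and L/min (x 0.06). NIfTI coordinates (mm) are
converted on read. The velocity grid is treated as node-centered samples
and interpolated trilinearly; trilinear interpolation reproduces affine
fields exactly and is second-order accurate for smooth fields, which the
validation suite exploits.

Two velocity file dialects are accepted (per-component-per-frame scalar
volumes, or one 5-D volume), with a YAML sidecar carrying frame times,
cycle length, units, component order and optionally venc. Velocities
beyond the declared venc produce a warning, not an error: aliasing
corrections belong upstream.

## Geometry stage

**Keyframe blending.** The vessel wall distends over the cycle. Given
minimum- and maximum-volume keyframe meshes with node correspondence, node
positions are blended linearly, `x(t) = (1-a(t)) x_min + a(t) x_max`, with
a clipped raised-cosine schedule by default. This deliberately replaces
diffeomorphic registration: linear blending of corresponded nodes is
enough to reproduce per-frame volumes and areas, which is what the metrics
consume; it cannot invent shape change that is not in the keyframes, and
that is a documented limitation rather than a defect.

**Branch splitting.** Each tetrahedron is assigned to the branch whose
centerline is nearest (point-to-segment distance from the element
centroid). The bifurcation region — the ball around the point where the
daughter centerlines first come within one local inscribed radius of the
trunk centerline — is flagged and excluded from all branch metrics, since
elements there belong to no single branch. The inscribed radius falls back
to a configurable constant when the centerlines carry no radii.

**Cross-sections.** A slice at arc-length fraction `f` of a branch is the
connected component, containing the centerline point, of the intersection
of the mesh with the plane through that point normal to the local
centerline tangent. Cut tetrahedra contribute triangles and quads; pieces
are glued across shared cut mesh-edges. Fractions are measured **from the
cap end** (pulmonary valve for the MPA, distal cap for the daughters), so
the 10% slice sits near each branch's inflow — the convention matching
"flows coming directly into each branch"; the mid-branch metrics use the
50% slice. Slice normals are oriented so the time-mean flux is positive;
that orientation *defines* the forward flow direction used by the flow
rate and the reverse-flow fraction.

**Quadrature.** Surface integrals over a slice use the edge-midpoint
triangle rule (field values sampled at the midpoints of the slice
triangulation's edges), which is exact for quadratic integrands; with
parabolic velocity profiles this removes the dominant O(h^2) quadrature
bias that a vertex-mean centroid rule leaves behind.

**Curvature.** The centerline radius of curvature uses
`kappa = |r' x r''| / |r'|^3` from centered finite differences on the
arc-length parameterization after a 5-point moving-average smoothing
(window configurable); curvature below 1e-6 / cm is reported as straight
(`R_c = Inf`), which sends the Dean number to 0.

## Field operators

Velocity gradients are piecewise constant per tetrahedron, from the
element's linear shape functions. This choice is deliberately simple: it
is *exact* for affine fields on any nondegenerate mesh, which turns the
solid-body and shear phantoms into machine-precision tests of the whole
resample-differentiate path. From the gradient: strain rate
`S = (G + G')/2`, rotation `W = (G - G')/2`, vorticity
`omega = curl u`, and `Q = (||W||_F^2 - ||S||_F^2)/2`.

Two branch-vorticity conventions exist in the field and genuinely differ:
the magnitude of the volume-mean vorticity vector (`vorticity_vectormean`,
the literal spatial average of curl u), and the volume mean of `|curl u|`
(`vorticity_magmean`). For rotationally symmetric shear — a Poiseuille
profile — the vector mean cancels to ~0 while the magnitude mean is
`4 u_max / 3R`. Both are computed and written to the metric table under
their own names; neither is silently preferred.

Vortex candidates are face-connected components of elements with `Q > 0`
and element-mean speed below 30 cm/s (configurable); the low-speed gate
suppresses the fast laminar core.

## Metrics

Per branch and per cardiac frame the pipeline extracts: branch volume; the
mid-slice area waveform with relative area change
`RAC = (A_max - A_min)/A_min`, compliance `(A_max - A_min)/(SPAP - DPAP)`
and distensibility `RAC/(SPAP - DPAP) x 100`; the proximal-slice flow
waveform; the centerline velocity (maximum speed within 0.3 of the
effective slice radius `sqrt(A/pi)` around the centerline point); the
reverse-flow area fraction (triangles with `u . n <= 0` — perpendicular
flow counts as reverse, by definition); helicity density `H_d = u . omega`
with the positive-helicity volume fraction (strictly `H_d > 0`; exact
zeros count as non-positive) and the helical flow index, the
volume-weighted mean of `|cos(angle(u, omega))|`. Elements with
`|u||omega|` below a floor (default 1e-6) have an undefined angle and are
excluded from the HFI average, with the exclusion count logged. The Dean
number `rho u_bar D / mu * sqrt(D / 2 R_c)` uses the area-weighted mean
*through-plane* velocity on the mid slice — Dean's number is defined by
the axial mean flow, not the mean speed — with `D = 2 sqrt(A/pi)`,
`rho = 1.06 g/cm^3`, `mu = 0.04 Poise`.

Every waveform is summarized as max/min/time-mean over the full cycle, the
systolic window `[t_ED, t_ES)` and the diastolic remainder; means are
trapezoidal in time with interpolated window edges, and max/min are taken
over samples in the half-open window. The window timepoints come from the
subject record when present, otherwise from the trunk flow waveform
(end-diastole = last sample before the upstroke exceeds 10% of peak flow,
end-systole = first post-peak sample below it); a flat waveform falls back
to a conventional 40% systolic fraction.

The printed definition of the acceleration time ratio has a sign ambiguity
(its numerator is negative under the convention that end-diastole starts
systole); the package implements the standard non-negative form
`(t_peak - t_ED)/(t_ES - t_ED)` with the peak searched inside systole.

The flow-conservation check `|Q_MPA - (Q_LPA + Q_RPA)| / Q_MPA` gates the
dataset at 20% error, and percent-predicted RV metrics normalize measured
RV values by `m_sex * Age^a * Ht^b * Wt^c` (age in years, height cm,
weight kg — the units the reference equations were fitted in).

## Synthetic phantoms and what they do (not) show

The phantom module is first-class, tested code: it generates tube and
Y-junction tetrahedral meshes (concentric-ring disc triangulation extruded
into prisms, each split into three tets by a global-min-index diagonal
rule, conforming and positively oriented), exact centerlines, and
voxelized analytic fields — Poiseuille, solid-body rotation, helical flow,
simple shear, a mirror-symmetric Dean vortex pair, a pulsating tube
(`r(t) = R(1 + delta sin(2 pi t/T))`), and a mass-conserving Y-junction
split. Defaults mirror a typical acquisition: 1 mm voxels (scanner range
1.1-1.8 mm), 20 frames per cycle, 1.2 mm elements. Fields are the smooth
analytic extensions without a wall mask: the mesh only samples inside the
vessel, and a hard zero outside the wall would corrupt near-wall gradients
with first-order error.

`ground_truth()` computes reference values by dense polar-grid quadrature
(>= 10^6 points) and closed forms, straight from the analytic definitions
— never through the mesh pipeline — so every pipeline metric is checked
against an independent oracle. Selected closed forms: Poiseuille flow
`u_max pi R^2 / 2` and magnitude-mean vorticity `4 u_max / 3R`; helical
HFI `2W(sqrt(W^2 + Omega^2 R^2) - W)/(R^2 Omega^2)` (= `2(sqrt(2)-1)`
at `W = Omega = R = 1`); pulsating-tube RAC
`((1+delta)^2 - (1-delta)^2)/(1-delta)^2`.

What passing phantom suites shows: the discrete operators, slicing,
quadrature and metric arithmetic are correct and converge. What it does
not show: robustness to acquisition noise, phase-offset residuals,
segmentation error, venc aliasing, or real vessel-wall motion beyond
affine-per-node blending — real 4D flow data carry all of these.
An optional Gaussian noise model (seeded) exists for sensitivity
experiments but all ground-truth comparisons run noiseless.

## Numerical choices

- Problem sizes in the validation suites: tubes R = 1 cm, L = 10 cm at
  1.2 mm elements (~96k tets) for the Poiseuille/helical suites; the
  Dean-pair, junction and pulsating suites use 1.5-2.5 mm elements, where
  the checked quantities are already resolution-exact (area ratios under
  uniform scaling) or well within tolerance.
- The Y-junction conservation check passes at < 1% only with the
  edge-midpoint quadrature; the vertex-mean rule leaves a radius-dependent
  O(h^2) bias that does not cancel between parent and daughters.
- Mesh refinement converges at second order for the volume-averaged
  vorticity (centroid-rule quadrature of a smooth integrand); the property
  test asserts at least first-order improvement.
- On-plane mesh vertices during slicing are nudged by 1e-12 of the
  coordinate scale to avoid degenerate cut polygons; duplicate consecutive
  centerline points are dropped with a warning; prism splitting chooses
  diagonals by global vertex index so adjacent prisms always conform.
- Determinism: all randomness (synthetic noise, statistical simulations)
  sits behind explicit seeds; identical specs yield byte-identical
  phantoms, and the `validate` subcommand run twice produces identical
  tables.

## Statistics stage

Paired pre/post comparisons apply a Shapiro-Wilk gate at 0.05 to the
paired differences: compatible with normality goes to the paired t-test,
otherwise the Wilcoxon signed-rank test, and the report names the test
that ran. Welch's t-test is exposed for unpaired group contrasts. Constant
differences are reported as degenerate rather than producing an infinite
t. Spearman correlations (average ranks for ties, p from the
t-approximation) are computed on pooled baseline values and on
longitudinal deltas (`X_post - X_pre` per subject, matched by id). No
multiple-testing correction is applied, matching the analysis this
implements; interpret families of correlations accordingly.

## Known limitations

- Linear keyframe blending cannot represent non-corresponded wall motion;
  per-frame mesh series are accepted when available.
- Branch assignment is purely metric (nearest centerline); pathological
  geometries with centerlines crossing other branches' lumens would need
  the configurable bifurcation radius.
- The Q-criterion vortex detector with low-speed thresholding is exposed
  as exploratory; on smooth laminar phantoms it is exact, but it is known
  not to isolate visual vortices robustly in patient data.
- Windows derived from the flow waveform depend on a 10%-of-peak
  threshold; noisy waveforms may need the subject-record timepoints.
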