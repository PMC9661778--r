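# pa4dflow

Post-processing of 4D flow CMR velocity fields in the pulmonary arteries:
from a time-resolved velocity grid, a tetrahedral vessel mesh and branch
centerlines to a per-branch table of geometric, velocity-profile and
secondary-flow metrics, with a phantom validation suite and the
longitudinal statistics for pre/post comparisons.

## Who this is for

Groups analyzing pulmonary-artery hemodynamics from time-resolved
three-directional phase-contrast CMR — e.g. tracking recovery of patients
with chronic thromboembolic pulmonary hypertension after pulmonary
endarterectomy — who have segmented vessel geometry and centerlines and
need reproducible, tested extraction of the derived metrics.

## What it computes

For each branch (MPA, LPA, RPA) and each cardiac window (cycle, systole
`[t_ED, t_ES)`, diastole), as max/min/time-mean:

- **Geometry & stiffness** — branch volume *V*; mid-branch cross-sectional
  area *A* (slice 50% down the branch); relative area change
  RAC = (A_max − A_min)/A_min; compliance (A_max − A_min)/(SPAP − DPAP);
  distensibility RAC/(SPAP − DPAP) × 100.
- **Velocity profile** — flow rate ∫ u · n dA on the proximal (10%) slice;
  centerline velocity (max speed in the central 30%-radius region of the
  mid slice); acceleration time ratio (t_peak − t_ED)/(t_ES − t_ED).
- **Secondary flow** — reverse-flow area fraction A(u·n ≤ 0)/A on the mid
  slice; branch-averaged vorticity (1/V)∫ ∇×u dV, in both the vector-mean
  and magnitude-mean conventions; helicity density H_d = u · ω with the
  positive-helicity volume fraction V(H_d > 0)/V; helical flow index
  HFI = (1/V)∫ |u·ω| / (|u||ω|) dV ∈ [0, 1]; Dean number
  ρūD/μ · √(D/2R_c); Q-criterion vortex regions (Q > 0, speed < 30 cm/s).
- **QC and normalization** — conservation of flow
  |Q_MPA − (Q_LPA + Q_RPA)|/Q_MPA with a 20% pass threshold; % predicted
  RV metrics, 100 · measured/(m_sex · Age^a · Ht^b · Wt^c).
- **Statistics** — Shapiro-gated paired t / Wilcoxon comparisons, Welch
  contrasts, Spearman correlations on baseline values and on per-subject
  pre→post deltas.

Inputs: NIfTI velocity volumes (+ YAML sidecar), VTK XML meshes (`.vtu`)
and centerlines (`.vtp`), CSV subject records. Output: a long-format
metrics CSV and a JSON run report.

## Worked example

No patient data ship with the package; the synthetic module generates
analytic phantoms that exercise every reader and metric. A mass-conserving
Y-junction with Poiseuille inflow (u_max = 40 cm/s, R = 1 cm):

```r
library(pa4dflow)
spec <- phantom_spec("y_junction", R = 1, L = 8, u_max = 40,
                     element_size = 0.25, frames = 4L)
ph <- make_y_junction(spec)
subject <- subject_records(data.frame(
  id = "P1", timepoint = "pre", sex = "M", age = 60, height = 170,
  weight = 75, SPAP = 25, DPAP = 15, RVEF = 55))
res <- run_pipeline(run_config(), ph$field, ph$mesh, ph$centerlines,
                    subject)
sprintf("conservation error: %.4f (QC %s)", res$qc$error,
        ifelse(res$qc$pass, "pass", "FAIL"))
#> [1] "conservation error: 0.0053 (QC pass)"
tab <- res$table
tab[tab$window == "cycle" & tab$statistic == "mean" &
    tab$metric %in% c("volume", "flow", "centerline_velocity", "HFI"),
    c("branch", "metric", "value", "units")]
#>  branch              metric        value    units
#>     MPA              volume 1.191406e+01      cm3
#>     MPA                flow 3.744707e+00    L/min
#>     MPA centerline_velocity 3.993232e+01     cm/s
#>     MPA                 HFI 8.384659e-08 fraction
#>     LPA              volume 5.234782e+00      cm3
#>     LPA                flow 1.862425e+00    L/min
#>     LPA centerline_velocity 3.549547e+01     cm/s
#>     LPA                 HFI 2.565867e-03 fraction
#>     RPA              volume 5.237014e+00      cm3
#>     RPA                flow 1.862494e+00    L/min
#>     RPA centerline_velocity 3.544439e+01     cm/s
#>     RPA                 HFI 2.394700e-03 fraction
```

Reading the numbers: the trunk carries 3.74 L/min and the two daughters
1.86 L/min each, so flow is conserved to 0.5% (QC pass, threshold 20%).
The centerline velocity recovers the 40 cm/s parabolic peak in the MPA
(39.9 cm/s; the daughters carry slower, thinner jets), and HFI ≈ 0 —
velocity and vorticity are everywhere orthogonal in pure pipe flow, so
there is no helical motion. A helical phantom instead yields
HFI = 2(√2 − 1) ≈ 0.828, which the pipeline matches to < 0.1%.

The command-line interface (`inst/cli/pa4dflow.R`) wraps the same
functions: `compute` (full extraction from files), `synth` (write a
phantom to disk), `stats` (paired + delta-correlation report from two
metric tables), and `validate` (run the phantom validation suites).

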