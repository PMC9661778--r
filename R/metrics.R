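# Per-branch, per-window hemodynamic metrics: flow rate, centerline
# velocity, acceleration time ratio, reverse-flow fraction, helicity
# metrics, Dean number, wall-stiffness indices, predicted RV
# normalization, and the cycle/systole/diastole summary statistics.

#' Blood fluid constants
#'
#' Density 1.06 g/cm^3 and dynamic viscosity 0.04 Poise
#' (g cm^-1 s^-1), the conventional values for whole blood; both may be
#' overridden.
#'
#' @param density g/cm^3.
#' @param viscosity Poise.
#' @return list with `density`, `viscosity`.
#' @export
fluid_constants <- function(density = 1.06, viscosity = 0.04) {
  stopifnot(density > 0, viscosity > 0)
  list(density = density, viscosity = viscosity)
}

#' Reference constants for percent-predicted RV metrics
#'
#' Allometric normalization of right-ventricular metrics for sex, age,
#' height and weight: predicted value = `m_sex * Age^a * Ht^b * Wt^c`
#' with age in years, height in cm, weight in kg.
#'
#' @return nested list keyed by metric (RVEF, RVEDV, RVESV, RVSV), each
#'   with exponents `a`, `b`, `c` and multipliers `m_female`, `m_male`.
#' @export
predicted_rv_constants <- function() {
  list(
    RVEF  = list(a =  0.0706, b = -0.00771, c = -0.0782,
                 m_female = 75.19, m_male = 71.52),
    RVEDV = list(a = -0.258,  b =  1.582,   c =  0.382,
                 m_female = 27.94, m_male = 31.50),
    RVESV = list(a = -0.417,  b =  1.501,   c =  0.617,
                 m_female = 5.58,  m_male = 7.24),
    RVSV  = list(a = -0.187,  b =  1.574,   c =  0.304,
                 m_female = 21.12, m_male = 22.42)
  )
}

#' A sampled scalar waveform over one cardiac cycle
#'
#' @param times sample times in s, strictly increasing, within one cycle.
#' @param values sampled values.
#' @param period cycle length in s.
#' @param label what the waveform measures (e.g. "flow_L_min",
#'   "area_cm2").
#' @return object of class `waveform`.
#' @export
waveform <- function(times, values, period, label = "") {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) < 4) stop("a waveform needs at least 4 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0) || any(times >= period))
    stop("times must lie in [0, period)")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = as.numeric(period), label = label),
            class = "waveform")
}

#' Cardiac windows from end-diastolic and end-systolic timepoints
#'
#' Systole is the half-open interval `[t_ED, t_ES)`; diastole is the rest
#' of the cycle (wrapping through the cycle seam).
#'
#' @param t_ED,t_ES end-diastolic / end-systolic time (s),
#'   `0 <= t_ED < t_ES < period`.
#' @param period cycle length (s).
#' @return object of class `cardiac_windows`.
#' @export
cardiac_windows <- function(t_ED, t_ES, period) {
  if (!(t_ED >= 0 && t_ED < t_ES && t_ES < period))
    stop("need 0 <= t_ED < t_ES < period")
  structure(list(t_ED = t_ED, t_ES = t_ES, period = period),
            class = "cardiac_windows")
}

#' Derive cardiac windows from a flow waveform
#'
#' When end-diastole / end-systole are not recorded: t_ED is the last
#' sample before the systolic upstroke exceeds `threshold` of the peak
#' flow, t_ES the first post-peak sample falling below it.
#'
#' @param wf a flow [waveform()].
#' @param threshold fraction of peak flow (default 0.1).
#' @return a [cardiac_windows()].
#' @export
windows_from_flow <- function(wf, threshold = 0.1) {
  v <- wf$values
  pk <- which.max(v)
  lev <- threshold * v[pk]
  pre <- which(v[seq_len(pk)] <= lev)
  t_ED <- if (length(pre)) wf$times[max(pre)] else wf$times[1]
  post <- which(v > lev)
  post <- post[post > pk]
  t_ES <- if (length(post) && max(post) < length(v))
    wf$times[max(post) + 1L] else wf$times[length(v)]
  if (t_ES <= t_ED) stop("could not locate a systolic window in the waveform")
  cardiac_windows(t_ED, t_ES, wf$period)
}

# linear interpolation of a periodic waveform at time t
waveform_at <- function(wf, t) {
  tt <- t %% wf$period
  n <- length(wf$times)
  i <- findInterval(tt, wf$times)
  if (i == 0L) {  # before first sample: wrap from the last
    gap <- wf$times[1] + wf$period - wf$times[n]
    w <- (tt + wf$period - wf$times[n]) / gap
    return((1 - w) * wf$values[n] + w * wf$values[1])
  }
  if (i == n) {
    gap <- wf$times[1] + wf$period - wf$times[n]
    w <- (tt - wf$times[n]) / gap
    return((1 - w) * wf$values[n] + w * wf$values[1])
  }
  w <- (tt - wf$times[i]) / (wf$times[i + 1] - wf$times[i])
  (1 - w) * wf$values[i] + w * wf$values[i + 1]
}

# trapezoid integral of the periodic waveform over [a, b] (b may wrap past
# the period); samples plus interpolated endpoints
integrate_waveform <- function(wf, a, b) {
  if (b <= a) b <- b + wf$period
  knots <- numeric(0)
  for (shift in c(0, wf$period))
    knots <- c(knots, wf$times + shift)
  knots <- sort(unique(c(a, b, knots[knots > a & knots < b])))
  vals <- vapply(knots, function(t) waveform_at(wf, t), numeric(1))
  sum(diff(knots) * (head(vals, -1) + vals[-1]) / 2)
}

#' Cycle / systole / diastole summary of a metric waveform
#'
#' Maxima, minima and time averages of a metric over the whole cycle, the
#' systolic window and the diastolic window. Means are time-weighted
#' (trapezoid over the unevenly spaced frames, window edges interpolated);
#' max/min are taken over the samples whose times fall in the half-open
#' window.
#'
#' @param wf a [waveform()].
#' @param windows a [cardiac_windows()].
#' @return data.frame with columns `window`, `statistic`, `value`.
#' @export
summarize_waveform <- function(wf, windows) {
  if (windows$period != wf$period)
    stop("waveform and windows disagree on the cycle length")
  in_win <- function(t, a, b) {  # membership in [a, b) on the circle
    tt <- (t - a) %% wf$period
    tt < ((b - a) %% wf$period + if (b == a) wf$period else 0)
  }
  win_def <- list(
    cycle = c(0, wf$period),
    systole = c(windows$t_ED, windows$t_ES),
    diastole = c(windows$t_ES, windows$t_ED + wf$period))
  out <- list()
  for (wn in names(win_def)) {
    a <- win_def[[wn]][1]; b <- win_def[[wn]][2]
    if (wn == "cycle") sel <- rep(TRUE, length(wf$times))
    else sel <- vapply(wf$times, in_win, logical(1), a = a, b = b)
    if (!any(sel)) stop("no waveform samples fall in the ", wn, " window")
    mean_v <- integrate_waveform(wf, a, b) / ((b - a) %% wf$period +
                                              if (b - a >= wf$period) wf$period else 0)
    out[[wn]] <- data.frame(
      window = wn,
      statistic = c("max", "min", "mean"),
      value = c(max(wf$values[sel]), min(wf$values[sel]), mean_v))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flow rate through a cross-section
#'
#' Midpoint-quadrature surface integral of `u . n` over the triangulated
#' slice, with the slice's oriented normal.
#'
#' @param slice a `cross_section` with sampled velocities.
#' @return list with `cm3_s` and `L_min` (`= cm3_s * 0.06`).
#' @export
flow_rate <- function(slice) {
  if (is.null(slice$velocity))
    stop("cross-section has no sampled velocities")
  q <- section_flux(slice, slice$velocity, slice$normal,
                    mid_velocity = slice$mid_velocity)
  list(cm3_s = q, L_min = q * 0.06)
}

#' Conservation-of-flow quality check
#'
#' Relative error between the trunk flow and the sum of the daughter
#' flows, `|Q_mpa - (Q_lpa + Q_rpa)| / Q_mpa`; the dataset passes QC when
#' the error is below `threshold` (default 20%).
#'
#' @param Q_mpa,Q_lpa,Q_rpa time-mean flows (any consistent unit);
#'   `Q_mpa > 0`.
#' @param threshold QC threshold on the fractional error.
#' @return list with `error` (fraction) and `pass` (logical).
#' @export
conservation_error <- function(Q_mpa, Q_lpa, Q_rpa, threshold = 0.20) {
  if (Q_mpa <= 0) stop("trunk flow must be positive, got ", Q_mpa)
  err <- abs(Q_mpa - (Q_lpa + Q_rpa)) / Q_mpa
  list(error = err, pass = err < threshold)
}

#' Centerline velocity of a mid-branch slice
#'
#' Maximum velocity magnitude over the slice sample points (polygon
#' vertices and triangle centroids) within the central region of radius
#' `center_fraction * r_eff` around the centerline point, where
#' `r_eff = sqrt(area / pi)` is the effective slice radius.
#'
#' @param slice a `cross_section` with sampled velocities, taken at the
#'   mid-branch (50%) position.
#' @param center_fraction fraction of the effective radius (default 0.3).
#' @return maximum speed in cm/s.
#' @export
centerline_velocity <- function(slice, center_fraction = 0.3) {
  if (is.null(slice$velocity))
    stop("cross-section has no sampled velocities")
  r_eff <- sqrt(slice$area / pi)
  pts <- slice$vertices
  spd <- sqrt(rowSums(slice$velocity^2))
  tri <- slice$triangles
  cpts <- (pts[tri[, 1], , drop = FALSE] + pts[tri[, 2], , drop = FALSE] +
           pts[tri[, 3], , drop = FALSE]) / 3
  cvel <- (slice$velocity[tri[, 1], , drop = FALSE] +
           slice$velocity[tri[, 2], , drop = FALSE] +
           slice$velocity[tri[, 3], , drop = FALSE]) / 3
  all_pts <- rbind(pts, cpts)
  all_spd <- c(spd, sqrt(rowSums(cvel^2)))
  d <- sqrt(rowSums(sweep(all_pts, 2, slice$origin)^2))
  sel <- d <= center_fraction * r_eff
  if (!any(sel)) stop("no sample points inside the center region")
  max(all_spd[sel])
}

#' Acceleration time ratio of a flow waveform
#'
#' Time from the start of systole to peak systolic flow, normalized by the
#' systolic duration: `(t_peak - t_ED) / (t_ES - t_ED)` with the peak
#' searched in `[t_ED, t_ES)`. Non-negative by construction; 0 means the
#' peak sits at end-diastole.
#'
#' @param wf a flow [waveform()].
#' @param windows a [cardiac_windows()].
#' @return dimensionless ratio in `[0, 1)`.
#' @export
acceleration_time_ratio <- function(wf, windows) {
  sel <- wf$times >= windows$t_ED & wf$times < windows$t_ES
  if (!any(sel)) stop("no waveform samples in the systolic window")
  t_sys <- wf$times[sel]
  t_peak <- t_sys[which.max(wf$values[sel])]
  if (t_peak == windows$t_ED || t_peak == max(t_sys))
    warning("peak systolic flow lies on the window boundary")
  (t_peak - windows$t_ED) / (windows$t_ES - windows$t_ED)
}

#' Area fraction of reverse flow on a slice
#'
#' Area-weighted fraction of slice triangles whose sampled through-plane
#' velocity `u . n` is `<= 0` — flow perpendicular or opposite to the
#' forward direction counts as reverse.
#'
#' @param slice an oriented `cross_section` with sampled velocities.
#' @return fraction in `[0, 1]`.
#' @export
reverse_flow_fraction <- function(slice) {
  if (is.null(slice$velocity))
    stop("cross-section has no sampled velocities")
  if (slice$area <= 0) stop("zero-area slice")
  tri <- slice$triangles
  v1 <- slice$vertices[tri[, 1], , drop = FALSE]
  v2 <- slice$vertices[tri[, 2], , drop = FALSE]
  v3 <- slice$vertices[tri[, 3], , drop = FALSE]
  a <- tri_areas(v1, v2, v3)
  un <- ((slice$velocity[tri[, 1], , drop = FALSE] +
          slice$velocity[tri[, 2], , drop = FALSE] +
          slice$velocity[tri[, 3], , drop = FALSE]) / 3) %*% slice$normal
  sum(a[un <= 0]) / sum(a)
}

#' Helicity metrics of a branch
#'
#' Helicity density `H_d = u . omega` per element (velocity at the element
#' centroid as the mean of its node values, vorticity from the element
#' gradient). Returns the per-element `H_d`, the volume fraction of the
#' branch with strictly positive helicity (clockwise rotation), and the
#' helical flow index: the volume-weighted mean of `|cos(angle(u,
#' omega))|`, in `[0, 1]`. Elements where `|u| |omega|` falls below
#' `floor_eps` have an undefined angle and are excluded from the HFI
#' average (the exclusion count is returned).
#'
#' @param nodefield a `node_field`.
#' @param gradfield the matching `gradient_field`.
#' @param mesh the [time_resolved_mesh()].
#' @param elements branch element ids (default: all).
#' @param floor_eps degeneracy floor on `|u| |omega|` (cm/s * 1/s).
#' @return list with `H_d` (per selected element), `fraction_positive`,
#'   `HFI`, `n_excluded`.
#' @export
helicity_metrics <- function(nodefield, gradfield, mesh, elements = NULL,
                             floor_eps = 1e-6) {
  conn <- mesh$connectivity
  if (is.null(elements)) elements <- seq_len(nrow(conn))
  if (!length(elements)) stop("empty branch: no elements")
  u <- nodefield$values
  uc <- (u[conn[elements, 1], , drop = FALSE] +
         u[conn[elements, 2], , drop = FALSE] +
         u[conn[elements, 3], , drop = FALSE] +
         u[conn[elements, 4], , drop = FALSE]) / 4
  om <- gradfield$vorticity[elements, , drop = FALSE]
  vol <- gradfield$volumes[elements]
  H_d <- rowSums(uc * om)
  fraction_positive <- sum(vol[H_d > 0]) / sum(vol)
  mag <- sqrt(rowSums(uc^2)) * sqrt(rowSums(om^2))
  ok <- mag >= floor_eps
  HFI <- if (any(ok)) sum(abs(H_d[ok]) / mag[ok] * vol[ok]) / sum(vol[ok])
         else 0
  list(H_d = H_d, fraction_positive = fraction_positive, HFI = HFI,
       n_excluded = sum(!ok))
}

#' Dean number of a branch
#'
#' `De = rho * u_bar * D / mu * sqrt(D / (2 R_c))` with `u_bar` the
#' area-weighted mean through-plane velocity on the mid-branch slice,
#' `D = 2 sqrt(area / pi)` the effective diameter, and `R_c` the
#' centerline radius of curvature at the slice position. Characterizes the
#' tendency of counter-rotating secondary-flow (Dean) vortices to form in
#' a curved vessel; a straight vessel (`R_c = Inf`) gives 0.
#'
#' @param mid_slice an oriented `cross_section` at the 50% position.
#' @param Rc radius of curvature (cm), e.g. from
#'   [centerline_curvature()].
#' @param fluid a [fluid_constants()] list.
#' @return dimensionless Dean number.
#' @export
dean_number <- function(mid_slice, Rc, fluid = fluid_constants()) {
  if (is.na(Rc) || Rc <= 0) stop("radius of curvature must be positive")
  q <- flow_rate(mid_slice)$cm3_s
  u_bar <- q / mid_slice$area
  D <- 2 * sqrt(mid_slice$area / pi)
  if (!is.finite(Rc)) return(0)
  fluid$density * abs(u_bar) * D / fluid$viscosity * sqrt(D / (2 * Rc))
}

#' Wall stiffness indices from an area waveform
#'
#' Relative area change `RAC = (A_max - A_min) / A_min` (pulsatility),
#' compliance `(A_max - A_min) / (SPAP - DPAP)` in cm^2/mmHg and
#' distensibility `RAC / (SPAP - DPAP) * 100` in %/mmHg. The
#' pressure-normalized indices are returned only when both pressures are
#' supplied.
#'
#' @param area_wf an area [waveform()] (cm^2).
#' @param SPAP,DPAP systolic / diastolic PA pressure (mmHg), optional.
#' @return list with `RAC`, `A_max`, `A_min`, and (when pressures given)
#'   `compliance`, `distensibility`.
#' @export
area_stiffness_metrics <- function(area_wf, SPAP = NULL, DPAP = NULL) {
  A_max <- max(area_wf$values); A_min <- min(area_wf$values)
  if (A_min <= 0) stop("non-positive minimum area")
  out <- list(RAC = (A_max - A_min) / A_min, A_max = A_max, A_min = A_min)
  if (!is.null(SPAP) && !is.null(DPAP)) {
    if (SPAP <= DPAP)
      stop("SPAP must exceed DPAP for pressure-normalized stiffness")
    pp <- SPAP - DPAP
    out$compliance <- (A_max - A_min) / pp
    out$distensibility <- out$RAC / pp * 100
  }
  out
}

#' Percent-predicted right-ventricular metric
#'
#' `100 * measured / (m_sex * Age^a * Ht^b * Wt^c)` with the reference
#' constants of [predicted_rv_constants()]; age in years, height in cm,
#' weight in kg.
#'
#' @param measured measured RV metric (same units as the reference:
#'   % for RVEF, ml for volumes).
#' @param metric_name one of `"RVEF"`, `"RVEDV"`, `"RVESV"`, `"RVSV"`.
#' @param sex `"F"` or `"M"`.
#' @param age years; `> 0`.
#' @param height cm; `> 0`.
#' @param weight kg; `> 0`.
#' @param constants reference constants.
#' @return percent of the predicted value.
#' @export
percent_predicted_rv <- function(measured, metric_name, sex, age, height,
                                 weight,
                                 constants = predicted_rv_constants()) {
  if (!metric_name %in% names(constants))
    stop("unknown RV metric: ", metric_name)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  if (age <= 0 || height <= 0 || weight <= 0)
    stop("age, height and weight must be positive")
  k <- constants[[metric_name]]
  m <- if (sex == "F") k$m_female else k$m_male
  predicted <- m * age^k$a * height^k$b * weight^k$c
  100 * measured / predicted
}
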