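# Long-format metric table and the end-to-end per-dataset computation.

mt_cols <- c("subject", "timepoint", "branch", "metric", "window",
             "statistic", "value", "units")

#' Long-format metrics table
#'
#' One row per (subject, timepoint, branch, metric, window, statistic);
#' the key must be unique and units nonempty.
#'
#' @param df data.frame with columns `subject`, `timepoint`, `branch`,
#'   `metric`, `window` (cycle/systole/diastole), `statistic`
#'   (max/min/mean), `value`, `units`.
#' @return data.frame of class `metrics_table`.
#' @export
metrics_table <- function(df = NULL) {
  if (is.null(df))
    df <- as.data.frame(stats::setNames(
      c(rep(list(character(0)), 6), list(numeric(0)), list(character(0))),
      mt_cols))
  miss <- setdiff(mt_cols, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[mt_cols]
  key <- df[setdiff(mt_cols, c("value", "units"))]
  if (anyDuplicated(key)) stop("duplicate metric key rows")
  if (nrow(df) && any(is.na(df$units) | df$units == ""))
    stop("units must be nonempty")
  class(df) <- c("metrics_table", "data.frame")
  df
}

#' Write a metrics table as CSV
#'
#' Fixed column order; read-back with [read_metrics_table()] reproduces
#' the table exactly.
#'
#' @param table a [metrics_table()].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_metrics_table <- function(table, path) {
  table <- metrics_table(as.data.frame(table))  # re-validate
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table CSV
#' @param path CSV written by [write_metrics_table()].
#' @return a [metrics_table()].
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path)
  metrics_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(value = "numeric")))
}

mt_row <- function(subject, timepoint, branch, metric, window, statistic,
                   value, units) {
  data.frame(subject = subject, timepoint = timepoint, branch = branch,
             metric = metric, window = window, statistic = statistic,
             value = value, units = units, stringsAsFactors = FALSE)
}

#' Compute the full per-branch metric set for one dataset
#'
#' Runs the whole extraction for one subject/timepoint: branch splitting,
#' per-frame cross-sections and node/gradient fields, and every metric —
#' time-averaged branch volume, mid-slice area waveform with wall
#' stiffness indices, proximal-slice flow waveform and acceleration time
#' ratio, centerline velocity, reverse-flow fraction, vorticity (both
#' averaging modes), helicity metrics, Dean number, and the
#' conservation-of-flow QC — each summarized over the cycle, systolic and
#' diastolic windows. Per-branch failures are recorded as warnings and the
#' run continues.
#'
#' @param field a [velocity_field4d()].
#' @param mesh a [time_resolved_mesh()] (same cycle).
#' @param centerlines a [centerline_set()] with one branch per label.
#' @param subject one-row [subject_records()] data.frame, or NULL.
#' @param config a [run_config()] list.
#' @return list with `table` (a [metrics_table()]), `qc` (list with
#'   conservation error and pass flag), `windows`, `warnings`.
#' @export
compute_all <- function(field, mesh, centerlines, subject = NULL,
                        config = run_config()) {
  labels <- names(centerlines$branches)
  nt <- length(mesh$nodes_per_frame)
  times <- mesh$frame_times
  period <- field$period
  subj_id <- if (!is.null(subject)) as.character(subject$id[1]) else "NA"
  tp <- if (!is.null(subject)) as.character(subject$timepoint[1]) else "NA"
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  regions <- split_branches(mesh, centerlines,
                            bifurcation_radius = config$bifurcation_radius)

  # per-frame node and gradient fields (volume metrics reuse these)
  nodefields <- lapply(seq_len(nt), function(f)
    resample_to_mesh(field, mesh, f, time_match = config$time_match))
  gradfields <- lapply(seq_len(nt), function(f)
    velocity_gradient(nodefields[[f]], mesh))

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- mt_row(...)
  flows_mean <- stats::setNames(rep(NA_real_, length(labels)), labels)
  flow_wfs <- list()

  for (lbl in labels) {
    el <- regions$branch[[lbl]]
    cl <- centerlines$branches[[lbl]]
    res <- try({
      # ---- volume (temporal average over the cycle)
      vols <- vapply(seq_len(nt), function(f) mesh_volume(mesh, f, el),
                     numeric(1))
      add(subj_id, tp, lbl, "volume", "cycle", "mean", mean(vols), "cm3")

      # ---- waveforms from slices at the proximal (flow) and mid
      # (area/velocity/reverse-flow) positions
      q_series <- a_series <- cv_series <- rf_series <- numeric(nt)
      for (f in seq_len(nt)) {
        vf <- nearest_frame(field, times[f])
        sl10 <- slice_at_fraction(mesh, cl, config$slice_fractions[1], f,
                                  field, elements = el, velocity_frame = vf)
        sl50 <- slice_at_fraction(mesh, cl, config$slice_fractions[2], f,
                                  field, elements = el, velocity_frame = vf)
        q_series[f] <- flow_rate(sl10)$cm3_s
        a_series[f] <- sl50$area
        cv_series[f] <- centerline_velocity(sl50, config$center_fraction)
        rf_series[f] <- reverse_flow_fraction(sl50)
      }
      flows_mean[lbl] <- mean(q_series)
      mk_wf <- function(v, label) waveform(times, v, period, label)
      flow_wf <- mk_wf(q_series * 0.06, "flow_L_min")
      flow_wfs[[lbl]] <- flow_wf

      # cardiac windows: subject record when present, else from the
      # trunk flow waveform (fallback: this branch's waveform)
      windows <- resolve_windows(subject, flow_wf, period, config)

      series <- list(
        flow = list(wf = flow_wf, units = "L/min"),
        area = list(wf = mk_wf(a_series, "area_cm2"), units = "cm2"),
        centerline_velocity = list(wf = mk_wf(cv_series, "cm_s"),
                                   units = "cm/s"),
        reverse_flow_fraction = list(wf = mk_wf(rf_series, "fraction"),
                                     units = "fraction"))
      # vorticity + helicity per frame
      for (mode in c("vector-mean", "magnitude-mean")) {
        v <- vapply(seq_len(nt), function(f)
          branch_vorticity(gradfields[[f]], el, mode), numeric(1))
        nm <- if (mode == "vector-mean") "vorticity_vectormean"
              else "vorticity_magmean"
        series[[nm]] <- list(wf = mk_wf(v, nm), units = "1/s")
      }
      hel <- lapply(seq_len(nt), function(f)
        helicity_metrics(nodefields[[f]], gradfields[[f]], mesh, el,
                         config$hfi_floor))
      series$helicity_fraction_positive <- list(
        wf = mk_wf(vapply(hel, `[[`, numeric(1), "fraction_positive"),
                   "fraction"), units = "fraction")
      series$HFI <- list(
        wf = mk_wf(vapply(hel, `[[`, numeric(1), "HFI"), "HFI"),
        units = "fraction")

      for (nm in names(series)) {
        sm <- summarize_waveform(series[[nm]]$wf, windows)
        for (r in seq_len(nrow(sm)))
          add(subj_id, tp, lbl, nm, sm$window[r], sm$statistic[r],
              sm$value[r], series[[nm]]$units)
      }

      # ---- scalar metrics
      atr <- acceleration_time_ratio(flow_wf, windows)
      add(subj_id, tp, lbl, "acceleration_time_ratio", "systole", "mean",
          atr, "fraction")

      stiff <- area_stiffness_metrics(
        series$area$wf,
        SPAP = subject_field(subject, "SPAP"),
        DPAP = subject_field(subject, "DPAP"))
      add(subj_id, tp, lbl, "RAC", "cycle", "mean", stiff$RAC, "fraction")
      if (!is.null(stiff$compliance)) {
        add(subj_id, tp, lbl, "compliance", "cycle", "mean",
            stiff$compliance, "cm2/mmHg")
        add(subj_id, tp, lbl, "distensibility", "cycle", "mean",
            stiff$distensibility, "%/mmHg")
      }

      Rc <- centerline_curvature(cl, config$slice_fractions[2],
                                 config$curvature_window)
      f_peak <- which.max(vapply(seq_len(nt), function(f)
        abs(waveform_at(flow_wf, times[f])), numeric(1)))
      sl50 <- slice_at_fraction(mesh, cl, config$slice_fractions[2],
                                f_peak, field, elements = el)
      add(subj_id, tp, lbl, "dean_number", "cycle", "max",
          dean_number(sl50, Rc, config$fluid), "dimensionless")
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note(sprintf("branch %s failed: %s", lbl,
                   conditionMessage(attr(res, "condition"))))
  }

  # ---- conservation QC (needs the standard three-branch layout)
  qc <- NULL
  if (all(c("MPA", "LPA", "RPA") %in% labels) &&
      all(is.finite(flows_mean[c("MPA", "LPA", "RPA")])) &&
      flows_mean[["MPA"]] > 0) {
    qc <- conservation_error(flows_mean[["MPA"]], flows_mean[["LPA"]],
                             flows_mean[["RPA"]],
                             threshold = config$conservation_threshold)
  }

  # ---- percent-predicted RV metrics from the subject record
  if (!is.null(subject)) {
    for (mn in c("RVEF", "RVEDV", "RVESV", "RVSV")) {
      v <- subject_field(subject, mn)
      if (!is.null(v))
        add(subj_id, tp, "RV", paste0("pct_predicted_", mn), "cycle",
            "mean",
            percent_predicted_rv(v, mn, subject$sex[1], subject$age[1],
                                 subject$height[1], subject$weight[1]),
            "%")
    }
  }

  windows_out <- tryCatch(
    resolve_windows(subject, flow_wfs[["MPA"]] %||% flow_wfs[[1]],
                    period, config),
    error = function(e) NULL)
  list(table = metrics_table(do.call(rbind, rows)), qc = qc,
       windows = windows_out, warnings = warnings)
}

subject_field <- function(subject, col) {
  if (is.null(subject) || !col %in% names(subject)) return(NULL)
  v <- subject[[col]][1]
  if (is.na(v)) NULL else v
}

resolve_windows <- function(subject, flow_wf, period, config) {
  t_ED <- subject_field(subject, "t_ED")
  t_ES <- subject_field(subject, "t_ES")
  if (config$windows_source == "record" && !is.null(t_ED) &&
      !is.null(t_ES))
    return(cardiac_windows(t_ED, t_ES, period))
  # a flat/zero waveform has no discernible upstroke; fall back to a
  # conventional 40% systolic fraction
  tryCatch(windows_from_flow(flow_wf, config$upstroke_threshold),
           error = function(e) cardiac_windows(0, 0.4 * period, period))
}
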