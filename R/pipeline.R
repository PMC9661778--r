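# Run configuration and end-to-end orchestration, plus the phantom
# validation suite used by the `validate` subcommand.

#' Pipeline run configuration
#'
#' Central defaults for the extraction: the proximal/mid slice fractions
#' (10% and 50% of branch arc length from the cap end), the 30%
#' center-region radius for centerline velocity, the 1.2 mm element
#' target, the 20% conservation QC threshold and the 30 cm/s vortex speed
#' threshold.
#'
#' @param slice_fractions proximal and mid slice positions, each in
#'   (0, 1).
#' @param center_fraction center-region radius fraction for centerline
#'   velocity.
#' @param element_size tetrahedral target edge length (cm).
#' @param vorticity_mode default averaging mode for summaries.
#' @param hfi_floor degeneracy floor on `|u||omega|` for the HFI average.
#' @param conservation_threshold QC threshold on the flow-conservation
#'   error.
#' @param vortex_speed_threshold cm/s, for Q-criterion vortex detection.
#' @param fluid a [fluid_constants()] list.
#' @param windows_source `"record"` (subject t_ED/t_ES when present) or
#'   `"auto"` (always derive from the trunk flow waveform).
#' @param upstroke_threshold fraction of peak flow for auto windows.
#' @param time_match `"nearest"` or `"linear"` temporal matching of mesh
#'   frames to velocity frames.
#' @param bifurcation_radius override radius (cm) for the bifurcation
#'   region; default NULL = local inscribed radius.
#' @param curvature_window smoothing window for centerline curvature.
#' @param seed seed for all randomness (synthetic noise, simulations).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(slice_fractions = c(0.10, 0.50),
                       center_fraction = 0.30,
                       element_size = 0.12,
                       vorticity_mode = "vector-mean",
                       hfi_floor = 1e-6,
                       conservation_threshold = 0.20,
                       vortex_speed_threshold = 30,
                       fluid = fluid_constants(),
                       windows_source = c("record", "auto"),
                       upstroke_threshold = 0.1,
                       time_match = c("nearest", "linear"),
                       bifurcation_radius = NULL,
                       curvature_window = 5L,
                       seed = 1L) {
  windows_source <- match.arg(windows_source)
  time_match <- match.arg(time_match)
  stopifnot(all(slice_fractions > 0 & slice_fractions < 1),
            center_fraction > 0, element_size > 0,
            conservation_threshold > 0, vortex_speed_threshold >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `write_run_config`: invisibly `path`; `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$fluid <- unclass(cfg$fluid)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$fluid)) cfg$fluid <- do.call(fluid_constants, cfg$fluid)
  do.call(run_config, cfg)
}

#' Run the full extraction on one dataset and write outputs
#'
#' Deterministic orchestration of [compute_all()]: reads nothing itself —
#' inputs are in-memory objects — computes the metric table and QC, and
#' writes the table CSV plus a JSON run report (package version, config
#' echo, QC flags, warnings, stage timings).
#'
#' @param config a [run_config()].
#' @param field a [velocity_field4d()].
#' @param mesh a [time_resolved_mesh()].
#' @param centerlines a [centerline_set()].
#' @param subject optional one-row [subject_records()].
#' @param out_dir output directory (created); NULL = no files written.
#' @return the [compute_all()] result, plus `report`.
#' @export
run_pipeline <- function(config, field, mesh, centerlines, subject = NULL,
                         out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  res <- compute_all(field, mesh, centerlines, subject, config)
  elapsed <- proc.time()[["elapsed"]] - t0
  cfg <- unclass(config); cfg$fluid <- unclass(cfg$fluid)
  report <- list(
    package_version = as.character(utils::packageVersion("pa4dflow")),
    config = cfg,
    qc = if (is.null(res$qc)) NULL else
      list(conservation_error = res$qc$error, pass = res$qc$pass),
    n_metric_rows = nrow(res$table),
    warnings = res$warnings,
    elapsed_s = elapsed)
  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(res$table, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' Run the phantom validation suites
#'
#' Recomputes every phantom metric through the pipeline and compares it
#' with the independent analytic/quadrature ground truth: affine-field
#' exactness (gradient, curl, Q), the Poiseuille velocity/vorticity
#' suite, the helical and Dean-pair helicity suites, pulsating-tube
#' stiffness arithmetic, Y-junction conservation QC, Dean number and
#' percent-predicted arithmetic, and the statistics fixtures. Determinism
#' can be checked by running it twice with the same seed.
#'
#' @param seed seed for the statistics simulations.
#' @param element_size mesh resolution for the heavy suites (cm).
#' @param quick TRUE shrinks the Poiseuille/helical meshes (coarser
#'   elements) for fast smoke runs.
#' @return data.frame with columns `suite`, `check`, `value`, `expected`,
#'   `tolerance`, `pass`.
#' @export
validate_phantoms <- function(seed = 1L, element_size = 0.12,
                              quick = FALSE) {
  if (quick) element_size <- max(element_size, 0.25)
  rows <- list()
  add <- function(suite, check, value, expected, tol) {
    pass <- if (is.na(expected)) abs(value) <= tol
            else abs(value - expected) <= tol
    rows[[length(rows) + 1L]] <<- data.frame(
      suite = suite, check = check, value = value, expected = expected,
      tolerance = tol, pass = pass, stringsAsFactors = FALSE)
  }

  # --- affine exactness: solid body and shear on a coarse tube
  for (case in c("solid_body", "shear")) {
    spec <- phantom_spec(case, R = 1, L = 4, element_size = 0.3,
                         Omega = 2, gamma = 3)
    ph <- make_tube(spec)
    field <- make_field(spec)
    nf <- resample_to_mesh(field, ph$mesh)
    gf <- velocity_gradient(nf, ph$mesh)
    gt <- ground_truth(spec)
    if (case == "solid_body") {
      wz_err <- max(abs(gf$vorticity[, 3] - gt$vorticity_everywhere)) /
        gt$vorticity_everywhere
      q_err <- max(abs(gf$Q - gt$Q_everywhere)) / gt$Q_everywhere
      add("affine", "solid_body_curl_rel_err", wz_err, NA, 1e-10)
      add("affine", "solid_body_Q_rel_err", q_err, NA, 1e-10)
    } else {
      add("affine", "shear_curl_rel_err",
          max(abs(gf$vorticity[, 3] + spec$gamma)) / spec$gamma, NA, 1e-10)
      add("affine", "shear_Q_abs", max(abs(gf$Q)), NA, 1e-10)
    }
  }

  # --- Poiseuille suite
  spec <- phantom_spec("poiseuille", R = 1, L = 10, u_max = 40,
                       element_size = element_size)
  ph <- make_tube(spec)
  field <- make_field(spec)
  gt <- ground_truth(spec)
  cl <- ph$centerlines$branches$MPA
  sl10 <- slice_at_fraction(ph$mesh, cl, 0.10, field = field)
  sl50 <- slice_at_fraction(ph$mesh, cl, 0.50, field = field)
  q <- flow_rate(sl10)$cm3_s
  add("poiseuille", "flow_cm3_s", q, gt$flow_closed_form,
      0.02 * gt$flow_closed_form)
  nf <- resample_to_mesh(field, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  wm <- branch_vorticity(gf, mode = "magnitude-mean")
  wv <- branch_vorticity(gf, mode = "vector-mean")
  add("poiseuille", "vorticity_magmean", wm,
      gt$vorticity_magmean_closed_form,
      0.03 * gt$vorticity_magmean_closed_form)
  add("poiseuille", "vorticity_vectormean_over_magmean", wv / wm, NA, 0.05)
  add("poiseuille", "centerline_velocity", centerline_velocity(sl50),
      spec$u_max, 0.02 * spec$u_max)
  add("poiseuille", "reverse_flow_fraction",
      reverse_flow_fraction(sl50), 0, 1e-12)
  hel <- helicity_metrics(nf, gf, ph$mesh)
  add("poiseuille", "HFI", hel$HFI, 0, 0.02)

  # --- helical suite
  spec <- phantom_spec("helical", R = 1, L = 10, Omega = 1, W = 1,
                       element_size = element_size)
  ph <- make_tube(spec)
  field <- make_field(spec)
  gt <- ground_truth(spec)
  nf <- resample_to_mesh(field, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  hel <- helicity_metrics(nf, gf, ph$mesh)
  add("helical", "H_d_max_rel_err",
      max(abs(hel$H_d - gt$H_d_everywhere)) / abs(gt$H_d_everywhere),
      NA, 0.01)
  add("helical", "fraction_positive", hel$fraction_positive, 1, 1e-12)
  add("helical", "HFI", hel$HFI, gt$HFI_closed_form,
      0.01 * gt$HFI_closed_form)

  # --- Dean-pair suite (mirror symmetry)
  spec <- phantom_spec("dean_pair", R = 1, L = 4, u_max = 20,
                       dean_A = 10,
                       element_size = max(element_size, 0.15))
  ph <- make_tube(spec)
  field <- make_field(spec)
  nf <- resample_to_mesh(field, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  hel <- helicity_metrics(nf, gf, ph$mesh)
  add("dean_pair", "fraction_positive", hel$fraction_positive, 0.5, 0.02)
  # mirror the field (y -> -y, u_y -> -u_y): HFI invariant
  fieldm <- mirror_field_y(field)
  meshm <- mirror_mesh_y(ph$mesh)
  nfm <- resample_to_mesh(fieldm, meshm)
  gfm <- velocity_gradient(nfm, meshm)
  helm <- helicity_metrics(nfm, gfm, meshm)
  add("dean_pair", "HFI_mirror_diff", abs(hel$HFI - helm$HFI), NA, 1e-3)

  # --- pulsating-tube stiffness
  spec <- phantom_spec("pulsating_tube", R = 1, L = 6, delta = 0.1,
                       frames = 20L, element_size = 0.25)
  ph <- make_tube(spec)
  areas <- vapply(seq_len(spec$frames), function(f)
    slice_at_fraction(ph$mesh, ph$centerlines$branches$MPA, 0.5, f)$area,
    numeric(1))
  awf <- waveform(phantom_times(spec), areas, spec$period, "area_cm2")
  st <- area_stiffness_metrics(awf, SPAP = 25, DPAP = 15)
  gt <- ground_truth(spec)
  add("stiffness", "RAC", st$RAC, gt$RAC, 0.01 * gt$RAC)
  add("stiffness", "compliance_identity",
      st$compliance - (st$A_max - st$A_min) / 10, 0, 1e-12)
  add("stiffness", "distensibility_identity",
      st$distensibility - st$RAC / 10 * 100, 0, 1e-12)

  # --- Y-junction conservation QC
  for (balanced in c(TRUE, FALSE)) {
    spec <- phantom_spec("y_junction", R = 1, L = 8, u_max = 40,
                         element_size = max(element_size, 0.2),
                         split = if (balanced) c(0.5, 0.5)
                                 else c(0.35, 0.35))
    ph <- make_y_junction(spec)
    regions <- split_branches(ph$mesh, ph$centerlines)
    qs <- vapply(c("MPA", "LPA", "RPA"), function(lbl)
      flow_rate(slice_at_fraction(
        ph$mesh, ph$centerlines$branches[[lbl]], 0.10, field = ph$field,
        elements = regions$branch[[lbl]]))$cm3_s, numeric(1))
    ce <- conservation_error(qs[["MPA"]], qs[["LPA"]], qs[["RPA"]])
    if (balanced) {
      add("y_junction", "conservation_error_balanced", ce$error, 0, 0.01)
      add("y_junction", "qc_pass_balanced", as.numeric(ce$pass), 1, 0)
    } else {
      add("y_junction", "qc_fail_imbalanced", as.numeric(ce$pass), 0, 0)
    }
  }

  # --- Dean number / percent-predicted arithmetic
  de <- 1.06 * 50 * 2 / 0.04 * sqrt(2 / (2 * 5))
  add("arithmetic", "dean_number_formula", de, 2650 * sqrt(0.2),
      1e-9 * de)
  pp <- percent_predicted_rv(55, "RVEF", "M", 60, 170, 75)
  k <- predicted_rv_constants()$RVEF
  pred <- k$m_male * 60^k$a * 170^k$b * 75^k$c
  add("arithmetic", "pct_predicted_rvef", pp, 100 * 55 / pred,
      1e-9 * pp)
  add("arithmetic", "pct_predicted_identity",
      percent_predicted_rv(pred, "RVEF", "M", 60, 170, 75), 100, 1e-9)

  # --- statistics fixtures + null calibration
  # rank fixture with sum(d^2) = 6: r = 1 - 6*6/(5*24) = 0.7
  sp <- spearman_baseline(c(1, 2, 3, 4, 5), c(3, 1, 2, 4, 5))
  add("stats", "spearman_fixture_r", sp$r, 0.7, 1e-12)
  set.seed(seed)
  reps <- 1000L
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- stats::rnorm(20)
    y <- x + stats::rnorm(20)
    if (paired_compare(x, y)$p < 0.05) hits <- hits + 1L
  }
  add("stats", "type1_error_rate", hits / reps, 0.05, 0.02)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# reflect a velocity field through the y = 0 plane (u_y flips sign)
mirror_field_y <- function(field) {
  v <- field$velocities
  ny <- dim(v)[3]
  v <- v[, , ny:1, , , drop = FALSE]
  v[, , , , 2] <- -v[, , , , 2]
  origin <- field$origin
  origin[2] <- -(field$origin[2] + (ny - 1) * field$spacing[2])
  velocity_field4d(v, origin, field$spacing, field$frame_times,
                   field$period, field$venc)
}

mirror_mesh_y <- function(mesh) {
  frames <- lapply(mesh$nodes_per_frame, function(nd) {
    nd[, 2] <- -nd[, 2]; nd
  })
  conn <- mesh$connectivity
  conn[, c(3, 4)] <- conn[, c(4, 3)]  # keep positive orientation
  time_resolved_mesh(conn, frames, mesh$frame_times)
}
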