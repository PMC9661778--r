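# I/O boundary: NIfTI velocity series, VTK meshes and centerlines,
# subject records and the metrics table, with unit/shape contracts.

test_that("velocity series round-trips bit-exactly through NIfTI + sidecar", {
  vel <- array(0, c(3, 2, 2, 2, 3))
  vel[, , , , 1] <- 10
  field <- velocity_field4d(vel, origin = c(0, 0, 0),
                            spacing = c(0.1, 0.1, 0.1),
                            frame_times = c(0, 0.2, 0.4), period = 0.8)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "v.nii.gz")
  write_velocity_series(field, p)
  back <- read_velocity_series(p, file.path(dir, "v.yaml"))
  expect_identical(dim(back$velocities), dim(field$velocities))
  expect_equal(back$velocities, field$velocities)
  expect_equal(back$spacing, field$spacing, tolerance = 1e-6)
  expect_equal(back$frame_times, field$frame_times)
})

test_that("frame-count mismatch between volumes and times is an error", {
  vel <- array(1, c(3, 2, 2, 2, 3))
  expect_error(
    velocity_field4d(vel, c(0, 0, 0), c(1, 1, 1),
                     frame_times = seq(0, 0.4, length.out = 4),
                     period = 0.8),
    "frame count mismatch")
  dir <- withr::local_tempdir()
  field <- velocity_field4d(vel, c(0, 0, 0), c(1, 1, 1), c(0, 0.2, 0.4),
                            0.8)
  p <- file.path(dir, "v.nii.gz")
  write_velocity_series(field, p)
  meta <- yaml::read_yaml(file.path(dir, "v.yaml"))
  meta$frame_times <- seq(0, 0.5, length.out = 20)  # 20 times, 3 volumes
  expect_error(read_velocity_series(p, meta), "frame count mismatch")
})

test_that("field invariants are enforced and venc violations warn", {
  vel <- array(1, c(1, 2, 2, 2, 3))
  expect_error(velocity_field4d(vel, c(0, 0, 0), c(1, -1, 1), 0, 1),
               "spacing")
  expect_error(velocity_field4d(vel, c(0, 0, 0), c(1, 1, 1), 1.2, 1),
               "period")
  vel[1, 1, 1, 1, 1] <- 500
  expect_warning(velocity_field4d(vel, c(0, 0, 0), c(1, 1, 1), 0, 1,
                                  venc = 160),
                 "exceed venc")
})

test_that("phantom written to disk reads back equal to the generator output", {
  spec <- phantom_spec("poiseuille", R = 1, L = 3, element_size = 0.3,
                       spacing = 0.15)
  field <- make_field(spec)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "v.nii.gz")
  write_velocity_series(field, p)
  back <- read_velocity_series(p, file.path(dir, "v.yaml"))
  expect_equal(back$velocities, field$velocities, tolerance = 1e-12)
})

test_that("unit conversion cm/s <-> m/s is involutive", {
  vel <- array(rnorm(2 * 8 * 3), c(2, 2, 2, 2, 3))
  field <- velocity_field4d(vel, c(0, 0, 0), c(1, 1, 1), c(0, 0.3), 0.8)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "v.nii.gz")
  write_velocity_series(field, p)
  meta <- yaml::read_yaml(file.path(dir, "v.yaml"))
  meta$velocity_units <- "m/s"       # pretend the file stores m/s
  up <- read_velocity_series(p, meta)
  expect_equal(up$velocities, field$velocities * 100, tolerance = 1e-12)
  expect_equal(up$velocities / 100, field$velocities, tolerance = 1e-15)
})

test_that("mesh series round-trips through .vtu with units in mm", {
  cube <- unit_cube_tets()
  mesh <- time_resolved_mesh(cube$tets, rep(list(cube$nodes), 5),
                             frame_times = (0:4) / 10)
  dir <- withr::local_tempdir()
  paths <- write_mesh_series(mesh, dir, "m")
  expect_length(paths, 5)
  back <- read_mesh_series(paths, frame_times = (0:4) / 10)
  expect_equal(length(back$nodes_per_frame), 5)
  for (f in 1:5) expect_equal(mesh_volume(back, f), 1.0, tolerance = 1e-12)
  expect_identical(back$connectivity, mesh$connectivity)
})

test_that("inverted tetrahedra are rejected with the offending element", {
  cube <- unit_cube_tets()
  bad <- cube$tets
  bad[3, c(1, 2)] <- bad[3, c(2, 1)]
  expect_error(time_resolved_mesh(bad, list(cube$nodes), 0),
               "tetrahedron 3")
  mesh5 <- lapply(1:2, function(i) cube$nodes)
  expect_error(time_resolved_mesh(cube$tets,
                                  list(cube$nodes, cube$nodes[-1, ]),
                                  0:1),
               "node count differs")
})

test_that("centerlines round-trip with labels, radii and arc length", {
  cl <- centerline_set(
    list(MPA = cbind(0, 0, c(0, 5, 10)),
         LPA = cbind(c(0, 1, 2, 3), 0, 10)),
    radii = list(MPA = c(1, 1, 1), LPA = rep(0.7, 4)))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cl.vtp")
  write_centerlines(cl, p)
  back <- read_centerlines(p)
  expect_named(back$branches, c("MPA", "LPA"))
  expect_equal(arc_length(back$branches$MPA), c(0, 5, 10),
               tolerance = 1e-9)
  expect_equal(back$radii$LPA, rep(0.7, 4), tolerance = 1e-9)
})

test_that("degenerate centerlines are rejected or repaired", {
  expect_error(centerline_set(list(A = cbind(0, 0, c(0, 1)))),
               "fewer than 3 points")
  expect_warning(
    cl <- centerline_set(list(A = cbind(0, 0, c(0, 1, 1, 2)))),
    "duplicate consecutive")
  expect_equal(nrow(cl$branches$A), 3)
  df <- list(cbind(0, 0, 0:3), cbind(0, 0, 0:3))
  names(df) <- c("MPA", "MPA")
  expect_error(centerline_set(df), "duplicate branch label")
})

test_that("quarter-circle arc length matches pi * R / 2", {
  th <- seq(0, pi / 2, length.out = 100)
  s <- arc_length(cbind(5 * cos(th), 5 * sin(th), 0))
  expect_equal(s[100], 5 * pi / 2, tolerance = 1e-3 * 5 * pi / 2)
})

test_that("metrics table round-trips exactly, rejects duplicate keys", {
  one <- metrics_table(data.frame(
    subject = "P1", timepoint = "pre", branch = "MPA", metric = "flow",
    window = "cycle", statistic = "mean", value = 3.7441, units = "L/min"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  write_metrics_table(one, p)
  expect_equal(as.data.frame(read_metrics_table(p)), as.data.frame(one))

  empty <- metrics_table()
  write_metrics_table(empty, p)
  expect_equal(nrow(read_metrics_table(p)), 0)

  set.seed(42)
  big <- metrics_table(data.frame(
    subject = rep(sprintf("P%02d", 1:50), each = 20),
    timepoint = "pre", branch = "MPA",
    metric = rep(sprintf("m%02d", 1:20), 50),
    window = "cycle", statistic = "mean",
    value = rnorm(1000), units = "x"))
  write_metrics_table(big, p)
  expect_equal(read_metrics_table(p)$value, big$value, tolerance = 1e-12)

  dup <- rbind(one, one)
  expect_error(metrics_table(dup), "duplicate")
})

test_that("subject records validate demographic and pressure constraints", {
  good <- data.frame(id = "P1", timepoint = "pre", sex = "M", age = 60,
                     height = 170, weight = 75, SPAP = 25, DPAP = 15)
  expect_s3_class(subject_records(good), "subject_records")
  bad <- good; bad$SPAP <- 10
  expect_error(subject_records(bad), "SPAP")
  bad <- good; bad$weight <- -1
  expect_error(subject_records(bad), "weight")
})
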