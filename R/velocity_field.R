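#' Time-resolved 3D velocity field on a regular grid
#'
#' Container for a 4D flow velocity dataset: a dense array of velocity
#' vectors sampled at the nodes of a regular Cartesian grid, one grid per
#' cardiac frame. All lengths are stored in cm, velocities in cm/s and
#' times in s. The grid is treated as node-centered samples: the sample at
#' index `(i, j, k)` (0-based) sits at `origin + c(i, j, k) * spacing`.
#'
#' @param velocities numeric array with dimensions
#'   `(n_frames, nx, ny, nz, 3)`, components ordered x, y, z in world axes,
#'   units cm/s.
#' @param origin numeric length-3, world position of voxel (0,0,0), cm.
#' @param spacing numeric length-3, strictly positive grid step per axis, cm.
#' @param frame_times numeric, strictly increasing frame times in s, all
#'   `< period`.
#' @param period cardiac cycle length in s.
#' @param venc optional velocity-encoding limit in cm/s; component
#'   magnitudes beyond it are reported with a warning (velocity aliasing is
#'   corrected upstream and is out of scope here).
#' @return An object of class `velocity_field4d`.
#' @export
velocity_field4d <- function(velocities, origin, spacing, frame_times,
                             period, venc = NULL) {
  stopifnot(is.array(velocities), length(dim(velocities)) == 5L)
  d <- dim(velocities)
  if (d[5] != 3L) stop("velocities must have 3 components in the last axis")
  if (length(frame_times) != d[1])
    stop("frame count mismatch: ", d[1], " volumes but ",
         length(frame_times), " frame times")
  if (any(d[2:4] < 2L)) stop("grid must have >= 2 samples per axis")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (any(frame_times >= period)) stop("all frame_times must be < period")
  if (!is.null(venc)) {
    n_clip <- sum(abs(velocities) > venc + 1e-9)
    if (n_clip > 0)
      warning(sprintf("%d velocity samples exceed venc = %g cm/s", n_clip,
                      venc))
  }
  structure(list(
    velocities = velocities,
    origin = origin, spacing = spacing,
    dims = as.integer(d[2:4]),
    frame_times = as.numeric(frame_times),
    period = as.numeric(period),
    venc = if (is.null(venc)) NULL else as.numeric(venc)
  ), class = "velocity_field4d")
}

#' @export
print.velocity_field4d <- function(x, ...) {
  cat("<velocity_field4d>\n")
  cat("  grid:", paste(x$dims, collapse = " x "),
      " spacing (cm):", paste(signif(x$spacing, 4), collapse = ", "), "\n")
  cat("  frames:", length(x$frame_times),
      " period:", x$period, "s\n")
  if (!is.null(x$venc)) cat("  venc:", x$venc, "cm/s\n")
  invisible(x)
}

#' @export
dim.velocity_field4d <- function(x) dim(x$velocities)

# nearest velocity frame index for a time t (periodic)
nearest_frame <- function(field, t) {
  dt <- abs(field$frame_times - (t %% field$period))
  dt2 <- abs(field$frame_times - (t %% field$period) + field$period)
  which.min(pmin(dt, dt2))
}

#' Sample a velocity field at arbitrary points
#'
#' Trilinear interpolation of one cardiac frame at a set of world points.
#' Trilinear interpolation reproduces any affine field exactly; for smooth
#' fields the error is second order in the grid spacing.
#'
#' @param field a [velocity_field4d()].
#' @param points numeric matrix `n x 3` of world coordinates (cm).
#' @param frame frame index (1-based).
#' @param outside `"zero"` (fill with 0 and warn with a count) or
#'   `"error"`.
#' @return numeric matrix `n x 3` of velocities (cm/s).
#' @export
sample_velocity <- function(field, points, frame = 1L,
                            outside = c("zero", "error")) {
  outside <- match.arg(outside)
  points <- rbind(points)  # tolerate a single point as a vector
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  n <- nrow(points)
  dims <- field$dims
  # continuous voxel coordinates (0-based)
  tx <- (points[, 1] - field$origin[1]) / field$spacing[1]
  ty <- (points[, 2] - field$origin[2]) / field$spacing[2]
  tz <- (points[, 3] - field$origin[3]) / field$spacing[3]
  eps <- 1e-9
  out <- tx < -eps | ty < -eps | tz < -eps |
    tx > dims[1] - 1 + eps | ty > dims[2] - 1 + eps | tz > dims[3] - 1 + eps
  if (any(out)) {
    if (outside == "error")
      stop(sum(out), " sample points fall outside the velocity grid")
    warning(sum(out), " sample points outside the velocity grid; zero-filled")
  }
  i0 <- pmin(pmax(floor(tx), 0), dims[1] - 2)
  j0 <- pmin(pmax(floor(ty), 0), dims[2] - 2)
  k0 <- pmin(pmax(floor(tz), 0), dims[3] - 2)
  wx <- pmin(pmax(tx - i0, 0), 1)
  wy <- pmin(pmax(ty - j0, 0), 1)
  wz <- pmin(pmax(tz - k0, 0), 1)
  res <- matrix(0, n, 3)
  vol <- field$velocities[frame, , , , , drop = TRUE]  # nx x ny x nz x 3
  dim(vol) <- c(dims, 3L)
  for (comp in 1:3) {
    v <- vol[, , , comp, drop = TRUE]
    dim(v) <- dims
    acc <- numeric(n)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
        (if (dz) wz else 1 - wz)
      acc <- acc + w * v[cbind(i0 + dx + 1, j0 + dy + 1, k0 + dz + 1)]
    }
    res[, comp] <- acc
  }
  res[out, ] <- 0
  res
}

#' Read a time-resolved velocity field from NIfTI volumes
#'
#' Two on-disk dialects are accepted: (i) one scalar NIfTI volume per
#' component per frame, ordered frame-major (`paths` of length
#' `n_frames * 3`, component fastest), or (ii) a single 5-D NIfTI with axes
#' `(x, y, z, frame, component)`. A YAML sidecar carries the acquisition
#' metadata that NIfTI headers do not: frame times, cycle length, input
#' velocity units, component order and optionally venc and the grid origin.
#'
#' @param paths character vector of NIfTI file paths (dialect i) or a
#'   single path (dialect ii).
#' @param metadata path to a YAML sidecar, or an equivalent named list with
#'   elements `frame_times` (s), `period` (s), optional `velocity_units`
#'   (`"cm/s"` or `"m/s"`, default `"cm/s"`), optional `component_order`
#'   (default `c("x","y","z")`), optional `venc` (cm/s), optional
#'   `origin_mm`.
#' @return a [velocity_field4d()].
#' @export
read_velocity_series <- function(paths, metadata) {
  meta <- if (is.character(metadata)) yaml::read_yaml(metadata) else metadata
  if (is.null(meta$frame_times) || is.null(meta$period))
    stop("metadata must provide frame_times and period")
  ft <- as.numeric(meta$frame_times)
  units <- if (is.null(meta$velocity_units)) "cm/s" else meta$velocity_units
  scale <- switch(units, "cm/s" = 1, "m/s" = 100,
                  stop("unsupported velocity_units: ", units))
  comp_order <- if (is.null(meta$component_order)) c("x", "y", "z")
                else meta$component_order
  perm <- match(c("x", "y", "z"), comp_order)
  if (anyNA(perm)) stop("component_order must name x, y and z")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing velocity file(s): ",
                            paste(missing, collapse = ", "))
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    a <- as.array(img)
    if (length(dim(a)) != 5L || dim(a)[5] != 3L)
      stop("single-file dialect requires a 5-D volume (x,y,z,frame,component)")
    nt <- dim(a)[4]
    if (nt != length(ft))
      stop("frame count mismatch: ", nt, " volumes but ", length(ft),
           " frame times")
    vel <- aperm(a, c(4, 1, 2, 3, 5))[, , , , perm, drop = FALSE]
    pix <- RNifti::pixdim(img)[1:3]
  } else {
    nt <- length(ft)
    if (length(paths) != nt * 3L)
      stop("expected ", nt * 3L, " component volumes (", nt,
           " frames x 3 components), got ", length(paths))
    first <- RNifti::readNifti(paths[1])
    dims <- dim(as.array(first))[1:3]
    pix <- RNifti::pixdim(first)[1:3]
    vel <- array(0, c(nt, dims, 3L))
    for (f in seq_len(nt)) for (c_in in 1:3) {
      img <- RNifti::readNifti(paths[(f - 1) * 3 + c_in])
      a <- as.array(img)
      if (!identical(dim(a)[1:3], dims))
        stop("grid mismatch in ", paths[(f - 1) * 3 + c_in])
      if (max(abs(RNifti::pixdim(img)[1:3] - pix)) > 1e-6)
        stop("voxel spacing mismatch in ", paths[(f - 1) * 3 + c_in])
      vel[f, , , , which(perm == c_in)] <- a
    }
  }
  origin_mm <- if (is.null(meta$origin_mm)) c(0, 0, 0)
               else as.numeric(meta$origin_mm)
  velocity_field4d(vel * scale,
                   origin = origin_mm / 10,  # mm -> cm
                   spacing = pix / 10,
                   frame_times = ft, period = as.numeric(meta$period),
                   venc = meta$venc)
}

#' Write a velocity field as a 5-D NIfTI plus YAML sidecar
#'
#' Inverse of the single-file dialect of [read_velocity_series()].
#'
#' @param field a [velocity_field4d()].
#' @param path output NIfTI path (`.nii` / `.nii.gz`).
#' @param sidecar output YAML path; defaults to `path` with extension
#'   replaced by `.yaml`.
#' @return invisibly, the sidecar path.
#' @export
write_velocity_series <- function(field, path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
  a <- aperm(field$velocities, c(2, 3, 4, 1, 5))
  img <- RNifti::asNifti(a)
  img <- RNifti::`pixdim<-`(img, field$spacing * 10)  # cm -> mm
  RNifti::writeNifti(img, path)
  meta <- list(frame_times = field$frame_times, period = field$period,
               velocity_units = "cm/s", component_order = c("x", "y", "z"),
               origin_mm = field$origin * 10)
  if (!is.null(field$venc)) meta$venc <- field$venc
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}
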