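# Analytic flow phantoms: tube and Y-junction tetrahedral meshes with
# exact centerlines, voxelized analytic velocity fields, and independent
# dense-quadrature ground truth for every metric. These phantoms are the
# validation surface for the whole pipeline.

#' Phantom specification
#'
#' Geometry, flow and grid parameters for the analytic phantom cases.
#' Defaults mirror a typical 4D flow acquisition: ~1 mm voxels, 20 frames
#' per cycle, 1.2 mm tetrahedral elements.
#'
#' @param case one of `"poiseuille"`, `"solid_body"`, `"helical"`,
#'   `"shear"`, `"dean_pair"`, `"pulsating_tube"`, `"y_junction"`.
#' @param R tube radius (cm).
#' @param L tube length (cm).
#' @param Rc centerline radius of curvature (cm); `Inf` = straight.
#' @param element_size tetrahedral target edge length (cm).
#' @param u_max peak axial velocity (cm/s) for Poiseuille-type cases.
#' @param Omega solid-body rotation rate (1/s).
#' @param W axial velocity of the helical case (cm/s).
#' @param gamma shear rate (1/s).
#' @param delta pulsating-tube radial amplitude (fraction of R).
#' @param dean_A in-plane stream-function amplitude of the Dean pair
#'   (cm^2/s).
#' @param frames number of cardiac frames (1 = steady; time-resolved
#'   cases need >= 4).
#' @param period cycle length (s).
#' @param spacing voxel spacing (cm).
#' @param margin grid margin beyond the mesh bounding box (cm).
#' @param split daughter flow fractions for the Y-junction (sums to 1 for
#'   a mass-conserving phantom; a deficit models unbalanced outlets).
#' @param daughter_R daughter tube radius (cm) for the Y-junction.
#' @param noise_sd additive Gaussian velocity noise, cm/s (0 = off).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(case = "poiseuille", R = 1, L = 10, Rc = Inf,
                         element_size = 0.12, u_max = 40, Omega = 1,
                         W = 1, gamma = 3, delta = 0.1, dean_A = 10,
                         frames = 1L, period = 1.0, spacing = 0.1,
                         margin = 0.3, split = c(0.5, 0.5),
                         daughter_R = 0.75, noise_sd = 0, seed = 1L) {
  case <- match.arg(case, c("poiseuille", "solid_body", "helical", "shear",
                            "dean_pair", "pulsating_tube", "y_junction"))
  stopifnot(element_size > 0, R > 0, L > 0, spacing > 0)
  if (is.finite(Rc) && Rc <= R) stop("Rc <= R gives a self-intersecting torus")
  if (case == "pulsating_tube" && frames < 4)
    stop("time-resolved cases need frames >= 4")
  structure(as.list(environment()), class = "phantom_spec")
}

# frame times: evenly spaced over the cycle, first frame at t = 0
phantom_times <- function(spec)
  seq(0, spec$period, length.out = spec$frames + 1L)[seq_len(spec$frames)]

# ---------------------------------------------------------------------------
# disc triangulation (concentric rings) + prism extrusion

# triangulate the strip between two concentric point rings by angular merge
stitch_rings <- function(inner, inner_ang, outer, outer_ang) {
  n <- length(inner); m <- length(outer)
  tris <- matrix(0L, n + m, 3)
  ai <- 1L; ak <- 1L; row <- 0L
  next_ang <- function(ang, idx, len) if (idx <= len) ang[idx] else ang[1] + 2 * pi
  while (ai <= n || ak <= m) {
    adv_inner <- next_ang(inner_ang, ai + 1L, n)
    adv_outer <- next_ang(outer_ang, ak + 1L, m)
    row <- row + 1L
    if (ak <= m && (ai > n || adv_outer <= adv_inner)) {
      tris[row, ] <- c(inner[(ai - 1L) %% n + 1L],
                       outer[(ak - 1L) %% m + 1L],
                       outer[ak %% m + 1L])
      ak <- ak + 1L
    } else {
      tris[row, ] <- c(inner[(ai - 1L) %% n + 1L],
                       outer[(ak - 1L) %% m + 1L],
                       inner[ai %% n + 1L])
      ai <- ai + 1L
    }
  }
  tris[seq_len(row), , drop = FALSE]
}

# unit-disc style triangulation of a disc of radius R, target edge h
disc_mesh <- function(R, h) {
  m <- max(2L, round(R / h))
  pts <- matrix(0, 1, 2)   # center
  ring_idx <- list(1L); ring_ang <- list(0)
  for (j in seq_len(m)) {
    nj <- 6L * j
    ang <- 2 * pi * (seq_len(nj) - 1L) / nj
    idx <- nrow(pts) + seq_len(nj)
    pts <- rbind(pts, cbind(j * R / m * cos(ang), j * R / m * sin(ang)))
    ring_idx[[j + 1L]] <- idx
    ring_ang[[j + 1L]] <- ang
  }
  tris <- list()
  # center fan
  r1 <- ring_idx[[2]]
  tris[[1]] <- cbind(1L, r1, c(r1[-1], r1[1]))
  for (j in 2:m)
    tris[[j]] <- stitch_rings(ring_idx[[j]], ring_ang[[j]],
                              ring_idx[[j + 1L]], ring_ang[[j + 1L]])
  list(points = pts, triangles = do.call(rbind, tris),
       boundary = ring_idx[[m + 1L]])
}

# split an extruded prism stack into conforming tets (min-index diagonals)
extrude_to_tets <- function(disc, L, h) {
  np <- nrow(disc$points)
  nz <- max(1L, round(L / h))
  zs <- seq(0, L, length.out = nz + 1L)
  nodes <- cbind(disc$points[rep(seq_len(np), nz + 1L), , drop = FALSE],
                 rep(zs, each = np))
  tets <- matrix(0L, nrow(disc$triangles) * nz * 3L, 4L)
  row <- 0L
  for (l in seq_len(nz)) {
    base <- (l - 1L) * np
    for (t in seq_len(nrow(disc$triangles))) {
      tri <- sort(disc$triangles[t, ])      # a < b < c by disc index
      A0 <- base + tri[1]; B0 <- base + tri[2]; C0 <- base + tri[3]
      A1 <- A0 + np; B1 <- B0 + np; C1 <- C0 + np
      tets[row + 1L, ] <- c(A0, B0, C0, C1)
      tets[row + 2L, ] <- c(A0, B0, C1, B1)
      tets[row + 3L, ] <- c(A0, B1, C1, A1)
      row <- row + 3L
    }
  }
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  list(nodes = nodes, tets = tets, n_layers = nz, n_disc = np)
}

# bend a straight tube (axis z) onto a torus arc of radius Rc in the x-z
# plane; preserves volume exactly in the continuum (Pappus)
bend_tube <- function(nodes, Rc) {
  theta <- nodes[, 3] / Rc
  x <- nodes[, 1]
  cbind(Rc - (Rc - x) * cos(theta), nodes[, 2], (Rc - x) * sin(theta))
}

#' Build a tube phantom mesh and its centerline
#'
#' Straight or torus-bent tube, tetrahedralized at the requested element
#' size by extruding a concentric-ring disc triangulation (conforming
#' prism split). The pulsating case scales the cross-section per frame:
#' `r(t) = R (1 + delta sin(2 pi t / period))`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (a [time_resolved_mesh()]) and `centerlines`
#'   (a [centerline_set()] with one branch labeled `"MPA"`).
#' @export
make_tube <- function(spec) {
  disc <- disc_mesh(spec$R, spec$element_size)
  ex <- extrude_to_tets(disc, spec$L, spec$element_size)
  times <- phantom_times(spec)
  if (spec$case == "pulsating_tube") {
    frames <- lapply(times, function(t) {
      s <- 1 + spec$delta * sin(2 * pi * t / spec$period)
      cbind(ex$nodes[, 1] * s, ex$nodes[, 2] * s, ex$nodes[, 3])
    })
  } else if (is.finite(spec$Rc)) {
    frames <- rep(list(bend_tube(ex$nodes, spec$Rc)), length(times))
  } else {
    frames <- rep(list(ex$nodes), length(times))
  }
  mesh <- time_resolved_mesh(ex$tets, frames, times)
  ncl <- max(33L, 2L * round(spec$L / spec$element_size) + 1L)
  zc <- seq(0, spec$L, length.out = ncl)
  cl_pts <- cbind(0, 0, zc)
  if (is.finite(spec$Rc) && spec$case != "pulsating_tube")
    cl_pts <- bend_tube(cl_pts, spec$Rc)
  cl <- centerline_set(list(MPA = cl_pts),
                       radii = list(MPA = rep(spec$R, ncl)))
  list(mesh = mesh, centerlines = cl)
}

# ---------------------------------------------------------------------------
# analytic velocity fields

#' Evaluate a phantom's analytic velocity at arbitrary points
#'
#' Direct evaluation of the case's defining formula (single frame, unit
#' temporal amplitude); used as the independent reference against the
#' voxelized/resampled path.
#'
#' @param spec a [phantom_spec()].
#' @param pts `n x 3` points (cm).
#' @return `n x 3` velocities (cm/s).
#' @export
analytic_velocity <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  r2 <- x^2 + y^2
  R2 <- spec$R^2
  u <- matrix(0, nrow(pts), 3)
  # fields are the smooth analytic extensions (no wall mask): the mesh
  # only samples inside the tube, and a smooth field keeps trilinear
  # sampling second-order accurate right up to the wall
  switch(spec$case,
    poiseuille = , pulsating_tube = {
      u[, 3] <- spec$u_max * (1 - r2 / R2)
    },
    solid_body = {
      u[, 1] <- -spec$Omega * y
      u[, 2] <- spec$Omega * x
    },
    helical = {
      u[, 1] <- -spec$Omega * y
      u[, 2] <- spec$Omega * x
      u[, 3] <- spec$W
    },
    shear = {
      u[, 1] <- spec$gamma * y
    },
    dean_pair = {
      # axial Poiseuille plug + mirror-symmetric in-plane vortex pair
      # from stream function psi = A y (1 - r^2/R^2)^2
      s <- 1 - r2 / R2
      A <- spec$dean_A
      u[, 1] <- A * s * (s - 4 * y^2 / R2)
      u[, 2] <- 4 * A * x * y * s / R2
      u[, 3] <- spec$u_max * (1 - r2 / R2)
    },
    stop("no analytic field for case ", spec$case))
  u
}

#' Analytic vorticity (curl) of a phantom field
#'
#' Closed forms where they exist; the Dean pair uses central differences
#' of the analytic field (still independent of the mesh pipeline).
#'
#' @inheritParams analytic_velocity
#' @return `n x 3` vorticity vectors (1/s).
#' @export
analytic_vorticity <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  r2 <- x^2 + y^2
  R2 <- spec$R^2
  om <- matrix(0, nrow(pts), 3)
  switch(spec$case,
    poiseuille = , pulsating_tube = {
      om[, 1] <- -2 * spec$u_max * y / R2
      om[, 2] <- 2 * spec$u_max * x / R2
    },
    solid_body = , helical = { om[, 3] <- 2 * spec$Omega },
    shear = { om[, 3] <- -spec$gamma },
    dean_pair = {
      h <- 1e-4
      for (d in 1:3) {
        e <- diag(3)[d, ]
        up <- analytic_velocity(spec, pts + rep(e * h, each = nrow(pts)))
        dn <- analytic_velocity(spec, pts - rep(e * h, each = nrow(pts)))
        der <- (up - dn) / (2 * h)   # d u / d x_d
        if (d == 1) { om[, 2] <- om[, 2] - der[, 3]; om[, 3] <- om[, 3] + der[, 2] }
        if (d == 2) { om[, 1] <- om[, 1] + der[, 3]; om[, 3] <- om[, 3] - der[, 1] }
        if (d == 3) { om[, 1] <- om[, 1] - der[, 2]; om[, 2] <- om[, 2] + der[, 1] }
      }
    },
    stop("no analytic vorticity for case ", spec$case))
  om
}

# temporal modulation: steady cases are constant; the pulsating tube
# scales velocity by a half-sine systolic waveform
phantom_time_scale <- function(spec, t) {
  if (spec$case != "pulsating_tube" || spec$frames == 1L) return(1)
  t_sys <- 0.4 * spec$period
  ifelse(t < t_sys, sin(pi * t / t_sys), 0)
}

#' Voxelize a phantom's analytic velocity field
#'
#' Samples the analytic field on a regular grid covering the bounding box
#' (plus margin) and returns it as a [velocity_field4d()]. Optional
#' additive Gaussian noise is seeded from the phantom specification.
#'
#' @param spec a [phantom_spec()].
#' @param bbox `2 x 3` matrix (min row, max row) in cm; default: the
#'   tube's own bounding box.
#' @return a [velocity_field4d()].
#' @export
make_field <- function(spec, bbox = NULL) {
  if (is.null(bbox)) {
    r_max <- spec$R * (1 + max(0, spec$delta) *
                         (spec$case == "pulsating_tube"))
    bbox <- rbind(c(-r_max, -r_max, 0), c(r_max, r_max, spec$L))
    if (is.finite(spec$Rc) && spec$case != "pulsating_tube") {
      th <- spec$L / spec$Rc
      xs <- spec$Rc - (spec$Rc + c(-spec$R, spec$R)) %o% cos(seq(0, th, length.out = 50))
      zs <- (spec$Rc + c(-spec$R, spec$R)) %o% sin(seq(0, th, length.out = 50))
      bbox <- rbind(c(min(xs), -spec$R, min(0, min(zs))),
                    c(max(xs), spec$R, max(zs)))
    }
  }
  lo <- bbox[1, ] - spec$margin; hi <- bbox[2, ] + spec$margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  if (any((hi - lo) / spec$spacing < 6) && spec$case != "shear")
    warning("fewer than 6 voxels across the phantom diameter")
  ax <- lapply(1:3, function(d) lo[d] + spec$spacing * (seq_len(dims[d]) - 1L))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  times <- phantom_times(spec)
  u1 <- analytic_velocity(spec, pts)
  vel <- array(0, c(spec$frames, dims, 3L))
  if (spec$noise_sd > 0) set.seed(spec$seed)
  for (f in seq_along(times)) {
    uf <- u1 * phantom_time_scale(spec, times[f])
    if (spec$noise_sd > 0)
      uf <- uf + matrix(stats::rnorm(length(uf), sd = spec$noise_sd),
                        ncol = 3)
    for (comp in 1:3)
      vel[f, , , , comp] <- array(uf[, comp], dims)
  }
  velocity_field4d(vel, origin = lo, spacing = rep(spec$spacing, 3),
                   frame_times = times, period = spec$period)
}

# rigid transform helper: rotate tube axis (z) onto direction d and shift
orient_tube <- function(nodes, direction, origin_pt) {
  d <- direction / sqrt(sum(direction^2))
  # rotation taking z to d (Rodrigues; handles d ~ z)
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (sqrt(sum(v^2)) < 1e-12) {
    Rm <- if (c_ > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    Rm <- diag(3) + vx + vx %*% vx / (1 + c_)
  }
  sweep(nodes %*% t(Rm), 2, -origin_pt)
}

#' Build the Y-junction phantom
#'
#' A symmetric planar Y: a parent tube (MPA, radius `R`) flowing in +z
#' into two daughters (LPA/RPA, radius `daughter_R`) at +/-45 degrees.
#' The analytic flow is a mass-conserving piecewise-Poiseuille split:
#' `Q_parent * split[i]` through daughter `i` (a `split` summing below 1
#' models flow loss for the conservation QC failure case). Centerlines
#' are ordered cap to bifurcation.
#'
#' @param spec a [phantom_spec()] with `case = "y_junction"`.
#' @return list with `mesh`, `centerlines`, `field`, and `flows`
#'   (analytic branch flows, cm^3/s).
#' @export
make_y_junction <- function(spec) {
  h <- spec$element_size
  Lp <- spec$L / 2; Ld <- spec$L / 2
  rd <- spec$daughter_R
  phi <- pi / 4
  dirs <- list(LPA = c(sin(phi), 0, cos(phi)),
               RPA = c(-sin(phi), 0, cos(phi)))
  if (sum(abs(spec$split)) > 1 + 1e-9)
    stop("daughter flow fractions cannot exceed 1")

  # parent: axis z from -Lp (cap) to 0
  disc_p <- disc_mesh(spec$R, h)
  ex_p <- extrude_to_tets(disc_p, Lp, h)
  nodes_p <- cbind(ex_p$nodes[, 1:2], ex_p$nodes[, 3] - Lp)
  # daughters: from origin outward along dirs
  disc_d <- disc_mesh(rd, h)
  ex_d <- extrude_to_tets(disc_d, Ld, h)
  all_nodes <- nodes_p; all_tets <- ex_p$tets
  for (lbl in names(dirs)) {
    nd <- orient_tube(ex_d$nodes, dirs[[lbl]], c(0, 0, 0))
    all_tets <- rbind(all_tets, ex_d$tets + nrow(all_nodes))
    all_nodes <- rbind(all_nodes, nd)
  }
  v <- tet_volumes(all_nodes, all_tets)
  all_tets[v < 0, c(3, 4)] <- all_tets[v < 0, c(4, 3)]
  times <- phantom_times(spec)
  mesh <- time_resolved_mesh(all_tets, rep(list(all_nodes), length(times)),
                             times)
  ncl <- 41L
  cls <- list(
    MPA = cbind(0, 0, seq(-Lp, 0, length.out = ncl)),
    LPA = t(vapply(seq(Ld, 0, length.out = ncl),
                   function(s) s * dirs$LPA, numeric(3))),
    RPA = t(vapply(seq(Ld, 0, length.out = ncl),
                   function(s) s * dirs$RPA, numeric(3))))
  cl <- centerline_set(cls, radii = list(MPA = rep(spec$R, ncl),
                                         LPA = rep(rd, ncl),
                                         RPA = rep(rd, ncl)))

  Q_parent <- spec$u_max * pi * spec$R^2 / 2
  Q_d <- spec$split * Q_parent
  u_max_d <- 2 * Q_d / (pi * rd^2)

  # voxelized piecewise field
  pad <- spec$margin
  lo <- c(-max(spec$R, Ld * sin(phi) + rd), -max(spec$R, rd), -Lp) - pad
  hi <- c(max(spec$R, Ld * sin(phi) + rd), max(spec$R, rd),
          Ld * cos(phi) + rd) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  ax <- lapply(1:3, function(d) lo[d] + spec$spacing * (seq_len(dims[d]) - 1L))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  # piecewise-smooth analytic split: the parent parabola fills z <= 0,
  # each half-space x >< 0 above the junction carries its daughter's
  # parabola (smooth within each region, so trilinear sampling on the
  # branch meshes stays second-order; the region seams lie inside the
  # excluded bifurcation zone)
  u <- matrix(0, nrow(pts), 3)
  r2p <- pts[, 1]^2 + pts[, 2]^2
  in_parent <- pts[, 3] <= 0
  u[in_parent, 3] <- spec$u_max * (1 - r2p[in_parent] / spec$R^2)
  for (i in seq_along(dirs)) {
    d <- dirs[[i]]
    tcoord <- pts %*% d
    radial2 <- pmax(rowSums(pts^2) - tcoord^2, 0)
    in_d <- !in_parent & (if (i == 1) pts[, 1] >= 0 else pts[, 1] < 0)
    prof <- u_max_d[i] * (1 - radial2[in_d] / rd^2)
    u[in_d, ] <- outer(as.numeric(prof), d)
  }
  vel <- array(0, c(length(times), dims, 3L))
  for (f in seq_along(times)) for (comp in 1:3)
    vel[f, , , , comp] <- array(u[, comp], dims)
  field <- velocity_field4d(vel, origin = lo,
                            spacing = rep(spec$spacing, 3),
                            frame_times = times, period = spec$period)
  list(mesh = mesh, centerlines = cl, field = field,
       flows = c(MPA = Q_parent, LPA = Q_d[1], RPA = Q_d[2]))
}

#' Independent ground-truth metric values for a phantom
#'
#' Reference values computed directly from the analytic field definitions
#' by dense quadrature (a polar product grid with >= 10^6 sample points
#' over the tube volume) and closed forms — never through the mesh
#' pipeline. Used as the oracle in the validation suites.
#'
#' @param spec a [phantom_spec()] for an analytic case.
#' @return named list of reference values (flow, vorticity means, HFI,
#'   fraction of positive helicity, Q, RAC, ...).
#' @export
ground_truth <- function(spec) {
  if (spec$case == "y_junction")
    stop("use make_y_junction()$flows for the junction phantom")
  nr <- 250L; nth <- 256L; nzq <- 16L
  r_mid <- (seq_len(nr) - 0.5) / nr * spec$R
  th <- (seq_len(nth) - 0.5) / nth * 2 * pi
  zq <- (seq_len(nzq) - 0.5) / nzq * spec$L
  g2 <- expand.grid(r = r_mid, th = th)
  w2 <- g2$r * (spec$R / nr) * (2 * pi / nth)      # area weights
  xy <- cbind(g2$r * cos(g2$th), g2$r * sin(g2$th))
  out <- list(case = spec$case)
  # cross-sectional quantities (z-invariant cases: sample one plane)
  pts2 <- cbind(xy, spec$L / 2)
  u2 <- analytic_velocity(spec, pts2)
  om2 <- analytic_vorticity(spec, pts2)
  out$flow_cm3_s <- sum(u2[, 3] * w2)
  out$mean_axial_velocity <- out$flow_cm3_s / (pi * spec$R^2)
  out$max_speed <- max(sqrt(rowSums(u2^2)))
  om_mag <- sqrt(rowSums(om2^2))
  out$vorticity_magmean <- sum(om_mag * w2) / sum(w2)
  out$vorticity_vectormean <- sqrt(sum((colSums(om2 * w2) / sum(w2))^2))
  H_d <- rowSums(u2 * om2)
  out$fraction_positive <- sum(w2[H_d > 0]) / sum(w2)
  mag <- sqrt(rowSums(u2^2)) * om_mag
  ok <- mag >= 1e-12
  out$HFI <- if (any(ok)) sum(abs(H_d[ok]) / mag[ok] * w2[ok]) / sum(w2[ok]) else 0
  # closed forms where they exist
  if (spec$case == "poiseuille") {
    out$flow_closed_form <- spec$u_max * pi * spec$R^2 / 2
    out$vorticity_magmean_closed_form <- 4 * spec$u_max / (3 * spec$R)
  }
  if (spec$case == "helical") {
    W <- spec$W; Om <- spec$Omega; R <- spec$R
    out$H_d_everywhere <- 2 * Om * W
    out$HFI_closed_form <- 2 * W / (R^2 * Om^2) *
      (sqrt(W^2 + Om^2 * R^2) - W)
  }
  if (spec$case == "solid_body") {
    out$Q_everywhere <- spec$Omega^2
    out$vorticity_everywhere <- 2 * spec$Omega
  }
  if (spec$case == "shear") out$Q_everywhere <- 0
  if (spec$case == "pulsating_tube") {
    A0 <- pi * spec$R^2
    A_max <- A0 * (1 + spec$delta)^2
    A_min <- A0 * (1 - spec$delta)^2
    out$RAC <- (A_max - A_min) / A_min
    out$A_max <- A_max; out$A_min <- A_min
  }
  out$n_quadrature <- nr * nth * nzq
  out
}

#' Write a phantom to disk (NIfTI + VTK + subject CSV + ground truth)
#'
#' Produces the full set of pipeline inputs for one phantom case: the
#' voxelized velocity (5-D NIfTI + YAML sidecar), the mesh frame series
#' (.vtu, mm), the centerlines (.vtp, mm), a synthetic subject record CSV
#' and the ground-truth reference values as JSON.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created).
#' @return invisibly, a named list of the written paths.
#' @export
write_phantom <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (spec$case == "y_junction") {
    ph <- make_y_junction(spec)
    gt <- list(case = "y_junction", flows = as.list(ph$flows))
  } else {
    ph <- make_tube(spec)
    ph$field <- make_field(spec)
    gt <- ground_truth(spec)
  }
  paths <- list(
    velocity = file.path(dir, "velocity.nii.gz"),
    mesh = write_mesh_series(ph$mesh, dir, "mesh"),
    centerlines = file.path(dir, "centerlines.vtp"),
    subjects = file.path(dir, "subjects.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_velocity_series(ph$field, paths$velocity)
  write_centerlines(ph$centerlines, paths$centerlines)
  subj <- data.frame(id = "phantom", timepoint = "pre", sex = "M",
                     age = 60, height = 170, weight = 75,
                     SPAP = 25, DPAP = 15, mPAP = 18,
                     stringsAsFactors = FALSE)
  utils::write.csv(subj, paths$subjects, row.names = FALSE)
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
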