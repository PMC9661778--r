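#' Time-resolved tetrahedral mesh with fixed connectivity
#'
#' A vessel mesh whose node positions move over the cardiac cycle while the
#' tetrahedral connectivity stays fixed (node correspondence across
#' frames). Coordinates are in cm.
#'
#' @param connectivity `m x 4` integer matrix of 1-based node indices.
#' @param nodes_per_frame list of `n x 3` node coordinate matrices (cm),
#'   one per frame; node count identical across frames.
#' @param frame_times numeric, strictly increasing (s).
#' @param surface optional `k x 3` boundary triangle connectivity.
#' @param cap_faces optional named list of integer vectors: for each
#'   labeled cap (inlet/outlet patch) the rows of `surface` belonging to it.
#' @return object of class `time_resolved_mesh`.
#' @export
time_resolved_mesh <- function(connectivity, nodes_per_frame, frame_times,
                               surface = NULL, cap_faces = NULL) {
  connectivity <- matrix(as.integer(connectivity), ncol = 4L)
  if (!is.list(nodes_per_frame)) nodes_per_frame <- list(nodes_per_frame)
  nn <- vapply(nodes_per_frame, nrow, integer(1))
  if (length(unique(nn)) != 1L)
    stop("node count differs across frames: ", paste(unique(nn), collapse = ", "))
  if (length(frame_times) != length(nodes_per_frame))
    stop("frame_times length must match number of frames")
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (max(connectivity) > nn[1] || min(connectivity) < 1L)
    stop("connectivity references nodes outside 1..", nn[1])
  for (f in seq_along(nodes_per_frame)) {
    v <- tet_volumes(nodes_per_frame[[f]], connectivity)
    bad <- which(v <= 0)
    if (length(bad))
      stop("tetrahedron ", bad[1], " has non-positive volume at frame ", f)
  }
  if (!is.null(cap_faces)) {
    idx <- unlist(cap_faces)
    if (anyDuplicated(idx))
      stop("cap_faces must be disjoint subsets of the surface")
  }
  structure(list(connectivity = connectivity,
                 nodes_per_frame = nodes_per_frame,
                 frame_times = as.numeric(frame_times),
                 surface = surface, cap_faces = cap_faces),
            class = "time_resolved_mesh")
}

#' @export
print.time_resolved_mesh <- function(x, ...) {
  cat("<time_resolved_mesh>\n")
  cat("  nodes:", nrow(x$nodes_per_frame[[1]]),
      " tets:", nrow(x$connectivity),
      " frames:", length(x$nodes_per_frame), "\n")
  if (!is.null(x$cap_faces))
    cat("  caps:", paste(names(x$cap_faces), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#'
#' @param nodes `n x 3` coordinates (cm).
#' @param tets `m x 4` connectivity.
#' @return numeric vector of signed volumes (cm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  d1 <- nodes[tets[, 2], , drop = FALSE] - a
  d2 <- nodes[tets[, 3], , drop = FALSE] - a
  d3 <- nodes[tets[, 4], , drop = FALSE] - a
  # det([d1; d2; d3]) / 6 via scalar triple product
  cx <- d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]
  cy <- d2[, 3] * d3[, 1] - d2[, 1] * d3[, 3]
  cz <- d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1]
  (d1[, 1] * cx + d1[, 2] * cy + d1[, 3] * cz) / 6
}

#' Total mesh volume at one frame
#'
#' Sum of signed tetrahedron volumes; the temporally averaged branch
#' volume metric averages this over all frames of the cycle.
#'
#' @param mesh a [time_resolved_mesh()].
#' @param frame frame index (1-based).
#' @param elements optional subset of element ids.
#' @return volume in cm^3.
#' @export
mesh_volume <- function(mesh, frame = 1L, elements = NULL) {
  conn <- mesh$connectivity
  if (!is.null(elements)) conn <- conn[elements, , drop = FALSE]
  v <- sum(tet_volumes(mesh$nodes_per_frame[[frame]], conn))
  if (v <= 0 && nrow(conn) > 0) stop("non-positive total volume: check element orientation")
  v
}

#' Element centroids at one frame
#' @param mesh a [time_resolved_mesh()].
#' @param frame frame index.
#' @return `m x 3` matrix (cm).
#' @export
element_centroids <- function(mesh, frame = 1L) {
  nd <- mesh$nodes_per_frame[[frame]]
  (nd[mesh$connectivity[, 1], , drop = FALSE] +
   nd[mesh$connectivity[, 2], , drop = FALSE] +
   nd[mesh$connectivity[, 3], , drop = FALSE] +
   nd[mesh$connectivity[, 4], , drop = FALSE]) / 4
}

#' Blend two keyframe meshes over the cardiac cycle
#'
#' The vessel wall distends between a minimum-volume and a maximum-volume
#' configuration. Given two keyframe meshes with node correspondence, node
#' positions at each requested frame are the convex blend
#' `x(t) = (1 - alpha(t)) x_min + alpha(t) x_max`. The default schedule is
#' a clipped raised-cosine between the two keyframe times: alpha rises
#' smoothly from 0 at `t_min` to 1 at `t_max` and back, which mimics the
#' distension/relaxation of the arterial wall without introducing new
#' shape information. Diffeomorphic registration that produces the
#' corresponded keyframes is an upstream concern.
#'
#' @param mesh_min,mesh_max single-frame [time_resolved_mesh()] objects
#'   sharing connectivity and node count.
#' @param frame_times frames to generate (s).
#' @param alpha optional numeric vector of blending weights in `[0,1]`,
#'   one per frame, overriding the cosine schedule.
#' @param t_min,t_max keyframe times for the default schedule (default:
#'   first and middle frame time).
#' @return a [time_resolved_mesh()] with `length(frame_times)` frames.
#' @export
interpolate_keyframes <- function(mesh_min, mesh_max, frame_times,
                                  alpha = NULL, t_min = NULL, t_max = NULL) {
  if (!identical(dim(mesh_min$connectivity), dim(mesh_max$connectivity)) ||
      any(mesh_min$connectivity != mesh_max$connectivity))
    stop("keyframe meshes must share connectivity")
  n1 <- nrow(mesh_min$nodes_per_frame[[1]])
  n2 <- nrow(mesh_max$nodes_per_frame[[1]])
  if (n1 != n2) stop("keyframe node counts differ: ", n1, " vs ", n2)
  if (is.null(alpha)) {
    if (is.null(t_min)) t_min <- frame_times[1]
    if (is.null(t_max)) t_max <- frame_times[ceiling(length(frame_times) / 2)]
    phase <- (frame_times - t_min) / (t_max - t_min)
    # raised cosine 0 -> 1 on [t_min, t_max], mirrored and clipped after
    alpha <- ifelse(phase <= 0, 0,
             ifelse(phase <= 1, (1 - cos(pi * phase)) / 2,
             ifelse(phase <= 2, (1 + cos(pi * (phase - 1))) / 2, 0)))
  }
  if (length(alpha) != length(frame_times))
    stop("alpha must have one weight per frame")
  if (any(alpha < 0 | alpha > 1)) stop("alpha weights must lie in [0,1]")
  x0 <- mesh_min$nodes_per_frame[[1]]
  x1 <- mesh_max$nodes_per_frame[[1]]
  frames <- lapply(alpha, function(a) (1 - a) * x0 + a * x1)
  time_resolved_mesh(mesh_min$connectivity, frames, frame_times,
                     surface = mesh_min$surface,
                     cap_faces = mesh_min$cap_faces)
}

#' Read a per-frame mesh series from VTK XML files
#'
#' All frames must share connectivity and node count. On-disk coordinates
#' are interpreted per `units` and converted to cm internally.
#'
#' @param paths character vector of `.vtu` paths, one per frame, in time
#'   order.
#' @param frame_times frame times (s); defaults to 0-based index seconds.
#' @param units on-disk length unit, `"mm"` (default) or `"cm"`.
#' @return a [time_resolved_mesh()].
#' @export
read_mesh_series <- function(paths, frame_times = NULL, units = c("mm", "cm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 0.1 else 1
  if (is.null(frame_times)) frame_times <- seq_along(paths) - 1
  frames <- vector("list", length(paths))
  conn <- NULL
  for (f in seq_along(paths)) {
    g <- read_vtu(paths[f])
    if (is.null(conn)) conn <- g$tets
    else if (!identical(dim(conn), dim(g$tets)) || any(conn != g$tets))
      stop("connectivity differs at frame ", f, " (", paths[f], ")")
    frames[[f]] <- g$points * scale
  }
  time_resolved_mesh(conn, frames, frame_times)
}

#' Write a mesh series as per-frame .vtu files
#'
#' @param mesh a [time_resolved_mesh()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param units on-disk unit, `"mm"` (default) or `"cm"`.
#' @param cell_data optional named list of per-element arrays written to
#'   every frame.
#' @return invisibly, the written paths.
#' @export
write_mesh_series <- function(mesh, dir, prefix = "mesh",
                              units = c("mm", "cm"), cell_data = NULL) {
  units <- match.arg(units)
  scale <- if (units == "mm") 10 else 1
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(mesh$nodes_per_frame))
  for (f in seq_along(mesh$nodes_per_frame)) {
    paths[f] <- file.path(dir, sprintf("%s_%03d.vtu", prefix, f - 1L))
    write_vtu(mesh$nodes_per_frame[[f]] * scale, mesh$connectivity,
              paths[f], cell_data = cell_data)
  }
  invisible(paths)
}
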