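# Discrete differential operators on the tetrahedral mesh: nodal velocity
# resampling, per-element velocity gradient, vorticity, Q-criterion and
# connected vortex regions.

#' Resample the velocity grid onto the mesh nodes
#'
#' Trilinear interpolation of the velocity field at the mesh node
#' positions of one frame. The mesh frame is matched to the nearest
#' velocity frame in time by default, or blended linearly in time.
#'
#' @param field a [velocity_field4d()].
#' @param mesh a [time_resolved_mesh()].
#' @param frame mesh frame index.
#' @param time_match `"nearest"` (default) or `"linear"`.
#' @param outside policy for nodes outside the grid: `"zero"` (warn) or
#'   `"error"`.
#' @return object of class `node_field`: list with `values` (`n x 3`
#'   cm/s), `frame`, `mesh_frame_time`.
#' @export
resample_to_mesh <- function(field, mesh, frame = 1L,
                             time_match = c("nearest", "linear"),
                             outside = c("zero", "error")) {
  time_match <- match.arg(time_match)
  outside <- match.arg(outside)
  nodes <- mesh$nodes_per_frame[[frame]]
  t_mesh <- mesh$frame_times[frame]
  if (time_match == "nearest" || length(field$frame_times) == 1L) {
    f <- nearest_frame(field, t_mesh)
    vals <- sample_velocity(field, nodes, f, outside)
  } else {
    tt <- t_mesh %% field$period
    ft <- field$frame_times
    i <- findInterval(tt, ft)
    if (i == 0L || i >= length(ft)) {       # wrap across the cycle seam
      f0 <- length(ft); f1 <- 1L
      gap <- ft[1] + field$period - ft[length(ft)]
      w <- ((tt - ft[length(ft)]) %% field$period) / gap
    } else {
      f0 <- i; f1 <- i + 1L
      w <- (tt - ft[i]) / (ft[i + 1] - ft[i])
    }
    vals <- (1 - w) * sample_velocity(field, nodes, f0, outside) +
      w * sample_velocity(field, nodes, f1, outside)
  }
  structure(list(values = vals, frame = frame, mesh_frame_time = t_mesh),
            class = "node_field")
}

node_field_from_values <- function(values, frame = 1L, t = 0) {
  structure(list(values = values, frame = frame, mesh_frame_time = t),
            class = "node_field")
}

#' Per-element velocity gradient, strain, rotation, vorticity, Q
#'
#' The velocity gradient tensor is piecewise constant per tetrahedron,
#' obtained from the element's linear shape functions; this is exact for
#' any affine velocity field on any nondegenerate mesh. From the gradient
#' `G` (`G[i, j] = d u_i / d x_j`): strain rate `S = (G + G')/2`, rotation
#' `W = (G - G')/2`, vorticity `omega = curl u` (twice the axial vector of
#' `W`), and `Q = (||W||_F^2 - ||S||_F^2) / 2`.
#'
#' @param nodefield a `node_field` from [resample_to_mesh()].
#' @param mesh the [time_resolved_mesh()] the node field lives on.
#' @return object of class `gradient_field`: `G` (`m x 3 x 3`, 1/s),
#'   `vorticity` (`m x 3`, 1/s), `Q` (`m`, 1/s^2), `volumes` (cm^3),
#'   `frame`.
#' @export
velocity_gradient <- function(nodefield, mesh) {
  conn <- mesh$connectivity
  nodes <- mesh$nodes_per_frame[[nodefield$frame]]
  u <- nodefield$values
  if (nrow(u) != nrow(nodes))
    stop("node field does not match mesh node count")
  m <- nrow(conn)
  a <- nodes[conn[, 1], , drop = FALSE]
  d1 <- nodes[conn[, 2], , drop = FALSE] - a
  d2 <- nodes[conn[, 3], , drop = FALSE] - a
  d3 <- nodes[conn[, 4], , drop = FALSE] - a
  cross3 <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                 p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                 p[, 1] * q[, 2] - p[, 2] * q[, 1])
  c1 <- cross3(d2, d3); c2 <- cross3(d3, d1); c3 <- cross3(d1, d2)
  det <- rowSums(d1 * c1)
  if (any(abs(det) < 1e-300)) stop("degenerate tetrahedron in mesh")
  G <- array(0, c(m, 3, 3))
  ua <- u[conn[, 1], , drop = FALSE]
  for (comp in 1:3) {
    e1 <- u[conn[, 2], comp] - ua[, comp]
    e2 <- u[conn[, 3], comp] - ua[, comp]
    e3 <- u[conn[, 4], comp] - ua[, comp]
    # grad(u_comp) = (c1 e1 + c2 e2 + c3 e3) / det
    G[, comp, 1] <- (c1[, 1] * e1 + c2[, 1] * e2 + c3[, 1] * e3) / det
    G[, comp, 2] <- (c1[, 2] * e1 + c2[, 2] * e2 + c3[, 2] * e3) / det
    G[, comp, 3] <- (c1[, 3] * e1 + c2[, 3] * e2 + c3[, 3] * e3) / det
  }
  omega <- cbind(G[, 3, 2] - G[, 2, 3],
                 G[, 1, 3] - G[, 3, 1],
                 G[, 2, 1] - G[, 1, 2])
  # ||W||_F^2 = |omega|^2 / 2 ; ||S||_F^2 = sum(diag^2) + off-diag means
  normW2 <- rowSums(omega^2) / 2
  normS2 <- G[, 1, 1]^2 + G[, 2, 2]^2 + G[, 3, 3]^2 +
    (G[, 1, 2] + G[, 2, 1])^2 / 2 +
    (G[, 1, 3] + G[, 3, 1])^2 / 2 +
    (G[, 2, 3] + G[, 3, 2])^2 / 2
  Q <- (normW2 - normS2) / 2
  structure(list(G = G, vorticity = omega, Q = Q,
                 volumes = abs(tet_volumes(nodes, conn)),
                 frame = nodefield$frame),
            class = "gradient_field")
}

#' Spatially averaged branch vorticity
#'
#' Two averaging conventions are exposed. `"vector-mean"` is the magnitude
#' of the volume-weighted mean vorticity vector, `|(1/V) integral of
#' curl u dV|`; for rotationally symmetric flow (e.g. the azimuthal
#' vorticity of a Poiseuille profile) the components cancel and this tends
#' to zero. `"magnitude-mean"` is the volume-weighted mean of `|curl u|`,
#' which measures the amount of local rotation regardless of direction.
#' Both are computed by the full pipeline; neither is silently preferred.
#'
#' @param gradfield a `gradient_field`.
#' @param elements element ids of the branch (default: all).
#' @param mode `"vector-mean"` or `"magnitude-mean"`.
#' @return scalar vorticity (1/s).
#' @export
branch_vorticity <- function(gradfield, elements = NULL,
                             mode = c("vector-mean", "magnitude-mean")) {
  mode <- match.arg(mode)
  om <- gradfield$vorticity
  vol <- gradfield$volumes
  if (!is.null(elements)) {
    om <- om[elements, , drop = FALSE]
    vol <- vol[elements]
  }
  if (!length(vol)) stop("empty branch: no elements")
  if (mode == "vector-mean")
    sqrt(sum((colSums(om * vol) / sum(vol))^2))
  else
    sum(sqrt(rowSums(om^2)) * vol) / sum(vol)
}

#' Per-element Q-criterion
#'
#' `Q = (||W||_F^2 - ||S||_F^2) / 2` with Frobenius norms of the rotation
#' and strain-rate tensors; positive where rotation dominates strain.
#'
#' @param gradfield a `gradient_field`.
#' @return numeric vector, one value per element (1/s^2).
#' @export
q_criterion <- function(gradfield) gradfield$Q

#' Detect candidate vortex regions
#'
#' A vortex is taken as a face-connected set of elements with `Q > 0` and
#' element-mean speed below `speed_threshold` (default 30 cm/s, which
#' suppresses the fast laminar core).
#'
#' @param gradfield a `gradient_field`.
#' @param nodefield the matching `node_field` (for element speeds).
#' @param mesh the [time_resolved_mesh()].
#' @param speed_threshold cm/s.
#' @return list with `labels` (per-element integer, 0 = background),
#'   `regions` (data.frame: id, n_elements, volume_cm3).
#' @export
detect_vortex_regions <- function(gradfield, nodefield, mesh,
                                  speed_threshold = 30) {
  conn <- mesh$connectivity
  u <- nodefield$values
  spd_node <- sqrt(rowSums(u^2))
  spd_el <- (spd_node[conn[, 1]] + spd_node[conn[, 2]] +
             spd_node[conn[, 3]] + spd_node[conn[, 4]]) / 4
  active <- which(gradfield$Q > 0 & spd_el < speed_threshold)
  labels <- integer(nrow(conn))
  regions <- data.frame(id = integer(0), n_elements = integer(0),
                        volume_cm3 = numeric(0))
  if (length(active)) {
    adj <- face_adjacency(conn, active)
    cid <- 0L
    for (st in seq_along(active)) {
      if (labels[active[st]] != 0L) next
      cid <- cid + 1L
      queue <- st
      labels[active[st]] <- cid
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (nb in adj[[cur]]) if (labels[active[nb]] == 0L) {
          labels[active[nb]] <- cid
          queue <- c(queue, nb)
        }
      }
    }
    vol <- gradfield$volumes
    regions <- do.call(rbind, lapply(seq_len(cid), function(id) {
      el <- which(labels == id)
      data.frame(id = id, n_elements = length(el),
                 volume_cm3 = sum(vol[el]))
    }))
  }
  list(labels = labels, regions = regions)
}

# adjacency lists (within `subset`) of tets sharing a face
face_adjacency <- function(conn, subset) {
  faces <- rbind(conn[subset, c(1, 2, 3)], conn[subset, c(1, 2, 4)],
                 conn[subset, c(1, 3, 4)], conn[subset, c(2, 3, 4)])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3], sep = "_")
  owner <- rep(seq_along(subset), 4)
  by_face <- split(owner, key)
  adj <- vector("list", length(subset))
  for (grp in by_face) if (length(grp) == 2) {
    adj[[grp[1]]] <- c(adj[[grp[1]]], grp[2])
    adj[[grp[2]]] <- c(adj[[grp[2]]], grp[1])
  }
  adj
}
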