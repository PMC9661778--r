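# Planar cross-sections perpendicular to the branch centerline, obtained
# by cutting the tetrahedral mesh with the plane through the centerline
# point at a requested arc-length fraction.

#' Extract a perpendicular cross-section at a fractional arc length
#'
#' Places a plane through the centerline point at `fraction` of the branch
#' arc length (measured from the cap end), normal to the local centerline
#' tangent, intersects it with the tetrahedra, and keeps the connected
#' intersection component containing that point. Each cut tetrahedron
#' contributes a triangle or quad; quads are split, and pieces are glued
#' by their shared cut mesh-edges.
#'
#' When a velocity field is supplied, velocities are sampled at the
#' polygon vertices (trilinear) and the normal is oriented so that the
#' time-mean flux through the slice is positive — this defines the forward
#' flow direction used by the flow-rate and reverse-flow metrics.
#'
#' @param mesh a [time_resolved_mesh()].
#' @param centerline `k x 3` ordered branch centerline points (cm).
#' @param fraction arc-length fraction in (0, 1) from the cap end.
#' @param frame mesh frame (and velocity frame when `field` is given and
#'   `velocity_frame` is not).
#' @param field optional [velocity_field4d()] for vertex velocities.
#' @param elements optional element-id subset (e.g. a branch region).
#' @param velocity_frame velocity frame index; default: nearest frame to
#'   the mesh frame time.
#' @param orient `"flux"` (default: flip normal so time-mean flux > 0) or
#'   `"tangent"` (keep centerline tangent direction).
#' @return object of class `cross_section`: `origin`, `normal` (unit),
#'   `vertices` (`v x 3` cm), `triangles` (`t x 3` vertex indices),
#'   `velocity` (`v x 3` cm/s or NULL), `area` (cm^2), `fraction`.
#' @export
slice_at_fraction <- function(mesh, centerline, fraction, frame = 1L,
                              field = NULL, elements = NULL,
                              velocity_frame = NULL,
                              orient = c("flux", "tangent")) {
  orient <- match.arg(orient)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1), got ", fraction)
  loc <- centerline_point_at(centerline, fraction)
  cut <- cut_mesh_by_plane(mesh, loc$point, loc$tangent, frame, elements)
  if (is.null(cut)) stop("empty plane/mesh intersection at fraction ", fraction)

  normal <- loc$tangent
  # unique triangle edges and their midpoints: quadrature nodes for the
  # edge-midpoint rule (exact for quadratic integrands)
  tri <- cut$triangles
  epairs <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  ekey <- paste(pmin(epairs[, 1], epairs[, 2]),
                pmax(epairs[, 1], epairs[, 2]))
  eid <- match(ekey, unique(ekey))
  uniq <- !duplicated(ekey)
  mid_pts <- (cut$vertices[epairs[uniq, 1], , drop = FALSE] +
              cut$vertices[epairs[uniq, 2], , drop = FALSE]) / 2
  tri_edges <- matrix(eid, ncol = 3)

  velocity <- NULL
  mid_velocity <- NULL
  if (!is.null(field)) {
    vf <- velocity_frame %||% nearest_frame(field, mesh$frame_times[frame])
    velocity <- sample_velocity(field, cut$vertices, vf)
    mid_velocity <- sample_velocity(field, mid_pts, vf)
    if (orient == "flux") {
      # time-mean flux decides the forward direction
      nt <- dim(field$velocities)[1]
      flux <- 0
      for (f in seq_len(nt)) {
        v_f <- if (f == vf) velocity
               else sample_velocity(field, cut$vertices, f)
        flux <- flux + section_flux(cut, v_f, normal)
      }
      if (flux / nt < 0) normal <- -normal
    }
  }
  structure(list(origin = loc$point, normal = normal,
                 vertices = cut$vertices, triangles = cut$triangles,
                 velocity = velocity, area = cut$area,
                 mid_points = mid_pts, tri_edges = tri_edges,
                 mid_velocity = mid_velocity,
                 fraction = fraction, frame = frame),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> fraction %.2f, area %.4f cm^2, %d vertices, %d triangles\n",
    x$fraction, x$area, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# raw surface integral of u . n over the triangulated section. With
# midpoint samples (mid_velocity) the edge-midpoint rule is used
# (A/3 * sum over the three edge midpoints; exact for quadratic
# integrands); otherwise the vertex-mean centroid rule.
section_flux <- function(cut, vertex_velocity, normal,
                         mid_velocity = NULL) {
  tri <- cut$triangles
  v1 <- cut$vertices[tri[, 1], , drop = FALSE]
  v2 <- cut$vertices[tri[, 2], , drop = FALSE]
  v3 <- cut$vertices[tri[, 3], , drop = FALSE]
  a <- tri_areas(v1, v2, v3)
  if (!is.null(mid_velocity)) {
    te <- cut$tri_edges
    uc <- (mid_velocity[te[, 1], , drop = FALSE] +
           mid_velocity[te[, 2], , drop = FALSE] +
           mid_velocity[te[, 3], , drop = FALSE]) / 3
  } else {
    uc <- (vertex_velocity[tri[, 1], , drop = FALSE] +
           vertex_velocity[tri[, 2], , drop = FALSE] +
           vertex_velocity[tri[, 3], , drop = FALSE]) / 3
  }
  sum((uc %*% normal) * a)
}

tri_areas <- function(v1, v2, v3) {
  e1 <- v2 - v1; e2 <- v3 - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Cut the mesh with a plane; return the connected component of the
# intersection surface containing (nearest) p0, or NULL if empty.
cut_mesh_by_plane <- function(mesh, p0, n, frame = 1L, elements = NULL) {
  nodes <- mesh$nodes_per_frame[[frame]]
  conn <- mesh$connectivity
  el_ids <- seq_len(nrow(conn))
  if (!is.null(elements)) {
    conn <- conn[elements, , drop = FALSE]
    el_ids <- elements
  }
  s <- as.numeric(sweep(nodes, 2, p0) %*% n)
  s[s == 0] <- 1e-12 * max(abs(s), 1)  # nudge on-plane vertices
  sg <- matrix(s[conn] > 0, ncol = 4)
  npos <- rowSums(sg)
  crossing <- which(npos > 0 & npos < 4)
  if (!length(crossing)) return(NULL)

  edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  vkey <- character(0); vidx <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nv <- 0L
  tris <- list(); piece_of_tri <- integer(0)
  piece_keys <- vector("list", length(crossing))

  for (pi in seq_along(crossing)) {
    e <- crossing[pi]
    ids <- conn[e, ]
    pts <- matrix(0, 0, 3); keys <- character(0)
    for (k in seq_len(6)) {
      i <- ids[edge_pairs[k, 1]]; j <- ids[edge_pairs[k, 2]]
      si <- s[i]; sj <- s[j]
      if (si * sj < 0) {
        w <- si / (si - sj)
        pts <- rbind(pts, (1 - w) * nodes[i, ] + w * nodes[j, ])
        keys <- c(keys, paste0(min(i, j), "_", max(i, j)))
      }
    }
    if (nrow(pts) < 3) next
    # global vertex ids keyed by the cut mesh edge (shared across tets)
    gid <- integer(length(keys))
    for (k in seq_along(keys)) {
      g <- vidx[[keys[k]]]
      if (is.null(g)) {
        nv <- nv + 1L
        vidx[[keys[k]]] <- nv
        verts[[nv]] <- pts[k, ]
        g <- nv
      }
      gid[k] <- g
    }
    if (nrow(pts) == 4) {
      # order the quad by angle about its centroid in the plane
      ctr <- colMeans(pts)
      b1 <- pts[1, ] - ctr; b1 <- b1 / sqrt(sum(b1^2))
      b2 <- c(n[2] * b1[3] - n[3] * b1[2],
              n[3] * b1[1] - n[1] * b1[3],
              n[1] * b1[2] - n[2] * b1[1])
      ang <- atan2((pts - rep(ctr, each = 4)) %*% b2,
                   (pts - rep(ctr, each = 4)) %*% b1)
      o <- order(ang)
      gid <- gid[o]
      new_tris <- rbind(gid[c(1, 2, 3)], gid[c(1, 3, 4)])
    } else new_tris <- rbind(gid)
    for (r in seq_len(nrow(new_tris))) {
      tris[[length(tris) + 1L]] <- new_tris[r, ]
      piece_of_tri <- c(piece_of_tri, pi)
    }
    piece_keys[[pi]] <- keys
  }
  if (!length(tris)) return(NULL)
  V <- do.call(rbind, verts)
  Tm <- do.call(rbind, tris)

  # connected components over pieces sharing a cut mesh-edge
  npieces <- length(crossing)
  comp <- integer(npieces)
  key_to_pieces <- new.env(hash = TRUE, parent = emptyenv())
  for (pi in seq_len(npieces)) for (k in piece_keys[[pi]])
    key_to_pieces[[k]] <- c(key_to_pieces[[k]], pi)
  cid <- 0L
  for (start in seq_len(npieces)) {
    if (comp[start] != 0L || is.null(piece_keys[[start]])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in piece_keys[[cur]]) for (nb in key_to_pieces[[k]]) {
        if (comp[nb] == 0L) { comp[nb] <- cid; queue <- c(queue, nb) }
      }
    }
  }
  # keep the component whose pieces come nearest the plane point
  piece_cent <- t(vapply(seq_len(npieces), function(pi) {
    tri_rows <- which(piece_of_tri == pi)
    if (!length(tri_rows)) return(c(Inf, Inf, Inf))
    colMeans(V[unique(as.vector(Tm[tri_rows, , drop = FALSE])), , drop = FALSE])
  }, numeric(3)))
  d0 <- sqrt(rowSums(sweep(piece_cent, 2, p0)^2))
  keep_comp <- comp[which.min(d0)]
  keep_tris <- which(comp[piece_of_tri] == keep_comp)
  Tm <- Tm[keep_tris, , drop = FALSE]
  # drop degenerate slivers left by the on-plane vertex nudge
  a_tri <- tri_areas(V[Tm[, 1], , drop = FALSE], V[Tm[, 2], , drop = FALSE],
                     V[Tm[, 3], , drop = FALSE])
  Tm <- Tm[a_tri > 1e-9 * max(a_tri), , drop = FALSE]
  used <- sort(unique(as.vector(Tm)))
  remap <- integer(nv); remap[used] <- seq_along(used)
  Tm <- matrix(remap[Tm], ncol = 3)
  V <- V[used, , drop = FALSE]
  area <- sum(tri_areas(V[Tm[, 1], , drop = FALSE],
                        V[Tm[, 2], , drop = FALSE],
                        V[Tm[, 3], , drop = FALSE]))
  if (area <= 0) return(NULL)
  list(vertices = V, triangles = Tm, area = area)
}

#' Export a cross-section as VTK PolyData with velocity point data
#'
#' @param slice a `cross_section`.
#' @param path output `.vtp` file (coordinates written in mm).
#' @return invisibly, `path`.
#' @export
write_cross_section <- function(slice, path) {
  pd <- NULL
  if (!is.null(slice$velocity)) pd <- list(Velocity = slice$velocity)
  write_vtp(slice$vertices * 10, path,
            polys = lapply(seq_len(nrow(slice$triangles)),
                           function(i) slice$triangles[i, ]),
            point_data = pd)
}
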