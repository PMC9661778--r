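#' Ordered branch centerlines
#'
#' A set of labeled vessel centerlines, one ordered polyline per branch
#' (typically MPA, LPA, RPA). Point 1 of each polyline is the cap (inflow
#' for the main trunk, distal cap for the daughters); the last point lies
#' at/near the bifurcation. Arc-length fractions used for slicing are
#' measured from the cap end.
#'
#' @param branches named list of `k x 3` point matrices (cm), `k >= 3`,
#'   ordered along the vessel; names are the branch labels and must be
#'   unique.
#' @param radii optional named list of per-point maximal inscribed radii
#'   (cm), matching `branches`.
#' @return object of class `centerline_set`.
#' @export
centerline_set <- function(branches, radii = NULL) {
  labels <- names(branches)
  if (is.null(labels) || any(labels == ""))
    stop("branches must be a named list")
  if (anyDuplicated(labels))
    stop("duplicate branch label: ", labels[duplicated(labels)][1])
  cleaned <- lapply(labels, function(lbl) {
    p <- branches[[lbl]]
    # drop duplicate consecutive points (zero-length segments)
    if (nrow(p) > 1) {
      seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
      if (any(seg == 0)) {
        warning("removed ", sum(seg == 0),
                " duplicate consecutive point(s) in branch ", lbl)
        p <- p[c(TRUE, seg > 0), , drop = FALSE]
      }
    }
    if (nrow(p) < 3) stop("branch ", lbl, " has fewer than 3 points")
    p
  })
  names(cleaned) <- labels
  structure(list(branches = cleaned, radii = radii),
            class = "centerline_set")
}

#' @export
print.centerline_set <- function(x, ...) {
  cat("<centerline_set>\n")
  for (lbl in names(x$branches)) {
    s <- arc_length(x$branches[[lbl]])
    cat(sprintf("  %s: %d points, length %.3f cm\n", lbl,
                nrow(x$branches[[lbl]]), s[length(s)]))
  }
  invisible(x)
}

#' Cumulative arc length of one branch polyline
#' @param points `k x 3` ordered points (cm).
#' @return numeric vector of length `k`, starting at 0, strictly
#'   increasing (cm).
#' @export
arc_length <- function(points) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# point and unit tangent at an arc-length fraction of a polyline
centerline_point_at <- function(points, fraction) {
  s <- arc_length(points)
  target <- fraction * s[length(s)]
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(points) - 1L)
  w <- (target - s[i]) / (s[i + 1] - s[i])
  pt <- (1 - w) * points[i, ] + w * points[i + 1, ]
  tang <- points[i + 1, ] - points[i, ]
  list(point = unname(pt), tangent = unname(tang / sqrt(sum(tang^2))),
       index = i)
}

#' Read branch centerlines from VTK XML PolyData
#'
#' Each polyline in the file is one branch; labels come from the
#' `BranchName` field array (falling back to `branch_1`, ... with a
#' warning). On-disk coordinates interpreted per `units`, stored in cm.
#'
#' @param path a `.vtp` file.
#' @param units `"mm"` (default) or `"cm"`.
#' @return a [centerline_set()].
#' @export
read_centerlines <- function(path, units = c("mm", "cm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 0.1 else 1
  g <- read_vtp(path)
  if (!length(g$lines)) stop("no polylines in ", path)
  labels <- g$line_names
  if (is.null(labels)) {
    warning("no BranchName field; using generic branch labels")
    labels <- paste0("branch_", seq_along(g$lines))
  }
  if (length(labels) != length(g$lines))
    stop("BranchName count does not match number of polylines")
  if (anyDuplicated(labels))
    stop("duplicate branch label: ", labels[duplicated(labels)][1])
  branches <- lapply(g$lines, function(idx) g$points[idx, , drop = FALSE] * scale)
  names(branches) <- labels
  radii <- NULL
  if (!is.null(g$point_data$MaximumInscribedSphereRadius)) {
    r <- g$point_data$MaximumInscribedSphereRadius * scale
    radii <- lapply(g$lines, function(idx) r[idx])
    names(radii) <- labels
  }
  centerline_set(branches, radii)
}

#' Write a centerline set to VTK XML PolyData
#' @param cl a [centerline_set()].
#' @param path output `.vtp` file.
#' @param units on-disk unit, `"mm"` (default) or `"cm"`.
#' @return invisibly, `path`.
#' @export
write_centerlines <- function(cl, path, units = c("mm", "cm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 10 else 1
  pts <- do.call(rbind, cl$branches) * scale
  counts <- vapply(cl$branches, nrow, integer(1))
  ends <- cumsum(counts)
  lines <- Map(function(s, e) s:e, ends - counts + 1L, ends)
  pd <- NULL
  if (!is.null(cl$radii))
    pd <- list(MaximumInscribedSphereRadius = unlist(cl$radii) * scale)
  write_vtp(pts, path, lines = lines, point_data = pd,
            line_names = names(cl$branches))
}

#' Radius of curvature of a centerline at an arc-length fraction
#'
#' The polyline is smoothed with a centered moving average (window
#' configurable) to suppress point noise, re-parameterized by arc length,
#' and differentiated with centered finite differences; the curvature is
#' `kappa = |r' x r''| / |r'|^3` and the returned value is `R_c = 1 /
#' kappa` in cm. Straight segments (kappa below `straight_tol`) return
#' `Inf`.
#'
#' @param points `k x 3` ordered polyline (cm), `k >= 5`.
#' @param fraction arc-length fraction in `[0, 1]`.
#' @param smooth_window odd moving-average window (default 5); 1 disables
#'   smoothing.
#' @param straight_tol curvature below this (1/cm) is treated as straight.
#' @return radius of curvature in cm (possibly `Inf`).
#' @export
centerline_curvature <- function(points, fraction, smooth_window = 5L,
                                 straight_tol = 1e-6) {
  if (nrow(points) < 5) stop("centerline needs >= 5 points for curvature")
  p <- smooth_polyline(points, smooth_window)
  s <- arc_length(p)
  n <- nrow(p)
  # centered first/second derivatives on (possibly uneven) arc length
  d1 <- matrix(NA_real_, n, 3); d2 <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
    d1[i, ] <- (h1^2 * p[i + 1, ] - h2^2 * p[i - 1, ] +
                (h2^2 - h1^2) * p[i, ]) / (h1 * h2 * (h1 + h2))
    d2[i, ] <- 2 * (h1 * p[i + 1, ] + h2 * p[i - 1, ] -
                    (h1 + h2) * p[i, ]) / (h1 * h2 * (h1 + h2))
  }
  target <- fraction * s[n]
  i <- which.min(abs(s - target))
  i <- min(max(i, 2L), n - 1L)
  cr <- c(d1[i, 2] * d2[i, 3] - d1[i, 3] * d2[i, 2],
          d1[i, 3] * d2[i, 1] - d1[i, 1] * d2[i, 3],
          d1[i, 1] * d2[i, 2] - d1[i, 2] * d2[i, 1])
  kappa <- sqrt(sum(cr^2)) / sqrt(sum(d1[i, ]^2))^3
  if (!is.finite(kappa) || kappa < straight_tol) return(Inf)
  1 / kappa
}

# centered moving average preserving endpoints (shrinking window near ends)
smooth_polyline <- function(points, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L) return(points)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- nrow(points)
  out <- points
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h > 0) out[i, ] <- colMeans(points[(i - h):(i + h), , drop = FALSE])
  }
  out
}
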