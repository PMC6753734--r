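# Oriented bounding boxes: PCA fitting, the 15-axis separating-axis overlap
# test, and a separation-gap lower bound on box-box distance used to prune the
# branch-and-bound traversal.

#' Fit an oriented bounding box to a point cloud
#'
#' Axes are the eigenvectors of the (population) covariance matrix of the
#' points, ordered by descending eigenvalue; extents are tight along those
#' axes. Eigenvector signs are fixed by making the largest-magnitude component
#' of each axis positive, so fits are deterministic.
#'
#' @param points n x 3 numeric matrix, n >= 1. Degenerate clouds (coincident
#'   or collinear points) yield zero extents on the degenerate axes.
#' @return An object of class `obb`: `center` (length 3), `axes` (3x3 matrix,
#'   columns are unit axes), `half` (length-3 non-negative half-extents, cm).
#' @export
fit_obb <- function(points) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (!all(is.finite(points))) stop("non-finite point coordinates")
  if (nrow(points) == 1L) {
    return(structure(list(center = as.numeric(points[1L, ]), axes = diag(3),
                          half = c(0, 0, 0)), class = "obb"))
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  cv <- crossprod(X) / nrow(X)
  eg <- eigen(cv, symmetric = TRUE)       # eigenvalues in decreasing order
  axes <- eg$vectors
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  proj <- X %*% axes
  lo <- apply(proj, 2L, min); hi <- apply(proj, 2L, max)
  structure(list(center = as.numeric(ctr + axes %*% ((lo + hi) / 2)),
                 axes = axes,
                 half = as.numeric((hi - lo) / 2)),
            class = "obb")
}

#' @export
print.obb <- function(x, ...) {
  cat("obb center:", paste(signif(x$center, 6), collapse = ", "),
      " half-extents:", paste(signif(x$half, 6), collapse = ", "), "cm\n")
  invisible(x)
}

# Signed separation gaps of two OBBs along the 15 SAT candidate axes
# (3 face normals each + 9 edge cross products), normalized to unit axes.
# A positive gap along any axis proves disjointness and is a lower bound on
# the Euclidean distance between the boxes. Degenerate cross products
# (parallel edges) are skipped. Returns the maximum normalized gap.
.obb_max_sat_gap <- function(a_center, a_axes, a_half, b_center, b_axes, b_half) {
  d <- b_center - a_center
  best <- -Inf
  for (k in 1:3) {
    for (src in 1:2) {
      L <- if (src == 1L) a_axes[, k] else b_axes[, k]
      ra <- sum(a_half * abs(crossprod(a_axes, L)))
      rb <- sum(b_half * abs(crossprod(b_axes, L)))
      g <- abs(sum(d * L)) - ra - rb
      if (g > best) best <- g
    }
  }
  for (i in 1:3) {
    u <- a_axes[, i]
    for (j in 1:3) {
      v <- b_axes[, j]
      L <- c(u[2L] * v[3L] - u[3L] * v[2L],
             u[3L] * v[1L] - u[1L] * v[3L],
             u[1L] * v[2L] - u[2L] * v[1L])
      n2 <- sum(L * L)
      if (n2 < 1e-24) next                # parallel edges: axis degenerate
      L <- L / sqrt(n2)
      ra <- sum(a_half * abs(crossprod(a_axes, L)))
      rb <- sum(b_half * abs(crossprod(b_axes, L)))
      g <- abs(sum(d * L)) - ra - rb
      if (g > best) best <- g
    }
  }
  best
}

#' Separating-axis overlap test for two oriented boxes
#'
#' Two convex boxes are disjoint iff their projections separate on at least
#' one of 15 candidate axes (each box's 3 face normals plus the 9 pairwise
#' edge cross products). Touching boxes count as overlapping.
#'
#' @param a,b `obb` objects.
#' @return `TRUE` iff no separating axis exists.
#' @export
obb_overlap_sat <- function(a, b) {
  stopifnot(inherits(a, "obb"), inherits(b, "obb"))
  .obb_max_sat_gap(a$center, a$axes, a$half, b$center, b$axes, b$half) <= 0
}

#' Lower bound on the distance between two oriented boxes
#'
#' The largest positive separation gap over the 15 separating-axis candidates,
#' or 0 when the boxes overlap. For any unit axis the projection gap bounds
#' the Euclidean distance from below, so this is always a valid lower bound on
#' the true box-box distance (and exact for axis-aligned face-to-face
#' separation); validity, not tightness, is what the branch-and-bound
#' traversal requires for exactness.
#'
#' @param a,b `obb` objects.
#' @return Non-negative lower bound in cm; 0 iff [obb_overlap_sat()] is `TRUE`.
#' @export
obb_distance_lower_bound <- function(a, b) {
  stopifnot(inherits(a, "obb"), inherits(b, "obb"))
  max(0, .obb_max_sat_gap(a$center, a$axes, a$half, b$center, b$axes, b$half))
}
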