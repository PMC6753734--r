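# Core geometric types: rigid transforms, triangle meshes, extents, and the
# exhaustive vertex-pair distance oracle. All lengths are centimetres in the
# fixed DICOM patient frame (+x patient-left, +y patient-posterior,
# +z patient-superior; origin at the plan isocenter).

.ORTHO_TOL <- 1e-9

#' Rigid transform (rotation + translation)
#'
#' A proper rigid-body transform acting on points as `rotation %*% p +
#' translation`. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 translation in cm.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 0, 0))
#' transform_points(t, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("invalid-transform: rotation must be a finite 3x3 matrix")
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("invalid-transform: translation must be a finite length-3 vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("invalid-transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("invalid-transform: rotation determinant is not +1 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(signif(x$rotation, 6))
  cat("  translation:", paste(signif(x$translation, 6), collapse = ", "), "cm\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param v translation vector in cm.
#' @export
rt_translation <- function(v) rigid_transform(diag(3), v)

#' Rotation about a coordinate axis
#'
#' Right-handed rotation by `deg` degrees about one of the patient-frame
#' coordinate axes.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param deg Angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), deg) {
  axis <- match.arg(axis)
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first and then `a`,
#' i.e. `(a %o% b)(p) = a(b(p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Apply a rigid transform to a matrix of points
#'
#' @param t A `rigid_transform`.
#' @param pts An n x 3 numeric matrix of points (rows).
#' @return The transformed n x 3 matrix.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  pts <- rbind(pts)  # promote a bare length-3 vector
  sweep(pts %*% t(t$rotation), 2L, t$translation, "+")
}

#' Triangle mesh
#'
#' The unit of all geometry: a vertex cloud plus triangular faces indexing it.
#' Collision queries in this package are vertex-pair based, so the vertex set
#' is the collision-relevant content; faces carry surface topology for file
#' round trips and scene export.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (cm).
#' @param faces m x 3 integer matrix of 1-based vertex indices. May have zero
#'   rows for a pure point cloud.
#' @param name Label used in reports.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces = matrix(integer(), 0L, 3L), name = "mesh") {
  vertices <- rbind(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertices must be finite")
  faces <- rbind(faces)
  if (length(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
      stop("face with repeated vertex indices")
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)[1L]),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex `v` is replaced by `rotation %*% v + translation`; faces are
#' unchanged.
#'
#' @param mesh A `triangle_mesh`.
#' @param t A `rigid_transform`.
#' @return The transformed `triangle_mesh` (datum attributes, if any, are
#'   translated along when the rotation is the identity).
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  out <- triangle_mesh(transform_points(t, mesh$vertices), mesh$faces, mesh$name)
  d <- attr(mesh, "datums")
  if (!is.null(d) && max(abs(t$rotation - diag(3))) < .ORTHO_TOL) {
    d$posterior_y <- d$posterior_y + t$translation[2L]
    d$midline_x <- d$midline_x + t$translation[1L]
    d$superior_z <- d$superior_z + t$translation[3L]
    attr(out, "datums") <- d
  }
  lm <- attr(mesh, "landmarks")
  if (!is.null(lm)) {
    attr(out, "landmarks") <- lapply(lm, function(p) as.numeric(transform_points(t, p)))
  }
  out
}

#' Axis-aligned extents of a mesh
#'
#' Componentwise minimum and maximum over all vertices — the quantities the
#' auto-registration aligns on (anterior-posterior, left-right, superior
#' extremes of the body contour).
#'
#' @param mesh A non-empty `triangle_mesh`.
#' @return A list of class `extents` with numeric length-3 `min` and `max`.
#' @export
mesh_extents <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("empty-mesh: extents of an empty mesh")
  structure(list(min = apply(mesh$vertices, 2L, min),
                 max = apply(mesh$vertices, 2L, max)),
            class = "extents")
}

#' @export
print.extents <- function(x, ...) {
  cat("extents (cm):\n  min:", paste(signif(x$min, 6), collapse = ", "),
      "\n  max:", paste(signif(x$max, 6), collapse = ", "), "\n")
  invisible(x)
}

# Shared primitive: minimum squared distance between two vertex blocks.
# Both the brute-force oracle and the tree traversal leaf step call this, so
# the two code paths evaluate identical arithmetic on any given vertex pair
# and their minima agree exactly.
# Returns list(d2, ia, ib) with local (row) indices, lexicographic tie-break.
.min_dist_block <- function(A, B) {
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  m <- min(d2)
  hits <- which(d2 == m, arr.ind = TRUE, useNames = FALSE)
  if (nrow(hits) > 1L) hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(d2 = m, ia = hits[1L, 1L], ib = hits[1L, 2L])
}

#' Exhaustive minimum vertex-pair distance between two meshes
#'
#' The point-to-point baseline: scans all `|A| * |B|` vertex pairs and returns
#' the exact minimum Euclidean distance with its witness pair. Quadratic cost
#' makes this the reference oracle against which the tree-accelerated query is
#' verified, not the production path.
#'
#' @param a,b Non-empty `triangle_mesh` objects.
#' @param chunk_size Number of `a` vertices processed per block (memory knob).
#' @return A list with `distance` (cm), `index_a`, `index_b` (1-based vertex
#'   indices; ties broken lexicographically on `(index_a, index_b)`),
#'   `point_a`, `point_b`.
#' @export
brute_force_min_distance <- function(a, b, chunk_size = 2048L) {
  stopifnot(inherits(a, "triangle_mesh"), inherits(b, "triangle_mesh"))
  if (nrow(a$vertices) == 0L || nrow(b$vertices) == 0L)
    stop("empty-mesh: brute_force_min_distance needs non-empty meshes")
  A <- a$vertices; B <- b$vertices
  best <- Inf; bi <- NA_integer_; bj <- NA_integer_
  starts <- seq.int(1L, nrow(A), by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, nrow(A))
    r <- .min_dist_block(A[s:e, , drop = FALSE], B)
    ia <- r$ia + s - 1L
    if (r$d2 < best || (r$d2 == best && (ia < bi || (ia == bi && r$ib < bj)))) {
      best <- r$d2; bi <- ia; bj <- r$ib
    }
  }
  list(distance = sqrt(best), index_a = bi, index_b = bj,
       point_a = A[bi, ], point_b = B[bj, ])
}
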