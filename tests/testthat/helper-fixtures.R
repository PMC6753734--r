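# Shared fixture builders and independent oracles. Heavy fixtures (the default
# gantry head and calibration phantom with their OBB trees) are memoised in a
# session-level cache because several files use them.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

default_head <- function() cached_fixture("head", function() build_gantry_head_mesh())
default_head_tree <- function() cached_fixture("head_tree", function() build_obb_tree(default_head()))
default_phantom <- function() cached_fixture("phantom", function() make_cuboid_phantom())
default_body_tree <- function() cached_fixture("body_tree", function() build_obb_tree(default_phantom()$body))
default_board_tree <- function() cached_fixture("board_tree", function() build_obb_tree(default_phantom()$board))

# random point-cloud mesh (no faces needed for distance work)
random_mesh <- function(n, offset = c(0, 0, 0), scale = 1, name = "random") {
  triangle_mesh(matrix(rnorm(n * 3, sd = scale), ncol = 3) +
                  rep(offset, each = n), name = name)
}

# random triangulated mesh for file round trips
random_tri_mesh <- function(n_vert = 50, n_face = 60, name = "rtri") {
  f <- t(replicate(n_face, sample.int(n_vert, 3L)))
  triangle_mesh(matrix(runif(n_vert * 3, -10, 10), ncol = 3), f, name)
}

# independent cross-check of the vertex-pair minimum: plain double loop
naive_min_distance <- function(a, b) {
  A <- a$vertices; B <- b$vertices
  best <- Inf; bi <- NA; bj <- NA
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d < best) { best <- d; bi <- i; bj <- j }
  }
  list(distance = best, index_a = bi, index_b = bj)
}

# random OBB with a random orientation (QR of a Gaussian matrix)
random_obb <- function(center_spread = 2, max_half = 1.5) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  structure(list(center = rnorm(3, sd = center_spread),
                 axes = q,
                 half = runif(3, 0.05, max_half)), class = "obb")
}

# Independent convex-intersection / distance oracle: alternating projections
# between the two boxes (projection onto a box is a clamp in its own frame).
# For two closed convex sets this converges to a closest pair, so the distance
# is 0 iff the boxes intersect.
ap_box_distance <- function(a, b, iters = 5000, tol = 1e-13) {
  proj <- function(box, p) {
    loc <- as.numeric(crossprod(box$axes, p - box$center))
    loc <- pmin(pmax(loc, -box$half), box$half)
    as.numeric(box$center + box$axes %*% loc)
  }
  y <- b$center; d_prev <- Inf
  for (k in seq_len(iters)) {
    x <- proj(a, y); y <- proj(b, x)
    d <- sqrt(sum((x - y)^2))
    if (d_prev - d < tol) break
    d_prev <- d
  }
  d
}

# structural audit of a built OBB tree: exact disjoint partition of the vertex
# set across leaves, and every node's box contains its subtree's vertices
audit_tree <- function(tree, inflate = 1e-7) {
  V <- tree$vertices
  leaves <- which(is.na(tree$left))
  all_idx <- sort(unlist(tree$leaf_vidx[leaves]))
  partition_ok <- identical(all_idx, seq_len(nrow(V)))
  owned <- function(k) {
    if (is.na(tree$left[k])) return(tree$leaf_vidx[[k]])
    c(owned(tree$left[k]), owned(tree$right[k]))
  }
  contain_ok <- TRUE
  for (k in seq_along(tree$left)) {
    idx <- owned(k)
    loc <- abs(sweep(V[idx, , drop = FALSE], 2L, tree$centers[k, ]) %*% tree$axes[[k]])
    if (any(sweep(loc, 2L, tree$half[k, ] + inflate) > 0)) contain_ok <- FALSE
  }
  list(partition_ok = partition_ok, contain_ok = contain_ok)
}
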