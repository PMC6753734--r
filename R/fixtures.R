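# Synthetic test geometry: a tessellated-box primitive, the cuboid calibration
# phantom (solid-water block on an immobilization board), a schematic
# anthropomorphic upper-body phantom (ellipsoid head, elliptic-cylinder neck,
# filleted chest slab), and named end-to-end scenes. Phantom realism is
# intentionally schematic: what the test surface exercises is geometry (oracle
# equivalence, lateral symmetry, margin behavior), not anatomical fidelity.

.grid_coords <- function(a, b, res) {
  n <- max(1L, as.integer(ceiling((b - a) / res - 1e-9)))
  v <- a + (0:n) * ((b - a) / n)
  v[n + 1L] <- b
  v
}

# one rectangular face of a box, gridded; fixed axis `k` at value `val`
.box_face <- function(k, val, u_coords, w_coords) {
  nu <- length(u_coords); nw <- length(w_coords)
  g <- cbind(rep(u_coords, times = nw), rep(w_coords, each = nu))
  verts <- matrix(0, nrow(g), 3L)
  other <- setdiff(1:3, k)
  verts[, k] <- val; verts[, other[1L]] <- g[, 1L]; verts[, other[2L]] <- g[, 2L]
  id <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nw - 1L)
  j <- rep(seq_len(nw - 1L), each = nu - 1L)
  faces <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                 cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  list(verts = verts, faces = faces)
}

#' Axis-aligned tessellated box mesh
#'
#' All six faces gridded at approximately `resolution` cm edge length, shared
#' edge/corner vertices welded exactly.
#'
#' @param lo,hi Length-3 opposite corners (cm), `lo < hi` componentwise.
#' @param resolution Target grid edge length, cm.
#' @param name Mesh label.
#' @return A `triangle_mesh`.
#' @export
tessellated_box <- function(lo, hi, resolution = 2, name = "box") {
  if (any(hi <= lo)) stop("box needs hi > lo componentwise")
  cs <- lapply(1:3, function(k) .grid_coords(lo[k], hi[k], resolution))
  parts <- list()
  for (k in 1:3) {
    other <- setdiff(1:3, k)
    parts[[length(parts) + 1L]] <- .box_face(k, lo[k], cs[[other[1L]]], cs[[other[2L]]])
    parts[[length(parts) + 1L]] <- .box_face(k, hi[k], cs[[other[1L]]], cs[[other[2L]]])
  }
  offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$verts), 0L)))
  verts <- do.call(rbind, lapply(parts, `[[`, "verts"))
  faces <- do.call(rbind, Map(function(p, o) p$faces + o, parts, offs[-length(offs)]))
  .weld_vertices(verts, faces, name)
}

#' Cuboid calibration phantom on an immobilization board
#'
#' A laterally symmetric solid block centered on the midsagittal plane
#' (`x = 0`) with its posterior face resting on the board plane, plus the
#' board itself. The phantom is placed so the chosen (laterally symmetric)
#' isocenter is the origin.
#'
#' @param dims Length-3 dims in cm: lateral (x), anterior-posterior (y),
#'   longitudinal (z). Default 30 x 20 x 20.
#' @param resolution Tessellation edge length, cm.
#' @param posterior_y y level of the phantom's posterior face (board plane).
#' @return A list with `body` and `board` (`triangle_mesh` objects).
#' @export
make_cuboid_phantom <- function(dims = c(30, 20, 20), resolution = 2,
                                posterior_y = 10) {
  if (any(dims <= 0) || resolution <= 0) stop("invalid phantom spec")
  body <- tessellated_box(
    c(-dims[1L] / 2, posterior_y - dims[2L], -dims[3L] / 2),
    c(dims[1L] / 2, posterior_y, dims[3L] / 2),
    resolution, name = "calibration_phantom")
  board <- build_couch_board_mesh("board_with_head_extension",
                                  dims = c(50, 5, 60), top_y = posterior_y,
                                  extension = c(30, 4, 20),
                                  resolution = max(resolution, 4),
                                  z_superior = dims[3L] / 2 + 5)
  list(body = body, board = board)
}

.phantom_scales <- c(small = 0.9, medium = 1, large = 1.1)

#' Schematic anthropomorphic upper-body phantom
#'
#' Ellipsoidal head, elliptic-cylinder neck, and a chest/shoulder slab with a
#' filleted (superelliptic) anterior profile, in three sizes. Exactly
#' laterally symmetric about `x = 0`. The returned mesh carries a
#' `base_of_skull` landmark (attribute `landmarks`) — the inferior-posterior
#' skull point used to place worst-case radiosurgery isocenters.
#'
#' @param size `"small"`, `"medium"`, or `"large"` (0.9x / 1x / 1.1x scale).
#' @param n_theta Vertices per ring (even).
#' @param posterior_y y level of the posterior (couch-side) surface, cm.
#' @param head_top_z Superior extreme of the head (the stature parameter), cm.
#' @return A `triangle_mesh` with `datums` and `landmarks` attributes.
#' @export
make_upper_body_phantom <- function(size = c("medium", "small", "large"),
                                    n_theta = 32L, posterior_y = 10,
                                    head_top_z = 12) {
  size <- match.arg(size)
  s <- .phantom_scales[[size]]
  n <- as.integer(n_theta)
  if (n %% 2L != 0L) stop("n_theta must be even (lateral symmetry)")

  head_rx <- 8 * s; head_ry <- 10 * s; head_rz <- 11.5 * s
  head_cy <- posterior_y - head_ry      # posterior scalp on the couch plane
  head_cz <- head_top_z - head_rz
  neck_r <- 5.5 * s; neck_len <- 6 * s
  neck_top <- head_cz                    # neck disappears into the head
  neck_bot <- neck_top - neck_len
  chest_w <- 44 * s; chest_ap <- 22 * s; chest_len <- 32 * s

  verts <- list(); faces <- list(); nv <- 0L
  add <- function(v, f) {
    faces[[length(faces) + 1L]] <<- f + nv
    verts[[length(verts) + 1L]] <<- v
    nv <<- nv + nrow(v)
  }

  # head: lat-long ellipsoid
  nphi <- n %/% 2L
  phis <- pi * seq_len(nphi - 1L) / nphi
  ring_v <- lapply(phis, function(ph)
    cbind(head_rx * sin(ph) * cos(2 * pi * (0:(n - 1L)) / n),
          head_cy + head_ry * sin(ph) * sin(2 * pi * (0:(n - 1L)) / n),
          head_cz + head_rz * cos(ph)))
  hv <- do.call(rbind, c(list(matrix(c(0, head_cy, head_cz + head_rz), 1L, 3L)),
                         ring_v,
                         list(matrix(c(0, head_cy, head_cz - head_rz), 1L, 3L))))
  i <- seq_len(n); j <- c(i[-1L], 1L)
  hf <- rbind(cbind(1L, 1L + i, 1L + j))
  for (k in seq_len(nphi - 2L)) {
    o1 <- 1L + (k - 1L) * n; o2 <- o1 + n
    hf <- rbind(hf, .ring_strip_faces(o1, o2, n))
  }
  last <- 1L + (nphi - 2L) * n
  hf <- rbind(hf, cbind(last + i, last + j, nrow(hv)))
  add(hv, hf)

  # neck: elliptic cylinder shell
  nz <- 4L
  zs <- neck_bot + (0:nz) * (neck_top - neck_bot) / nz
  nvrt <- do.call(rbind, lapply(zs, function(z)
    cbind(neck_r * cos(2 * pi * (0:(n - 1L)) / n),
          head_cy + 1.1 * neck_r * sin(2 * pi * (0:(n - 1L)) / n),
          z)))
  nf <- do.call(rbind, lapply(seq_len(nz), function(k)
    .ring_strip_faces((k - 1L) * n, k * n, n)))
  add(nvrt, nf)

  # chest: extruded superellipse (filleted-rectangle) cross-section
  m <- 4                                 # superellipse exponent
  th <- 2 * pi * (0:(n - 1L)) / n
  cx <- (chest_w / 2) * sign(cos(th)) * abs(cos(th))^(2 / m)
  cy0 <- posterior_y - chest_ap / 2
  cyv <- cy0 + (chest_ap / 2) * sign(sin(th)) * abs(sin(th))^(2 / m)
  z1 <- neck_bot; z0 <- z1 - chest_len
  nzc <- 8L
  zc <- z0 + (0:nzc) * (z1 - z0) / nzc
  cvrt <- do.call(rbind, lapply(zc, function(z) cbind(cx, cyv, z)))
  cf <- do.call(rbind, lapply(seq_len(nzc), function(k)
    .ring_strip_faces((k - 1L) * n, k * n, n)))
  # end caps (fans)
  cvrt <- rbind(cvrt, c(0, cy0, z0), c(0, cy0, z1))
  cap0 <- nrow(cvrt) - 1L; cap1 <- nrow(cvrt)
  cf <- rbind(cf, cbind(j, i, cap0), cbind(nzc * n + i, nzc * n + j, cap1))
  add(cvrt, cf)

  mesh <- triangle_mesh(do.call(rbind, verts), do.call(rbind, faces),
                        sprintf("upper_body_%s", size))
  ext <- mesh_extents(mesh)
  attr(mesh, "datums") <- list(posterior_y = ext$max[2L],
                               midline_x = (ext$min[1L] + ext$max[1L]) / 2,
                               superior_z = ext$max[3L])
  attr(mesh, "landmarks") <- list(base_of_skull = c(0, head_cy + 0.6 * head_ry,
                                                    neck_top))
  mesh
}

#' Generate a named end-to-end scene
#'
#' Deterministic per seed. Scenarios:
#' \describe{
#'   \item{`calibration_sweep`}{Cuboid calibration phantom on its board with a
#'     13-beam plan, one full-circle arc at each couch angle 90..270 in 15 deg
#'     steps (the calibration sweep design).}
#'   \item{`srs_four_isocenters`}{Upper-body phantom with four plans whose
#'     isocenters sit at the base of skull shifted anterior/posterior x
#'     left/right — the worst-case radiosurgery isocenter grid.}
#'   \item{`collision_demo`}{A block whose anterior face touches the gantry
#'     face at gantry 0, so at least one pose is verified (by brute force) to
#'     be exactly intersecting.}
#'   \item{`clear_demo`}{A small central block every pose clears widely.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed recorded in the manifest and used for any jitter.
#' @return A list of class `scene`: `scenario`, `seed`, `body`, `couch`,
#'   `addons`, `machine_params`, `chirality`, `plans` (named list of
#'   `treatment_plan`), `manifest`.
#' @export
make_scene <- function(scenario = c("calibration_sweep", "srs_four_isocenters",
                                    "collision_demo", "clear_demo"),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  machine <- gantry_head_params()
  couch_angles <- seq(90, 270, by = 15)
  full_arc <- function(id, couch, shift = c(0, 0, 0))
    plan_beam(beam_id = id, couch_deg = couch, collimator_deg = 0,
              gantry_start_deg = 0, gantry_stop_deg = 355,
              rotation_direction = "CW", isocenter_shift = shift)

  if (scenario == "calibration_sweep") {
    ph <- make_cuboid_phantom()
    beams <- Map(function(k, c_) full_arc(sprintf("arc_c%03d", c_), c_),
                 seq_along(couch_angles), couch_angles)
    plans <- list(calibration = treatment_plan("calibration_sweep", beams))
    body <- ph$body; couch <- ph$board; addons <- list()
  } else if (scenario == "srs_four_isocenters") {
    body <- make_upper_body_phantom("medium")
    couch <- build_couch_board_mesh("board_with_head_extension",
                                    dims = c(50, 5, 80), top_y = 10,
                                    extension = c(30, 4, 20), resolution = 4,
                                    z_superior = 2)
    bos <- attr(body, "landmarks")$base_of_skull
    shifts <- list(right_post = bos + c(-2, 2, 0), right_ant = bos + c(-2, -2, 0),
                   left_post = bos + c(2, 2, 0), left_ant = bos + c(2, -2, 0))
    plans <- lapply(names(shifts), function(nm) {
      beams <- Map(function(k, c_) full_arc(sprintf("%s_c%03d", nm, c_), c_,
                                            shifts[[nm]]),
                   seq_along(couch_angles), couch_angles)
      treatment_plan(nm, beams, isocenter_shift = shifts[[nm]])
    })
    names(plans) <- names(shifts)
    addons <- list()
  } else if (scenario == "collision_demo") {
    f <- machine$face_to_iso
    body <- tessellated_box(c(-10, -f, -10), c(10, -f + 20, 10), 2,
                            name = "collision_block")
    couch <- build_couch_board_mesh("flat_couch_top", dims = c(40, 5, 60),
                                    top_y = 15, resolution = 5, z_superior = 30)
    plans <- list(demo = treatment_plan("collision_demo",
                                        list(full_arc("arc_c000", 0))))
    addons <- list()
  } else {                               # clear_demo
    body <- tessellated_box(c(-5, -5, -5), c(5, 5, 5), 2, name = "clear_block")
    couch <- build_couch_board_mesh("flat_couch_top", dims = c(30, 4, 40),
                                    top_y = 8, resolution = 5, z_superior = 20)
    plans <- list(demo = treatment_plan("clear_demo",
                                        list(full_arc("arc_c000", 0))))
    addons <- list()
  }

  scene <- structure(list(scenario = scenario, seed = as.integer(seed),
                          body = body, couch = couch, addons = addons,
                          machine_params = machine, chirality = 1,
                          plans = plans,
                          manifest = list(scenario = scenario, seed = as.integer(seed),
                                          n_body_vertices = nrow(body$vertices),
                                          n_couch_vertices = nrow(couch$vertices),
                                          plan_ids = names(plans))),
                     class = "scene")

  if (scenario == "collision_demo") {
    # verify the constructed intersection: the block's anterior-face center
    # vertex coincides with the gantry face center at gantry 0
    head <- build_gantry_head_mesh(machine)
    d0 <- brute_force_min_distance(
      body, apply_transform(head, machine_pose(0, 0, 0)))$distance
    if (d0 != 0) stop("collision_demo failed its intersection audit")
    scene$manifest$verified_intersection_gantry_deg <- 0
  }
  scene
}

#' Write a scene to a directory
#'
#' Writes `body.stl`, `couch.stl`, any addons, `machine.json`, one
#' `plan_<id>.json` per plan, and `manifest.json`.
#'
#' @param scene A `scene` from [make_scene()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(scene$body, file.path(out_dir, "body.stl"))
  write_mesh(scene$couch, file.path(out_dir, "couch.stl"))
  for (nm in names(scene$addons))
    write_mesh(scene$addons[[nm]], file.path(out_dir, paste0(nm, ".stl")))
  write_machine_config(scene$machine_params, file.path(out_dir, "machine.json"),
                       chirality = scene$chirality)
  for (nm in names(scene$plans))
    write_plan(scene$plans[[nm]], file.path(out_dir, sprintf("plan_%s.json", nm)))
  jsonlite::write_json(scene$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
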