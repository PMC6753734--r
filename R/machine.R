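# Parametric linac machine model: gantry-head mesh built from physical casing
# measurements (circumference-vs-height profile, face projections such as
# locking pins and the tray insert), couch/board meshes, and the rigid pose of
# the machine for any (gantry, couch, collimator) triple in the fixed DICOM
# patient frame.
#
# Coordinate conventions (Varian IEC scale, head-first supine):
#   * patient frame: +x patient-left, +y patient-posterior, +z patient-superior
#   * room-vertical (up) = patient -y at couch 0
#   * gantry rotates about patient +z at couch 0; gantry 0 = source anterior;
#     the angle increases toward patient-left (gantry 90: source on the
#     patient's left)
#   * couch angle rotates the machine by -couch_deg about room-vertical
#     (equivalently the patient by +couch_deg); the patient and couch meshes
#     themselves never move
#   * collimator spins the head about the beam axis
# A chirality flag flips the gantry sense for non-Varian scales.

#' Gantry head parameters
#'
#' Physical description of the gantry head used to build the collision model:
#' the casing is an extrusion of a circumference-vs-height profile (linearly
#' interpolated between measured heights), only the `casing_length` cm nearest
#' the face — the part relevant to collision prevention — is modeled, and
#' cylindrical bosses on the face represent major projections (locking pins,
#' horseshoe tray insert).
#'
#' @param casing_length Modeled casing depth behind the face, cm (default 14).
#' @param face_to_iso Distance from the face plane to isocenter, cm. The
#'   default 40 is a machine-specific placeholder users should calibrate; it
#'   is adjustable exactly because it varies between installations.
#' @param profile Data frame with columns `height` (cm behind the face,
#'   strictly increasing, starting at 0) and `circumference` (cm).
#' @param projections Data frame with columns `name`, `diameter` (cm),
#'   `projection` (cm toward isocenter), `offset_x`, `offset_z` (cm position
#'   in the face plane). May have zero rows.
#' @param n_theta Vertices per circumferential ring (even, so the mesh is
#'   exactly mirror-symmetric about the sagittal plane at gantry 0).
#' @param ring_spacing Axial spacing of casing rings, cm.
#' @param n_boss_theta Vertices per boss ring.
#' @param target_vertex_count Reference vertex count of the CAD model the
#'   defaults emulate (1639); [build_gantry_head_mesh()] checks the built mesh
#'   is within +/-20% of it.
#' @return A list of class `gantry_head_params`.
#' @export
gantry_head_params <- function(casing_length = 14,
                               face_to_iso = 40,
                               profile = data.frame(
                                 height = c(0, 4, 8, 14),
                                 circumference = c(220, 238, 256, 276)),
                               projections = data.frame(
                                 name = c("locking_pin_left", "locking_pin_right",
                                          "horseshoe_tray_insert"),
                                 diameter = c(4, 4, 26),
                                 projection = c(2.5, 2.5, 4),
                                 offset_x = c(18, -18, 0),
                                 offset_z = c(8, 8, -4)),
                               n_theta = 48L,
                               ring_spacing = 0.6,
                               n_boss_theta = 32L,
                               target_vertex_count = 1639L) {
  if (casing_length <= 0 || face_to_iso <= 0 || ring_spacing <= 0)
    stop("parameter error: lengths must be positive")
  if (nrow(profile) < 2L || any(diff(profile$height) <= 0))
    stop("parameter error: profile heights must be strictly increasing")
  if (any(profile$circumference <= 0))
    stop("parameter error: circumferences must be positive")
  if (nrow(projections) > 0L) {
    if (any(projections$diameter <= 0) || any(projections$projection <= 0))
      stop("parameter error: projection dimensions must be positive")
    if (max(projections$projection) >= face_to_iso)
      stop("parameter error: face_to_iso must exceed the largest projection")
    face_r <- profile$circumference[1L] / (2 * pi)
    reach <- sqrt(projections$offset_x^2 + projections$offset_z^2) +
      projections$diameter / 2
    if (any(reach > face_r))
      stop("parameter error: projection overlaps the casing boundary")
  }
  structure(list(casing_length = casing_length, face_to_iso = face_to_iso,
                 profile = profile, projections = projections,
                 n_theta = as.integer(n_theta),
                 ring_spacing = ring_spacing,
                 n_boss_theta = as.integer(n_boss_theta),
                 target_vertex_count = as.integer(target_vertex_count)),
            class = "gantry_head_params")
}

# ring of n points of radius r in the x-z plane at height y
.ring <- function(r, y, n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(th), rep(y, n), r * sin(th))
}

# faces joining two consecutive rings of equal length (1-based offsets)
.ring_strip_faces <- function(off1, off2, n) {
  i <- seq_len(n); j <- c(seq_len(n - 1L) + 1L, 1L)
  rbind(cbind(off1 + i, off1 + j, off2 + i),
        cbind(off2 + i, off1 + j, off2 + j))
}

#' Build the parametric gantry-head mesh
#'
#' Constructs the head in its canonical frame: the face plane at
#' `y = -face_to_iso` (gantry 0, source anterior), the casing extruded away
#' from isocenter along -y with ring radii from the linearly interpolated
#' circumference profile, the face triangulated as concentric rings, and each
#' face projection as a cylindrical boss protruding toward isocenter. With no
#' projections the vertex nearest the isocenter is the face center at distance
#' `face_to_iso`; a centered boss brings it to `face_to_iso - projection`.
#'
#' @param p A `gantry_head_params` object.
#' @return A `triangle_mesh` named `"gantry_head"`.
#' @export
build_gantry_head_mesh <- function(p = gantry_head_params()) {
  stopifnot(inherits(p, "gantry_head_params"))
  f <- p$face_to_iso; n <- p$n_theta
  heights <- unique(c(seq(0, p$casing_length, by = p$ring_spacing), p$casing_length))
  radii <- approx(p$profile$height, p$profile$circumference, xout = heights,
                  rule = 2)$y / (2 * pi)
  verts <- list(); faces <- list(); nv <- 0L

  # casing rings (height h behind the face -> y = -(f + h))
  ring_off <- integer(length(heights))
  for (k in seq_along(heights)) {
    ring_off[k] <- nv
    verts[[length(verts) + 1L]] <- .ring(radii[k], -(f + heights[k]), n)
    nv <- nv + n
  }
  for (k in seq_len(length(heights) - 1L))
    faces[[length(faces) + 1L]] <- .ring_strip_faces(ring_off[k], ring_off[k + 1L], n)

  # face disk: concentric rings from the casing rim down to a center vertex
  nr_face <- 4L
  inner_off <- ring_off[1L]
  for (jr in seq_len(nr_face - 1L)) {
    r_in <- radii[1L] * (nr_face - jr) / nr_face
    off <- nv
    verts[[length(verts) + 1L]] <- .ring(r_in, -f, n)
    nv <- nv + n
    faces[[length(faces) + 1L]] <- .ring_strip_faces(inner_off, off, n)
    inner_off <- off
  }
  verts[[length(verts) + 1L]] <- matrix(c(0, -f, 0), 1L, 3L)
  face_center <- nv + 1L; nv <- nv + 1L
  i <- seq_len(n); j <- c(i[-1L], 1L)
  faces[[length(faces) + 1L]] <- cbind(inner_off + i, inner_off + j, face_center)

  # back cap: fan from the last ring to its center
  verts[[length(verts) + 1L]] <- matrix(c(0, -(f + p$casing_length), 0), 1L, 3L)
  back_center <- nv + 1L; nv <- nv + 1L
  bo <- ring_off[length(heights)]
  faces[[length(faces) + 1L]] <- cbind(bo + j, bo + i, back_center)

  # face projections: open cylinders with a capped tip, protruding toward iso
  nb <- p$n_boss_theta
  if (nrow(p$projections) > 0L) {
    for (q in seq_len(nrow(p$projections))) {
      pr <- p$projections[q, ]
      shift <- c(pr$offset_x, 0, pr$offset_z)
      base_off <- nv
      verts[[length(verts) + 1L]] <-
        sweep(.ring(pr$diameter / 2, -f, nb), 2L, shift, "+")
      nv <- nv + nb
      tip_off <- nv
      verts[[length(verts) + 1L]] <-
        sweep(.ring(pr$diameter / 2, -f + pr$projection, nb), 2L, shift, "+")
      nv <- nv + nb
      faces[[length(faces) + 1L]] <- .ring_strip_faces(base_off, tip_off, nb)
      verts[[length(verts) + 1L]] <-
        matrix(shift + c(0, -f + pr$projection, 0), 1L, 3L)
      tc <- nv + 1L; nv <- nv + 1L
      ib <- seq_len(nb); jb <- c(ib[-1L], 1L)
      faces[[length(faces) + 1L]] <- cbind(tip_off + ib, tip_off + jb, tc)
    }
  }

  mesh <- triangle_mesh(do.call(rbind, verts), do.call(rbind, faces), "gantry_head")
  dev <- abs(nrow(mesh$vertices) - p$target_vertex_count) / p$target_vertex_count
  if (dev > 0.2)
    warning(sprintf("gantry head has %d vertices, > 20%% from the reference %d",
                    nrow(mesh$vertices), p$target_vertex_count))
  mesh
}

#' Build a couch / immobilization-board mesh
#'
#' Cuboid-composite couch-side structures: a flat couch top, or an
#' immobilization board whose head extension reaches superiorly beyond the
#' couch top. The posterior (patient-down, +y) structure surface sits at
#' `top_y`. Meshes carry registration datums (posterior plane, lateral
#' midline, superior face) as the `datums` attribute.
#'
#' @param kind `"flat_couch_top"` or `"board_with_head_extension"`.
#' @param dims Length-3 positive dims in cm: lateral (x), thickness (y),
#'   longitudinal (z). For the board, the dims of the board itself.
#' @param top_y y level of the structure's anterior (patient-side) surface, cm.
#' @param extension For the board kind: `c(width, thickness, length)` of the
#'   head extension protruding superiorly, cm.
#' @param resolution Target tessellation edge length, cm.
#' @param z_superior Superior z of the main slab, cm.
#' @return A `triangle_mesh` with a `datums` attribute.
#' @export
build_couch_board_mesh <- function(kind = c("flat_couch_top", "board_with_head_extension"),
                                   dims = c(50, 5, 200), top_y = 10,
                                   extension = c(30, 4, 25), resolution = 5,
                                   z_superior = 20) {
  kind <- match.arg(kind)
  if (any(dims <= 0)) stop("non-positive couch dims")
  slab <- tessellated_box(
    c(-dims[1L] / 2, top_y, z_superior - dims[3L]),
    c(dims[1L] / 2, top_y + dims[2L], z_superior),
    resolution, name = kind)
  if (kind == "board_with_head_extension") {
    if (any(extension <= 0)) stop("non-positive extension dims")
    ext <- tessellated_box(
      c(-extension[1L] / 2, top_y, z_superior),
      c(extension[1L] / 2, top_y + extension[2L], z_superior + extension[3L]),
      resolution, name = "head_extension")
    slab <- merge_meshes(list(slab, ext), name = kind)
  }
  ext <- mesh_extents(slab)
  attr(slab, "datums") <- list(posterior_y = ext$max[2L],
                               midline_x = (ext$min[1L] + ext$max[1L]) / 2,
                               superior_z = ext$max[3L])
  slab
}

#' Concatenate meshes into one
#'
#' @param meshes List of `triangle_mesh` objects.
#' @param name Name for the combined mesh.
#' @return A `triangle_mesh`.
#' @export
merge_meshes <- function(meshes, name = "merged") {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), 0L)))
  triangle_mesh(do.call(rbind, lapply(meshes, `[[`, "vertices")),
                do.call(rbind, Map(function(m, o) m$faces + o,
                                   meshes, offs[-length(offs)])),
                name)
}

.normalize_angle <- function(deg, what) {
  if (any(deg < 0 | deg >= 360)) {
    warning(sprintf("%s angle outside [0,360); normalizing", what))
    deg <- deg %% 360
  }
  deg
}

#' Rigid pose of the gantry head for a machine configuration
#'
#' Composes, right to left: the collimator spin about the beam axis, the
#' gantry rotation about the gantry axis, the couch rotation of the machine by
#' `-couch_deg` about room-vertical (the patient frame stays fixed), and the
#' isocenter shift translating the whole machine assembly. Applying the result
#' to the canonical head mesh yields its pose in the fixed patient frame; at
#' (0, 0, 0) with zero shift the face center sits at `(0, -face_to_iso, 0)`.
#'
#' @param gantry_deg,couch_deg,collimator_deg Angles in degrees, `[0, 360)`
#'   (values outside are normalized with a warning).
#' @param isocenter_shift Position of the plan isocenter relative to the
#'   patient mesh origin, cm; translates the machine assembly (the patient
#'   never moves).
#' @param chirality `+1` for the Varian IEC sense (gantry angle increases
#'   toward patient-left); `-1` flips it.
#' @return A `rigid_transform`.
#' @export
machine_pose <- function(gantry_deg, couch_deg = 0, collimator_deg = 0,
                         isocenter_shift = c(0, 0, 0), chirality = 1) {
  g <- .normalize_angle(gantry_deg, "gantry")
  c_ <- .normalize_angle(couch_deg, "couch")
  k <- .normalize_angle(collimator_deg, "collimator")
  s <- if (chirality >= 0) 1 else -1
  R <- rotation_about_axis("y", s * c_) %*%
    rotation_about_axis("z", s * g) %*%
    rotation_about_axis("y", k)
  rigid_transform(R, isocenter_shift)
}

#' Write / read a machine configuration JSON
#'
#' Versioned description of the gantry-head parameters and the coordinate
#' convention flags, so a site-calibrated model travels with its plans.
#'
#' @param params A `gantry_head_params` object.
#' @param path Path of the JSON file.
#' @param chirality Convention flag stored alongside (see [machine_pose()]).
#' @return For the writer, `path` invisibly; for the reader, a list with
#'   `params` and `chirality`.
#' @export
write_machine_config <- function(params, path, chirality = 1) {
  obj <- list(version = 1L,
              chirality = chirality,
              gantry_head = list(
                casing_length = params$casing_length,
                face_to_iso = params$face_to_iso,
                profile = params$profile,
                projections = params$projections,
                n_theta = params$n_theta,
                ring_spacing = params$ring_spacing,
                n_boss_theta = params$n_boss_theta,
                target_vertex_count = params$target_vertex_count))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_machine_config
#' @export
read_machine_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gh <- obj$gantry_head
  proj <- gh$projections
  if (is.null(proj) || length(proj) == 0L)
    proj <- data.frame(name = character(), diameter = numeric(),
                       projection = numeric(), offset_x = numeric(),
                       offset_z = numeric())
  list(params = gantry_head_params(
         casing_length = gh$casing_length, face_to_iso = gh$face_to_iso,
         profile = as.data.frame(gh$profile),
         projections = as.data.frame(proj),
         n_theta = gh$n_theta, ring_spacing = gh$ring_spacing,
         n_boss_theta = gh$n_boss_theta,
         target_vertex_count = gh$target_vertex_count),
       chirality = if (is.null(obj$chirality)) 1 else obj$chirality)
}
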