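# Extremal-coordinate auto-registration: places auxiliary body additions
# (e.g. a shoulders/chest phantom extending a chin-to-crown scan inferiorly)
# and detailed couch structures onto the patient body contour using the body's
# anterior-posterior, left-right and superior extremes. Translation-only by
# design: couch-mounted hardware shares the patient frame axes, and a
# translation is reproducible and manually adjustable.

#' Declare registration datums on an add-on mesh
#'
#' Add-on structures carry three reference datums the aligner maps onto body
#' extremes: the posterior plane (`posterior_y`), the lateral midline
#' (`midline_x`), and the superior face (`superior_z`).
#'
#' @param mesh A `triangle_mesh`.
#' @param posterior_y,midline_x,superior_z Datum coordinates, cm. Defaults are
#'   taken from the mesh extents (posterior extreme, lateral midpoint,
#'   superior extreme).
#' @return The mesh with a `datums` attribute.
#' @export
set_mesh_datums <- function(mesh, posterior_y = NULL, midline_x = NULL,
                            superior_z = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- mesh_extents(mesh)
  attr(mesh, "datums") <- list(
    posterior_y = if (is.null(posterior_y)) ext$max[2L] else posterior_y,
    midline_x = if (is.null(midline_x)) (ext$min[1L] + ext$max[1L]) / 2 else midline_x,
    superior_z = if (is.null(superior_z)) ext$max[3L] else superior_z)
  mesh
}

#' Automatically register an add-on structure to the body contour
#'
#' Translation-only alignment from the body's extremal coordinates:
#' the add-on's posterior datum goes to the body's posterior extreme (AP), its
#' lateral midline to the midpoint of the body's lateral extremes (LR), and in
#' the longitudinal direction its superior face goes to the body's inferior
#' extreme for `mode = "body_addition"` (extending a head-only scan
#' inferiorly) or to the body's superior extreme minus `head_offset_cm` for
#' `mode = "couch_structure"`.
#'
#' @param body Patient body `triangle_mesh` (non-empty).
#' @param addon Add-on `triangle_mesh` carrying datums (see
#'   [set_mesh_datums()]); couch meshes built by [build_couch_board_mesh()]
#'   already carry them.
#' @param mode `"body_addition"` or `"couch_structure"`.
#' @param head_offset_cm Superior setback of a couch structure below the body
#'   superior extreme, cm.
#' @param overlap_tolerance_cm Extents-based penetration depth above which a
#'   warning (not an error — placement is manually adjustable) is issued.
#' @return An object of class `registration_result`: `transform`
#'   (translation-only `rigid_transform`), `aligned_structure`, `mode`.
#' @export
auto_register <- function(body, addon,
                          mode = c("body_addition", "couch_structure"),
                          head_offset_cm = 0, overlap_tolerance_cm = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(body, "triangle_mesh"), inherits(addon, "triangle_mesh"))
  if (nrow(body$vertices) == 0L || nrow(addon$vertices) == 0L)
    stop("empty-mesh: registration needs non-empty meshes")
  d <- attr(addon, "datums")
  if (is.null(d)) stop("addon has no registration datums (see set_mesh_datums)")
  be <- mesh_extents(body)
  dx <- (be$min[1L] + be$max[1L]) / 2 - d$midline_x
  dy <- be$max[2L] - d$posterior_y
  dz <- if (mode == "body_addition") be$min[3L] - d$superior_z
        else (be$max[3L] - head_offset_cm) - d$superior_z
  tr <- rt_translation(c(dx, dy, dz))
  aligned <- apply_transform(addon, tr)

  ae <- mesh_extents(aligned)
  pen <- pmin(ae$max, be$max) - pmax(ae$min, be$min)
  if (all(pen > overlap_tolerance_cm))
    warning(sprintf(
      "registered addon overlaps body extents by %.1f cm; adjust manually if needed",
      min(pen)))
  structure(list(transform = tr, aligned_structure = aligned, mode = mode),
            class = "registration_result")
}

#' Apply a manual offset to a registration
#'
#' Numeric stand-in for interactive adjustment of an unsatisfactory automatic
#' placement: composes a pure translation with the existing registration.
#' Idempotent with a zero offset.
#'
#' @param result A `registration_result`.
#' @param offset Length-3 translation, cm.
#' @return The adjusted `registration_result`.
#' @export
apply_manual_offset <- function(result, offset) {
  stopifnot(inherits(result, "registration_result"))
  offset <- as.numeric(offset)
  if (length(offset) != 3L || !all(is.finite(offset))) stop("offset must be finite length-3")
  tr <- rt_compose(rt_translation(offset), result$transform)
  result$aligned_structure <- apply_transform(result$aligned_structure,
                                              rt_translation(offset))
  result$transform <- tr
  result
}

#' Save / load an add-on structure with its registration sidecar
#'
#' The add-on library convention: a mesh file plus a JSON sidecar declaring
#' the registration datums and intended mode, so site-specific immobilization
#' hardware is stored once and reused.
#'
#' @param mesh A `triangle_mesh` with datums.
#' @param dir Library directory.
#' @param name Add-on name (file stem).
#' @param mode Intended registration mode.
#' @return Writer: the mesh path invisibly. Reader: the mesh with `datums`
#'   attribute and a `mode` attribute.
#' @export
write_addon <- function(mesh, dir, name,
                        mode = c("body_addition", "couch_structure")) {
  mode <- match.arg(mode)
  d <- attr(mesh, "datums")
  if (is.null(d)) stop("addon has no registration datums (see set_mesh_datums)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(name, ".stl"))
  write_mesh(mesh, mp)
  jsonlite::write_json(list(name = name, mode = mode, datums = d),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_addon
#' @export
read_addon <- function(dir, name) {
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  mesh <- read_mesh(file.path(dir, paste0(name, ".stl")), name = name)
  attr(mesh, "datums") <- as.list(side$datums)
  attr(mesh, "mode") <- side$mode
  mesh
}
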