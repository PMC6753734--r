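# Arc sampling, per-beam and per-plan collision testing, risk classification,
# maximum gantry-range search, and scene export. Gantry arcs are sampled at
# discrete control points (default every 5 degrees) with both endpoints always
# included; between-sample collisions are not detected, which is part of what
# the clinical safety margin absorbs.

#' Treatment beam description
#'
#' @param beam_id Identifier string.
#' @param couch_deg Couch angle, degrees in `[0, 360)`.
#' @param collimator_deg Collimator angle for the beam, degrees.
#' @param gantry_start_deg,gantry_stop_deg Arc control points, degrees.
#' @param rotation_direction `"CW"` (gantry angle increasing) or `"CCW"`.
#' @param static_beam `TRUE` for a fixed-gantry beam (start must equal stop).
#' @param isocenter_shift Isocenter position relative to the patient mesh
#'   origin, cm.
#' @return A list of class `plan_beam`.
#' @export
plan_beam <- function(beam_id, couch_deg, collimator_deg = 0,
                      gantry_start_deg, gantry_stop_deg,
                      rotation_direction = c("CW", "CCW"),
                      static_beam = FALSE, isocenter_shift = c(0, 0, 0)) {
  rotation_direction <- match.arg(rotation_direction)
  if (!static_beam && gantry_start_deg %% 360 == gantry_stop_deg %% 360)
    stop("zero-length arc: set static_beam = TRUE for a fixed-gantry beam")
  structure(list(beam_id = as.character(beam_id), couch_deg = couch_deg,
                 collimator_deg = collimator_deg,
                 gantry_start_deg = gantry_start_deg,
                 gantry_stop_deg = gantry_stop_deg,
                 rotation_direction = rotation_direction,
                 static_beam = isTRUE(static_beam),
                 isocenter_shift = as.numeric(isocenter_shift)),
            class = "plan_beam")
}

#' Treatment plan: a set of beams
#'
#' @param plan_id Identifier string.
#' @param beams List of `plan_beam` objects (>= 1).
#' @param isocenter_shift Plan-level isocenter shift applied to beams that do
#'   not set their own.
#' @return A list of class `treatment_plan`.
#' @export
treatment_plan <- function(plan_id, beams, isocenter_shift = c(0, 0, 0)) {
  if (length(beams) < 1L) stop("a plan needs at least one beam")
  stopifnot(all(vapply(beams, inherits, TRUE, "plan_beam")))
  structure(list(plan_id = as.character(plan_id), beams = beams,
                 isocenter_shift = as.numeric(isocenter_shift)),
            class = "treatment_plan")
}

#' Sample gantry angles along an arc
#'
#' Steps from the start control point in `step_deg` increments along the
#' travel direction, wrapping through 0/360, and always appends the stop
#' control point when it is off the step lattice (control points are physical
#' limits of travel).
#'
#' @param start_deg,stop_deg Arc control points, degrees in `[0, 360)`.
#' @param direction `"CW"` (increasing angle) or `"CCW"`.
#' @param step_deg Sampling interval, degrees (> 0); default 5.
#' @param static_beam `TRUE` returns the single start angle.
#' @return Numeric vector of gantry angles in `[0, 360)`, monotone along the
#'   travel direction, inclusive of both endpoints.
#' @export
sample_arc <- function(start_deg, stop_deg, direction = c("CW", "CCW"),
                       step_deg = 5, static_beam = FALSE) {
  direction <- match.arg(direction)
  if (step_deg <= 0) stop("step_deg must be > 0")
  if (static_beam) return(start_deg %% 360)
  travel <- if (direction == "CW") (stop_deg - start_deg) %% 360
            else (start_deg - stop_deg) %% 360
  if (travel == 0) stop("zero-length arc without static_beam")
  offs <- seq(0, travel, by = step_deg)
  if (offs[length(offs)] < travel) offs <- c(offs, travel)
  ang <- if (direction == "CW") start_deg + offs else start_deg - offs
  ang %% 360
}

#' Couch angles of the standard validation sweep
#'
#' The couch-range convention of the phantom validation studies: couch angles
#' every 15 degrees from 90 to 270 — 13 angles spanning the couch rotations a
#' noncoplanar treatment can use.
#'
#' @param from,to,by Sweep bounds and step, degrees.
#' @return Numeric vector of couch angles.
#' @export
couch_sweep_angles <- function(from = 90, to = 270, by = 15) seq(from, to, by = by)

#' Classify collision risk from a minimum clearance
#'
#' A beam is a `"CollisionRisk"` when its minimum predicted distance is
#' strictly below the safety margin, a `"NearCollisionRisk"` when the distance
#' lies within `near_band_cm` above the margin (half-open: exactly
#' `margin + near_band` is `"Clear"`), and `"Clear"` otherwise.
#'
#' @param min_distance_cm Minimum predicted clearance, cm (>= 0).
#' @param margin_cm Safety margin, cm; clinical default 5.
#' @param near_band_cm Width of the near-collision band above the margin, cm;
#'   default 10.
#' @return One of `"CollisionRisk"`, `"NearCollisionRisk"`, `"Clear"`
#'   (vectorized over `min_distance_cm`).
#' @export
classify_risk <- function(min_distance_cm, margin_cm = 5, near_band_cm = 10) {
  if (margin_cm < 0 || near_band_cm < 0) stop("margins must be >= 0")
  ifelse(min_distance_cm < margin_cm, "CollisionRisk",
         ifelse(min_distance_cm < margin_cm + near_band_cm,
                "NearCollisionRisk", "Clear"))
}

# one clearance evaluation: gantry tree posed against a fixed structure tree
.clearance_at <- function(structure_tree, gantry_tree, gantry_deg, beam, chirality) {
  tr <- machine_pose(gantry_deg, beam$couch_deg, beam$collimator_deg,
                     beam$isocenter_shift, chirality)
  tree_min_distance(structure_tree, gantry_tree, tr)
}

#' Test one beam for collisions along its arc
#'
#' Poses the gantry head at every sampled gantry angle of the beam's arc and
#' records the minimum vertex-pair distance to the body and to the couch
#' structure separately. The overall minimum (ties broken by earliest position
#' along the travel direction, body before couch at the same angle) determines
#' the beam's risk label.
#'
#' @param beam A `plan_beam`.
#' @param body_tree,couch_tree,gantry_tree `obb_tree` objects for the patient
#'   body, the couch structure, and the canonical gantry-head mesh.
#' @param margin_cm Safety margin, cm (default 5).
#' @param step_deg Gantry sampling interval, degrees (default 5).
#' @param near_band_cm Near-collision band width, cm (default 10).
#' @param chirality Machine convention flag (see [machine_pose()]).
#' @return An object of class `beam_result`: `beam_id`, `samples` (data frame
#'   with `couch_deg`, `gantry_deg`, `against`, `min_distance_cm` and witness
#'   coordinates), `overall_min` (one row of `samples`), `risk_label`, and the
#'   summed traversal stats.
#' @export
test_beam <- function(beam, body_tree, couch_tree, gantry_tree,
                      margin_cm = 5, step_deg = 5, near_band_cm = 10,
                      chirality = 1) {
  stopifnot(inherits(beam, "plan_beam"))
  if (is.null(body_tree)) stop("missing structure tree: body")
  if (is.null(couch_tree)) stop("missing structure tree: couch")
  if (is.null(gantry_tree)) stop("missing structure tree: gantry")
  angles <- sample_arc(beam$gantry_start_deg, beam$gantry_stop_deg,
                       beam$rotation_direction, step_deg, beam$static_beam)
  targets <- list(body = body_tree, couch = couch_tree)
  rows <- vector("list", 2L * length(angles))
  nv <- 0L; np <- 0
  k <- 0L
  for (g in angles) {
    for (tn in names(targets)) {
      r <- .clearance_at(targets[[tn]], gantry_tree, g, beam, chirality)
      nv <- nv + r$stats$n_volume_tests; np <- np + r$stats$n_primitive_tests
      k <- k + 1L
      rows[[k]] <- data.frame(
        beam_id = beam$beam_id, couch_deg = beam$couch_deg, gantry_deg = g,
        against = tn, min_distance_cm = r$distance,
        witness_structure_x = r$witness_a[1L], witness_structure_y = r$witness_a[2L],
        witness_structure_z = r$witness_a[3L],
        witness_gantry_x = r$witness_b[1L], witness_gantry_y = r$witness_b[2L],
        witness_gantry_z = r$witness_b[3L])
    }
  }
  samples <- do.call(rbind, rows)
  best <- which(samples$min_distance_cm == min(samples$min_distance_cm))[1L]
  structure(list(beam_id = beam$beam_id, beam = beam, samples = samples,
                 overall_min = samples[best, ],
                 risk_label = classify_risk(samples$min_distance_cm[best],
                                            margin_cm, near_band_cm),
                 margin_cm = margin_cm, near_band_cm = near_band_cm,
                 stats = list(n_volume_tests = nv, n_primitive_tests = np)),
            class = "beam_result")
}

#' @export
print.beam_result <- function(x, ...) {
  m <- x$overall_min
  cat(sprintf("beam %s [%s]: min %.3f cm at couch %g / gantry %g (vs %s)\n",
              x$beam_id, x$risk_label, m$min_distance_cm, m$couch_deg,
              m$gantry_deg, m$against))
  invisible(x)
}

#' Test every beam of a plan
#'
#' Per-beam errors are caught, reported in the summary, and do not stop the
#' remaining beams from being tested. The plan is flagged unsafe if any beam
#' is a collision risk.
#'
#' @param plan A `treatment_plan`.
#' @param structures List with `body`, `couch`, `gantry` `obb_tree` entries.
#' @param margin_cm,step_deg,near_band_cm,chirality As in [test_beam()].
#' @return An object of class `plan_result`: `plan_id`, `beam_results`,
#'   `summary` data frame (`beam_id`, `couch_deg`, `gantry_deg_at_min`,
#'   `min_distance_cm`, `against`, `risk_label`), `errors`, and `plan_safe`.
#' @export
test_plan <- function(plan, structures, margin_cm = 5, step_deg = 5,
                      near_band_cm = 10, chirality = 1) {
  stopifnot(inherits(plan, "treatment_plan"))
  results <- list(); errors <- character()
  srows <- list()
  for (b in plan$beams) {
    if (all(b$isocenter_shift == 0) && any(plan$isocenter_shift != 0))
      b$isocenter_shift <- plan$isocenter_shift
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(test_beam(b, structures$body, structures$couch,
                            structures$gantry, margin_cm, step_deg,
                            near_band_cm, chirality),
                  error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(r, "error")) {
      errors[b$beam_id] <- conditionMessage(r)
      next
    }
    r$runtime_s <- dt
    results[[b$beam_id]] <- r
    m <- r$overall_min
    srows[[b$beam_id]] <- data.frame(
      beam_id = b$beam_id, couch_deg = m$couch_deg,
      gantry_deg_at_min = m$gantry_deg, min_distance_cm = m$min_distance_cm,
      against = m$against, risk_label = r$risk_label, runtime_s = dt)
  }
  summary <- if (length(srows)) do.call(rbind, c(srows, make.row.names = FALSE))
             else data.frame()
  structure(list(plan_id = plan$plan_id, beam_results = results,
                 summary = summary, errors = errors,
                 margin_cm = margin_cm,
                 plan_safe = length(errors) == 0L &&
                   !any(summary$risk_label == "CollisionRisk")),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("plan %s: %s (margin %g cm)\n", x$plan_id,
              if (x$plan_safe) "SAFE" else "UNSAFE", x$margin_cm))
  if (nrow(x$summary))
    print(x$summary[, c("beam_id", "couch_deg", "gantry_deg_at_min",
                        "min_distance_cm", "against", "risk_label")],
          row.names = FALSE)
  if (length(x$errors))
    cat("errors:", paste(names(x$errors), x$errors, sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Maximum collision-free gantry range at a couch angle
#'
#' Scans the full gantry lattice (`360 / step_deg` angles) at one couch angle
#' and isocenter, and returns the maximal contiguous runs (circular) where the
#' clearance to both body and couch is at least the safety margin, each as a
#' `[start, stop]` interval along clockwise travel. Useful to open up
#' conservative clinical arcs.
#'
#' @param couch_deg Couch angle, degrees.
#' @param isocenter_shift Isocenter shift, cm.
#' @param structures List with `body`, `couch`, `gantry` `obb_tree` entries.
#' @param margin_cm Safety margin, cm.
#' @param step_deg Lattice step, degrees.
#' @param collimator_deg Collimator angle, degrees.
#' @param chirality Machine convention flag.
#' @return A data frame with columns `start_deg`, `stop_deg`, `n_angles`, plus
#'   attribute `full_circle`. Zero rows when no lattice angle is safe.
#' @export
max_gantry_range <- function(couch_deg, isocenter_shift = c(0, 0, 0),
                             structures, margin_cm = 5, step_deg = 5,
                             collimator_deg = 0, chirality = 1) {
  angles <- seq(0, 360 - step_deg, by = step_deg)
  beam <- plan_beam("maxrange", couch_deg, collimator_deg, 0, 0,
                    rotation_direction = "CW", static_beam = TRUE,
                    isocenter_shift = isocenter_shift)
  safe <- vapply(angles, function(g) {
    db <- .clearance_at(structures$body, structures$gantry, g, beam, chirality)$distance
    if (db < margin_cm) return(FALSE)
    dc <- .clearance_at(structures$couch, structures$gantry, g, beam, chirality)$distance
    dc >= margin_cm
  }, TRUE)
  n <- length(angles)
  if (!any(safe)) {
    out <- data.frame(start_deg = numeric(), stop_deg = numeric(),
                      n_angles = integer())
    attr(out, "full_circle") <- FALSE
    return(out)
  }
  if (all(safe)) {
    out <- data.frame(start_deg = 0, stop_deg = 360 - step_deg, n_angles = n)
    attr(out, "full_circle") <- TRUE
    return(out)
  }
  # rotate so the scan starts just after an unsafe angle, then split runs
  first_unsafe <- which(!safe)[1L]
  ord <- ((seq_len(n) + first_unsafe - 1L - 1L) %% n) + 1L
  runs <- rle(safe[ord])
  pos <- cumsum(c(0L, runs$lengths[-length(runs$lengths)])) + 1L
  rows <- list()
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    idx <- ord[pos[k]:(pos[k] + runs$lengths[k] - 1L)]
    rows[[length(rows) + 1L]] <- data.frame(
      start_deg = angles[idx[1L]], stop_deg = angles[idx[length(idx)]],
      n_angles = length(idx))
  }
  out <- do.call(rbind, rows)
  attr(out, "full_circle") <- FALSE
  out
}

#' Export the posed scene for a beam result
#'
#' Writes the patient, couch and posed gantry meshes plus a JSON manifest with
#' the witness segment endpoints — the file-based equivalent of a 3D
#' minimum-clearance view.
#'
#' @param beam_result A `beam_result`.
#' @param body_mesh,couch_mesh,gantry_mesh The scene meshes (gantry in its
#'   canonical frame).
#' @param out_dir Output directory.
#' @param pose `"min"` for the overall-minimum pose, or a row index into
#'   `beam_result$samples`.
#' @param chirality Machine convention flag.
#' @return Invisibly, the manifest list.
#' @export
export_scene <- function(beam_result, body_mesh, couch_mesh, gantry_mesh,
                         out_dir, pose = "min", chirality = 1) {
  stopifnot(inherits(beam_result, "beam_result"))
  row <- if (identical(pose, "min")) beam_result$overall_min
         else beam_result$samples[pose, ]
  if (nrow(row) != 1L || is.na(row$gantry_deg)) stop("invalid pose selector")
  beam <- beam_result$beam
  tr <- machine_pose(row$gantry_deg, beam$couch_deg, beam$collimator_deg,
                     beam$isocenter_shift, chirality)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(body_mesh, file.path(out_dir, "body.stl"))
  write_mesh(couch_mesh, file.path(out_dir, "couch.stl"))
  write_mesh(apply_transform(gantry_mesh, tr), file.path(out_dir, "gantry_posed.stl"))
  manifest <- list(
    beam_id = beam_result$beam_id, couch_deg = row$couch_deg,
    gantry_deg = row$gantry_deg, against = row$against,
    min_distance_cm = row$min_distance_cm,
    witness_structure = c(row$witness_structure_x, row$witness_structure_y,
                          row$witness_structure_z),
    witness_gantry = c(row$witness_gantry_x, row$witness_gantry_y,
                       row$witness_gantry_z),
    risk_label = beam_result$risk_label)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a plan JSON
#'
#' @param plan A `treatment_plan`.
#' @param path JSON path.
#' @return Writer: `path` invisibly. Reader: a `treatment_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "treatment_plan"))
  obj <- list(plan_id = plan$plan_id,
              isocenter_shift = plan$isocenter_shift,
              beams = lapply(plan$beams, function(b)
                list(beam_id = b$beam_id, couch_deg = b$couch_deg,
                     collimator_deg = b$collimator_deg,
                     gantry_start_deg = b$gantry_start_deg,
                     gantry_stop_deg = b$gantry_stop_deg,
                     rotation_direction = b$rotation_direction,
                     static_beam = b$static_beam,
                     isocenter_shift = b$isocenter_shift)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  beams <- lapply(obj$beams, function(b)
    plan_beam(b$beam_id, b$couch_deg, b$collimator_deg,
              b$gantry_start_deg, b$gantry_stop_deg,
              b$rotation_direction, isTRUE(b$static_beam),
              unlist(b$isocenter_shift)))
  treatment_plan(obj$plan_id, beams,
                 isocenter_shift = unlist(obj$isocenter_shift))
}
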