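test_that("arc sampling includes endpoints, wraps, and honors direction", {
  expect_equal(sample_arc(0, 15, "CW", 5), c(0, 5, 10, 15))
  expect_equal(sample_arc(350, 10, "CW", 5), c(350, 355, 0, 5, 10))
  expect_equal(sample_arc(10, 3, "CCW", 5), c(10, 5, 3))
  expect_equal(sample_arc(0, 13, "CW", 5), c(0, 5, 10, 13))  # stop off-lattice
  expect_equal(sample_arc(90, 90, "CW", 5, static_beam = TRUE), 90)
  expect_error(sample_arc(90, 90, "CW", 5), "zero-length")
  expect_error(sample_arc(0, 90, "CW", 0), "step_deg")
  # monotone along travel: CCW angles decrease modulo the wrap
  a <- sample_arc(20, 300, "CCW", 5)
  travel <- (20 - a) %% 360
  expect_true(all(diff(travel) > 0))
})

test_that("risk classification uses strict margin and half-open near band", {
  expect_identical(classify_risk(4, 5), "CollisionRisk")
  expect_identical(classify_risk(12, 5), "NearCollisionRisk")
  expect_identical(classify_risk(15, 5), "Clear")       # boundary: 15 >= 5+10
  expect_identical(classify_risk(5, 5), "NearCollisionRisk")  # at margin: safe
  expect_identical(classify_risk(0, 0), "NearCollisionRisk")
  expect_equal(classify_risk(c(1, 7, 30), 5),
               c("CollisionRisk", "NearCollisionRisk", "Clear"))
})

test_that("couch sweep helper emits the 13 validation angles", {
  ang <- couch_sweep_angles()
  expect_length(ang, 13L)
  expect_equal(ang, seq(90, 270, by = 15))
})

test_that("beam testing matches the brute-force oracle pose by pose", {
  ph <- default_phantom()
  beam <- plan_beam("arc1", couch_deg = 0, gantry_start_deg = 0,
                    gantry_stop_deg = 330, rotation_direction = "CW")
  res <- test_beam(beam, default_body_tree(), default_board_tree(),
                   default_head_tree(), margin_cm = 5, step_deg = 30)
  head <- default_head()
  for (i in seq_len(nrow(res$samples))) {
    s <- res$samples[i, ]
    posed <- apply_transform(head, machine_pose(s$gantry_deg, beam$couch_deg))
    target <- if (s$against == "body") ph$body else ph$board
    expect_identical(s$min_distance_cm,
                     brute_force_min_distance(target, posed)$distance)
  }
  expect_identical(res$overall_min$min_distance_cm, min(res$samples$min_distance_cm))
  expect_error(test_beam(beam, NULL, default_board_tree(), default_head_tree()),
               "body")
})

test_that("an intersecting pose is flagged as a collision risk", {
  sc <- make_scene("collision_demo", 1)
  trees <- list(body = build_obb_tree(sc$body), couch = build_obb_tree(sc$couch),
                gantry = build_obb_tree(build_gantry_head_mesh(sc$machine_params)))
  beam <- plan_beam("hit", couch_deg = 0, gantry_start_deg = 350,
                    gantry_stop_deg = 10, rotation_direction = "CW")
  res <- test_beam(beam, trees$body, trees$couch, trees$gantry,
                   margin_cm = 5, step_deg = 5)
  expect_identical(res$risk_label, "CollisionRisk")
  expect_identical(res$overall_min$min_distance_cm, 0)
  expect_equal(res$overall_min$gantry_deg, 0)
  # margin 0 never labels a collision risk: the comparison is strict, and
  # exact vertex contact (distance 0) is not below a 0 margin
  res0 <- test_beam(beam, trees$body, trees$couch, trees$gantry,
                    margin_cm = 0, step_deg = 5)
  expect_false(res0$risk_label == "CollisionRisk")
})

test_that("plan testing aggregates beams and tolerates per-beam failures", {
  sc <- make_scene("clear_demo", 1)
  trees <- list(body = build_obb_tree(sc$body), couch = build_obb_tree(sc$couch),
                gantry = default_head_tree())
  mk <- function(id, couch) plan_beam(id, couch, gantry_start_deg = 0,
                                      gantry_stop_deg = 270,
                                      rotation_direction = "CW")
  plan <- treatment_plan("three_arcs", list(mk("a1", 0), mk("a2", 45), mk("a3", 315)))
  pr <- test_plan(plan, trees, margin_cm = 5, step_deg = 45)
  expect_true(pr$plan_safe)
  expect_equal(nrow(pr$summary), 3L)
  expect_true(all(pr$summary$risk_label != "CollisionRisk"))

  # beam-by-beam equals all-at-once
  solo <- lapply(plan$beams, function(b)
    test_beam(b, trees$body, trees$couch, trees$gantry, 5, 45))
  for (k in 1:3)
    expect_equal(pr$beam_results[[k]]$samples, solo[[k]]$samples)

  # a broken beam is reported and does not stop the others
  broken <- treatment_plan("mixed", list(mk("ok", 0), mk("bad", NA_real_)))
  pr2 <- suppressWarnings(test_plan(broken, trees, margin_cm = 5, step_deg = 90))
  expect_equal(nrow(pr2$summary), 1L)
  expect_named(pr2$errors, "bad")
  expect_false(pr2$plan_safe)

  # one colliding arc makes the plan unsafe with exactly one risk row
  scc <- make_scene("collision_demo", 1)
  ctrees <- list(body = build_obb_tree(scc$body), couch = build_obb_tree(scc$couch),
                 gantry = default_head_tree())
  plan3 <- treatment_plan("one_hot", list(
    plan_beam("safe1", 0, gantry_start_deg = 90, gantry_stop_deg = 270,
              rotation_direction = "CW"),
    plan_beam("hot", 0, gantry_start_deg = 350, gantry_stop_deg = 10,
              rotation_direction = "CW"),
    plan_beam("safe2", 0, gantry_start_deg = 100, gantry_stop_deg = 250,
              rotation_direction = "CW")))
  pr3 <- test_plan(plan3, ctrees, margin_cm = 2, step_deg = 10)
  expect_false(pr3$plan_safe)
  expect_equal(sum(pr3$summary$risk_label == "CollisionRisk"), 1L)
})

test_that("max gantry range finds the complement of blocked angles", {
  sc <- make_scene("clear_demo", 1)
  trees <- list(body = build_obb_tree(sc$body), couch = build_obb_tree(sc$couch),
                gantry = default_head_tree())
  all_free <- max_gantry_range(0, c(0, 0, 0), trees, margin_cm = 5, step_deg = 15)
  expect_true(attr(all_free, "full_circle"))
  expect_equal(all_free$n_angles, 24L)

  none <- max_gantry_range(0, c(0, 0, 0), trees, margin_cm = 1e6, step_deg = 30)
  expect_equal(nrow(none), 0L)

  # block a narrow gantry sector with an off-axis pillar and expect its
  # complement: pillar on the patient-left where the gantry-90 face arrives
  # (its grid contains the exact face-center position (40, 0, 0))
  pillar <- tessellated_box(c(36, -8, -8), c(60, 8, 8), 2, name = "pillar")
  blocked_trees <- list(body = build_obb_tree(pillar), couch = trees$couch,
                        gantry = trees$gantry)
  rng <- max_gantry_range(0, c(0, 0, 0), blocked_trees, margin_cm = 1,
                          step_deg = 15)
  expect_false(attr(rng, "full_circle"))
  blocked <- setdiff(seq(0, 345, 15), unlist(
    apply(rng, 1, function(r) {
      s <- r[["start_deg"]]; e <- r[["stop_deg"]]
      if (s <= e) seq(s, e, 15) else c(seq(s, 345, 15), seq(0, e, 15))
    }, simplify = FALSE)))
  expect_true(90 %in% blocked)
  expect_true(all(abs(((blocked - 90) + 180) %% 360 - 180) <= 45))
})

test_that("scene export reproduces the posed geometry and its distance", {
  sc <- make_scene("clear_demo", 1)
  trees <- list(body = build_obb_tree(sc$body), couch = build_obb_tree(sc$couch),
                gantry = default_head_tree())
  beam <- plan_beam("exp", 30, gantry_start_deg = 0, gantry_stop_deg = 180,
                    rotation_direction = "CW")
  res <- test_beam(beam, trees$body, trees$couch, trees$gantry, 5, 45)
  dir <- withr::local_tempdir()
  man <- export_scene(res, sc$body, sc$couch, default_head(), dir)
  expect_identical(man$min_distance_cm, res$overall_min$min_distance_cm)

  posed <- read_mesh(file.path(dir, "gantry_posed.stl"))
  expected <- apply_transform(default_head(),
                              machine_pose(man$gantry_deg, beam$couch_deg))
  # float32 STL storage bounds the coordinate error
  expect_lt(max(abs(mesh_extents(posed)$max - mesh_extents(expected)$max)), 1e-4)

  body_back <- read_mesh(file.path(dir, "body.stl"))
  gantry_back <- read_mesh(file.path(dir, "gantry_posed.stl"))
  redo <- brute_force_min_distance(body_back, gantry_back)$distance
  if (man$against == "body") expect_lt(abs(redo - man$min_distance_cm), 1e-4)

  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$min_distance_cm, man$min_distance_cm)
})

test_that("plan JSON round trips", {
  plan <- treatment_plan("rt", list(
    plan_beam("b1", 45, 30, 181, 179, "CCW", isocenter_shift = c(1, -2, 0.5)),
    plan_beam("b2", 0, 0, 90, 90, "CW", static_beam = TRUE)),
    isocenter_shift = c(0, 0, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_identical(back$plan_id, "rt")
  expect_equal(back$isocenter_shift, c(0, 0, 1))
  expect_equal(back$beams[[1]]$isocenter_shift, c(1, -2, 0.5))
  expect_identical(back$beams[[1]]$rotation_direction, "CCW")
  expect_true(back$beams[[2]]$static_beam)
})
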