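test_that("gantry head mesh matches its parametric contract", {
  p <- gantry_head_params()
  head <- default_head()
  # vertex count near the reference CAD model's 1639
  expect_gte(nrow(head$vertices), 1311)
  expect_lte(nrow(head$vertices), 1967)

  no_proj <- gantry_head_params(projections = data.frame(
    name = character(), diameter = numeric(), projection = numeric(),
    offset_x = numeric(), offset_z = numeric()))
  shell <- build_gantry_head_mesh(no_proj)
  # nearest vertex to the isocenter is the face center at face_to_iso
  expect_equal(min(sqrt(rowSums(shell$vertices^2))), no_proj$face_to_iso)

  one <- gantry_head_params(projections = data.frame(
    name = "boss", diameter = 10, projection = 3, offset_x = 0, offset_z = 0))
  boss <- build_gantry_head_mesh(one)
  expect_equal(min(sqrt(rowSums(boss$vertices^2))), one$face_to_iso - 3)
})

test_that("gantry head parameters are validated", {
  expect_error(gantry_head_params(casing_length = -1), "positive")
  expect_error(gantry_head_params(profile = data.frame(
    height = c(0, 0), circumference = c(200, 210))), "strictly increasing")
  # boss poking outside the casing rim
  expect_error(gantry_head_params(projections = data.frame(
    name = "far", diameter = 10, projection = 2, offset_x = 40, offset_z = 0)),
    "overlaps the casing")
  # projection longer than the face-isocenter distance
  expect_error(gantry_head_params(projections = data.frame(
    name = "long", diameter = 4, projection = 50, offset_x = 0, offset_z = 0)),
    "face_to_iso")
})

test_that("couch and board meshes have the requested extents", {
  flat <- build_couch_board_mesh("flat_couch_top", dims = c(50, 5, 200),
                                 top_y = 10, z_superior = 20)
  e <- mesh_extents(flat)
  expect_equal(e$max - e$min, c(50, 5, 200))
  expect_equal(e$min[2], 10)

  board <- build_couch_board_mesh("board_with_head_extension",
                                  dims = c(50, 5, 60), top_y = 10,
                                  extension = c(30, 4, 20), z_superior = 15)
  eb <- mesh_extents(board)
  expect_equal(eb$max[3], 15 + 20)  # extension reaches past the couch top
  expect_error(build_couch_board_mesh("flat_couch_top", dims = c(-1, 5, 10)),
               "non-positive")
})

test_that("machine pose follows the pinned coordinate conventions", {
  f <- gantry_head_params()$face_to_iso
  fc <- c(0, -f, 0)  # canonical face center
  expect_equal(as.numeric(transform_points(machine_pose(0, 0, 0), fc)),
               c(0, -f, 0))
  expect_equal(as.numeric(transform_points(machine_pose(180, 0, 0), fc)),
               c(0, f, 0), tolerance = 1e-12)
  # gantry 90: source (and face center) on the patient's left (+x)
  expect_equal(as.numeric(transform_points(machine_pose(90, 0, 0), fc)),
               c(f, 0, 0), tolerance = 1e-12)
  # chirality flag mirrors the sense
  expect_equal(as.numeric(transform_points(machine_pose(90, 0, 0, chirality = -1), fc)),
               c(-f, 0, 0), tolerance = 1e-12)
  # isocenter shift translates the machine assembly
  expect_equal(as.numeric(transform_points(machine_pose(0, 0, 0, c(1, 2, 3)), fc)),
               c(1, -f + 2, 3))
  expect_warning(machine_pose(370, 0, 0), "normaliz")
})

test_that("clearance is mirror-symmetric for a symmetric phantom", {
  tb <- default_body_tree(); tg <- default_head_tree()
  for (pair in list(c(35, 105), c(200, 250), c(90, 90))) {
    g <- pair[1]; c_ <- pair[2]
    d1 <- tree_min_distance(tb, tg, machine_pose(g, c_))$distance
    d2 <- tree_min_distance(tb, tg, machine_pose((360 - g) %% 360,
                                                 (360 - c_) %% 360))$distance
    expect_lt(abs(d1 - d2), 1e-6)
  }
})

test_that("collimator spin leaves clearance unchanged for a symmetric head", {
  p0 <- gantry_head_params(projections = data.frame(
    name = character(), diameter = numeric(), projection = numeric(),
    offset_x = numeric(), offset_z = numeric()))
  tg <- build_obb_tree(build_gantry_head_mesh(p0))
  tb <- default_body_tree()
  step <- 360 / p0$n_theta   # ring lattice spacing: vertex set maps to itself
  d0 <- tree_min_distance(tb, tg, machine_pose(40, 120, 0))$distance
  for (col in step * c(3, 10, 24)) {
    d <- tree_min_distance(tb, tg, machine_pose(40, 120, col))$distance
    expect_lt(abs(d - d0), 1e-9)
  }
})

test_that("pose at couch 0 is independent of the couch code path", {
  t1 <- machine_pose(123, 0, 45)
  t2 <- rt_compose(rigid_transform(rotation_about_axis("y", 0)),
                   machine_pose(123, 0, 45))
  expect_equal(t1$rotation, t2$rotation, tolerance = 1e-15)
})

test_that("machine config JSON round trips", {
  p <- gantry_head_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_machine_config(p, path, chirality = -1)
  back <- read_machine_config(path)
  expect_equal(back$chirality, -1)
  expect_equal(back$params$face_to_iso, p$face_to_iso)
  expect_equal(back$params$profile, p$profile)
  expect_equal(back$params$projections$projection, p$projections$projection)
  h1 <- build_gantry_head_mesh(p)
  h2 <- build_gantry_head_mesh(back$params)
  expect_identical(h1$vertices, h2$vertices)
})
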