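test_that("landmark building projects, orders and validates annotations", {
  ph <- phantom_clean()
  cl <- truth_centerline(ph)
  ann <- truth_annotations(ph)
  lms <- build_landmarks(ann, cl)
  expect_equal(lms$name, c("STJ", "MAA", "PROX", "MID_ARCH", "DIST",
                           "DESC", "DIAPHRAGM"))
  expect_lt(max(abs(lms$s - ph$truth$landmarks$s)), 2)
  # normals are unit tangents
  expect_lt(max(abs(sqrt(lms$nx^2 + lms$ny^2 + lms$nz^2) - 1)), 1e-6)
  # shuffled input order yields the identical landmark set
  lms2 <- build_landmarks(ann[sample(names(ann))], cl)
  expect_equal(lms, lms2)
  # off-centerline annotations are projected; too-far ones are errors
  ann_off <- ann
  ann_off$DESC <- ann$DESC + c(0, 8, 0)
  lms3 <- build_landmarks(ann_off, cl)
  expect_lt(abs(lms3$s[lms3$name == "DESC"] - lms$s[lms$name == "DESC"]), 3)
  ann_far <- ann
  ann_far$MAA <- ann$MAA + c(0, 80, 0)
  expect_error(build_landmarks(ann_far, cl), "MAA")
  expect_error(build_landmarks(ann[-3], cl), "exactly the landmarks")
})

test_that("cross-sections of an analytic cylinder obey circle geometry", {
  cl <- make_centerline(cbind(0, 0, seq(-60, 60, by = 2)))
  mesh <- init_tube_mesh(cl, 15, rings_per_cm = 2, vertices_per_ring = 48)
  cs <- cross_section(mesh, c(0, 0, 0), c(0, 0, 1))
  rr <- sqrt(rowSums(cs$polygon[, 1:2]^2))
  expect_lt(max(abs(rr - 15)), 0.1)
  expect_lt(abs(cs$area_mm2 - pi * 225) / (pi * 225), 0.01)
  expect_lt(abs(cs$max_diameter_mm - 30) / 30, 0.01)
  # plane tilt law: max diameter scales as d / cos(theta)
  for (th in c(30, 60, 75) * pi / 180) {
    n <- c(sin(th), 0, cos(th))
    cst <- cross_section(mesh, c(0, 0, 0), n)
    expect_lt(abs(cst$max_diameter_mm - 30 / cos(th)) / (30 / cos(th)),
              0.01)
  }
  expect_error(cross_section(mesh, c(0, 0, 500), c(0, 0, 1)),
               "out of range")
  # plane slicing through the open end crosses the boundary loop
  expect_error(cross_section(mesh, c(0, 0, 58), c(sin(1.2), 0, cos(1.2))),
               "boundary")
})

test_that("max_diameter equals the brute-force pairwise maximum", {
  expect_equal(max_diameter(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(0, 1, 0)))$diameter, sqrt(2))
  th <- 2 * pi * (0:63) / 64
  poly64 <- cbind(7 * cos(th), 7 * sin(th), 1)
  expect_lt(abs(max_diameter(poly64)$diameter - 14) / 14, 0.002)
  set.seed(11)
  for (rep in 1:5) {
    ang <- sort(runif(500, 0, 2 * pi))
    rad <- 5 + runif(500, 0, 2)
    poly <- cbind(rad * cos(ang), rad * sin(ang), -3)
    md <- max_diameter(poly)
    expect_identical(md$diameter, max(dist(poly)))
    expect_equal(sqrt(sum((md$endpoints[1, ] - md$endpoints[2, ])^2)),
                 md$diameter)
  }
  expect_error(max_diameter(cbind(0:5, 0, 0)), "collinear")
  expect_error(max_diameter(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
})

test_that("measure_pair differences are exact and antisymmetric", {
  ph <- phantom_clean()
  cl <- truth_centerline(ph)
  mesh_b <- baseline_mesh_clean()
  lms <- build_landmarks(truth_annotations(ph), cl)
  same <- measure_pair(mesh_b, mesh_b, lms)
  expect_equal(nrow(same), 7)
  expect_true(all(same$difference_mm == 0))
  # swapped meshes negate every difference exactly
  mesh_f <- mesh_b
  mesh_f$control_vertices <- mesh_b$control_vertices * 1.03
  mesh_f <- aortrack:::refresh_subdivision(mesh_f)
  ab <- measure_pair(mesh_b, mesh_f, lms)
  ba <- measure_pair(mesh_f, mesh_b, lms)
  expect_equal(ab$difference_mm, -ba$difference_mm)
  expect_equal(ab$difference_mm, ab$followup_mm - ab$baseline_mm)
})

test_that("diameter curve reflects radius profiles", {
  # constant-radius cylinder: flat curve
  cl <- make_centerline(cbind(0, 0, seq(-60, 60, by = 2)))
  mesh <- init_tube_mesh(cl, 12, vertices_per_ring = 32)
  crv <- diameter_curve(mesh, cl, step = 5)
  expect_gt(nrow(crv), 15)
  expect_lt(diff(range(crv$diameter_mm)), 0.5)
  # linear taper 15 -> 10 mm: fitted slope matches the analytic taper
  z <- seq(-60, 60, by = 2)
  clt <- make_centerline(cbind(0, 0, z))
  mt <- init_tube_mesh(clt, 12, vertices_per_ring = 32)
  r_of_s <- 15 - 5 * (mt$ring_arc / 120)
  scale <- r_of_s[mt$ring_index] / 12
  mt$control_vertices[, 1:2] <- mt$control_vertices[, 1:2] * scale
  mt <- aortrack:::refresh_subdivision(mt)
  crvt <- diameter_curve(mt, clt, step = 4)
  core <- crvt$s > 15 & crvt$s < 105
  fit <- coef(lm(diameter_mm ~ s, data = crvt[core, ]))
  expect_lt(abs(fit[2] - (-10 / 120)) / (10 / 120), 0.05)
  # degenerate sampling still returns at least one sample
  crv1 <- diameter_curve(mesh, cl, step = 1000)
  expect_gte(nrow(crv1), 1)
})

test_that("dilatation field localizes diameter change on the rings", {
  mesh_b <- baseline_mesh_clean()
  same <- dilatation_field(mesh_b, mesh_b)
  expect_true(all(abs(same$field) < 1e-9))
  # uniform +5 mm radius => +10 mm diameter everywhere
  mesh_f <- mesh_b
  ctr <- aortrack:::ring_centroids(mesh_b)
  rad <- mesh_b$control_vertices - ctr[mesh_b$ring_index, ]
  rl <- sqrt(rowSums(rad^2))
  mesh_f$control_vertices <- ctr[mesh_b$ring_index, ] +
    rad * (rl + 5) / rl
  mesh_f <- aortrack:::refresh_subdivision(mesh_f)
  fld <- dilatation_field(mesh_b, mesh_f)
  expect_lt(max(abs(fld$field - 10)), 0.2)
  # localized change shows only on the affected rings
  mesh_l <- mesh_b
  bump <- ifelse(mesh_b$ring_arc > 200 & mesh_b$ring_arc < 240, 3, 0)
  mesh_l$control_vertices <- ctr[mesh_b$ring_index, ] +
    rad * (rl + bump[mesh_b$ring_index]) / rl
  mesh_l <- aortrack:::refresh_subdivision(mesh_l)
  fl <- dilatation_field(mesh_b, mesh_l)
  expect_true(all(abs(fl$field[mesh_b$ring_arc < 195 |
                                 mesh_b$ring_arc > 245]) < 0.2))
  expect_true(all(abs(fl$field[mesh_b$ring_arc > 205 &
                                 mesh_b$ring_arc < 235] - 6) < 0.2))
})
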