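test_that("gradient cost matches the Gaussian-derivative closed form", {
  v0 <- image_volume(array(150, c(20, 20, 20)), c(1, 1, 1))
  g0 <- gradient_cost(v0, 1)
  expect_lt(max(g0$voxels), 1e-9)
  # ideal step of 280 HU blurred with sigma: peak gradient 280/(sigma*sqrt(2pi))
  dims <- c(80, 20, 20)
  step <- array(rep(c(20, 300), each = 40), dims)
  v <- image_volume(step, c(0.5, 0.5, 0.5), c(-20, 0, 0))
  sg <- 2
  g <- gradient_cost(v, sg)
  peak <- max(g$voxels[, 10, 10])
  expect_lt(abs(peak - 280 / (sg * sqrt(2 * pi))) / peak, 0.05)
  # on a cylinder, the cost ridge sits at the true radius
  cost <- cylinder_cost(radius = 15, spacing = 1)
  rr <- seq(10, 20, by = 0.05)
  vals <- sample_volume(cost, cbind(rr, 0, 0))$values
  expect_lt(abs(rr[which.max(vals)] - 15), 0.5)
})

test_that("adaptive thresholding clamps bone but preserves the lumen edge", {
  # bone sphere adjacent to the descending limb
  spec <- noisy_spec(distractors = list(
    list(center = c(57, 0, -55), radius = 8, hu = 700)),
    texture_sigma_hu = 0)
  ph <- generate_baseline(spec)
  cl <- truth_centerline(ph)
  thr <- adaptive_threshold(ph$volume, cl)
  # bone voxels clamped to about m + 2 s_local (lumen stats, s ~ 10)
  bone_pt <- cbind(57, 0, -55)
  expect_lt(sample_volume(thr, bone_pt, "nearest")$values, 335)
  # gradient peak at the bone-background interface drops by > 50%
  g0 <- gradient_cost(ph$volume, 1.4)
  g1 <- gradient_cost(thr, 1.4)
  ray_out <- cbind(57 + seq(4, 14, by = 0.2), 0, -55)   # far side of bone
  expect_lt(max(sample_volume(g1, ray_out)$values),
            0.5 * max(sample_volume(g0, ray_out)$values))
  # lumen edge on the opposite side changes < 10%
  ray_lum <- cbind(35 - seq(8, 18, by = 0.2), 0, -55)
  p0 <- max(sample_volume(g0, ray_lum)$values)
  p1 <- max(sample_volume(g1, ray_lum)$values)
  expect_lt(abs(p1 - p0) / p0, 0.1)
})

test_that("adaptive thresholding is inactive when nothing is out of range", {
  v <- cylinder_volume(radius = 12, spacing = 1.4, half = c(20, 20, 30),
                       blur = 0, lumen = 300, wallhu = 295, bg = 290)
  cl <- make_centerline(cbind(0, 0, seq(-25, 25, by = 1)))
  thr <- adaptive_threshold(v, cl, window = 20, influence_radius = 100)
  expect_equal(thr$voxels, v$voxels, tolerance = 1e-12)
  expect_warning(adaptive_threshold(v, cl, window = 1000), "single global")
})

test_that("surface fitting converges to the edge from both sides", {
  cost <- cylinder_cost(radius = 15, spacing = 1, half = c(30, 30, 40))
  cl <- make_centerline(cbind(0, 0, seq(-35, 35, by = 2)))
  for (r0 in c(11, 19)) {
    fit <- fit_surface(init_tube_mesh(cl, r0), cost, search_range = 10)
    rad <- as.numeric(aortrack:::mean_ring_radius(fit))
    interior <- fit$ring_arc > 10 & fit$ring_arc < 60
    expect_lt(max(abs(rad[interior] - 15)), 0.5)   # within 0.5 voxel
  }
  # starting on the ridge is a fixed point
  f0 <- fit_surface(init_tube_mesh(cl, 15), cost)
  expect_lt(attr(f0, "iterations"), 5)
  expect_true(attr(f0, "converged"))
  # a mesh outside the volume is a fit failure
  clf <- make_centerline(cbind(200, 200, seq(-35, 35, by = 2)))
  expect_error(fit_surface(init_tube_mesh(clf, 10), cost), "fit failure")
})

test_that("vertex-summed cost is non-decreasing without smoothing", {
  cost <- cylinder_cost(radius = 15, spacing = 1, half = c(25, 25, 30))
  cl <- make_centerline(cbind(0, 0, seq(-25, 25, by = 2)))
  mesh <- init_tube_mesh(cl, 12)
  tot <- function(m)
    sum(sample_volume(cost, m$control_vertices, background = 0)$values)
  prev <- tot(mesh)
  for (i in 1:12) {
    mesh <- suppressWarnings(
      fit_surface(mesh, cost, iterations = 1, smooth_weight = 0))
    cur <- tot(mesh)
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("baseline segmentation recovers the phantom radius profile", {
  ph <- phantom_clean()
  tr <- ph$truth
  mesh <- baseline_mesh_clean()
  rad <- as.numeric(aortrack:::mean_ring_radius(mesh))
  err <- rad - tr$radius_fun(mesh$ring_arc)
  vox <- ph$volume$spacing[1]
  expect_gte(mean(abs(err) < 0.5 * vox), 0.95)
  # noisy defaults: mean radius error < 0.5 mm
  phn <- phantom_noisy()
  meshn <- baseline_mesh_noisy()
  errn <- as.numeric(aortrack:::mean_ring_radius(meshn)) -
    phn$truth$radius_fun(meshn$ring_arc)
  expect_lt(mean(abs(errn)), 0.5)
  # a centerline offset beyond the lumen radius is caught by the validity
  # check (gross radius error)
  off <- truth_centerline(ph)
  off$points[, 2] <- off$points[, 2] + 20
  badfit <- tryCatch(suppressWarnings(segment_baseline(ph$volume, off)),
                     error = function(e) e)
  if (!inherits(badfit, "error")) {
    bade <- as.numeric(aortrack:::mean_ring_radius(badfit)) -
      tr$radius_fun(badfit$ring_arc)
    expect_gt(mean(abs(bade)), 2)
  } else succeed()
})

test_that("follow-up segmentation is a near-identity on identical volumes", {
  ph <- phantom_noisy()
  cl <- truth_centerline(ph)
  mesh_b <- baseline_mesh_noisy()
  mesh_f <- segment_followup(ph$volume, mesh_b, cl)
  dist <- mean(sqrt(rowSums((mesh_f$vertices - mesh_b$vertices)^2)))
  expect_lt(dist, 0.2)
})

test_that("follow-up segmentation tracks uniform and localized dilation", {
  spec <- noisy_spec()
  ph <- phantom_noisy()
  cl <- truth_centerline(ph)
  mesh_b <- baseline_mesh_noisy()
  fu <- generate_followup(spec, 3, seed = 7)
  mesh_u <- segment_followup(fu$volume, mesh_b, cl)
  dr <- as.numeric(aortrack:::mean_ring_radius(mesh_u)) -
    as.numeric(aortrack:::mean_ring_radius(mesh_b))
  interior <- mesh_b$ring_arc > 10 & mesh_b$ring_arc < 270
  expect_lt(max(abs(dr[interior] - 3)), 0.5 * ph$volume$spacing[1])
  # localized dilation stays localized
  dil <- function(s) 5 * pmax(0, pmin(1, pmin((s - 205) / 8, (245 - s) / 8)))
  fl <- generate_followup(spec, dil, seed = 8)
  mesh_l <- segment_followup(fl$volume, mesh_b, cl)
  drl <- as.numeric(aortrack:::mean_ring_radius(mesh_l)) -
    as.numeric(aortrack:::mean_ring_radius(mesh_b))
  s <- mesh_b$ring_arc
  inside <- s > 215 & s < 235
  outside <- (s > 15 & s < 190) | (s > 262 & s < 270)
  expect_lt(max(abs(drl[inside] - 5)), 0.7)
  expect_lt(max(abs(drl[outside])), 0.7)
})

test_that("region growing respects intervals and connectivity", {
  spec <- clean_spec(branches = TRUE)
  ph <- generate_baseline(spec)
  seed <- as.numeric(centerline_at(ph$truth$centerline, 115)$points)
  mask <- region_grow(ph$volume, seed, c(160, 340))
  # coverage of true lumen voxels (tube + branches)
  d <- dim(ph$volume$voxels)
  idx <- which(ph$volume$voxels > 290 & ph$volume$voxels < 310)
  expect_gt(mean(mask[idx]), 0.95)
  expect_error(region_grow(ph$volume, seed + c(0, 22, 0), c(160, 340)),
               "outside interval")
  # interval excluding every neighbour yields a single voxel
  v <- image_volume(array(0, c(5, 5, 5)), c(1, 1, 1))
  v$voxels[3, 3, 3] <- 10
  m1 <- region_grow(v, c(2, 2, 2), c(9, 11))
  expect_equal(sum(m1), 1)
  # two disjoint tubes: the mask never leaks into the second one
  v2 <- image_volume(array(20, c(30, 10, 10)), c(1, 1, 1))
  v2$voxels[3:8, 4:6, ] <- 300
  v2$voxels[20:25, 4:6, ] <- 300
  m2 <- region_grow(v2, c(5, 4, 4), c(250, 350))
  expect_equal(sum(m2[20:26, , ]), 0)
  expect_gt(sum(m2[3:9, , ]), 0)
})
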