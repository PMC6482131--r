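test_that("fixed-image mask is the expanded mesh bounding box", {
  ref <- image_volume(array(0, c(30, 30, 30)), c(1, 1, 1), c(0, 0, 0))
  # unit-cube cloud of points in [10, 20]^3
  pts <- as.matrix(expand.grid(c(10, 20), c(10, 20), c(10, 20)))
  m0 <- make_fixed_mask(pts, ref, margin = 0)
  idx <- which(m0, arr.ind = TRUE) - 1
  expect_equal(range(idx[, 1]), c(10, 20))
  expect_equal(range(idx[, 3]), c(10, 20))
  m10 <- make_fixed_mask(pts, ref, margin = 4)
  idx10 <- which(m10, arr.ind = TRUE) - 1
  expect_equal(range(idx10[, 1]), c(6, 24))
  m_clip <- make_fixed_mask(pts, ref, margin = 100)
  expect_true(all(m_clip))
  expect_error(make_fixed_mask(matrix(0, 0, 3), ref), "empty")
})

test_that("mutual information satisfies its identities", {
  ph <- phantom_noisy()
  v <- ph$volume
  mask <- array(TRUE, dim(v$voxels))
  # self-MI equals the marginal entropy of the binned histogram
  mi <- mutual_information(v, v, affine_transform(), mask, bins = 32,
                           samples = 5000, seed = 1)
  set.seed(1)
  take <- sample(which(mask), 5000)
  fv <- v$voxels[take]
  bi <- pmax(1, pmin(32, 1 + floor((fv - min(fv) + 1e-9) /
                                     ((diff(range(fv)) + 2e-9) / 32))))
  p <- tabulate(bi, 32) / length(bi)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  expect_lt(abs(mi - H), 1e-9)
  # independence: spatially shuffled intensities give near-zero MI
  set.seed(2)
  vs <- v
  vs$voxels <- array(sample(v$voxels), dim(v$voxels))
  mi0 <- mutual_information(v, vs, affine_transform(), mask, bins = 64,
                            samples = 10000, seed = 3)
  expect_lt(mi0, 0.3)
  # metric ordering: identity beats a 10 mm shift
  mi_id <- mutual_information(v, v, affine_transform(), mask, 32, 5000,
                              seed = 4)
  mi_sh <- mutual_information(v, v, rigid_transform(c(0, 0, 0), c(10, 0, 0)),
                              mask, 32, 5000, seed = 4)
  expect_gt(mi_id, mi_sh)
  expect_error(mutual_information(v, v, samples = 1e9), "sample count")
})

test_that("insufficient overlap raises a registration error", {
  ph <- phantom_clean()
  v <- ph$volume
  far <- rigid_transform(c(0, 0, 0), c(1000, 0, 0))
  expect_error(mutual_information(v, v, far, NULL, 32, 2000, seed = 1),
               "insufficient overlap")
  cfg <- registration_config(iterations = 5, samples = 256, levels = 1)
  moved <- v
  moved$origin <- moved$origin + c(5000, 0, 0)
  expect_error(register_rigid(v, moved, NULL, cfg), "insufficient overlap")
})

test_that("rigid registration recovers identity and a known transform", {
  spec <- noisy_spec()
  ph <- phantom_noisy()
  mesh_b <- baseline_mesh_noisy()
  mask <- make_fixed_mask(mesh_b, ph$volume, 10)
  cfg <- registration_config(iterations = 150, seed = 5)
  # moving = fixed: identity recovered
  t0 <- register_rigid(ph$volume, ph$volume, mask, cfg)
  d0 <- decompose_transform(t0)
  expect_lt(d0$rotation_deg, 0.5)
  expect_lt(sqrt(sum(d0$translation^2)), 0.5)
  # known misalignment (with dilation, as in a follow-up visit)
  G <- rigid_transform(c(2, -3, 5), c(4, -3, 6), center = c(0, 0, -40))
  fu <- generate_followup(spec, 3, transform = G, seed = 7)
  tr <- register_rigid(ph$volume, fu$volume, mask, cfg)
  P <- as.matrix(ph$truth$landmarks[, c("x", "y", "z")])
  err <- sqrt(rowSums((apply_transform(tr, P) - apply_transform(G, P))^2))
  expect_lt(max(err), 1)
  res <- decompose_transform(compose_transform(invert_transform(G), tr))
  expect_lt(res$rotation_deg, 1)
  # determinism: bit-identical parameters for the same config/seed
  tr2 <- register_rigid(ph$volume, fu$volume, mask, cfg)
  expect_identical(tr$linear, tr2$linear)
  expect_identical(tr$translation, tr2$translation)
})

test_that("affine refinement recovers scale and respects its init", {
  ph <- phantom_noisy()
  mesh_b <- baseline_mesh_noisy()
  mask <- make_fixed_mask(mesh_b, ph$volume, 10)
  cfg <- registration_config(iterations = 200, seed = 6)
  ctr <- aortrack:::mask_centroid(ph$volume, mask)
  # moving = fixed shrunk by 1/1.04 about the mask centroid, so the
  # transform that aligns it (fixed frame -> moving frame) has scale 1.04
  S <- affine_transform(diag(3) * 1.04, c(0, 0, 0), ctr)
  moved <- resample_to_reference(ph$volume, invert_transform(S), ph$volume,
                                 "linear", 20)
  amask <- mask & !lumen_exclusion_mask(mesh_b, ph$volume, 6)
  init <- register_rigid(ph$volume, moved, mask, cfg)
  tra <- register_affine(ph$volume, moved, amask, init, cfg)
  sc <- decompose_transform(tra)$scales
  expect_lt(max(abs(sc - 1.04)), 0.01)
  # init already optimal: output stays within 0.2% of it
  tr_id <- register_affine(ph$volume, ph$volume, mask,
                           affine_transform(diag(3), c(0, 0, 0), ctr), cfg)
  expect_lt(max(abs(tr_id$linear - diag(3))), 0.005)
  # rigid-only misalignment: no spurious scaling in the affine result
  spec <- noisy_spec()
  G <- rigid_transform(c(0, 0, 4), c(3, 0, -2), center = c(0, 0, -40))
  fu <- generate_followup(spec, 0, G, seed = 9)
  trr <- register_rigid(ph$volume, fu$volume, mask, cfg)
  amask <- mask & !lumen_exclusion_mask(mesh_b, ph$volume, 6)
  traf <- register_affine(ph$volume, fu$volume, amask, trr, cfg)
  expect_lt(max(abs(decompose_transform(traf)$scales - 1)), 0.01)
})

test_that("affine refinement never degrades MI below its rigid init", {
  ph <- phantom_noisy()
  spec <- noisy_spec()
  mesh_b <- baseline_mesh_noisy()
  mask <- make_fixed_mask(mesh_b, ph$volume, 10)
  cfg <- registration_config(iterations = 60, seed = 8)
  G <- rigid_transform(c(1, 2, -3), c(-3, 2, 4), center = c(0, 0, -40))
  fu <- generate_followup(spec, 0, G, seed = 11)
  trr <- register_rigid(ph$volume, fu$volume, mask, cfg)
  tra <- register_affine(ph$volume, fu$volume, mask, trr, cfg)
  ns <- 8192
  mi_r <- mutual_information(ph$volume, fu$volume, trr, mask, 32, ns,
                             seed = 123)
  mi_a <- mutual_information(ph$volume, fu$volume, tra, mask, 32, ns,
                             seed = 123)
  expect_gte(mi_a, mi_r - 0.02)
})

test_that("align_followup composes mask, registration and resampling", {
  spec <- noisy_spec()
  ph <- phantom_noisy()
  mesh_b <- baseline_mesh_noisy()
  G <- rigid_transform(c(3, -2, 5), c(4, -3, 6), center = c(0, 0, -40))
  fu <- generate_followup(spec, 3, transform = G, seed = 7)
  al <- align_followup(ph$volume, fu$volume, mesh_b,
                       registration_config(iterations = 120, seed = 3))
  P <- as.matrix(ph$truth$landmarks[, c("x", "y", "z")])
  err <- sqrt(rowSums((apply_transform(al$transform, P) -
                         apply_transform(G, P))^2))
  expect_lt(max(err), 1)
  expect_equal(dim(al$aligned$voxels), dim(ph$volume$voxels))
  # aligned lumen sits on the baseline lumen: high correlation in-mask
  mask <- make_fixed_mask(mesh_b, ph$volume, 0)
  expect_gt(cor(ph$volume$voxels[mask], al$aligned$voxels[mask]), 0.75)
})
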