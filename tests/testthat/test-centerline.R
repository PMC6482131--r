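test_that("lumen model fits ball statistics with an SD floor", {
  v <- image_volume(array(300, c(20, 20, 20)), c(1, 1, 1), c(0, 0, 0))
  m <- fit_lumen_model(v, c(10, 10, 10), 5)
  expect_equal(m$mean, 300)
  expect_equal(m$sd, 1)                      # constant region -> floor
  expect_error(fit_lumen_model(v, c(100, 0, 0)), "outside")
  # on the phantom, a lumen seed recovers the lumen intensity
  ph <- phantom_clean()
  seed <- as.numeric(centerline_at(ph$truth$centerline, 140)$points)
  m2 <- fit_lumen_model(ph$volume, seed, 5)
  expect_lt(abs(m2$mean - 300), 5)
  # a background seed is recognizably different
  m3 <- fit_lumen_model(ph$volume, seed + c(0, 25, 0), 5)
  expect_lt(m3$mean, 100)
})

test_that("voxel cost is the shifted Gaussian NLL", {
  m <- structure(list(mean = 120, sd = 15), class = "lumen_model")
  expect_equal(voxel_cost(120, m), 0)
  for (k in 1:3)
    expect_equal(voxel_cost(120 + k * 15, m), k^2 / 2)
  d <- runif(20, -50, 50)
  expect_equal(voxel_cost(120 + d, m), voxel_cost(120 - d, m))
})

test_that("grid Dijkstra agrees with independent shortest-path oracles", {
  skip_if_not_installed("igraph")
  set.seed(7)
  spacing <- c(1, 1.3, 0.8)
  for (rep in 1:3) {
    dims <- c(5, 5, 5)
    cost <- runif(prod(dims), 0, 4)
    cost[sample(length(cost), 10)] <- Inf    # blocked voxels
    start <- c(0, 0, 0); end <- dims - 1
    cost[1] <- 0.5; cost[length(cost)] <- 0.5
    res <- aortrack:::cpp_dijkstra(cost, dims, spacing, 0,
                                   prod(dims) - 1, 0.05)
    oracle <- igraph_grid_shortest(cost, dims, spacing, start, end, 0.05)
    expect_equal(res$cost, oracle, tolerance = 1e-10)
    # path cost recomputed from the returned path matches
    path <- aortrack:::lin_to_sub(res$path - 1, dims)
    w <- 0
    for (i in 2:nrow(path)) {
      ca <- cost[res$path[i - 1]]; cb <- cost[res$path[i]]
      w <- w + (0.5 * (ca + cb) + 0.05) *
        sqrt(sum(((path[i, ] - path[i - 1, ]) * spacing)^2))
    }
    expect_equal(w, res$cost, tolerance = 1e-10)
  }
  # exhaustive enumeration oracle on a tiny grid
  dims <- c(3, 3, 2)
  set.seed(8)
  cost <- runif(prod(dims), 0, 2)
  res <- aortrack:::cpp_dijkstra(cost, dims, c(1, 1, 1), 0, prod(dims) - 1, 0)
  expect_equal(res$cost,
               enumerate_shortest(cost, dims, c(1, 1, 1), c(0, 0, 0),
                                  dims - 1, 0),
               tolerance = 1e-10)
})

test_that("extract_path stays inside a straight noiseless tube", {
  v <- cylinder_volume(radius = 15, spacing = 1.4, half = c(25, 25, 40),
                       blur = 0)
  m <- structure(list(mean = 300, sd = 1), class = "lumen_model")
  cl <- extract_path(v, m, c(0, 0, -35), c(0, 0, 35))
  expect_true(all(sqrt(rowSums(cl$points[, 1:2]^2)) < 1))
  expect_true(all(diff(cl$arc) > 0))
  expect_lt(max(abs(sqrt(rowSums(cl$tangents^2)) - 1)), 1e-9)
  expect_error(extract_path(v, m, c(0, 0, 10), c(0, 0, 10)), "coincide")
  # endpoint in background is inadmissible
  expect_error(extract_path(v, m, c(22, 22, 0), c(0, 0, 35)),
               "not admissible")
})

test_that("path is invariant under a uniform intensity shift", {
  v <- cylinder_volume(radius = 12, spacing = 1.4, half = c(25, 25, 30),
                       blur = 0.6)
  m1 <- structure(list(mean = 300, sd = 10), class = "lumen_model")
  v2 <- v; v2$voxels <- v$voxels + 150
  m2 <- structure(list(mean = 450, sd = 10), class = "lumen_model")
  cl1 <- extract_path(v, m1, c(0, 0, -25), c(0, 0, 25))
  cl2 <- extract_path(v2, m2, c(0, 0, -25), c(0, 0, 25))
  expect_equal(cl1$points, cl2$points, tolerance = 1e-12)
})

test_that("recentring restores the medial position", {
  v <- cylinder_volume(radius = 15, spacing = 1, half = c(25, 25, 40))
  m <- structure(list(mean = 300, sd = 10), class = "lumen_model")
  # a point already on the axis barely moves
  cl0 <- make_centerline(cbind(0, 0, seq(-30, 30, by = 1)))
  r1 <- recenter(cl0, v, m, search_radius = 20, passes = 1)
  mid <- abs(r1$points[, 3]) < 20
  expect_lt(max(sqrt(rowSums(r1$points[mid, 1:2, drop = FALSE]^2))), 0.2)
  # a 5 mm offset is pulled > 3 mm back toward the axis in one pass
  cl5 <- make_centerline(cbind(5, 0, seq(-30, 30, by = 1)))
  r2 <- recenter(cl5, v, m, search_radius = 20, passes = 1)
  offs <- sqrt(rowSums(r2$points[mid, 1:2, drop = FALSE]^2))
  expect_lt(mean(offs), 2)
})

test_that("full centerline extraction tracks the phantom ground truth", {
  ph <- phantom_clean()
  tr <- ph$truth
  seed <- as.numeric(centerline_at(tr$centerline, 140)$points)
  ends <- centerline_at(tr$centerline, c(2, tr$total_length - 2))
  cl <- extract_centerline(ph$volume, seed, start = ends$points[1, ],
                           end = ends$points[2, ])
  expect_lt(centerline_error(cl, tr$centerline), 1)
  expect_lt(max(diff(cl$arc)), 2)           # resampled spacing contract
})

test_that("endpoint detection lands near the tube ends and fails cleanly", {
  ph <- phantom_clean()
  tr <- ph$truth
  m <- structure(list(mean = 300, sd = 10), class = "lumen_model")
  ep <- detect_endpoints(ph$volume, m)
  root_true <- as.numeric(centerline_at(tr$centerline, 0)$points)
  desc_true <- as.numeric(centerline_at(tr$centerline,
                                        tr$total_length)$points)
  expect_lt(sqrt(sum((ep$start - root_true)^2)), 5)
  expect_lt(sqrt(sum((ep$end - desc_true)^2)), 5)
  # no admissible voxels anywhere -> detection error
  m2 <- structure(list(mean = 5000, sd = 1), class = "lumen_model")
  expect_error(detect_endpoints(ph$volume, m2), "no admissible")
  # manual override bypasses detection entirely
  cl <- extract_centerline(ph$volume,
                           as.numeric(centerline_at(tr$centerline,
                                                    140)$points),
                           start = root_true, end = desc_true)
  expect_s3_class(cl, "centerline")
})
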