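test_that("Bland-Altman statistics match hand-computed cases", {
  b1 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(b1$mean_diff, 0)
  expect_equal(b1$sd_diff, 0)
  b2 <- bland_altman(c(10, 20, 30), c(9, 19, 29))
  expect_equal(b2$mean_diff, 1)
  expect_equal(b2$sd_diff, 0)
  expect_equal(b2$loa, c(1, 1))
  expect_equal(b2$points$mean, c(9.5, 19.5, 29.5))
  expect_error(bland_altman(1, 2), "at least 2")
  # Monte Carlo against the generating distribution
  set.seed(21)
  n <- 1000
  base <- rnorm(n, 30, 5)
  d <- rnorm(n, 0.3, 1.3)
  bm <- bland_altman(base + d, base)
  expect_lt(abs(bm$mean_diff - 0.3), 0.13)
  expect_lt(abs(bm$sd_diff - 1.3), 0.1)
  expect_equal(bm$loa[2] - bm$loa[1], 2 * 1.96 * bm$sd_diff)
})

test_that("ICC(A,1) matches the two-way mean-squares decomposition", {
  # perfect agreement
  expect_equal(icc_two_way(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # exact hand-computable 3-subject case, cross-checked against aov
  a <- c(8, 11, 14); b <- c(9, 13, 16)
  icc <- icc_two_way(a, b)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:3, 2)),
                   rater = factor(rep(1:2, each = 3)))
  ms <- anova(aov(y ~ subj + rater, data = df))["Mean Sq"]
  MSR <- ms["subj", 1]; MSC <- ms["rater", 1]; MSE <- ms["Residuals", 1]
  icc_oracle <- (MSR - MSE) / (MSR + MSE + (2 / 3) * (MSC - MSE))
  expect_equal(icc, icc_oracle, tolerance = 1e-12)
  expect_error(icc_two_way(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_two_way(c(2, 2, 2), c(2, 2, 2)), "degenerate")
})

test_that("ICC behaves correctly under null and variance-component models", {
  set.seed(22)
  x <- rnorm(200, 30, 4)
  expect_lt(abs(icc_two_way(x, sample(x))), 0.15)   # independent raters
  # subjects N(0, 4^2), rater noise N(0, 1): ICC = 16 / 17
  subj <- rnorm(500, 0, 4)
  r1 <- subj + rnorm(500)
  r2 <- subj + rnorm(500)
  expect_lt(abs(icc_two_way(r1, r2) - 16 / 17), 0.05)
})

test_that("agreement evaluation compares report batches per landmark", {
  ph <- phantom_clean()
  cl <- truth_centerline(ph)
  mesh <- baseline_mesh_clean()
  lms <- build_landmarks(truth_annotations(ph), cl)
  rep1 <- measure_pair(mesh, mesh, lms)
  batch <- lapply(1:4, function(i) {
    r <- rep1
    r$baseline_mm <- r$baseline_mm + rnorm(7, 0, 0.1)
    r
  })
  agr <- evaluate_agreement(batch, batch)
  expect_equal(nrow(agr), 7)
  expect_true(all(agr$mean_diff_mm == 0))
  expect_true(all(agr$icc == 1))
  expect_error(evaluate_agreement(batch, batch[1:2]), "different lengths")
  bad <- batch
  bad[[1]]$name[1] <- "OTHER"
  expect_error(evaluate_agreement(batch, bad), "mismatched landmark")
})

test_that("pipeline configuration validates keys and ranges", {
  cfg <- pipeline_config(segmentation = list(iterations = 50))
  expect_equal(cfg$segmentation$iterations, 50)
  expect_equal(cfg$segmentation$smooth_weight, 0.3)
  expect_error(pipeline_config(segmentation = list(bogus = 1)), "unknown key")
  expect_error(pipeline_config(nonsense = 1), "unknown key")
  expect_error(pipeline_config(registration = list(bins = 2)), "bins")
})

test_that("pipeline runs deterministically and halts on bad input", {
  ph <- phantom_clean()
  spec <- clean_spec()
  fu <- generate_followup(spec, 2, seed = 5)
  ann <- truth_annotations(ph)
  seedp <- as.numeric(centerline_at(ph$truth$centerline, 140)$points)
  ends <- centerline_at(ph$truth$centerline,
                        c(2, ph$truth$total_length - 2))
  cfg <- pipeline_config(seed = 2,
                         centerline = list(seed_point = seedp,
                                           start = ends$points[1, ],
                                           end = ends$points[2, ]),
                         segmentation = list(iterations = 60),
                         registration = list(enabled = FALSE))
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  r1 <- suppressMessages(run_pipeline(ph$volume, fu$volume, ann, cfg, d1))
  r2 <- suppressMessages(run_pipeline(ph$volume, fu$volume, ann, cfg, d2))
  expect_equal(nrow(r1$report), 7)
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
  expect_true(file.exists(file.path(d1, "baseline_mesh.ply")))
  expect_true(file.exists(file.path(d1, "transform.json")))
  expect_lt(max(abs(r1$report$difference_mm - 4)), 1)
  # corrupt follow-up file halts at the read stage with the path
  bad <- tempfile(fileext = ".mha")
  writeLines("not a metaimage", bad)
  expect_error(suppressMessages(run_pipeline(ph$volume, bad, ann, cfg)),
               "read_followup")
  # missing seed point is surfaced as a centerline-stage error
  cfg2 <- pipeline_config(registration = list(enabled = FALSE))
  expect_error(suppressMessages(run_pipeline(ph$volume, fu$volume, ann,
                                             cfg2)), "seed point")
})

test_that("serialization round-trips centerlines and transforms", {
  ph <- phantom_clean()
  cl <- truth_centerline(ph)
  f <- tempfile(fileext = ".json")
  write_centerline_json(cl, f)
  cl2 <- read_centerline_json(f)
  expect_equal(cl2$points, unname(as.matrix(cl$points)), tolerance = 1e-12)
  tr <- rigid_transform(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  ft <- tempfile(fileext = ".json")
  write_transform_json(tr, ft)
  tr2 <- read_transform_json(ft)
  expect_equal(tr2$linear, tr$linear, tolerance = 1e-12)
  expect_equal(tr2$translation, tr$translation)
  expect_equal(tr2$center, tr$center)
})

test_that("manual measurement CSVs import as agreement batches", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(case = rep(c("p1", "p2"), each = 2),
                       landmark = rep(c("STJ", "DESC"), 2),
                       diameter_mm = c(30, 25, 31, 26)),
            f, row.names = FALSE)
  batch <- import_manual_measurements(f)
  expect_length(batch, 2)
  expect_equal(batch[["p1"]]$baseline_mm, c(30, 25))
  agr <- evaluate_agreement(batch, batch)
  expect_true(all(agr$mean_diff_mm == 0))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(import_manual_measurements(bad), "must have columns")
})
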