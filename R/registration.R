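#' Fixed-image mask from the baseline segmentation
#'
#' Axis-aligned minimum bounding box of the segmented baseline surface,
#' expanded by `margin` and clipped to the reference volume; used as the
#' region of interest of the fixed image during registration (keeps the rib
#' cage and other structures out of the metric).
#'
#' @param mesh baseline `surface_mesh` (or an N x 3 matrix of points).
#' @param reference `image_volume` providing the grid.
#' @param margin expansion, mm.
#' @return logical 3-D array mask on the reference grid.
#' @export
make_fixed_mask <- function(mesh, reference, margin = 10) {
  pts <- if (inherits(mesh, "surface_mesh")) mesh$vertices else rbind3(mesh)
  if (nrow(pts) == 0) stop("make_fixed_mask: empty mesh")
  vc <- world_to_voxel(reference, pts)
  mg <- ceiling(margin / reference$spacing)
  d <- dim(reference$voxels)
  lo <- pmax(0L, as.integer(floor(apply(vc, 2, min))) - as.integer(mg))
  hi <- pmin(d - 1L, as.integer(ceiling(apply(vc, 2, max))) + as.integer(mg))
  mask <- array(FALSE, d)
  mask[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- TRUE
  mask
}

# MI in nats from binned joint histogram of paired intensity samples
mi_from_values <- function(fv, mv, bins, frange, mrange) {
  bi <- pmax(1, pmin(bins, 1 + floor((fv - frange[1]) /
                                       (diff(frange) / bins + 1e-12))))
  bj <- pmax(1, pmin(bins, 1 + floor((mv - mrange[1]) /
                                       (diff(mrange) / bins + 1e-12))))
  p <- tabulate(bi + bins * (bj - 1), bins * bins) / length(fv)
  pj <- matrix(p, bins, bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (outer(px, py)[nz])))
}

#' Mutual information between two volumes under a transform
#'
#' MI (nats) of the joint histogram of fixed intensities and moving
#' intensities sampled at transform-mapped points, over `samples` voxels
#' drawn uniformly from the mask.  Deterministic given `seed`.  Points
#' mapping outside the moving volume are discarded; fewer than 50% valid
#' samples is an insufficient-overlap error.
#'
#' @param fixed,moving `image_volume`s.
#' @param transform `affine_transform` mapping fixed world points into the
#'   moving frame.
#' @param mask logical array on the fixed grid (NULL = whole volume).
#' @param bins histogram bins per axis (>= 8).
#' @param samples number of sample points.
#' @param seed RNG seed (NULL = use the current RNG state).
#' @return MI in nats (>= 0 up to estimation noise).
#' @export
mutual_information <- function(fixed, moving, transform = affine_transform(),
                               mask = NULL, bins = 32, samples = 5000,
                               seed = NULL) {
  stopifnot(bins >= 8)
  if (is.null(mask)) mask <- array(TRUE, dim(fixed$voxels))
  idx <- which(mask)
  if (samples > length(idx))
    stop("mutual_information: sample count exceeds mask voxel count")
  if (!is.null(seed)) set.seed(seed)
  take <- sample(idx, samples)
  d <- dim(fixed$voxels)
  sub <- lin_to_sub(take - 1, d)
  fv <- fixed$voxels[take]
  pts <- voxel_to_world(fixed, sub)
  mp <- apply_transform(transform, pts)
  sv <- sample_volume(moving, mp, background = NA)
  ok <- sv$valid
  if (mean(ok) < 0.5)
    stop("mutual_information: insufficient overlap (",
         round(100 * mean(ok)), "% of samples map inside the moving volume)")
  mi_from_values(fv[ok], sv$values[ok], bins,
                 range(fv) + c(-1e-9, 1e-9),
                 range(sv$values[ok]) + c(-1e-9, 1e-9))
}

#' Registration configuration
#'
#' @param bins histogram bins (>= 8).
#' @param samples samples per iteration (>= 256).
#' @param iterations iterations per pyramid level.
#' @param levels pyramid levels (downsampling 2^(levels-1) ... 1).
#' @param initial_step initial SGD step, mm.
#' @param step_decay gain decay exponent (gain ~ (t + A)^-decay).
#' @param seed RNG seed.
#' @return list of class `registration_config`.
#' @export
registration_config <- function(bins = 32, samples = 2048, iterations = 200,
                                levels = 3, initial_step = 2,
                                step_decay = 0.6, seed = 1) {
  stopifnot(bins >= 8, levels >= 1, samples >= 256)
  structure(list(bins = bins, samples = samples, iterations = iterations,
                 levels = levels, initial_step = initial_step,
                 step_decay = step_decay, seed = seed),
            class = "registration_config")
}

# lever arm (mm) converting rotation/scale parameters to mm-scale units
reg_lever <- 50

params_to_transform <- function(theta, model, center) {
  if (model == "rigid") {
    rigid_transform(theta[1:3] / reg_lever * 180 / pi, theta[4:6], center)
  } else {
    affine_transform(diag(3) + matrix(theta[1:9], 3, 3) / reg_lever,
                     theta[10:12], center)
  }
}

transform_to_params <- function(transform, model) {
  if (model == "rigid") {
    L <- transform$linear
    # xyz Euler extraction from Rz Ry Rx
    ry <- asin(pmax(-1, pmin(1, -L[3, 1])))
    rx <- atan2(L[3, 2], L[3, 3])
    rz <- atan2(L[2, 1], L[1, 1])
    c(c(rx, ry, rz) * reg_lever, transform$translation)
  } else {
    c(as.numeric((transform$linear - diag(3)) * reg_lever),
      transform$translation)
  }
}

# one pyramid of volumes and (subsampled) masks, coarse to fine
build_pyramid <- function(fixed, moving, mask, levels) {
  factors <- rev(2^(seq_len(levels) - 1))
  lapply(factors, function(f) {
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    mk <- if (f > 1) {
      d <- dim(mask)
      mask[seq(1, d[1], by = f), seq(1, d[2], by = f), seq(1, d[3], by = f),
           drop = FALSE]
    } else mask
    list(fixed = fx, moving = mv, mask = mk, factor = f)
  })
}

register_sgd <- function(fixed, moving, mask, config, model, theta0,
                         center) {
  set.seed(config$seed)
  pyr <- build_pyramid(fixed, moving, mask, config$levels)
  theta <- theta0
  np <- length(theta)
  h <- 0.5
  any_overlap <- FALSE
  for (lev in pyr) {
    idx <- which(lev$mask)
    if (length(idx) < 8) next
    d <- dim(lev$fixed$voxels)
    fvox <- lev$fixed$voxels
    mrange <- range(lev$moving$voxels) + c(-1e-9, 1e-9)
    frange <- range(fvox[idx]) + c(-1e-9, 1e-9)
    nsamp <- min(config$samples, length(idx))
    eval_mi <- function(th, take_sub, take_val, pts) {
      tr <- params_to_transform(th, model, center)
      mp <- apply_transform(tr, pts)
      sv <- sample_volume(lev$moving, mp, background = NA)
      ok <- sv$valid
      if (mean(ok) < 0.5) return(NA_real_)
      mi_from_values(take_val[ok], sv$values[ok], config$bins, frange, mrange)
    }
    # overlap check at this level
    take <- if (length(idx) > nsamp) sample(idx, nsamp) else idx
    sub <- lin_to_sub(take - 1, d)
    pts <- voxel_to_world(lev$fixed, sub)
    if (!is.na(eval_mi(theta, sub, fvox[take], pts))) any_overlap <- TRUE
    else next
    acc <- matrix(0, 0, np)
    for (t in seq_len(config$iterations)) {
      take <- if (length(idx) > nsamp) sample(idx, nsamp) else idx
      sub <- lin_to_sub(take - 1, d)
      pts <- voxel_to_world(lev$fixed, sub)
      tv <- fvox[take]
      g <- numeric(np)
      for (i in seq_len(np)) {
        e <- numeric(np); e[i] <- h
        fp <- eval_mi(theta + e, sub, tv, pts)
        fm <- eval_mi(theta - e, sub, tv, pts)
        if (is.na(fp) || is.na(fm)) { g[i] <- 0; next }
        g[i] <- (fp - fm) / (2 * h)
      }
      gn <- sqrt(sum(g^2))
      if (gn > 1e-12) {
        gain <- config$initial_step * lev$factor /
          (t + 20)^config$step_decay
        theta <- theta + gain * g / gn
      }
      if (t > 0.7 * config$iterations) acc <- rbind(acc, theta)
    }
    if (nrow(acc) > 0) theta <- colMeans(acc)
  }
  if (!any_overlap)
    stop("registration failure: insufficient overlap at every pyramid level")
  # deterministic simplex polish at the finest level: the stochastic
  # iterates land in the optimum's basin, a Nelder-Mead pass on a fixed
  # large sample set removes the residual sampling jitter
  lev <- pyr[[length(pyr)]]
  idx <- which(lev$mask)
  if (length(idx) >= 8) {
    nsamp <- min(32768, length(idx))
    take <- if (length(idx) > nsamp) sample(idx, nsamp) else idx
    sub <- lin_to_sub(take - 1, dim(lev$fixed$voxels))
    # jitter sample positions inside their voxels: breaks the grid-phase
    # locking of the linearly interpolated MI landscape
    subj <- sub + matrix(runif(3 * nrow(sub), -0.5, 0.5), ncol = 3)
    d <- dim(lev$fixed$voxels)
    subj <- sweep(subj, 2, pmax(d - 1, 1), pmin)
    subj[subj < 0] <- 0
    pts <- voxel_to_world(lev$fixed, subj)
    tv <- cpp_sample(as.numeric(lev$fixed$voxels), d, subj, 0, FALSE)$values
    frange <- range(tv) + c(-1e-9, 1e-9)
    negmi <- function(th) {
      tr <- params_to_transform(th, model, center)
      mp <- apply_transform(tr, pts)
      sv <- sample_volume(lev$moving, mp, background = NA)
      ok <- sv$valid
      if (mean(ok) < 0.5) return(1e6)
      -mi_from_values(tv[ok], sv$values[ok], config$bins, frange,
                      range(sv$values[ok]) + c(-1e-9, 1e-9))
    }
    pol <- stats::optim(theta, negmi, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-8))
    # one restart: re-inflates the collapsed simplex, which matters in 12-D
    pol2 <- stats::optim(pol$par, negmi, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-8))
    best <- if (pol2$value < pol$value) pol2 else pol
    if (best$value < negmi(theta)) theta <- best$par
  }
  theta
}

#' Rigid registration of the follow-up scan to the baseline
#'
#' Maximizes mutual information over 6 rigid parameters (Euler angles about
#' the mask centroid + translation) by stochastic gradient ascent over a
#' coarse-to-fine pyramid; deterministic given the config seed.
#'
#' @param fixed,moving `image_volume`s (baseline, follow-up).
#' @param mask logical fixed-image mask from [make_fixed_mask()].
#' @param config `registration_config`.
#' @return rigid `affine_transform` mapping fixed world points to moving.
#' @export
register_rigid <- function(fixed, moving, mask = NULL,
                           config = registration_config()) {
  if (is.null(mask)) mask <- array(TRUE, dim(fixed$voxels))
  center <- mask_centroid(fixed, mask)
  theta <- register_sgd(fixed, moving, mask, config, "rigid",
                        numeric(6), center)
  params_to_transform(theta, "rigid", center)
}

#' Affine refinement of a rigid alignment
#'
#' 12-parameter MI maximization initialized at the rigid result; if the
#' refinement does not improve MI (evaluated on a common deterministic
#' sample set), the initialization is returned unchanged.
#'
#' @param fixed,moving `image_volume`s.
#' @param mask logical fixed-image mask.
#' @param init initial (rigid) `affine_transform`.
#' @param config `registration_config`.
#' @return `affine_transform`.
#' @export
register_affine <- function(fixed, moving, mask = NULL, init = NULL,
                            config = registration_config()) {
  if (is.null(mask)) mask <- array(TRUE, dim(fixed$voxels))
  if (is.null(init)) init <- affine_transform()
  center <- mask_centroid(fixed, mask)
  init <- retarget_center(init, center)
  cfg <- config
  cfg$seed <- config$seed + 1
  theta <- register_sgd(fixed, moving, mask, cfg, "affine",
                        transform_to_params(init, "affine"), center)
  out <- params_to_transform(theta, "affine", center)
  ns <- min(8192, sum(mask))
  mi_new <- tryCatch(mutual_information(fixed, moving, out, mask,
                                        config$bins, ns,
                                        seed = config$seed + 99),
                     error = function(e) -Inf)
  mi_old <- tryCatch(mutual_information(fixed, moving, init, mask,
                                        config$bins, ns,
                                        seed = config$seed + 99),
                     error = function(e) -Inf)
  if (mi_new >= mi_old) out else init
}

#' Lumen-interior exclusion mask
#'
#' Marks voxels inside (and within `margin` mm outside) the fitted baseline
#' lumen surface.  Excluding this region from the affine-stage metric keeps
#' the refinement anchored to stable anatomy: a dilating lumen would
#' otherwise be partially absorbed as spurious affine scaling, biasing the
#' very change the pipeline measures.
#'
#' @param mesh fitted baseline `surface_mesh`.
#' @param reference `image_volume` grid.
#' @param margin extra exclusion beyond the fitted radius, mm.
#' @return logical array, TRUE inside the exclusion zone.
#' @export
lumen_exclusion_mask <- function(mesh, reference, margin = 6) {
  ctr <- ring_centroids(mesh)
  rr <- as.numeric(mean_ring_radius(mesh))
  fld <- cpp_polyline_field(dim(reference$voxels), reference$spacing,
                            reference$origin, reference$direction,
                            ctr, mesh$ring_arc)
  r_at <- approx(mesh$ring_arc, rr, xout = fld$s, rule = 2)$y
  array(fld$dist < r_at + margin, dim(reference$voxels))
}

mask_centroid <- function(fixed, mask) {
  idx <- which(mask)
  sub <- lin_to_sub(idx - 1, dim(fixed$voxels))
  colMeans(voxel_to_world(fixed, sub))
}

# re-express T(p) = A(p - c0) + c0 + t0 about a new rotation center:
# t1 = t0 + (A - I)(c1 - c0)
retarget_center <- function(transform, new_center) {
  t1 <- transform$translation +
    as.numeric((transform$linear - diag(3)) %*%
                 (new_center - transform$center))
  affine_transform(transform$linear, t1, new_center)
}

#' Align the follow-up volume to the baseline
#'
#' Bounding-box mask from the baseline mesh, rigid then affine MI
#' registration, and a single resampling of the follow-up volume onto the
#' baseline grid.
#'
#' @param fixed baseline `image_volume`.
#' @param moving follow-up `image_volume`.
#' @param baseline_mesh fitted baseline `surface_mesh`.
#' The rigid stage uses the full bounding-box mask; the affine stage
#' additionally excludes the baseline lumen interior (plus a margin), so
#' that true dilatation of the lumen is not absorbed as affine scaling (see
#' [lumen_exclusion_mask()]).
#'
#' @param config `registration_config`.
#' @param margin mask margin, mm.
#' @param affine if FALSE stop after the rigid stage.
#' @param exclusion_margin lumen exclusion margin for the affine stage, mm.
#' @return list(transform = composite `affine_transform`,
#'   aligned = `image_volume` on the baseline grid).
#' @export
align_followup <- function(fixed, moving, baseline_mesh,
                           config = registration_config(), margin = 10,
                           affine = TRUE, exclusion_margin = 6) {
  mask <- make_fixed_mask(baseline_mesh, fixed, margin)
  tr <- register_rigid(fixed, moving, mask, config)
  if (affine) {
    amask <- mask & !lumen_exclusion_mask(baseline_mesh, fixed,
                                          exclusion_margin)
    if (mean(amask) < 0.05) amask <- mask
    tr <- register_affine(fixed, moving, amask, tr, config)
  }
  bg <- as.numeric(quantile(moving$voxels, 0.01))
  aligned <- resample_to_reference(moving, tr, fixed, "linear", bg)
  list(transform = tr, aligned = aligned)
}
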