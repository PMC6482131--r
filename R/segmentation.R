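#' Gradient-magnitude cost image
#'
#' Gaussian-smoothed gradient magnitude in HU/mm on the input grid; the
#' deformable surface is attracted to its ridges (vessel edges).
#'
#' @param volume `image_volume`.
#' @param sigma smoothing sigma, mm (>= 0).
#' @return `image_volume` of nonnegative gradient magnitudes (class keeps
#'   `cost_image` first).
#' @export
gradient_cost <- function(volume, sigma = 1) {
  stopifnot(sigma >= 0)
  v <- if (sigma > 0) gaussian_smooth(volume, sigma) else volume
  a <- v$voxels
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    lo <- array(0, d); hi <- array(0, d)
    n <- d[ax]
    idx_hi <- pmin(seq_len(n) + 1, n)
    idx_lo <- pmax(seq_len(n) - 1, 1)
    if (ax == 1) { hi <- a[idx_hi, , , drop = FALSE]; lo <- a[idx_lo, , , drop = FALSE] }
    if (ax == 2) { hi <- a[, idx_hi, , drop = FALSE]; lo <- a[, idx_lo, , drop = FALSE] }
    if (ax == 3) { hi <- a[, , idx_hi, drop = FALSE]; lo <- a[, , idx_lo, drop = FALSE] }
    den <- (idx_hi - idx_lo) * v$spacing[ax]
    den_arr <- if (ax == 1) array(den, d) else if (ax == 2)
      aperm(array(den, d[c(2, 1, 3)]), c(2, 1, 3)) else
        aperm(array(den, d[c(3, 1, 2)]), c(2, 3, 1))
    g2 <- g2 + ((hi - lo) / den_arr)^2
  }
  out <- image_volume(sqrt(g2), v$spacing, v$origin, v$direction)
  class(out) <- c("cost_image", class(out))
  out
}

#' Centerline-based adaptive thresholding
#'
#' Suppresses surrounding tissue (bright bone, dark muscle) before follow-up
#' segmentation: in each arc-length window along the centerline, voxels
#' within `influence_radius` of the centerline are clamped to
#' `[m - 4*s_slab, m + 2*s_lumen]`, where m and s_lumen are the local lumen
#' mean/SD (ball of `sample_radius` around the centerline) and s_slab is the
#' SD of the whole local slab.  The asymmetric upper bound suppresses bone
#' just above the lumen range; the slab-based lower bound stays below the
#' background so the lumen edge itself is untouched.
#'
#' @param volume `image_volume` (the aligned follow-up scan).
#' @param centerline `centerline` (baseline).
#' @param window arc-length window, mm.
#' @param sample_radius lumen sampling radius, mm.
#' @param influence_radius slab radius around the centerline, mm.
#' @return `image_volume`, same geometry.
#' @export
adaptive_threshold <- function(volume, centerline, window = 20,
                               sample_radius = 5, influence_radius = 40) {
  total <- max(centerline$arc)
  if (window > total) {
    warning("adaptive_threshold: window exceeds centerline length; ",
            "using a single global window")
    window <- total
  }
  cl <- resample_centerline(centerline, step = 2, smooth_passes = 0)
  fld <- cpp_polyline_field(dim(volume$voxels), volume$spacing,
                            volume$origin, volume$direction,
                            cl$points, cl$arc)
  vox <- as.numeric(volume$voxels)
  breaks <- unique(c(seq(0, total, by = window), total))
  for (i in seq_len(length(breaks) - 1)) {
    inwin <- fld$s >= breaks[i] &
      (fld$s < breaks[i + 1] | i == length(breaks) - 1)
    lum <- inwin & fld$dist < sample_radius
    slab <- inwin & fld$dist < influence_radius
    if (sum(lum) < 10 || sum(slab) < 10) next
    m <- mean(vox[lum]); s_l <- max(1, sd(vox[lum]))
    s_s <- max(1, sd(vox[slab]))
    vox[slab] <- pmin(m + 2 * s_l, pmax(m - 4 * s_s, vox[slab]))
  }
  image_volume(array(vox, dim = dim(volume$voxels)), volume$spacing,
               volume$origin, volume$direction)
}

# ridge selection along a sampled ray: first local maximum, scanning outward,
# that exceeds `frac` of the ray maximum; fall back to the global maximum.
# The default fraction accepts the (weaker) lumen-wall edge even when a
# brighter structure such as bone sits just beyond the search range.
ray_ridge_index <- function(vals, frac = 0.3) {
  n <- length(vals)
  raymax <- max(vals)
  if (!is.finite(raymax) || raymax <= 0) return(NA_integer_)
  is_max <- vals >= c(-Inf, vals[-n]) & vals >= c(vals[-1], -Inf)
  cand <- which(is_max & vals >= frac * raymax)
  if (length(cand) == 0) which.max(vals) else cand[1]
}

#' Deformable subdivision-surface fitting
#'
#' Iteratively deforms the control mesh toward edge ridges: each control
#' vertex samples the cost image along its outward normal in
#' `[-search_range, +search_range]`, targets the first ridge (scanning
#' outward) exceeding 50% of the ray maximum, moves toward it scaled by
#' `step` (landing on the best-cost point between the current position and
#' the scaled target, so the vertex-summed cost is non-decreasing when
#' `smooth_weight = 0`), and the displacement field is Laplacian-smoothed
#' over the ring/angular neighbours.  Stops when the largest vertex
#' displacement falls below 0.05 mm or at the iteration cap.
#'
#' @param mesh initial `surface_mesh`.
#' @param cost `cost_image` from [gradient_cost()].
#' @param iterations iteration cap.
#' @param step relaxation factor in (0, 1].
#' @param smooth_weight Laplacian smoothing weight in [0, 1).
#' @param smooth_passes Laplacian passes per iteration (the per-pass weight
#'   stays at `smooth_weight`; more passes widen the smoothing support and
#'   suppress voxel-phase wiggle of the fitted rings).
#' @param search_range normal search half-range, mm.
#' @param ridge_frac ridge acceptance fraction of the ray maximum.
#' @return fitted `surface_mesh` (attribute "iterations", "converged").
#' @export
fit_surface <- function(mesh, cost, iterations = 200, step = 0.5,
                        smooth_weight = 0.3, smooth_passes = 8,
                        search_range = 10, ridge_frac = 0.3) {
  stopifnot(search_range > 0)
  offs <- seq(-search_range, search_range,
              by = min(0.25, min(cost$spacing) / 4))
  zero_i <- which.min(abs(offs))
  nv <- nrow(mesh$control_vertices)
  nb <- ring_neighbours(mesh)
  converged <- FALSE
  it <- 0
  for (it in seq_len(iterations)) {
    nrm <- vertex_normals(mesh$control_vertices, mesh$control_faces)
    P <- mesh$control_vertices
    samp <- P[rep(seq_len(nv), each = length(offs)), ] +
      nrm[rep(seq_len(nv), each = length(offs)), ] * rep(offs, nv)
    sv <- sample_volume(cost, samp, background = NA)
    vals <- matrix(sv$values, nrow = length(offs), ncol = nv)
    valid <- matrix(sv$valid, nrow = length(offs), ncol = nv)
    if (any(colSums(valid) == 0))
      stop("fit_surface: mesh left the volume bounds (fit failure)")
    vals[!valid] <- -Inf
    disp <- numeric(nv)
    refine <- smooth_weight > 0   # sub-sample ridge refinement; grid landing
    for (i in seq_len(nv)) {      # keeps exact cost monotonicity at weight 0
      ti <- ray_ridge_index(vals[, i], ridge_frac)
      if (is.na(ti)) next
      toff <- offs[ti]
      if (refine && ti > 1 && ti < length(offs)) {
        y0 <- vals[ti - 1, i]; y1 <- vals[ti, i]; y2 <- vals[ti + 1, i]
        den <- y0 - 2 * y1 + y2
        if (is.finite(den) && den < 0)
          toff <- toff + (offs[2] - offs[1]) *
            max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
      }
      target <- step * toff
      if (refine) {
        disp[i] <- target
      } else {
        # monotone landing: best sampled point between 0 and the target
        seg <- if (target >= 0) which(offs >= 0 & offs <= target) else
          which(offs <= 0 & offs >= target)
        seg <- union(zero_i, seg)
        disp[i] <- offs[seg[which.max(vals[seg, i])]]
      }
    }
    if (smooth_weight > 0) {
      for (p in seq_len(smooth_passes)) {
        nbm <- (disp[nb[, 1]] + disp[nb[, 2]] + disp[nb[, 3]] +
                  disp[nb[, 4]]) / 4
        disp <- (1 - smooth_weight) * disp + smooth_weight * nbm
      }
    }
    mesh$control_vertices <- P + nrm * disp
    if (max(abs(disp)) < 0.05) { converged <- TRUE; break }
  }
  mesh <- refresh_subdivision(mesh)
  attr(mesh, "iterations") <- it
  attr(mesh, "converged") <- converged
  if (!converged)
    warning("fit_surface: iteration cap reached before convergence")
  mesh
}

# 4-neighbourhood (ring above/below, angular left/right) on the structured tube
ring_neighbours <- function(mesh) {
  R <- mesh$rings; K <- mesh$K
  id <- function(r, k) (r - 1) * K + ((k - 1) %% K) + 1
  r <- mesh$ring_index; k <- mesh$ang_index
  cbind(id(pmax(1, r - 1), k), id(pmin(R, r + 1), k),
        id(r, k - 1), id(r, k + 1))
}

# estimate lumen radius from cost ridges along radial rays
estimate_radius <- function(centerline, cost, max_radius = 30,
                            ridge_frac = 0.3) {
  s <- seq(0.1, 0.9, length.out = 9) * max(centerline$arc)
  at <- centerline_at(centerline, s)
  frames <- transport_frames(at$tangents)
  rr <- seq(1, max_radius, by = min(0.5, min(cost$spacing) / 2))
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  est <- c()
  for (i in seq_along(s)) {
    for (a in th) {
      dirv <- cos(a) * frames$u[i, ] + sin(a) * frames$v[i, ]
      pts <- sweep(outer(rr, dirv), 2, at$points[i, ], "+")
      sv <- sample_volume(cost, pts, background = NA)
      v <- sv$values; v[!sv$valid] <- -Inf
      ti <- ray_ridge_index(v, ridge_frac)
      if (!is.na(ti)) est <- c(est, rr[ti])
    }
  }
  if (length(est) == 0)
    stop("estimate_radius: no edge ridge found around the centerline")
  stats::median(est)
}

#' Segment the baseline aorta
#'
#' Initializes a tube mesh on the centerline at the cost-ridge radius
#' estimate, subdivides, and fits it to the gradient cost of the baseline
#' volume.
#'
#' @param volume baseline `image_volume`.
#' @param centerline baseline `centerline`.
#' @param config list of overrides: `sigma`, `rings_per_cm`,
#'   `vertices_per_ring`, `levels`, `iterations`, `step`, `smooth_weight`,
#'   `search_range` (default 10 mm), `init_radius` (estimated if NULL).
#' @return fitted `surface_mesh`.
#' @export
segment_baseline <- function(volume, centerline, config = list()) {
  cfg <- modifyList(list(sigma = NULL, rings_per_cm = 2,
                         vertices_per_ring = 16, levels = 2,
                         iterations = 200, step = 0.5, smooth_weight = 0.3,
                         smooth_passes = 8, search_range = 10,
                         init_radius = NULL), config)
  if (is.null(cfg$sigma)) cfg$sigma <- 1.4 * max(volume$spacing)
  cost <- gradient_cost(volume, cfg$sigma)
  r0 <- if (is.null(cfg$init_radius)) estimate_radius(centerline, cost) else
    cfg$init_radius
  mesh <- init_tube_mesh(centerline, r0, cfg$rings_per_cm,
                         cfg$vertices_per_ring, cfg$levels)
  fit_surface(mesh, cost, cfg$iterations, cfg$step, cfg$smooth_weight,
              cfg$smooth_passes, cfg$search_range)
}

#' Segment the aligned follow-up aorta
#'
#' Adaptive thresholding of the aligned follow-up volume, then surface
#' fitting initialized with the baseline mesh (narrower search range, since
#' alignment leaves only dilatation differences).
#'
#' @param aligned follow-up `image_volume`, already resampled into the
#'   baseline frame.
#' @param baseline_mesh fitted baseline `surface_mesh`.
#' @param baseline_centerline baseline `centerline`.
#' @param config overrides as in [segment_baseline()] plus `window`
#'   (adaptive-threshold window, mm) and `search_range` (default 6 mm).
#' @return fitted `surface_mesh`.
#' @export
segment_followup <- function(aligned, baseline_mesh, baseline_centerline,
                             config = list()) {
  cfg <- modifyList(list(sigma = NULL, iterations = 200, step = 0.5,
                         smooth_weight = 0.3, smooth_passes = 8,
                         search_range = 6, window = 20), config)
  if (is.null(cfg$sigma)) cfg$sigma <- 1.4 * max(aligned$spacing)
  thr <- adaptive_threshold(aligned, baseline_centerline, cfg$window)
  cost <- gradient_cost(thr, cfg$sigma)
  fit_surface(baseline_mesh, cost, cfg$iterations, cfg$step,
              cfg$smooth_weight, cfg$smooth_passes, cfg$search_range)
}

#' Region growing (QC overlay)
#'
#' 26-connected component of voxels whose intensity lies in `interval`,
#' grown from the seed; reported as a QC mask for the arch and its branches,
#' not coupled back into the fitted surface.
#'
#' @param volume `image_volume`.
#' @param seed_point world mm; its intensity must lie inside `interval`.
#' @param interval length-2 HU range.
#' @return logical 3-D array mask.
#' @export
region_grow <- function(volume, seed_point, interval) {
  d <- dim(volume$voxels)
  vs <- round(as.numeric(world_to_voxel(volume, seed_point)))
  if (any(vs < 0) || any(vs > d - 1))
    stop("region_grow: seed outside volume")
  sval <- volume$voxels[matrix(vs + 1, 1)]
  if (sval < interval[1] || sval > interval[2])
    stop("region_grow: seed intensity ", round(sval, 1),
         " outside interval [", interval[1], ", ", interval[2], "]")
  mask <- volume$voxels >= interval[1] & volume$voxels <= interval[2]
  lab <- cpp_label26(as.integer(mask), d)
  seedlab <- lab[lin_index(vs, d)]
  array(lab == seedlab, dim = d)
}

#' @importFrom utils modifyList
NULL
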