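#' Centerline objects
#'
#' An ordered polyline of world points through the vessel lumen with
#' cumulative arc length (mm) and unit tangents.  Tangents come from central
#' differences after smoothing, so measurement planes are stable.
#'
#' @param points N x 3 matrix of world mm points.
#' @return Object of class `centerline` with `points`, `arc`, `tangents`.
#' @export
make_centerline <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 2) stop("make_centerline: need at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, seg > 1e-9)
  points <- points[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, arc = arc, tangents = tang),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.1f mm\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' Resample and smooth a centerline
#'
#' Linear resampling at `step` mm followed by a 5-point moving average of the
#' coordinates (endpoints kept fixed).
#'
#' @param cl `centerline`.
#' @param step target spacing, mm.
#' @param smooth_passes number of moving-average passes.
#' @return `centerline`.
#' @export
resample_centerline <- function(cl, step = 1, smooth_passes = 1) {
  total <- max(cl$arc)
  s <- unique(c(seq(0, total, by = step), total))
  pts <- sapply(1:3, function(j) approx(cl$arc, cl$points[, j], xout = s)$y)
  for (p in seq_len(smooth_passes)) pts <- moving_average5(pts)
  make_centerline(pts)
}

moving_average5 <- function(pts) {
  n <- nrow(pts)
  if (n < 5) return(pts)
  out <- pts
  k <- 3:(n - 2)
  out[k, ] <- (pts[k - 2, ] + pts[k - 1, ] + pts[k, ] + pts[k + 1, ] +
                 pts[k + 2, ]) / 5
  k2 <- c(2, n - 1)
  out[k2, ] <- (pts[k2 - 1, ] + pts[k2, ] + pts[k2 + 1, ]) / 3
  out
}

#' Interpolate centerline position/tangent at arc lengths
#' @param cl `centerline`.
#' @param s arc lengths, mm (clamped to range).
#' @return list(points = N x 3, tangents = N x 3 unit vectors).
#' @export
centerline_at <- function(cl, s) {
  s <- pmin(max(cl$arc), pmax(0, s))
  pts <- sapply(1:3, function(j) approx(cl$arc, cl$points[, j], xout = s)$y)
  tg <- sapply(1:3, function(j) approx(cl$arc, cl$tangents[, j], xout = s)$y)
  pts <- matrix(pts, ncol = 3); tg <- matrix(tg, ncol = 3)
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg)
}

#' Gaussian lumen intensity model
#'
#' Mean and standard deviation of intensities in a ball around a user seed
#' inside the contrast-filled lumen; SD floored at 1 HU.
#'
#' @param volume `image_volume`.
#' @param seed_point world mm, inside the volume.
#' @param sample_radius ball radius, mm.
#' @return list(mean, sd) of class `lumen_model`.
#' @export
fit_lumen_model <- function(volume, seed_point, sample_radius = 5) {
  vc <- as.numeric(world_to_voxel(volume, seed_point))
  d <- dim(volume$voxels)
  if (any(vc < 0) || any(vc > d - 1))
    stop("fit_lumen_model: seed point outside volume")
  r <- ceiling(sample_radius / volume$spacing)
  ir <- lapply(1:3, function(a) {
    v <- round(vc[a]) + (-r[a]:r[a])
    v[v >= 0 & v <= d[a] - 1]
  })
  idx <- as.matrix(expand.grid(x = ir[[1]], y = ir[[2]], z = ir[[3]]))
  w <- voxel_to_world(volume, idx)
  keep <- rowSums(sweep(w, 2, as.numeric(rbind3(seed_point)))^2) <= sample_radius^2
  vals <- volume$voxels[idx[keep, , drop = FALSE] + 1]
  structure(list(mean = mean(vals), sd = max(1, sd(vals))),
            class = "lumen_model")
}

#' Voxel cost under the lumen model
#'
#' Shifted Gaussian negative log-likelihood: `((i - mean)/sd)^2 / 2`, zero at
#' the model mean and symmetric in the deviation.
#'
#' @param intensity HU values.
#' @param model `lumen_model`.
#' @return nonnegative costs.
#' @export
voxel_cost <- function(intensity, model) {
  ((intensity - model$mean) / model$sd)^2 / 2
}

# admissibility ceiling: default 3 sigma -> cost 4.5
cost_ceiling <- function(k_sigma = 3) k_sigma^2 / 2

#' Extract a lumen path by wave propagation
#'
#' Dijkstra shortest path on the 26-connected voxel grid with edge weight
#' `mean(cost_a, cost_b) * step length`; costs above the admissibility
#' ceiling are blocked.  The voxel path is converted to world mm, smoothed
#' with a 5-point moving average and resampled at 1 mm.
#'
#' @param volume `image_volume`.
#' @param model `lumen_model`.
#' A small per-millimetre length penalty regularizes the path where the
#' likelihood cost is flat (ties inside homogeneous contrast are broken in
#' favour of the shorter route).
#'
#' @param start,end world mm endpoints (inside the lumen).
#' @param k_sigma admissibility ceiling in model SDs (default 3).
#' @param resample_step resampling step, mm.
#' @param length_penalty additive cost per mm of path length.
#' @return `centerline`.
#' @export
extract_path <- function(volume, model, start, end, k_sigma = 3,
                         resample_step = 1, length_penalty = 0.05) {
  d <- dim(volume$voxels)
  vs <- round(as.numeric(world_to_voxel(volume, start)))
  ve <- round(as.numeric(world_to_voxel(volume, end)))
  for (v in list(vs, ve))
    if (any(v < 0) || any(v > d - 1))
      stop("extract_path: endpoint outside volume")
  if (all(vs == ve)) stop("extract_path: start and end coincide")
  ceiling_cost <- cost_ceiling(k_sigma)
  cost <- voxel_cost(as.numeric(volume$voxels), model)
  if (cost[lin_index(vs, d)] > ceiling_cost ||
      cost[lin_index(ve, d)] > ceiling_cost)
    stop("extract_path: endpoint intensity not admissible under lumen model")
  cost[cost > ceiling_cost] <- Inf
  res <- cpp_dijkstra(cost, d, volume$spacing,
                      lin_index(vs, d) - 1, lin_index(ve, d) - 1,
                      length_penalty)
  if (length(res$path) == 0)
    stop("extract_path: no admissible path between endpoints (centerline ",
         "extraction failed; supply manual seeds or relax the ceiling)")
  idx <- lin_to_sub(res$path - 1, d)
  pts <- voxel_to_world(volume, idx)
  cl <- make_centerline(pts)
  cl <- resample_centerline(cl, step = resample_step, smooth_passes = 2)
  attr(cl, "total_cost") <- res$cost
  cl
}

lin_index <- function(v, d) 1 + v[1] + v[2] * d[1] + v[3] * d[1] * d[2]

lin_to_sub <- function(lin, d) {
  z <- lin %/% (d[1] * d[2])
  rem <- lin %% (d[1] * d[2])
  y <- rem %/% d[1]
  x <- rem %% d[1]
  cbind(x, y, z)
}

#' Recenter a path to the lumen medial axis
#'
#' Shortest paths hug the inner curve of bends; each point is moved to the
#' intensity-weighted centroid of admissible lumen samples in the plane
#' normal to the local tangent, then the curve is re-smoothed.
#'
#' @param cl `centerline`.
#' @param volume `image_volume`.
#' @param model `lumen_model`.
#' @param search_radius in-plane search radius, mm.
#' @param k_sigma admissibility ceiling in model SDs.
#' @param passes recentring passes (default 8).
#' @return `centerline`.
#' @export
recenter <- function(cl, volume, model, search_radius = 20, k_sigma = 3,
                     passes = 8) {
  ceiling_cost <- cost_ceiling(k_sigma)
  rr <- seq(0, search_radius, by = max(0.5, min(volume$spacing) / 2))
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  disc <- cbind(rep(rr, each = length(th)) * cos(th),
                rep(rr, each = length(th)) * sin(th))
  # polar sampling is denser near the centre; annulus-area weights make the
  # weighted mean an unbiased area centroid
  area_w <- pmax(rep(rr, each = length(th)), 0.25)
  for (p in seq_len(passes)) {
    frames <- transport_frames(cl$tangents)
    newpts <- cl$points
    for (i in seq_len(nrow(cl$points))) {
      u <- frames$u[i, ]; v <- frames$v[i, ]
      samp <- sweep(disc[, 1, drop = FALSE] %*% rbind(u) +
                      disc[, 2, drop = FALSE] %*% rbind(v),
                    2, cl$points[i, ], "+")
      sv <- sample_volume(volume, samp, background = NA)
      ok <- sv$valid & !is.na(sv$values) &
        voxel_cost(sv$values, model) <= ceiling_cost
      if (!any(ok)) next
      w <- pmax(0, sv$values[ok] - model$mean + 3 * model$sd) * area_w[ok]
      if (sum(w) <= 0) w <- area_w[ok]
      newpts[i, ] <- colSums(samp[ok, , drop = FALSE] * w) / sum(w)
    }
    cl <- resample_centerline(make_centerline(newpts), step = 1,
                              smooth_passes = 2)
  }
  cl
}

# rotation-minimizing frame transport along a tangent sequence
transport_frames <- function(tangents) {
  n <- nrow(tangents)
  u <- matrix(0, n, 3); v <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u[1, ] <- cross3(t1, ref); u[1, ] <- u[1, ] / sqrt(sum(u[1, ]^2))
  v[1, ] <- cross3(t1, u[1, ])
  for (i in 2:n) {
    ti <- tangents[i, ]
    up <- u[i - 1, ] - sum(u[i - 1, ] * ti) * ti
    nu <- sqrt(sum(up^2))
    if (nu < 1e-9) up <- cross3(ti, v[i - 1, ]) else up <- up / nu
    u[i, ] <- up
    v[i, ] <- cross3(ti, up)
  }
  list(u = u, v = v)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Detect aortic endpoints automatically
#'
#' Best-effort endpoint detection on a volume cropped to the thoracic extent:
#' the descending endpoint is the centroid of the largest admissible in-plane
#' component on the most caudal slice; the aortic-root endpoint is the
#' centroid of the separate ascending component on the most caudal slice
#' where it exists (scanning caudally to cranially).  Manual seeds always
#' override detection.
#'
#' @param volume `image_volume`.
#' @param model `lumen_model`.
#' @param k_sigma admissibility ceiling in model SDs.
#' @return list(start, end): aortic-root and descending world points.
#' @export
detect_endpoints <- function(volume, model, k_sigma = 3) {
  d <- dim(volume$voxels)
  adm <- voxel_cost(volume$voxels, model) <= cost_ceiling(k_sigma)
  pxarea <- prod(volume$spacing[1:2])
  slice_components <- function(z) {
    m <- adm[, , z + 1]
    matrix(cpp_label26(as.integer(m), c(d[1], d[2], 1L)), d[1], d[2])
  }
  comp_info <- function(lab) {
    ks <- setdiff(unique(as.integer(lab)), 0L)
    lapply(ks, function(k) {
      idx <- which(lab == k, arr.ind = TRUE) - 1
      list(idx = idx, centroid = colMeans(idx),
           radius = sqrt(nrow(idx) * pxarea / pi))
    })
  }
  # follow a component upward from slice z_start, matching in-plane centroids
  track_component <- function(z_start, ctr0, span_mm = 25) {
    nz <- min(d[3] - 1, z_start + ceiling(span_mm / volume$spacing[3]))
    ctr <- ctr0
    out <- list()
    for (z in z_start:nz) {
      ci <- comp_info(slice_components(z))
      if (length(ci) == 0) break
      dxy <- vapply(ci, function(c0)
        sqrt(sum(((c0$centroid - ctr) * volume$spacing[1:2])^2)), numeric(1))
      j <- which.min(dxy)
      if (dxy[j] > 10) break
      ctr <- ci[[j]]$centroid
      out[[length(out) + 1]] <- list(z = z, centroid = ctr,
                                     radius = ci[[j]]$radius)
    }
    out
  }
  # the tube end is where the tracked component first reaches ~full caliber
  # (rounded/partial-volume end caps taper below it)
  end_from_track <- function(track) {
    r <- vapply(track, `[[`, numeric(1), "radius")
    i <- which(r >= 0.95 * max(r))[1]
    e <- track[[i]]
    as.numeric(voxel_to_world(volume, c(e$centroid, e$z)))
  }
  # most caudal slice with any admissible component
  z0 <- NA
  for (z in 0:(d[3] - 1)) {
    lab <- slice_components(z)
    if (any(lab > 0)) { z0 <- z; break }
  }
  if (is.na(z0))
    stop("detect_endpoints: no admissible lumen voxels on boundary slices")
  ci0 <- comp_info(slice_components(z0))
  big <- ci0[[which.max(vapply(ci0, `[[`, numeric(1), "radius"))]]
  desc_track <- track_component(z0, big$centroid)
  desc_pt <- end_from_track(desc_track)
  desc_xy <- big$centroid
  # scan upward for a separate (ascending) component and track it
  root_pt <- NULL
  for (z in z0:(d[3] - 1)) {
    ci <- comp_info(slice_components(z))
    if (length(ci) < 2) next
    away <- Filter(function(c0)
      sqrt(sum(((c0$centroid - desc_xy) * volume$spacing[1:2])^2)) > 15, ci)
    if (length(away) == 0) next
    best <- away[[which.max(vapply(away, `[[`, numeric(1), "radius"))]]
    root_pt <- end_from_track(track_component(z, best$centroid))
    break
  }
  if (is.null(root_pt))
    stop("detect_endpoints: could not find a separate ascending component; ",
         "supply manual seed points")
  list(start = as.numeric(root_pt), end = as.numeric(desc_pt))
}

#' Full baseline centerline extraction
#'
#' Lumen model fit at the seed, endpoint detection (unless manual endpoints
#' are given), wave-propagation shortest path, and recentring.
#'
#' @param volume `image_volume`.
#' @param seed_point world mm inside the lumen.
#' @param start,end optional manual endpoints (world mm); detected otherwise.
#' @param sample_radius lumen model ball radius, mm.
#' @param k_sigma admissibility ceiling in model SDs.
#' @param search_radius recentring search radius, mm.
#' @return `centerline` with the fitted `lumen_model` in attribute "model".
#' @export
extract_centerline <- function(volume, seed_point, start = NULL, end = NULL,
                               sample_radius = 5, k_sigma = 3,
                               search_radius = 20) {
  model <- fit_lumen_model(volume, seed_point, sample_radius)
  if (is.null(start) || is.null(end)) {
    ep <- detect_endpoints(volume, model, k_sigma)
    if (is.null(start)) start <- ep$start
    if (is.null(end)) end <- ep$end
  }
  cl <- extract_path(volume, model, start, end, k_sigma)
  cl <- recenter(cl, volume, model, search_radius, k_sigma)
  attr(cl, "model") <- model
  cl
}
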