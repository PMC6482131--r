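#' Synthetic aortic CTA phantom specification
#'
#' A candy-cane thoracic aorta: ascending limb, semicircular arch and
#' descending limb in the x-z (LPS) plane, with a piecewise-linear lumen
#' radius profile, a fixed 2 mm wall shell, optional bone-like spherical
#' distractors and optional supra-aortic branch tubes.  Intensities follow a
#' typical CTA contrast regime (lumen 300 HU, wall 60 HU, background 20 HU,
#' bone 700 HU); the volume is blurred (partial volume) and corrupted by
#' additive Gaussian noise under a fixed seed.
#'
#' @param ascending_length,descending_length limb lengths, mm.
#' @param arch_radius arch semicircle radius, mm.
#' @param radius_knots 2-column matrix: arc length mm, lumen radius mm
#'   (piecewise linear; default tapers 16 -> 12 mm root to diaphragm).
#' @param lumen_hu,wall_hu,background_hu,bone_hu intensities, HU.
#' @param wall_thickness wall shell thickness, mm.
#' @param distractors list of `list(center = mm, radius = mm, hu = HU)`
#'   spheres; defaults to three vertebra-like 700 HU spheres posterior to the
#'   descending aorta.  Use `list()` for none.
#' @param branches if TRUE, add three thin (4 mm radius) supra-aortic branch
#'   tubes on the arch.
#' @param texture_sigma_hu SD of the correlated soft-tissue background
#'   texture, HU (0 disables).  The texture is anchored to the scene (same
#'   pattern at both time points, mapped by the follow-up transform), as
#'   patient anatomy is; uncorrelated scan noise is added separately.
#' @param texture_scale_mm correlation length of the background texture, mm.
#' @param texture_seed RNG seed of the scene texture (fixed per patient).
#' @param blur_sigma partial-volume Gaussian blur, mm.
#' @param noise_sigma additive Gaussian noise SD, HU.
#' @param spacing isotropic voxel size of the rasterization grid, mm.
#' @param margin grid margin around the tube, mm (must be >= 5).
#' @param seed RNG seed for the noise.
#' @return `aorta_phantom_spec` list.
#' @export
aorta_phantom_spec <- function(ascending_length = 60, descending_length = 110,
                               arch_radius = 35,
                               radius_knots = NULL,
                               lumen_hu = 300, wall_hu = 60,
                               background_hu = 20, bone_hu = 700,
                               wall_thickness = 2,
                               distractors = NULL, branches = FALSE,
                               texture_sigma_hu = 35, texture_scale_mm = 8,
                               texture_seed = 2024,
                               blur_sigma = 0.6, noise_sigma = 10,
                               spacing = 0.7, margin = 10, seed = 42) {
  total <- ascending_length + pi * arch_radius + descending_length
  if (is.null(radius_knots)) {
    radius_knots <- cbind(c(0, ascending_length,
                            ascending_length + pi * arch_radius, total),
                          c(16, 15, 13, 12))
  }
  if (any(radius_knots[, 2] <= 0))
    stop("aorta_phantom_spec: radius profile must be strictly positive")
  if (lumen_hu <= background_hu)
    stop("aorta_phantom_spec: lumen intensity must exceed background")
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("aorta_phantom_spec: blur/noise sigma must be >= 0")
  if (is.null(distractors)) {
    # vertebra-like column posterior to the descending aorta plus a
    # sternum-like anterior chain: stable bony anatomy that anchors the
    # intensity-based alignment, as the rib cage does in patient scans
    distractors <- c(
      lapply(seq(-100, 0, by = 18), function(z)
        list(center = c(0, 30, z), radius = 10, hu = bone_hu)),
      lapply(seq(-90, 10, by = 25), function(z)
        list(center = c(0, -27, z), radius = 6, hu = bone_hu)),
      unlist(lapply(c(-85, -45, -5), function(z)
        lapply(list(c(52, 21), c(-52, 21), c(52, -21), c(-52, -21)),
               function(xy) list(center = c(xy[1], xy[2], z), radius = 5,
                                 hu = bone_hu))), recursive = FALSE))
  }
  structure(list(ascending_length = ascending_length,
                 descending_length = descending_length,
                 arch_radius = arch_radius, radius_knots = radius_knots,
                 lumen_hu = lumen_hu, wall_hu = wall_hu,
                 background_hu = background_hu, bone_hu = bone_hu,
                 wall_thickness = wall_thickness, distractors = distractors,
                 branches = branches,
                 texture_sigma_hu = texture_sigma_hu,
                 texture_scale_mm = texture_scale_mm,
                 texture_seed = texture_seed, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, spacing = spacing,
                 margin = margin, seed = seed, total_length = total),
            class = "aorta_phantom_spec")
}

# analytic candy-cane path sampled at `step` mm; arch apex at z = arch_radius,
# arch center at origin, limbs descend toward negative z.
candy_cane_points <- function(spec, step = 1) {
  R <- spec$arch_radius
  La <- spec$ascending_length; Ld <- spec$descending_length
  total <- spec$total_length
  s <- unique(c(seq(0, total, by = step), total))
  pt <- function(si) {
    if (si <= La) {                       # ascending limb, going up
      c(-R, 0, si - La)
    } else if (si <= La + pi * R) {       # arch, 180 deg
      th <- (si - La) / R                 # 0..pi
      c(-R * cos(th), 0, R * sin(th))
    } else {                              # descending limb, going down
      c(R, 0, -(si - La - pi * R))
    }
  }
  list(points = t(vapply(s, pt, numeric(3))), s = s)
}

#' Lumen radius of the phantom at arc length s
#' @param spec `aorta_phantom_spec`.
#' @param s arc lengths, mm.
#' @return radii, mm.
#' @export
phantom_radius <- function(spec, s) {
  approx(spec$radius_knots[, 1], spec$radius_knots[, 2], xout = s,
         rule = 2)$y
}

#' Default landmark arc lengths of the phantom
#'
#' Seven standardized thoracic-aorta landmarks (STJ, mid ascending, proximal
#' arch, mid arch, proximal descending, mid descending, diaphragm) placed at
#' fixed positions along the candy-cane path.
#'
#' @param spec `aorta_phantom_spec`.
#' @return data.frame(name, s) in anatomical order.
#' @export
phantom_landmarks <- function(spec) {
  La <- spec$ascending_length; R <- spec$arch_radius
  arch <- pi * R; total <- spec$total_length
  data.frame(name = c("STJ", "MAA", "PROX", "MID_ARCH", "DIST", "DESC",
                      "DIAPHRAGM"),
             s = c(8, La / 2, La + 0.1 * arch, La + 0.5 * arch,
                   La + arch + 10, La + arch + 0.5 * spec$descending_length,
                   total - 10),
             stringsAsFactors = FALSE)
}

# grid geometry large enough for the (possibly dilated / transformed) tube
phantom_grid <- function(spec, extra_mm = 0, transform = NULL) {
  cc <- candy_cane_points(spec, step = 2)
  pts <- cc$points
  if (!is.null(transform)) pts <- apply_transform(transform, pts)
  rmax <- max(spec$radius_knots[, 2]) + spec$wall_thickness + extra_mm
  lo <- apply(pts, 2, min) - rmax - spec$margin
  hi <- apply(pts, 2, max) + rmax + spec$margin
  if (spec$branches) hi[3] <- hi[3] + 30
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  list(dims = dims, origin = lo, spacing = rep(spec$spacing, 3))
}

rasterize_tube <- function(spec, grid, poly, arc, radius_at_s,
                           dilation_fun = NULL) {
  fld <- cpp_polyline_field(grid$dims, grid$spacing, grid$origin, diag(3),
                            poly, arc)
  r_s <- radius_at_s(fld$s)
  vol <- rep(spec$background_hu, length(fld$dist))
  vol[fld$dist < r_s + spec$wall_thickness] <- spec$wall_hu
  vol[fld$dist < r_s] <- spec$lumen_hu
  list(vol = vol, field = fld)
}

add_sphere <- function(vol, grid, center, radius, hu) {
  lo <- pmax(0L, as.integer(floor((center - radius - grid$origin) /
                                    grid$spacing)))
  hi <- pmin(grid$dims - 1L, as.integer(ceiling((center + radius -
                                                   grid$origin) /
                                                  grid$spacing)))
  if (any(lo > hi)) return(vol)
  idx <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  w <- sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
  inside <- rowSums(sweep(w, 2, center)^2) <= radius^2
  lin <- 1 + idx[inside, 1] + idx[inside, 2] * grid$dims[1] +
    idx[inside, 3] * grid$dims[1] * grid$dims[2]
  vol[lin] <- pmax(vol[lin], hu)
  vol
}

branch_paths <- function(spec) {
  R <- spec$arch_radius
  lapply(c(0.35, 0.5, 0.65) * pi, function(th) {
    base <- c(-R * cos(th), 0, R * sin(th))
    top <- base + c(0, 0, 28)
    rbind(base, top)
  })
}

#' Generate the baseline phantom volume with exact ground truth
#'
#' @param spec `aorta_phantom_spec`.
#' @param dilation_fun optional function(s) -> radius increment mm (used by
#'   the follow-up generator).
#' @param transform optional `affine_transform` applied to the whole scene
#'   before rasterization (follow-up repositioning).
#' @param seed noise seed override (defaults to `spec$seed`).
#' @return list(volume = `image_volume`, truth = list(centerline, radius_fun,
#'   landmarks, transform, dilation_fun, total_length)).
#' @export
generate_baseline <- function(spec, dilation_fun = NULL, transform = NULL,
                              seed = NULL) {
  if (spec$margin < 5)
    stop("generate_baseline: tube must fit inside the grid with >= 5 mm margin")
  grid <- phantom_grid(spec,
                       extra_mm = if (is.null(dilation_fun)) 0 else
                         max(dilation_fun(seq(0, spec$total_length, by = 1))),
                       transform = transform)
  cc <- candy_cane_points(spec, step = 1)
  poly <- cc$points
  if (!is.null(transform)) poly <- apply_transform(transform, poly)
  # geometry check: tube (with dilation) must stay inside the grid
  rad_fun <- function(s) {
    r <- phantom_radius(spec, s)
    if (!is.null(dilation_fun)) r <- r + dilation_fun(s)
    r
  }
  rmax <- max(rad_fun(cc$s)) + spec$wall_thickness
  glo <- grid$origin; ghi <- grid$origin + (grid$dims - 1) * grid$spacing
  if (any(sweep(poly, 2, glo + rmax + 5) < -1e-9) ||
      any(sweep(poly, 2, ghi - rmax - 5) > 1e-9))
    stop("generate_baseline: tube exits the grid (geometry error)")
  ras <- rasterize_tube(spec, grid, poly, cc$s, rad_fun)
  vol <- ras$vol
  if (spec$branches) {
    for (bp in branch_paths(spec)) {
      bpoly <- bp
      if (!is.null(transform)) bpoly <- apply_transform(transform, bpoly)
      bl <- sqrt(sum((bpoly[2, ] - bpoly[1, ])^2))
      bsub <- cbind(seq(bpoly[1, 1], bpoly[2, 1], length.out = 15),
                    seq(bpoly[1, 2], bpoly[2, 2], length.out = 15),
                    seq(bpoly[1, 3], bpoly[2, 3], length.out = 15))
      bf <- cpp_polyline_field(grid$dims, grid$spacing, grid$origin, diag(3),
                               bsub, seq(0, bl, length.out = 15))
      wallmask <- bf$dist < 4 + spec$wall_thickness &
        vol == spec$background_hu
      vol[wallmask] <- spec$wall_hu
      vol[bf$dist < 4] <- spec$lumen_hu
    }
  }
  if (spec$texture_sigma_hu > 0) {
    bg <- vol == spec$background_hu
    tex <- scene_texture(spec, grid, transform)
    vol[bg] <- vol[bg] + tex[bg]
  }
  for (sp in spec$distractors)
    vol <- add_sphere(vol, grid, sp$center, sp$radius, sp$hu)
  volume <- image_volume(array(vol, dim = grid$dims), grid$spacing,
                         grid$origin, diag(3))
  if (spec$blur_sigma > 0) volume <- gaussian_smooth(volume, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    if (is.null(seed)) seed <- spec$seed
    set.seed(seed)
    volume$voxels <- volume$voxels +
      array(rnorm(length(volume$voxels), 0, spec$noise_sigma),
            dim = dim(volume$voxels))
  }
  lm <- phantom_landmarks(spec)
  cl <- make_centerline(poly)
  lmp <- centerline_at(cl, lm$s)$points
  truth <- list(centerline = cl,
                radius_fun = function(s) phantom_radius(spec, s),
                dilated_radius_fun = rad_fun,
                landmarks = cbind(lm, x = lmp[, 1], y = lmp[, 2],
                                  z = lmp[, 3]),
                transform = if (is.null(transform))
                  affine_transform() else transform,
                dilation_fun = dilation_fun,
                total_length = spec$total_length)
  list(volume = volume, truth = truth)
}

#' Generate the follow-up phantom twin
#'
#' Same geometry as the baseline with the lumen radius increased by a known
#' dilation profile and the whole scene mapped by a known (rigid) transform;
#' ground-truth landmark positions are mapped accordingly.
#'
#' @param spec the baseline `aorta_phantom_spec`.
#' @param dilation_fun function(s mm) -> radius increment mm (>= 0), or a
#'   single number for uniform dilation.
#' @param transform `affine_transform` (patient repositioning); identity by
#'   default.
#' @param seed noise seed (use a different seed than baseline for independent
#'   noise; same seed + zero dilation + identity transform reproduces the
#'   baseline bit-exactly).
#' @return list(volume, truth) as in [generate_baseline()].
#' @export
generate_followup <- function(spec, dilation_fun = 0,
                              transform = affine_transform(), seed = NULL) {
  if (is.numeric(dilation_fun)) {
    dd <- dilation_fun[1]
    if (dd < 0) stop("generate_followup: dilation must be >= 0")
    dilation_fun <- function(s) rep(dd, length(s))
  }
  if (any(dilation_fun(seq(0, spec$total_length, by = 5)) < 0))
    stop("generate_followup: dilation profile must be >= 0")
  generate_baseline(spec, dilation_fun = dilation_fun, transform = transform,
                    seed = seed)
}


# correlated background texture, fixed in scene coordinates: a smoothed
# coarse random lattice sampled at the (inverse-)transformed voxel centres,
# so baseline and follow-up share the same anatomy-like pattern
scene_texture <- function(spec, grid, transform = NULL) {
  step <- spec$texture_scale_mm
  # lattice bounds fixed in scene coordinates (independent of the output
  # grid and of the follow-up transform) so both time points share the
  # same pattern
  cc <- candy_cane_points(spec, step = 5)
  lo <- apply(cc$points, 2, min) - 60
  hi <- apply(cc$points, 2, max) + 60
  dims <- as.integer(ceiling((hi - lo) / step)) + 1L
  set.seed(spec$texture_seed)
  lat <- array(rnorm(prod(dims)), dim = dims)
  latvol <- image_volume(lat, rep(step, 3), lo, diag(3))
  latvol <- gaussian_smooth(latvol, step)
  latvol$voxels <- latvol$voxels / sd(latvol$voxels) * spec$texture_sigma_hu
  tr <- if (is.null(transform)) affine_transform() else
    invert_transform(transform)
  ref <- image_volume(array(0, grid$dims), grid$spacing, grid$origin, diag(3))
  out <- resample_to_reference(latvol, tr, ref, "linear", 0)
  as.numeric(out$voxels)
}
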