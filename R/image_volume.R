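#' Image volume container
#'
#' A regular 3-D scalar grid of CT intensities (HU) with world geometry in
#' the LPS (DICOM) frame.  Voxel indices are 0-based, ordered (x, y, z)
#' fastest-to-slowest; the world position of index v is
#' `origin + direction %*% (spacing * v)`.  Intensities are stored as doubles
#' regardless of the on-disk type.
#'
#' @param voxels 3-D numeric array (nx x ny x nz).
#' @param spacing per-axis voxel size, mm, all > 0.
#' @param origin world position of voxel (0,0,0), mm.
#' @param direction 3x3 orthonormal direction-cosine matrix (columns = axes).
#' @return Object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3,
            length(origin) == 3, all(dim(direction) == c(3, 3)))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (any(spacing <= 0)) stop("image_volume: spacing must be strictly positive")
  if (max(abs(t(direction) %*% direction - diag(3))) > 1e-6)
    stop("image_volume: direction matrix must be orthonormal")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s, spacing %s mm, origin %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @rdname image_volume
#' @param volume `image_volume`.
#' @export
volume_dims <- function(volume) dim(volume$voxels)

#' Voxel/world coordinate maps
#'
#' `voxel_to_world` maps continuous 0-based voxel indices to world mm;
#' `world_to_voxel` is its exact inverse.
#'
#' @param volume `image_volume`.
#' @param idx,points N x 3 matrix (or length-3 vector).
#' @return N x 3 matrix.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- rbind3(idx)
  sweep(sweep(idx, 2, volume$spacing, "*") %*% t(volume$direction),
        2, volume$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, points) {
  p <- rbind3(points)
  sweep(sweep(p, 2, volume$origin) %*% volume$direction, 2, volume$spacing, "/")
}

#' Sample a volume at world points
#'
#' Trilinear (default) or nearest-neighbour interpolation; points outside the
#' grid return `background`.
#'
#' @param volume `image_volume`.
#' @param points N x 3 world mm.
#' @param interpolation "linear" or "nearest".
#' @param background value for out-of-bounds points.
#' @return list(values, valid).
#' @export
sample_volume <- function(volume, points, interpolation = "linear",
                          background = -1024) {
  vc <- world_to_voxel(volume, points)
  cpp_sample(as.numeric(volume$voxels), dim(volume$voxels), vc,
             background, identical(interpolation, "nearest"))
}

#' Crop a volume along z
#'
#' Keeps slices `[z_lo, z_hi)` (0-based, half-open) and shifts the origin so
#' that every retained voxel keeps its world position.  Mirrors the manual
#' removal of scan regions outside the thoracic extent.
#'
#' @param volume `image_volume`.
#' @param z_lo,z_hi 0-based slice range, half open; `0 <= z_lo < z_hi <= nz`.
#' @return Cropped `image_volume`.
#' @export
crop_z <- function(volume, z_lo, z_hi) {
  nz <- dim(volume$voxels)[3]
  if (!(z_lo >= 0 && z_lo < z_hi && z_hi <= nz))
    stop("crop_z: need 0 <= z_lo < z_hi <= number of slices")
  vox <- volume$voxels[, , (z_lo + 1):z_hi, drop = FALSE]
  origin <- as.numeric(voxel_to_world(volume, c(0, 0, z_lo)))
  image_volume(vox, volume$spacing, origin, volume$direction)
}

#' Resample a moving volume onto a reference grid
#'
#' Output has the reference geometry; the value at world point p is the moving
#' volume sampled at `transform(p)`.  This is the fixed-frame resampling used
#' to bring the follow-up scan into the baseline frame after registration.
#'
#' @param moving `image_volume` to sample from.
#' @param transform `affine_transform` mapping reference world points into the
#'   moving volume's world frame.
#' @param reference `image_volume` providing the output grid.
#' @param interpolation "linear" or "nearest".
#' @param background HU value for points mapping outside `moving`.
#' @return `image_volume` on the reference grid.
#' @export
resample_to_reference <- function(moving, transform, reference,
                                  interpolation = "linear",
                                  background = -1024) {
  if (abs(det(transform$linear)) < 1e-12)
    stop("resample_to_reference: singular transform")
  d <- dim(reference$voxels)
  # affine map: reference voxel index -> moving voxel index
  # world(ref, v) = o_r + D_r S_r v ; T(p) = A(p-c)+c+t ; voxel(mov, q)
  A <- transform$linear
  M1 <- diag(1 / moving$spacing) %*% t(moving$direction)
  M2 <- A %*% reference$direction %*% diag(reference$spacing)
  B <- M1 %*% M2
  p0 <- as.numeric(apply_transform(transform, reference$origin))
  b0 <- as.numeric(M1 %*% (p0 - moving$origin))
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  vc <- sweep(idx %*% t(B), 2, b0, "+")
  sm <- cpp_sample(as.numeric(moving$voxels), dim(moving$voxels), vc,
                   background, identical(interpolation, "nearest"))
  image_volume(array(sm$values, dim = d), reference$spacing,
               reference$origin, reference$direction)
}

# separable gaussian smoothing, sigma in mm per axis (scalar recycled)
gaussian_smooth <- function(volume, sigma_mm) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  vox <- as.numeric(volume$voxels)
  d <- dim(volume$voxels)
  for (ax in 1:3) {
    sv <- sigma_mm[ax] / volume$spacing[ax]   # sigma in voxels
    if (sv <= 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * sv)))
    k <- exp(-0.5 * ((-r:r) / sv)^2)
    k <- k / sum(k)
    vox <- cpp_convolve_dim(vox, d, k, ax - 1L)
  }
  image_volume(array(vox, dim = d), volume$spacing, volume$origin,
               volume$direction)
}

# downsample by integer factor with matched smoothing (registration pyramid)
downsample_volume <- function(volume, factor) {
  if (factor <= 1) return(volume)
  sm <- gaussian_smooth(volume, volume$spacing * factor / 2)
  d <- dim(volume$voxels)
  ix <- seq(1, d[1], by = factor); iy <- seq(1, d[2], by = factor)
  iz <- seq(1, d[3], by = factor)
  image_volume(sm$voxels[ix, iy, iz, drop = FALSE], volume$spacing * factor,
               volume$origin, volume$direction)
}
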