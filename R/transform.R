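#' 3-D affine transforms
#'
#' An affine transform maps a world point p to
#' `linear %*% (p - center) + center + translation`.  The rigid subtype has an
#' orthogonal linear part with determinant +1 (rotation + translation).
#'
#' @param linear 3x3 matrix, invertible.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, mm; center of rotation.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  stopifnot(length(translation) == 3, length(center) == 3)
  if (abs(det(linear)) < 1e-12)
    stop("affine_transform: linear part is singular")
  structure(list(linear = linear,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' Rigid transform from Euler angles
#'
#' Rotations (degrees) applied in x, y, z order about `center`.
#'
#' @param angles_deg numeric length-3, rotations about x, y, z axes (degrees).
#' @param translation numeric length-3, mm.
#' @param center rotation center, mm.
#' @return `affine_transform` with orthogonal linear part.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  affine_transform(Rz %*% Ry %*% Rx, translation, center)
}

#' Apply an affine transform to points
#'
#' @param transform `affine_transform`.
#' @param points N x 3 matrix (or length-3 vector) of world points, mm.
#' @return N x 3 matrix of mapped points.
#' @export
apply_transform <- function(transform, points) {
  p <- rbind3(points)
  out <- sweep(p, 2, transform$center) %*% t(transform$linear)
  sweep(out, 2, transform$center + transform$translation, "+")
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

#' Invert an affine transform
#' @param transform `affine_transform`.
#' @return The inverse `affine_transform` (same center).
#' @export
invert_transform <- function(transform) {
  Ainv <- solve(transform$linear)
  # q = A(p-c)+c+t  =>  p = Ainv(q - c - t) + c
  affine_transform(Ainv, as.numeric(-Ainv %*% transform$translation),
                   transform$center)
}

#' Compose transforms (first `b`, then `a`)
#' @param a,b `affine_transform`s.
#' @return `affine_transform` equal to a(b(p)), expressed about a's center.
#' @export
compose_transform <- function(a, b) {
  # a(b(p)) = Aa (Ab (p - cb) + cb + tb - ca) + ca + ta
  A <- a$linear %*% b$linear
  c0 <- a$center
  # offset so that A (p - c0) + c0 + t == a(b(p))
  p0 <- c(0, 0, 0)
  img <- apply_transform(a, apply_transform(b, p0))
  t0 <- as.numeric(img) - as.numeric(A %*% (p0 - c0)) - c0
  affine_transform(A, t0, c0)
}

#' Test for rigidity
#' @param transform `affine_transform`.
#' @param tol orthonormality tolerance.
#' @return TRUE if the linear part is a rotation within `tol`.
#' @export
is_rigid <- function(transform, tol = 1e-6) {
  L <- transform$linear
  isTRUE(max(abs(t(L) %*% L - diag(3))) < tol) && det(L) > 0
}

# Decompose the linear part: rotation angles (deg, xyz order) and scales.
# Used for reporting recovery errors against known ground truth.
#' Summarize a transform as rotation / translation / scale
#' @param transform `affine_transform`.
#' @return list with `angles_deg` (length 3), `translation`, `scales`
#'   (singular values of the linear part), `rotation_deg` (total rotation
#'   angle of the orthogonal polar factor).
#' @export
decompose_transform <- function(transform) {
  L <- transform$linear
  sv <- svd(L)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { # reflectivity folded into scales
    sv$u[, 3] <- -sv$u[, 3]
    R <- sv$u %*% t(sv$v)
  }
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(rotation_deg = ang,
       translation = transform$translation,
       scales = sv$d)
}
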