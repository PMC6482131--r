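#' Tube surface meshes
#'
#' The lumen surface is a structured triangulated tube: R control rings of K
#' vertices each, open at both ends, refined by Loop subdivision for
#' measurement.  Control vertices carry (ring, angular) labels; subdivided
#' vertices carry an interpolated continuous ring coordinate used to map
#' them back to arc length.
#'
#' @name surface_mesh
NULL

new_surface_mesh <- function(control_vertices, control_faces, rings, K,
                             ring_index, ang_index, ring_arc, levels = 2) {
  m <- structure(list(control_vertices = control_vertices,
                      control_faces = control_faces,
                      rings = rings, K = K,
                      ring_index = ring_index, ang_index = ang_index,
                      ring_arc = ring_arc, levels = levels,
                      field = NULL),
                 class = "surface_mesh")
  refresh_subdivision(m)
}

refresh_subdivision <- function(mesh) {
  sub <- subdivide_mesh(mesh$control_vertices, mesh$control_faces,
                        mesh$ring_index, mesh$levels)
  if (mesh$levels > 0) {
    # cage-to-surface calibration: the Loop-refined surface of a K-gon ring
    # cage contracts by ~(2 + cos(2*pi/K))/3 radially; inflate the refined
    # vertices about the interpolated ring axis so the surface passes
    # through the fitted cage (the cage vertices are what the image fit
    # places on the lumen edge).
    f <- 3 / (2 + cos(2 * pi / mesh$K))
    ctr <- ring_centroids(mesh)
    vr <- pmin(mesh$rings, pmax(1, sub$scalar))
    lo <- floor(vr); hi <- pmin(mesh$rings, lo + 1); w <- vr - lo
    cint <- ctr[lo, , drop = FALSE] * (1 - w) + ctr[hi, , drop = FALSE] * w
    sub$vertices <- cint + (sub$vertices - cint) * f
  }
  mesh$vertices <- sub$vertices
  mesh$faces <- sub$faces
  mesh$v_ring <- sub$scalar
  mesh
}

ring_centroids <- function(mesh) {
  rs <- rowsum(mesh$control_vertices, mesh$ring_index, reorder = TRUE)
  rs / as.numeric(table(mesh$ring_index))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "surface_mesh: %d control rings x %d, %d control vertices; %d subdivided vertices (%d levels)\n",
    x$rings, x$K, nrow(x$control_vertices), nrow(x$vertices), x$levels))
  invisible(x)
}

#' Initialize a tube control mesh around a centerline
#'
#' Control rings are placed at equal arc-length intervals; each ring is a
#' regular K-gon of the given radius in the plane normal to the local
#' tangent.  Rotation-minimizing frame transport keeps adjacent rings
#' untwisted.
#'
#' @param centerline `centerline`.
#' @param radius initial tube radius, mm (> 0).
#' @param rings_per_cm control ring density (default 2, i.e. 5 mm spacing).
#' @param vertices_per_ring K (default 16).
#' @param levels Loop subdivision levels for the refined surface.
#' @return `surface_mesh`.
#' @export
init_tube_mesh <- function(centerline, radius, rings_per_cm = 2,
                           vertices_per_ring = 16, levels = 2) {
  if (radius <= 0) stop("init_tube_mesh: radius must be > 0")
  stopifnot(inherits(centerline, "centerline"))
  total <- max(centerline$arc)
  R <- max(2L, as.integer(round(total * rings_per_cm / 10)) + 1L)
  K <- as.integer(vertices_per_ring)
  ring_arc <- seq(0, total, length.out = R)
  # frames on the full centerline, picked at nearest samples (keeps RMF
  # continuity along the rings)
  frames <- transport_frames(centerline$tangents)
  nearest <- vapply(ring_arc, function(s) which.min(abs(centerline$arc - s)),
                    integer(1))
  ctr <- centerline_at(centerline, ring_arc)$points
  th <- 2 * pi * (0:(K - 1)) / K
  verts <- matrix(0, R * K, 3)
  ring_index <- rep(seq_len(R), each = K)
  ang_index <- rep(seq_len(K), R)
  for (i in seq_len(R)) {
    u <- frames$u[nearest[i], ]; v <- frames$v[nearest[i], ]
    ring <- sweep(outer(cos(th), u) + outer(sin(th), v), 1, radius, "*")
    verts[(i - 1) * K + (1:K), ] <- sweep(ring, 2, ctr[i, ], "+")
  }
  faces <- tube_faces(R, K)
  m <- new_surface_mesh(verts, faces, R, K, ring_index, ang_index, ring_arc,
                        levels)
  orient_outward(m, ctr)
}

tube_faces <- function(R, K) {
  f <- matrix(0L, 2 * (R - 1) * K, 3)
  row <- 1
  for (i in seq_len(R - 1)) {
    for (k in seq_len(K)) {
      k2 <- if (k == K) 1L else k + 1L
      a <- (i - 1) * K + k; b <- (i - 1) * K + k2
      c0 <- i * K + k2; d0 <- i * K + k
      f[row, ] <- c(a, b, c0); f[row + 1, ] <- c(a, c0, d0)
      row <- row + 2
    }
  }
  f
}

# flip all faces if normals point toward the axis
orient_outward <- function(mesh, ring_centers) {
  nrm <- vertex_normals(mesh$control_vertices, mesh$control_faces)
  radial <- mesh$control_vertices - ring_centers[mesh$ring_index, ,
                                                 drop = FALSE]
  if (mean(rowSums(nrm * radial)) < 0) {
    mesh$control_faces <- mesh$control_faces[, c(1, 3, 2)]
    mesh <- refresh_subdivision(mesh)
  }
  mesh
}

# area-weighted vertex normals (unit length)
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c0 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c0 - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    rs <- rowsum(fn, faces[, j], reorder = FALSE)
    rid <- as.integer(rownames(rs))
    n[rid, ] <- n[rid, ] + rs
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Loop subdivision of a triangle mesh
#'
#' One or more rounds of Loop subdivision with cubic B-spline rules on the
#' two open boundary loops.  Linear in the vertex positions; the optional
#' scalar (ring coordinate) is refined with the same stencils.
#'
#' @param mesh `surface_mesh`.
#' @param levels number of rounds (>= 0).
#' @return `surface_mesh` with `levels` set and refined vertices/faces.
#' @export
subdivide <- function(mesh, levels) {
  stopifnot(levels >= 0)
  mesh$levels <- as.integer(levels)
  refresh_subdivision(mesh)
}

subdivide_mesh <- function(vertices, faces, scalar, levels) {
  scalar <- as.numeric(scalar)
  for (l in seq_len(levels)) {
    res <- loop_once(vertices, faces, scalar)
    vertices <- res$vertices; faces <- res$faces; scalar <- res$scalar
  }
  list(vertices = vertices, faces = faces, scalar = scalar)
}

loop_once <- function(V, F0, S) {
  nv <- nrow(V); nf <- nrow(F0)
  ea <- rbind(F0[, c(1, 2)], F0[, c(2, 3)], F0[, c(3, 1)])
  opp <- c(F0[, 3], F0[, 1], F0[, 2])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  ek <- match(key, unique(key))
  ne <- max(ek)
  cnt <- tabulate(ek, ne)
  boundary_edge <- cnt == 1
  # endpoints per unique edge
  first <- match(seq_len(ne), ek)
  e1 <- pmin(ea[first, 1], ea[first, 2])
  e2 <- pmax(ea[first, 1], ea[first, 2])
  # opposite vertices (sum, then split by count)
  opp_sum_v <- rowsum(V[opp, , drop = FALSE], ek, reorder = TRUE)
  opp_sum_s <- as.numeric(rowsum(S[opp], ek, reorder = TRUE))
  # odd (edge) points
  EP <- matrix(0, ne, 3); ES <- numeric(ne)
  intn <- !boundary_edge
  EP[intn, ] <- 0.375 * (V[e1[intn], , drop = FALSE] +
                           V[e2[intn], , drop = FALSE]) +
    0.125 * opp_sum_v[intn, , drop = FALSE]
  ES[intn] <- 0.375 * (S[e1[intn]] + S[e2[intn]]) + 0.125 * opp_sum_s[intn]
  EP[boundary_edge, ] <- 0.5 * (V[e1[boundary_edge], , drop = FALSE] +
                                  V[e2[boundary_edge], , drop = FALSE])
  ES[boundary_edge] <- 0.5 * (S[e1[boundary_edge]] + S[e2[boundary_edge]])
  # even (original) points
  bvert <- unique(c(e1[boundary_edge], e2[boundary_edge]))
  is_b <- logical(nv); is_b[bvert] <- TRUE
  # neighbor sums over unique edges
  nb_sum <- rowsum(rbind(V[e2, , drop = FALSE], V[e1, , drop = FALSE]),
                   c(e1, e2), reorder = TRUE)
  nb_s <- as.numeric(rowsum(c(S[e2], S[e1]), c(e1, e2), reorder = TRUE))
  nb_n <- tabulate(c(e1, e2), nv)
  rid <- as.integer(rownames(nb_sum))
  full_sum <- matrix(0, nv, 3); full_sum[rid, ] <- nb_sum
  full_s <- numeric(nv); full_s[rid] <- nb_s
  NV <- V; NS <- S
  # interior rule
  n_int <- which(!is_b & nb_n > 0)
  if (length(n_int)) {
    n <- nb_n[n_int]
    beta <- (1 / n) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / n))^2)
    NV[n_int, ] <- (1 - n * beta) * V[n_int, , drop = FALSE] +
      beta * full_sum[n_int, , drop = FALSE]
    NS[n_int] <- (1 - n * beta) * S[n_int] + beta * full_s[n_int]
  }
  # boundary (B-spline) rule: neighbors restricted to boundary edges
  if (any(is_b)) {
    be1 <- e1[boundary_edge]; be2 <- e2[boundary_edge]
    bsum <- rowsum(rbind(V[be2, , drop = FALSE], V[be1, , drop = FALSE]),
                   c(be1, be2), reorder = TRUE)
    bs <- as.numeric(rowsum(c(S[be2], S[be1]), c(be1, be2), reorder = TRUE))
    brid <- as.integer(rownames(bsum))
    bn <- tabulate(c(be1, be2), nv)
    ok <- brid[bn[brid] == 2]
    NV[ok, ] <- 0.75 * V[ok, , drop = FALSE] +
      0.125 * bsum[match(ok, brid), , drop = FALSE]
    NS[ok] <- 0.75 * S[ok] + 0.125 * bs[match(ok, brid)]
  }
  # new faces
  eix <- matrix(ek, nf, 3)          # per-face edge ids (12, 23, 31)
  E12 <- nv + eix[, 1]; E23 <- nv + eix[, 2]; E31 <- nv + eix[, 3]
  NF <- rbind(cbind(F0[, 1], E12, E31),
              cbind(F0[, 2], E23, E12),
              cbind(F0[, 3], E31, E23),
              cbind(E12, E23, E31))
  list(vertices = rbind(NV, EP), faces = NF, scalar = c(NS, ES))
}

#' Per-ring maximal diameter of a tube mesh
#'
#' Maximum pairwise distance among the control vertices of each ring.
#'
#' @param mesh `surface_mesh`.
#' @return data.frame(ring, s, diameter_mm).
#' @export
ring_diameters <- function(mesh) {
  out <- numeric(mesh$rings)
  for (i in seq_len(mesh$rings)) {
    P <- mesh$control_vertices[mesh$ring_index == i, , drop = FALSE]
    out[i] <- max(dist(P))
  }
  data.frame(ring = seq_len(mesh$rings), s = mesh$ring_arc,
             diameter_mm = out)
}

# per-ring mean radius about the ring centroid (robust to the ring plane
# tilting away from the centerline tangent during fitting)
mean_ring_radius <- function(mesh, centerline = NULL) {
  ctr <- ring_centroids(mesh)
  r <- sqrt(rowSums((mesh$control_vertices -
                       ctr[mesh$ring_index, , drop = FALSE])^2))
  tapply(r, mesh$ring_index, mean)
}

#' Write a mesh to ASCII PLY
#'
#' The subdivided surface is written; if a per-vertex scalar field is
#' attached (dilatation, mm) it is stored in a `quality` property.
#'
#' @param mesh `surface_mesh`.
#' @param path output `.ply` path.
#' @return path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; F0 <- mesh$faces
  q <- mesh_vertex_field(mesh)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(V)),
           "property float x", "property float y", "property float z",
           if (!is.null(q)) "property float quality",
           paste("element face", nrow(F0)),
           "property list uchar int vertex_indices", "end_header")
  vl <- if (is.null(q))
    sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3])
  else sprintf("%.6f %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3], q)
  fl <- sprintf("3 %d %d %d", F0[, 1] - 1, F0[, 2] - 1, F0[, 3] - 1)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Write a mesh to legacy ASCII VTK polydata
#' @param mesh `surface_mesh`.
#' @param path output `.vtk` path.
#' @return path, invisibly.
#' @export
write_vtk <- function(mesh, path) {
  V <- mesh$vertices; F0 <- mesh$faces
  q <- mesh_vertex_field(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aortrack surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(V), "float")), con)
  writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  writeLines(paste("POLYGONS", nrow(F0), 4 * nrow(F0)), con)
  writeLines(sprintf("3 %d %d %d", F0[, 1] - 1, F0[, 2] - 1, F0[, 3] - 1),
             con)
  if (!is.null(q)) {
    writeLines(c(paste("POINT_DATA", nrow(V)),
                 "SCALARS dilatation_mm float 1", "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.6f", q), con)
  }
  invisible(path)
}

# propagate the per-control-ring field to subdivided vertices (nearest ring)
mesh_vertex_field <- function(mesh) {
  if (is.null(mesh$field)) return(NULL)
  ring <- pmin(mesh$rings, pmax(1, round(mesh$v_ring)))
  mesh$field[ring]
}
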