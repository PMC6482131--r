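landmark_vocabulary <- c("STJ", "MAA", "PROX", "MID_ARCH", "DIST", "DESC",
                         "DIAPHRAGM")

#' Build the landmark measurement planes
#'
#' Each annotated point (a user click on the baseline scan) is projected to
#' its nearest centerline position; the measurement plane passes through that
#' position with the centerline tangent as its normal.  The seven landmark
#' names are fixed (STJ, MAA, PROX, MID_ARCH, DIST, DESC, DIAPHRAGM) and the
#' projected arc lengths must respect the anatomical order.
#'
#' @param annotations named list of world points, or a data.frame with
#'   columns name, x, y, z.
#' @param centerline baseline `centerline`.
#' @param max_distance maximum allowed click-to-centerline distance, mm.
#' @return data.frame(name, s, x, y, z, nx, ny, nz) in anatomical order,
#'   class `landmark_set`.
#' @export
build_landmarks <- function(annotations, centerline, max_distance = 30) {
  if (is.data.frame(annotations)) {
    nm <- as.character(annotations$name)
    pts <- as.matrix(annotations[, c("x", "y", "z")])
  } else {
    nm <- names(annotations)
    pts <- do.call(rbind, lapply(annotations, as.numeric))
  }
  if (is.null(nm) || !setequal(nm, landmark_vocabulary))
    stop("build_landmarks: annotations must contain exactly the landmarks ",
         paste(landmark_vocabulary, collapse = ", "))
  rownames(pts) <- nm
  s <- numeric(length(nm)); names(s) <- nm
  for (n in nm) {
    d2 <- rowSums(sweep(centerline$points, 2, pts[n, ])^2)
    i <- which.min(d2)
    if (sqrt(d2[i]) > max_distance)
      stop("build_landmarks: annotation '", n, "' is ",
           round(sqrt(d2[i]), 1), " mm from the centerline (limit ",
           max_distance, " mm)")
    s[n] <- centerline$arc[i]
  }
  s <- s[landmark_vocabulary]
  if (any(diff(s) <= 0))
    stop("build_landmarks: projected landmarks are not in anatomical order ",
         "(STJ to DIAPHRAGM must have increasing arc length)")
  at <- centerline_at(centerline, s)
  out <- data.frame(name = landmark_vocabulary, s = as.numeric(s),
                    x = at$points[, 1], y = at$points[, 2],
                    z = at$points[, 3],
                    nx = at$tangents[, 1], ny = at$tangents[, 2],
                    nz = at$tangents[, 3], stringsAsFactors = FALSE)
  class(out) <- c("landmark_set", class(out))
  out
}

#' Cross-section of a mesh with a plane
#'
#' Intersects the plane (point, normal) with the subdivided triangle mesh,
#' assembles the crossing segments into closed loops, and returns the loop
#' whose centroid is nearest the plane point, ordered counterclockwise about
#' the normal.
#'
#' @param mesh `surface_mesh`.
#' @param point world mm point on the plane.
#' @param normal plane normal (normalized internally).
#' @return list(polygon, centroid, area_mm2, max_diameter_mm,
#'   diameter_endpoints), class `cross_section`.
#' @export
cross_section <- function(mesh, point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal); normal <- normal / sqrt(sum(normal^2))
  V <- mesh$vertices; F0 <- mesh$faces
  dsg <- as.numeric(sweep(V, 2, point) %*% normal)
  dsg[abs(dsg) < 1e-9] <- 1e-9
  s1 <- dsg[F0[, 1]]; s2 <- dsg[F0[, 2]]; s3 <- dsg[F0[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing))
    stop("cross_section: plane does not intersect the mesh (out of range)")
  Fc <- F0[crossing, , drop = FALSE]
  # per-face crossing edges and intersection points
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seg_edges <- vector("list", nrow(Fc))
  seg_pts <- vector("list", nrow(Fc))
  for (i in seq_len(nrow(Fc))) {
    vv <- Fc[i, ]
    dd <- dsg[vv]
    ek <- character(0); ep <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- vv[e[1]]; b <- vv[e[2]]
      if (dsg[a] * dsg[b] < 0) {
        t <- dsg[a] / (dsg[a] - dsg[b])
        ek <- c(ek, edge_key(a, b))
        ep[[length(ep) + 1]] <- V[a, ] + t * (V[b, ] - V[a, ])
      }
    }
    seg_edges[[i]] <- ek
    seg_pts[[i]] <- ep
  }
  keep <- lengths(seg_edges) == 2
  seg_edges <- seg_edges[keep]; seg_pts <- seg_pts[keep]
  if (length(seg_edges) == 0)
    stop("cross_section: plane does not intersect the mesh (out of range)")
  # chain segments: nodes = edge keys, links = faces
  all_keys <- unique(unlist(seg_edges))
  pt_of <- new.env()
  for (i in seq_along(seg_edges))
    for (j in 1:2) assign(seg_edges[[i]][j], seg_pts[[i]][[j]], envir = pt_of)
  adj <- new.env()
  for (i in seq_along(seg_edges)) {
    for (j in 1:2) {
      k <- seg_edges[[i]][j]
      other <- seg_edges[[i]][3 - j]
      cur <- if (exists(k, envir = adj, inherits = FALSE))
        get(k, envir = adj) else character(0)
      assign(k, c(cur, other), envir = adj)
    }
  }
  visited <- new.env()
  loops <- list(); open_loops <- 0
  for (start in all_keys) {
    if (exists(start, envir = visited, inherits = FALSE)) next
    chain <- start
    assign(start, TRUE, envir = visited)
    cur <- start; prev <- ""
    closed <- FALSE
    repeat {
      nxt <- setdiff(get(cur, envir = adj), prev)
      nxt <- nxt[!vapply(nxt, function(k)
        exists(k, envir = visited, inherits = FALSE) && k != start,
        logical(1))]
      if (length(nxt) == 0) break
      if (nxt[1] == start) { closed <- TRUE; break }
      prev <- cur; cur <- nxt[1]
      chain <- c(chain, cur)
      assign(cur, TRUE, envir = visited)
    }
    if (!closed) {
      # try extending backwards from the start before declaring open
      prev <- if (length(chain) > 1) chain[2] else ""
      cur <- start
      repeat {
        nxt <- setdiff(get(cur, envir = adj), prev)
        nxt <- nxt[!vapply(nxt, function(k)
          exists(k, envir = visited, inherits = FALSE), logical(1))]
        if (length(nxt) == 0) break
        prev <- cur; cur <- nxt[1]
        chain <- c(cur, chain)
        assign(cur, TRUE, envir = visited)
      }
      open_loops <- open_loops + 1
      attr(chain, "open") <- TRUE
    }
    loops[[length(loops) + 1]] <- chain
  }
  polys <- lapply(loops, function(ch)
    do.call(rbind, lapply(ch, function(k) get(k, envir = pt_of))))
  cents <- t(vapply(polys, colMeans, numeric(3)))
  is_open <- vapply(loops, function(ch) isTRUE(attr(ch, "open")), logical(1))
  dctr <- sqrt(rowSums(sweep(cents, 2, point)^2))
  best <- which.min(dctr)
  if (is_open[best])
    stop("cross_section: plane crosses the mesh boundary ",
         "(open intersection loop)")
  poly <- polys[[best]]
  # CCW orientation about the normal
  basis <- plane_basis(normal)
  uv <- sweep(poly, 2, point) %*% cbind(basis$u, basis$v)
  a2 <- sum(uv[, 1] * c(uv[-1, 2], uv[1, 2]) -
              c(uv[-1, 1], uv[1, 1]) * uv[, 2])
  if (a2 < 0) { poly <- poly[rev(seq_len(nrow(poly))), ]; a2 <- -a2 }
  md <- max_diameter(poly)
  structure(list(polygon = poly, centroid = colMeans(poly),
                 area_mm2 = a2 / 2, max_diameter_mm = md$diameter,
                 diameter_endpoints = md$endpoints),
            class = "cross_section")
}

plane_basis <- function(normal) {
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- cross3(normal, ref); u <- u / sqrt(sum(u^2))
  v <- cross3(normal, u)
  list(u = u, v = v)
}

#' Maximal cross-sectional diameter of a polygon
#'
#' Diameter of the vertex set (maximum pairwise distance), computed on the
#' convex hull; equals the brute-force pairwise maximum exactly.
#'
#' @param section `cross_section` or an N x 3 (planar) point matrix.
#' @return list(diameter, endpoints = 2 x 3 matrix).
#' @export
max_diameter <- function(section) {
  poly <- if (inherits(section, "cross_section")) section$polygon else
    rbind3(section)
  if (nrow(poly) < 3) stop("max_diameter: polygon needs at least 3 points")
  ctr <- colMeans(poly)
  sv <- svd(sweep(poly, 2, ctr))
  uv <- sweep(poly, 2, ctr) %*% sv$v[, 1:2]
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("max_diameter: degenerate (collinear) polygon")
  h <- chull(uv)
  hp <- poly[h, , drop = FALSE]
  dm <- as.matrix(dist(hp))
  w <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  list(diameter = max(dm), endpoints = hp[w, , drop = FALSE])
}

#' Measure both time points at the landmark planes
#'
#' Cross-sections and maximal diameters of the baseline and follow-up meshes
#' on the same baseline-defined planes; the difference column is
#' follow-up minus baseline.  Per-landmark failures are recorded as NA with
#' a reason, not raised.
#'
#' When the centerline is supplied, landmark planes that fall within
#' `end_margin` mm of the open tube ends are nudged inward along the
#' centerline so the plane cannot clip the boundary ring (a landmark such as
#' the STJ sits close to where the segmented surface stops).
#'
#' @param baseline_mesh,followup_mesh `surface_mesh`es in the baseline frame.
#' @param landmarks `landmark_set`.
#' @param centerline optional `centerline` (the one the meshes were built
#'   on); enables the end-margin nudge.
#' @param end_margin minimum distance of a measurement plane from the mesh
#'   ends, mm.
#' @return data.frame(name, s, baseline_mm, followup_mm, difference_mm,
#'   note).
#' @export
measure_pair <- function(baseline_mesh, followup_mesh, landmarks,
                         centerline = NULL, end_margin = 10) {
  if (!is.null(centerline)) {
    lo <- min(baseline_mesh$ring_arc) + end_margin
    hi <- max(baseline_mesh$ring_arc) - end_margin
    sc <- pmin(hi, pmax(lo, landmarks$s))
    moved <- which(abs(sc - landmarks$s) > 1e-9)
    if (length(moved)) {
      at <- centerline_at(centerline, sc[moved])
      landmarks$s[moved] <- sc[moved]
      landmarks[moved, c("x", "y", "z")] <- at$points
      landmarks[moved, c("nx", "ny", "nz")] <- at$tangents
    }
  }
  rows <- lapply(seq_len(nrow(landmarks)), function(i) {
    p <- as.numeric(landmarks[i, c("x", "y", "z")])
    n <- as.numeric(landmarks[i, c("nx", "ny", "nz")])
    meas <- function(mesh) tryCatch(
      cross_section(mesh, p, n)$max_diameter_mm,
      error = function(e) structure(NA_real_, reason = conditionMessage(e)))
    b <- meas(baseline_mesh); f <- meas(followup_mesh)
    note <- paste(c(attr(b, "reason"), attr(f, "reason")), collapse = "; ")
    data.frame(name = landmarks$name[i], s = landmarks$s[i],
               baseline_mm = as.numeric(b), followup_mm = as.numeric(f),
               difference_mm = as.numeric(f) - as.numeric(b),
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diameter-versus-arc-length curve
#'
#' Maximal cross-sectional diameter at every `step` mm along the centerline;
#' positions where the plane crosses the mesh boundary are omitted.  Arc
#' length is reported relative to `origin_s` (e.g. the STJ landmark) when
#' given.
#'
#' @param mesh `surface_mesh`.
#' @param centerline `centerline`.
#' @param step sampling step, mm (> 0).
#' @param origin_s arc length of the curve origin, mm (default 0).
#' @return data.frame(s, diameter_mm) with NA-free rows only.
#' @export
diameter_curve <- function(mesh, centerline, step = 2, origin_s = 0) {
  stopifnot(step > 0)
  total <- max(centerline$arc)
  s <- unique(c(seq(0, total, by = step), total))
  at <- centerline_at(centerline, s)
  dmm <- vapply(seq_along(s), function(i) {
    tryCatch(cross_section(mesh, at$points[i, ],
                           at$tangents[i, ])$max_diameter_mm,
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(s = s - origin_s, diameter_mm = dmm)
  out[!is.na(out$diameter_mm), , drop = FALSE]
}

#' Per-vertex dilatation field
#'
#' Signed diameter change (follow-up minus baseline, mm) per baseline
#' control ring, matched by ring arc length, stored as the baseline mesh's
#' scalar channel (exported to PLY/VTK for the color-coded 3-D overview,
#' where 0/5/10 mm map to distinct colors).
#'
#' @param baseline_mesh,followup_mesh `surface_mesh`es sharing ring
#'   structure (the follow-up fit is initialized from the baseline mesh).
#' @return `baseline_mesh` with `$field` set (one value per ring).
#' @export
dilatation_field <- function(baseline_mesh, followup_mesh) {
  db <- ring_diameters(baseline_mesh)
  df <- ring_diameters(followup_mesh)
  if (nrow(db) == nrow(df) && max(abs(db$s - df$s)) < 1e-6) {
    field <- df$diameter_mm - db$diameter_mm
  } else {
    fi <- approx(df$s, df$diameter_mm, xout = db$s)$y  # NA outside span
    field <- fi - db$diameter_mm
  }
  baseline_mesh$field <- field
  baseline_mesh
}
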