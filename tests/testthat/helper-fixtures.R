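# shared fixtures, built once per test run and cached in the session

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# coarse (1.4 mm) candy-cane specs: clean = no noise/texture/distractors,
# noisy = generator defaults
clean_spec <- function(...) {
  args <- modifyList(list(spacing = 1.4, noise_sigma = 0,
                          texture_sigma_hu = 0, distractors = list()),
                     list(...))
  do.call(aorta_phantom_spec, args)
}

noisy_spec <- function(...) aorta_phantom_spec(spacing = 1.4, ...)

phantom_clean <- function() cached("phantom_clean",
                                   generate_baseline(clean_spec()))
phantom_noisy <- function() cached("phantom_noisy",
                                   generate_baseline(noisy_spec()))

truth_centerline <- function(ph) resample_centerline(ph$truth$centerline, 1, 0)

truth_annotations <- function(ph) {
  lm <- ph$truth$landmarks
  setNames(lapply(seq_len(nrow(lm)), function(i)
    as.numeric(lm[i, c("x", "y", "z")])), lm$name)
}

baseline_mesh_clean <- function() cached("mesh_clean", {
  ph <- phantom_clean()
  segment_baseline(ph$volume, truth_centerline(ph))
})

baseline_mesh_noisy <- function() cached("mesh_noisy", {
  ph <- phantom_noisy()
  segment_baseline(ph$volume, truth_centerline(ph))
})

# mean distance from the points of `cl` to the ground-truth centerline
centerline_error <- function(cl, truth) {
  d <- vapply(seq_len(nrow(cl$points)), function(i)
    min(sqrt(rowSums(sweep(truth$points, 2, cl$points[i, ])^2))),
    numeric(1))
  mean(d)
}

# a straight-cylinder test volume (noiseless, blurred)
cylinder_volume <- function(radius = 15, wall = 2, spacing = 1,
                            half = c(30, 30, 40), blur = 0.6,
                            lumen = 300, wallhu = 60, bg = 20) {
  dims <- as.integer(2 * half / spacing) + 1L
  org <- -half
  idx <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                               0:(dims[3] - 1)))
  w <- sweep(sweep(idx, 2, rep(spacing, 3), "*"), 2, org, "+")
  r2 <- w[, 1]^2 + w[, 2]^2
  vox <- ifelse(r2 < radius^2, lumen,
                ifelse(r2 < (radius + wall)^2, wallhu, bg))
  v <- image_volume(array(vox, dims), rep(spacing, 3), org)
  if (blur > 0) v <- aortrack:::gaussian_smooth(v, blur)
  v
}

cylinder_cost <- function(...) gradient_cost(cylinder_volume(...), 1.4)

# independent shortest-path oracle on a 26-connected grid (igraph)
igraph_grid_shortest <- function(cost, dims, spacing, start, end,
                                 length_penalty = 0) {
  lin <- function(v) 1 + v[1] + v[2] * dims[1] + v[3] * dims[1] * dims[2]
  edges <- NULL; weights <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  el <- list(); wl <- list(); k <- 0
  for (z in 0:(dims[3] - 1)) for (y in 0:(dims[2] - 1))
    for (x in 0:(dims[1] - 1)) {
      u <- c(x, y, z)
      cu <- cost[lin(u)]
      if (!is.finite(cu)) next
      for (o in seq_len(nrow(offs))) {
        v <- u + offs[o, ]
        if (any(v < 0) || any(v >= dims)) next
        if (lin(v) < lin(u)) next          # each undirected edge once
        cv <- cost[lin(v)]
        if (!is.finite(cv)) next
        k <- k + 1
        el[[k]] <- c(lin(u), lin(v))
        wl[[k]] <- (0.5 * (cu + cv) + length_penalty) *
          sqrt(sum((offs[o, ] * spacing)^2))
      }
    }
  g <- igraph::make_empty_graph(n = prod(dims), directed = FALSE)
  g <- igraph::add_edges(g, unlist(el))
  igraph::E(g)$weight <- unlist(wl)
  igraph::distances(g, v = lin(start), to = lin(end))[1, 1]
}

# exhaustive DFS enumeration of all simple paths (tiny grids only)
enumerate_shortest <- function(cost, dims, spacing, start, end,
                               length_penalty = 0) {
  lin <- function(v) 1 + v[1] + v[2] * dims[1] + v[3] * dims[1] * dims[2]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  best <- Inf
  visited <- rep(FALSE, prod(dims))
  dfs <- function(u, acc) {
    if (acc >= best) return()
    if (all(u == end)) { best <<- acc; return() }
    visited[lin(u)] <<- TRUE
    for (o in seq_len(nrow(offs))) {
      v <- u + offs[o, ]
      if (any(v < 0) || any(v >= dims)) next
      if (visited[lin(v)]) next
      cv <- cost[lin(v)]
      if (!is.finite(cv)) next
      w <- (0.5 * (cost[lin(u)] + cv) + length_penalty) *
        sqrt(sum((offs[o, ] * spacing)^2))
      dfs(v, acc + w)
    }
    visited[lin(u)] <<- FALSE
  }
  dfs(start, 0)
  best
}

## minimal DICOM writer (test fixture only): explicit VR little endian,
## uncompressed 16-bit single-frame slices
write_test_dicom_slice <- function(path, pixels, rows, cols,
                                   position = c(0, 0, 0),
                                   orientation = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),
                                   slope = 1, intercept = -1024,
                                   series_uid = "1.2.3.4", signed = TRUE) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  pad_even <- function(s, pad = " ") {
    if (nchar(s, type = "bytes") %% 2 == 1) paste0(s, pad) else s
  }
  el_str <- function(g, e, vr, s, pad = " ") {
    s <- pad_even(s, pad)
    u16(g); u16(e); writeChar(vr, con, eos = NULL)
    u16(nchar(s, type = "bytes"))
    writeChar(s, con, eos = NULL)
  }
  el_us <- function(g, e, val) {
    u16(g); u16(e); writeChar("US", con, eos = NULL); u16(2); u16(val)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group (group length computed for the single UI element)
  ts <- pad_even("1.2.840.10008.1.2.1", " ")
  meta_len <- 8 + nchar(ts, type = "bytes")
  u16(0x0002); u16(0x0000); writeChar("UL", con, eos = NULL); u16(4)
  u32(meta_len)
  u16(0x0002); u16(0x0010); writeChar("UI", con, eos = NULL)
  u16(nchar(ts, type = "bytes")); writeChar(ts, con, eos = NULL)
  # dataset (tag order)
  el_str(0x0008, 0x0060, "CS", "CT")
  el_str(0x0018, 0x0050, "DS", "1")
  el_str(0x0020, 0x000E, "UI", series_uid, " ")
  el_str(0x0020, 0x0032, "DS", paste(position, collapse = "\\"))
  el_str(0x0020, 0x0037, "DS", paste(orientation, collapse = "\\"))
  el_us(0x0028, 0x0010, rows)
  el_us(0x0028, 0x0011, cols)
  el_str(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\"))
  el_us(0x0028, 0x0100, 16)
  el_us(0x0028, 0x0103, if (signed) 1 else 0)
  el_str(0x0028, 0x1052, "DS", format(intercept))
  el_str(0x0028, 0x1053, "DS", format(slope))
  n <- rows * cols
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  u32(2 * n)
  writeBin(as.integer(pixels), con, size = 2, endian = "little")
  invisible(path)
}
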