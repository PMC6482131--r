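#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage, validated against documented
#' ranges; unknown keys are rejected.
#'
#' @param ... overrides as nested lists, e.g.
#'   `segmentation = list(iterations = 100)`.
#' @return configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    crop = NULL,                       # c(z_lo, z_hi) or NULL
    centerline = list(seed_point = NULL, start = NULL, end = NULL,
                      sample_radius = 5, k_sigma = 3, search_radius = 20),
    segmentation = list(sigma = NULL, rings_per_cm = 2,
                        vertices_per_ring = 16, levels = 2, iterations = 200,
                        step = 0.5, smooth_weight = 0.3, smooth_passes = 8,
                        search_range = 10, followup_search_range = 6,
                        window = 20),
    registration = list(enabled = TRUE, bins = 32, samples = 2048,
                        iterations = 200, levels = 3, initial_step = 2,
                        margin = 10),
    measurement = list(curve_step = 2))
  ov <- list(...)
  check_keys <- function(given, ref, path = "") {
    bad <- setdiff(names(given), names(ref))
    if (length(bad))
      stop("pipeline_config: unknown key(s): ",
           paste0(path, bad, collapse = ", "))
    for (nm in names(given))
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
          is.list(given[[nm]]))
        check_keys(given[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  check_keys(ov, defaults)
  cfg <- modifyList(defaults, ov)
  stopifnot(cfg$registration$bins >= 8, cfg$registration$levels >= 1,
            cfg$registration$samples >= 256,
            cfg$segmentation$iterations >= 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(NULL)
}

#' Run the full longitudinal measurement pipeline
#'
#' Baseline centerline + segmentation, follow-up alignment (rigid then
#' affine mutual-information registration), adaptive thresholding and
#' follow-up segmentation, landmark diameter measurement, diameter curves
#' and the per-ring dilatation field.  Every stage is logged; intermediate
#' artifacts are written to `out_dir` when given.  A stage failure halts the
#' pipeline with the stage name in the error (the semi-automatic fallback:
#' failed cases are surfaced for manual interaction).
#'
#' @param baseline path or `image_volume` of the baseline CTA.
#' @param followup path or `image_volume` of the follow-up CTA.
#' @param landmarks named list / data.frame of seven baseline annotations
#'   (world mm), or a JSON file path.
#' @param config `pipeline_config`.
#' @param out_dir optional output directory for intermediates and reports.
#' @return list(report, curves = list(baseline, followup), landmarks,
#'   centerline, baseline_mesh, followup_mesh, transform, provenance).
#' @export
run_pipeline <- function(baseline, followup, landmarks,
                         config = pipeline_config(), out_dir = NULL) {
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(out_dir, "pipeline.log")
  }
  set.seed(config$seed)
  stage <- function(name, expr) {
    stage_log(log, name, "start")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    stage_log(log, name, sprintf("done (%.1f s)",
                                 as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  inputs <- list(baseline = if (is.character(baseline)) baseline else
    "<in-memory>", followup = if (is.character(followup)) followup else
      "<in-memory>")
  checksums <- lapply(inputs, function(f)
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_)
  emit <- function(fname, writer) {          # incremental intermediates
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, fname)
    writer(path)
    stage_log(log, "write", path)
  }
  vb <- stage("read_baseline",
              if (is.character(baseline)) read_volume(baseline) else baseline)
  vf <- stage("read_followup",
              if (is.character(followup)) read_volume(followup) else followup)
  if (!is.null(config$crop))
    vb <- stage("crop", crop_z(vb, config$crop[1], config$crop[2]))
  if (is.character(landmarks)) {
    ann <- jsonlite::fromJSON(landmarks)
    landmarks <- lapply(ann, as.numeric)
  }
  cc <- config$centerline
  if (is.null(cc$seed_point))
    stop("pipeline halted at stage 'centerline': a lumen seed point is ",
         "required (config$centerline$seed_point)")
  cl <- stage("centerline",
              extract_centerline(vb, cc$seed_point, cc$start, cc$end,
                                 cc$sample_radius, cc$k_sigma,
                                 cc$search_radius))
  emit("centerline.json", function(p) write_centerline_json(cl, p))
  sc <- config$segmentation
  mesh_b <- stage("segment_baseline",
                  segment_baseline(vb, cl, sc[c("sigma", "rings_per_cm",
                                                "vertices_per_ring", "levels",
                                                "iterations", "step",
                                                "smooth_weight",
                                                "smooth_passes",
                                                "search_range")]))
  emit("baseline_mesh.ply", function(p) write_ply(mesh_b, p))
  rc <- config$registration
  if (isTRUE(rc$enabled)) {
    al <- stage("register",
                align_followup(vb, vf, mesh_b,
                               registration_config(rc$bins, rc$samples,
                                                   rc$iterations, rc$levels,
                                                   rc$initial_step,
                                                   seed = config$seed),
                               rc$margin))
    transform <- al$transform
    aligned <- al$aligned
    emit("transform.json", function(p) write_transform_json(transform, p))
  } else {
    transform <- affine_transform()
    aligned <- stage("resample",
                     resample_to_reference(vf, transform, vb, "linear",
                                           as.numeric(quantile(vf$voxels,
                                                               0.01))))
  }
  fu_cfg <- sc[c("sigma", "iterations", "step", "smooth_weight",
                 "smooth_passes", "window")]
  fu_cfg$search_range <- sc$followup_search_range
  mesh_f <- stage("segment_followup",
                  segment_followup(aligned, mesh_b, cl, fu_cfg))
  emit("followup_mesh.ply", function(p) write_ply(mesh_f, p))
  lms <- stage("landmarks", build_landmarks(landmarks, cl))
  report <- stage("measure", measure_pair(mesh_b, mesh_f, lms, cl))
  stj <- lms$s[lms$name == "STJ"]
  curves <- stage("curves", list(
    baseline = diameter_curve(mesh_b, cl, config$measurement$curve_step, stj),
    followup = diameter_curve(mesh_f, cl, config$measurement$curve_step,
                              stj)))
  mesh_dil <- stage("dilatation_field", dilatation_field(mesh_b, mesh_f))
  prov <- list(inputs = inputs, input_md5 = checksums,
               config = unclass(config),
               config_hash = config_hash(config),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               transform = list(linear = transform$linear,
                                translation = transform$translation,
                                center = transform$center))
  out <- list(report = report, curves = curves, landmarks = lms,
              centerline = cl, baseline_mesh = mesh_b,
              followup_mesh = mesh_f, dilatation_mesh = mesh_dil,
              transform = transform, provenance = prov)
  if (!is.null(out_dir)) {
    write_ply(mesh_dil, file.path(out_dir, "dilatation_mesh.ply"))
    write_transform_json(transform, file.path(out_dir, "transform.json"))
    write.csv(format(report, digits = 10),
              file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(report = report, curves = curves,
                              provenance = prov),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log(log, "write", paste("artifacts in", out_dir))
  }
  out
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  as.character(tools::md5sum(f))
}

#' Serialize a centerline to JSON
#' @param cl `centerline`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_centerline_json <- function(cl, path) {
  jsonlite::write_json(list(points = unname(as.matrix(cl$points)),
                            arc = cl$arc),
                       path, digits = NA)
  invisible(path)
}

#' Read a centerline from JSON
#' @param path JSON written by [write_centerline_json()].
#' @return `centerline`.
#' @export
read_centerline_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  make_centerline(as.matrix(j$points))
}

#' Serialize a transform to JSON (row-major linear part, mm, LPS)
#' @param transform `affine_transform`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(linear = as.numeric(t(transform$linear)),
                            translation = transform$translation,
                            center = transform$center),
                       path, digits = NA)
  invisible(path)
}

#' Read a transform from JSON
#' @param path JSON written by [write_transform_json()].
#' @return `affine_transform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  affine_transform(matrix(j$linear, 3, 3, byrow = TRUE), j$translation,
                   j$center)
}
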