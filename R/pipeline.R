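#' End-to-end planning pipeline
#'
#' Ties the stages into the operator workflow: scan the liver surface from a
#' tracked frame stream, segment the tumor on a chosen frozen frame from a
#' seed click, lift it to the 3D sphere model, fit the conical resection
#' shape with the chosen safety margin, and derive the resection line. Every
#' stage is also runnable standalone from the previous stage's serialized
#' outputs; the pipeline writes a run manifest (config snapshot, input
#' checksums, stage timings, output paths) so a run is reproducible from its
#' inputs alone.
#'
#' @name cli-pipeline
NULL

#' Pipeline configuration
#'
#' @param frames_dir directory of frame PNGs (sorted lexicographically; index
#'   order must match the pose log).
#' @param poses_csv pose log CSV (columns index, r00..r23).
#' @param calib_yaml probe calibration YAML.
#' @param model_json contact-model JSON archive.
#' @param seed_json seed-click JSON: `frame_index`, `center_px`, `diameter_mm`,
#'   optional `ring_margin_mm`, optional `refine_clicks` (list of [x, y]).
#' @param out_dir output directory.
#' @param margin_mm safety margin (default 10 mm).
#' @param half_angle_deg cone half-angle (default 45).
#' @param scan,segment lists of overrides for [scan_stream()] and
#'   [graph_cut_segment()].
#' @param r0_threshold_mm R0 threshold for downstream margin analysis
#'   (default 1 mm).
#' @param seed integer seed recorded in the manifest.
#' @export
pipeline_config <- function(frames_dir, poses_csv, calib_yaml, model_json,
                            seed_json, out_dir,
                            margin_mm = 10, half_angle_deg = 45,
                            scan = list(), segment = list(),
                            r0_threshold_mm = 1.0, seed = 1L) {
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  structure(list(frames_dir = frames_dir, poses_csv = poses_csv,
                 calib_yaml = calib_yaml, model_json = model_json,
                 seed_json = seed_json, out_dir = out_dir,
                 margin_mm = margin_mm, half_angle_deg = half_angle_deg,
                 scan = scan, segment = segment,
                 r0_threshold_mm = r0_threshold_mm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load tracked frames from a directory of PNGs plus a pose log
#'
#' @param frames_dir directory of PNG frames.
#' @param poses_csv pose log path.
#' @return list of `tracked_frame`.
#' @export
read_frames <- function(frames_dir, poses_csv) {
  files <- sort(list.files(frames_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no PNG frames in %s", frames_dir))
  poses <- read_pose_log(poses_csv)
  if (length(files) != length(poses)) {
    stop(sprintf("%d frames but %d poses", length(files), length(poses)))
  }
  lapply(seq_along(files), function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    tracked_frame(img * 255, poses[[i]], index = as.integer(names(poses)[i]))
  })
}

#' Write tracked frames as PNGs plus a pose log
#'
#' @param frames list of `tracked_frame`.
#' @param frames_dir,poses_csv output locations.
#' @export
write_frames <- function(frames, frames_dir, poses_csv) {
  dir.create(frames_dir, showWarnings = FALSE, recursive = TRUE)
  for (fr in frames) {
    png::writePNG(pmin(pmax(fr$image / 255, 0), 1),
                  file.path(frames_dir, sprintf("frame_%05d.png", fr$index)))
  }
  write_pose_log(lapply(frames, `[[`, "c_t_ms"), poses_csv,
                 indices = vapply(frames, `[[`, integer(1), "index"))
  invisible(frames_dir)
}

#' Run the full planning pipeline
#'
#' @param config a `pipeline_config`.
#' @return The run manifest (also written to `out_dir/manifest.json`),
#'   invisibly a list with the stage objects under `results`.
#' @export
run_planning_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(config$poses_csv, config$calib_yaml, config$model_json, config$seed_json)
  for (p in inputs) if (!file.exists(p)) stop(sprintf("input file missing: %s", p))
  if (!dir.exists(config$frames_dir)) stop(sprintf("frames directory missing: %s", config$frames_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  calib <- read_calibration(config$calib_yaml)
  model <- read_contact_model(config$model_json)
  frames <- tick("load_frames", read_frames(config$frames_dir, config$poses_csv))
  seedj <- jsonlite::read_json(config$seed_json, simplifyVector = TRUE)

  scan <- tick("scan", do.call(scan_stream,
                               c(list(frames, calib, model), config$scan)))
  mesh_path <- file.path(config$out_dir, "surface.ply")
  write_ply(scan$mesh, mesh_path)
  cloud_path <- file.path(config$out_dir, "cloud.ply")
  write_ply(scan$cloud, cloud_path)

  fi <- seedj$frame_index + 1L
  seg_frame <- frames[[fi]]
  seed <- seed_init(as.numeric(seedj$center_px), seedj$diameter_mm,
                    seedj$ring_margin_mm %||% 20)
  seg <- tick("segment", {
    labels <- init_labels(dim(seg_frame$image), seed, calib)
    res <- do.call(graph_cut_segment,
                   c(list(seg_frame$image, labels, calib), config$segment))
    for (cl in seedj$refine_clicks %||% list()) {
      res <- refine_click(seg_frame$image, res, as.numeric(cl))
    }
    res
  })
  mask_path <- file.path(config$out_dir, "tumor_mask.png")
  write_mask_png(seg$mask, mask_path)

  tumor <- tick("tumor_model", mask_to_tumor_model(seg, seg_frame, calib))
  tumor_path <- file.path(config$out_dir, "tumor.json")
  write_tumor_model(tumor, tumor_path)

  plan <- tick("plan", fit_resection_shape(tumor, scan$mesh, config$margin_mm,
                                           half_angle_deg = config$half_angle_deg))
  plan_path <- file.path(config$out_dir, "plan.json")
  write_plan(plan, plan_path)

  overlay <- tick("overlay", project_overlay(plan, tumor, seg_frame, calib))
  overlay_path <- file.path(config$out_dir, "overlay.json")
  jsonlite::write_json(
    list(contours = lapply(overlay$contours, function(m) unname(apply(m, 1, as.numeric, simplify = FALSE))),
         visible = as.list(overlay$visible)),
    overlay_path, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    software = paste0("sononav ", as.character(utils::packageVersion("sononav"))),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(inputs)),
    stage_timings_s = as.list(timings),
    outputs = list(surface = mesh_path, cloud = cloud_path, mask = mask_path,
                   tumor = tumor_path, plan = plan_path, overlay = overlay_path)
  )
  manifest_tmp <- file.path(config$out_dir, ".manifest.json.tmp")
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_tmp, auto_unbox = TRUE, digits = NA)
  file.rename(manifest_tmp, manifest_path)    # atomic finalisation

  invisible(c(manifest, list(results = list(scan = scan, segmentation = seg,
                                            tumor = tumor, plan = plan,
                                            overlay = overlay))))
}
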