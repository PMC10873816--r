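#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults mirror the
#' published processing settings: binning factor 8, one frame every 5
#' seconds of video (1/5 fps), and a 5-degree minimum movement change.
#' The configuration is serialized alongside the outputs for provenance.
#'
#' @param input Directory of per-timepoint slice-stack folders.
#' @param output Output directory for all stages.
#' @param bin_factor Voxel binning factor applied before rendering.
#' @param azimuth_step Turntable step in degrees (must divide 360).
#' @param frame_rate Video frame rate in fps; accepts `"1/5"` fraction syntax.
#' @param rot_range Registration coarse-search half-range, degrees.
#' @param min_change Minimum angular change for movement events, degrees.
#' @param angles_csv Optional CSV of per-organ angles to quantify
#'   (columns `day`, `orientation_deg` and/or `roll_deg`).
#' @param overwrite Remove a previous completed run instead of aborting?
#' @param seed Seed propagated to any stochastic component.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output, bin_factor = 8, azimuth_step = 10,
                            frame_rate = 0.2, rot_range = 25, min_change = 5,
                            angles_csv = NULL, overwrite = FALSE, seed = 1L) {
  frame_rate <- parse_rate(frame_rate)
  stopifnot(is.character(input), is.character(output))
  if (bin_factor < 1 || bin_factor != round(bin_factor)) {
    stop("bin_factor must be a positive integer")
  }
  if (azimuth_step <= 0 || 360 %% azimuth_step != 0) {
    stop("invalid azimuth step: ", azimuth_step, " does not divide 360")
  }
  if (min_change < 0) {
    stop("min_change must be non-negative")
  }
  structure(
    list(input = input, output = output, bin_factor = as.integer(bin_factor),
         azimuth_step = azimuth_step, frame_rate = frame_rate,
         rot_range = rot_range, min_change = min_change,
         angles_csv = angles_csv, overwrite = isTRUE(overwrite),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

manifest_path <- function(outdir) file.path(outdir, "manifest.json")

#' Has this output directory hosted a completed run?
#'
#' `TRUE` iff a completed-run manifest exists. Partial outputs without a
#' manifest are treated as an interrupted run, not a previous one.
#'
#' @param outdir Output directory.
#' @return Logical.
#' @export
detect_previous_run <- function(outdir) {
  file.exists(manifest_path(outdir))
}

#' Verify a run manifest against the files on disk
#'
#' Re-hashes every output file listed in the manifest and reports mismatches
#' (post-hoc tampering or corruption).
#'
#' @param outdir Output directory with a manifest.
#' @return Invisibly `TRUE`; stops with the offending files otherwise.
#' @export
verify_manifest <- function(outdir) {
  mf <- jsonlite::read_json(manifest_path(outdir), simplifyVector = TRUE)
  files <- file.path(outdir, mf$files$path)
  now <- unname(tools::md5sum(files))
  bad <- which(is.na(now) | now != mf$files$md5)
  if (length(bad) > 0) {
    stop("manifest verification failed for: ", paste(mf$files$path[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full time-lapse pipeline
#'
#' Executes the stages in order: harmonize (trim to a common grid, repair
#' geometry metadata), register (rigid alignment of every timepoint to the
#' first), bin, render (annotated turntable projections), video assembly,
#' and — when an angle CSV is configured — movement quantification. A
#' completed run leaves a manifest of every output file with its MD5 hash;
#' re-running on the same output directory aborts unless `overwrite` is set,
#' in which case all previously written data from the prior run (including
#' the generated time-lapse) is removed first. Stage failures abort with the
#' failing stage named; partial outputs are retained for inspection.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and key output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$output
  if (detect_previous_run(outdir)) {
    if (!config$overwrite) {
      stop("previous completed run detected in ", outdir,
           "; re-run with overwrite = TRUE to remove it and continue")
    }
    old <- jsonlite::read_json(manifest_path(outdir), simplifyVector = TRUE)
    unlink(file.path(outdir, old$files$path))
    unlink(manifest_path(outdir))
  }
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log <- file.path(outdir, "run.log")
  run_log(log, "run_pipeline: start (input ", config$input, ")")
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  seq0 <- stage("scan", scan_dataset(config$input, log = log))
  harmonized <- stage("harmonize", {
    s <- trim_to_common(seq0, log = log)
    ensure_geometry(s, log = log)
  })
  harm_dir <- file.path(outdir, "harmonized")
  for (s in harmonized$scans) {
    write_volume_stack(s, file.path(harm_dir, s$scan_label))
  }

  transforms <- stage("register", register_sequence(harmonized,
                                                    rot_range = config$rot_range,
                                                    log = log))
  aligned <- stage("register", scan_sequence(
    Map(apply_transform, harmonized$scans, transforms)
  ))
  jsonlite::write_json(
    lapply(transforms, function(t) list(
      rotation_deg = t$rotation, translation_vox = t$translation, score = t$score
    )),
    file.path(outdir, "transforms.json"),
    auto_unbox = FALSE, digits = NA, pretty = TRUE
  )

  binned <- stage("bin", scan_sequence(
    lapply(aligned$scans, bin_volume, factor = config$bin_factor, log = log)
  ))

  frames_dir <- file.path(outdir, "frames")
  stage("render", render_turntable(binned, azimuth_step = config$azimuth_step,
                                   out_dir = frames_dir, log = log))
  video <- stage("video", assemble_video(frames_dir,
                                         file.path(outdir, "3D_lapse.mp4"),
                                         rate = config$frame_rate, log = log))

  events_path <- NULL
  if (!is.null(config$angles_csv)) {
    events_path <- file.path(outdir, "events.csv")
    stage("quantify", {
      series <- read_angle_series(config$angles_csv)
      events <- detect_events(series, min_change = config$min_change)
      movement_log(events, events_path)
      jsonlite::write_json(
        list(n_events = nrow(events),
             kinds = as.list(table(events$kind))),
        file.path(outdir, "events_summary.json"), auto_unbox = TRUE
      )
    })
  }

  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  files <- list.files(outdir, recursive = TRUE)
  files <- setdiff(files, c("manifest.json", "run.log"))
  mf <- list(
    completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    files = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(mf, manifest_path(outdir), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  run_log(log, "run_pipeline: completed; ", length(files), " output files")
  invisible(list(manifest = mf, video = as.character(video),
                 frames_dir = frames_dir, events = events_path,
                 transforms = transforms))
}
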