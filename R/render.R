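#' Maximum-intensity turntable projection of a volume
#'
#' Rotates the volume by `azimuth` degrees about the vertical (z) axis (and
#' optionally tilts it by `elevation` about x), then projects it in parallel
#' along the viewing (y) direction: each output pixel is the maximum voxel
#' intensity along its ray. The image height spans z bottom-to-top, so the
#' base of the plant (container bottom) sits at the bottom of the image.
#' Maximum-intensity projection is deterministic and parameter-free, which
#' suits thin bright plant tissue against a dark background.
#'
#' @param scan A [volume_scan()].
#' @param azimuth Viewing azimuth in degrees (reduced mod 360).
#' @param elevation Viewing elevation in degrees (default 0).
#' @return An object of class `render_frame`: a list with `pixels` (matrix,
#'   rows top-to-bottom), `azimuth`, `timepoint_index`, `scan_label`.
#' @details The projection splats voxels forward: each voxel center is
#'   rotated and assigned to its nearest output pixel, and every pixel
#'   keeps the maximum intensity it receives. Unlike resampling the volume
#'   first, this preserves maxima exactly (a single bright voxel stays at
#'   full intensity from every viewing angle) and is strictly monotone in
#'   the voxel intensities.
#' @export
project_mip <- function(scan, azimuth, elevation = 0) {
  stopifnot(inherits(scan, "volume_scan"))
  azimuth <- azimuth %% 360
  vol <- scan$intensities
  d <- dim(vol)
  a <- azimuth * pi / 180
  e <- elevation * pi / 180
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  px <- rep.int(0:(d[1] - 1), d[2] * d[3]) - cx
  py <- rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]) - cy
  pz <- rep(0:(d[3] - 1), each = d[1] * d[2]) - cz
  # rotate by azimuth about z, then tilt by elevation about x; view along y
  rx <- cos(a) * px - sin(a) * py
  ry <- sin(a) * px + cos(a) * py
  rz <- cos(e) * pz - sin(e) * ry
  col <- round(rx + cx)
  row <- round(rz + cz)
  keep <- col >= 0 & col < d[1] & row >= 0 & row < d[3]
  img <- matrix(0, d[1], d[3])             # [x, z]
  idx <- 1 + col[keep] + d[1] * row[keep]
  v <- vol[keep]
  o <- order(v)                            # last write wins = per-pixel max
  img[idx[o]] <- v[o]
  pixels <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]  # top slice first
  structure(
    list(pixels = pixels, azimuth = azimuth, timepoint_index = NA_integer_,
         scan_label = scan$scan_label),
    class = "render_frame"
  )
}

#' @export
print.render_frame <- function(x, ...) {
  cat(sprintf("<render_frame> %dx%d px, azimuth %g deg, label '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$azimuth, x$scan_label))
  invisible(x)
}

#' Burn a text label into a frame
#'
#' Draws `label` in bright pixels at the bottom-left corner (the time-lapse
#' carries its scan numbers so the exact week of each movement can be read
#' off the video). Pixels outside the label region are untouched.
#'
#' @param frame A `render_frame`.
#' @param label Text to draw; defaults to the frame's `scan_label`.
#' @param value Pixel value for the text (default: frame maximum).
#' @param margin Pixels between the label and the image border.
#' @return The annotated frame.
#' @export
annotate_frame <- function(frame, label = frame$scan_label, value = NULL, margin = 2L) {
  stopifnot(inherits(frame, "render_frame"))
  if (!nzchar(label)) {
    return(frame)
  }
  if (is.null(value)) value <- max(frame$pixels)
  bm <- render_text_bitmap(label)
  h <- nrow(frame$pixels); w <- ncol(frame$pixels)
  rows <- (h - margin - nrow(bm) + 1):(h - margin)
  cols <- (margin + 1):(margin + ncol(bm))
  keep_r <- rows >= 1 & rows <= h
  keep_c <- cols >= 1 & cols <= w
  sub <- frame$pixels[rows[keep_r], cols[keep_c], drop = FALSE]
  bm <- bm[keep_r, keep_c, drop = FALSE]
  sub[bm == 1] <- value
  frame$pixels[rows[keep_r], cols[keep_c]] <- sub
  frame
}

#' Render a rotating time-lapse frame sequence
#'
#' For each timepoint in order, renders `360 / azimuth_step` maximum-intensity
#' projections at azimuths `0, step, 2*step, ...` (the volume is rotated a
#' step further after each captured frame). Frames are numbered globally from
#' 0 and, when `out_dir` is given, written as `capture_00000.png` upward.
#' Each frame is annotated with its scan label unless `annotate = FALSE`.
#'
#' @param seq A [scan_sequence()].
#' @param azimuth_step Degrees between consecutive frames; must divide 360.
#' @param out_dir Optional directory to write PNG frames into.
#' @param annotate Burn scan labels into the frames?
#' @param elevation Viewing elevation in degrees.
#' @param scale Intensity mapped to white in the PNGs; default is the global
#'   maximum over the sequence, so brightness is comparable across timepoints.
#' @param log Optional run-log path.
#' @return Invisibly, a list of `render_frame` objects in global frame order,
#'   with a `tibble` inventory in attribute `"inventory"`.
#' @export
render_turntable <- function(seq, azimuth_step = 10, out_dir = NULL, annotate = TRUE,
                             elevation = 0, scale = NULL, log = NULL) {
  stopifnot(inherits(seq, "scan_sequence"))
  if (azimuth_step <= 0 || 360 %% azimuth_step != 0) {
    stop("invalid azimuth step: ", azimuth_step, " does not divide 360")
  }
  azimuths <- seq(0, 360 - azimuth_step, by = azimuth_step)
  if (is.null(scale)) {
    scale <- max(vapply(seq$scans, function(s) max(s$intensities), numeric(1)))
  }
  if (scale <= 0) scale <- 1
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  frames <- vector("list", length(seq$scans) * length(azimuths))
  inv <- vector("list", length(frames))
  n <- 0L
  for (i in seq_along(seq$scans)) {
    for (az in azimuths) {
      frame <- project_mip(seq$scans[[i]], az, elevation = elevation)
      frame$timepoint_index <- i - 1L
      if (annotate) {
        frame <- annotate_frame(frame, value = scale)
      }
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, sprintf("capture_%05d.png", n))
        png::writePNG(pmin(pmax(frame$pixels / scale, 0), 1), path)
      }
      n <- n + 1L
      frames[[n]] <- frame
      label <- frame$scan_label
      inv[[n]] <- tibble::tibble(
        frame = n - 1L, timepoint = i - 1L, azimuth = az,
        scan_label = label, path = path
      )
    }
  }
  run_log(log, "render_turntable: ", n, " frames (", length(seq$scans),
          " timepoints x ", length(azimuths), " azimuths, step ", azimuth_step, " deg)")
  attr(frames, "inventory") <- do.call(rbind, inv)
  invisible(frames)
}

#' Assemble numbered frames into a time-lapse video
#'
#' Collects `capture_N` frame images from `frames_dir` (zero-padded or not),
#' checks that the numbering is contiguous from `start_index`, and encodes
#' them at `rate` frames per second — by default 1 frame per 5 seconds, the
#' slow cadence that turns weekly scans into a watchable time-lapse. When an
#' `ffmpeg` binary is on the PATH the frames are encoded to MP4 (H.264,
#' yuv420p); otherwise a built-in RIFF writer produces an uncompressed RGB24
#' AVI container with the same frame timing, and the output extension is
#' switched to `.avi`. Frames remain the authoritative archival output.
#'
#' @param frames_dir Directory of `capture_*.png` frames.
#' @param out_file Output video path (`.mp4` with ffmpeg, else `.avi`).
#' @param rate Frames per second; a number or a fraction string like `"1/5"`.
#' @param start_index First expected frame number (default 0).
#' @param encoder `"auto"` (default), `"ffmpeg"`, or `"avi"`.
#' @param log Optional run-log path.
#' @return Invisibly, the written video path, with attributes `duration_s`
#'   and `n_frames`.
#' @export
assemble_video <- function(frames_dir, out_file, rate = 0.2, start_index = 0L,
                           encoder = c("auto", "ffmpeg", "avi"), log = NULL) {
  encoder <- match.arg(encoder)
  rate <- parse_rate(rate)
  files <- list.files(frames_dir, pattern = "^capture_[0-9]+\\.png$", full.names = TRUE)
  if (length(files) == 0) {
    stop("empty frame sequence: no capture_*.png in ", frames_dir)
  }
  idx <- as.integer(sub("^capture_0*([0-9]+)\\.png$", "\\1", basename(files)))
  idx[is.na(idx)] <- as.integer(sub("^capture_([0-9]+)\\.png$", "\\1", basename(files)[is.na(idx)]))
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  expected <- seq(from = start_index, length.out = max(idx) - start_index + 1L)
  missing <- setdiff(expected, idx)
  if (length(missing) > 0) {
    stop("gap in frame numbering: capture_", min(missing), " is missing")
  }
  have_ffmpeg <- nzchar(Sys.which("ffmpeg"))
  use_ffmpeg <- (encoder == "ffmpeg") || (encoder == "auto" && have_ffmpeg)
  if (encoder == "ffmpeg" && !have_ffmpeg) {
    stop("ffmpeg not found on PATH")
  }
  if (use_ffmpeg) {
    pad <- nchar(sub("^capture_([0-9]+)\\.png$", "\\1", basename(files[[1]])))
    pattern <- file.path(frames_dir, sprintf("capture_%%0%dd.png", pad))
    status <- system2("ffmpeg", c(
      "-y", "-start_number", start_index, "-framerate", format(rate, digits = 10),
      "-i", shQuote(pattern), "-c:v", "libx264", "-pix_fmt", "yuv420p",
      "-r", format(max(rate, 1), digits = 10), shQuote(out_file)
    ), stdout = FALSE, stderr = FALSE)
    if (status != 0) {
      stop("ffmpeg failed with status ", status)
    }
  } else {
    if (!grepl("\\.avi$", out_file, ignore.case = TRUE)) {
      out_file <- paste0(sub("\\.[A-Za-z0-9]+$", "", out_file), ".avi")
      run_log(log, "assemble_video: no ffmpeg on PATH; writing uncompressed AVI ", out_file)
    }
    write_avi(files, out_file, fps = rate)
  }
  duration <- length(files) / rate
  run_log(log, "assemble_video: ", length(files), " frames at ", rate,
          " fps -> ", out_file, " (", duration, " s)")
  structure(invisible(out_file), duration_s = duration, n_frames = length(files))
}

parse_rate <- function(rate) {
  if (is.character(rate)) {
    parts <- as.numeric(strsplit(rate, "/", fixed = TRUE)[[1]])
    rate <- if (length(parts) == 2) parts[1] / parts[2] else parts[1]
  }
  if (!is.finite(rate) || rate <= 0) {
    stop("frame rate must be positive")
  }
  rate
}
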