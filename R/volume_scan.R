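#' A single reconstructed micro-CT volume
#'
#' `volume_scan` is the in-memory unit of the pipeline: one reconstructed
#' 3D grid of non-negative grayscale intensities for one scan session.
#' Voxels are indexed `(x, y, z)` with `z` the slice index counted
#' bottom-to-top (slice files sort in ascending z). Coordinates are 0-based
#' in all user-facing transform parameters.
#'
#' @param intensities Numeric 3D array, finite and `>= 0`.
#' @param voxel_size Physical edge length per axis in mm; scalar or length-3,
#'   strictly positive.
#' @param day Acquisition time in integer days (days after germination for
#'   roots, days after pollination for fruits).
#' @param scan_label Identifier shown in rendered frames.
#' @param source_path Provenance string (folder the stack was read from).
#' @param bit_depth Bits per sample the stack was (or will be) stored at:
#'   8 or 16 for integer data, 32 for floating point.
#' @return An object of class `volume_scan`.
#' @export
#' @examples
#' v <- volume_scan(array(0, c(4, 4, 2)), voxel_size = 0.02, day = 7)
#' dim(v$intensities)
volume_scan <- function(intensities, voxel_size = 1, day = NA_integer_,
                        scan_label = "", source_path = "", bit_depth = 32L) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3) {
    stop("intensities must be a 3D array")
  }
  if (any(dim(intensities) < 1)) {
    stop("all three grid extents must be >= 1")
  }
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be strictly positive on all axes")
  }
  structure(
    list(
      intensities = intensities,
      voxel_size = voxel_size,
      day = as.integer(day),
      scan_label = as.character(scan_label),
      source_path = as.character(source_path),
      bit_depth = as.integer(bit_depth),
      geometry = NULL
    ),
    class = "volume_scan"
  )
}

#' @export
print.volume_scan <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<volume_scan> %dx%dx%d voxels, voxel size %s mm, day %s, label '%s'\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = "x"),
    ifelse(is.na(x$day), "?", x$day), x$scan_label
  ))
  invisible(x)
}

#' @export
dim.volume_scan <- function(x) dim(x$intensities)

#' Geometry metadata for one scan
#'
#' Mirrors the per-timepoint `geometry.toml` file: physical voxel size and the
#' offset of the tomographic rotation axis from the grid center. Defaults are
#' explicit (1 mm voxels, zero offset) and used to repair missing files.
#'
#' @param voxel_size mm per axis (scalar or length 3), strictly positive.
#' @param rotation_axis_offset Offset of the rotation axis in voxels.
#' @param notes Free-text provenance notes.
#' @return An object of class `geometry_meta`.
#' @export
geometry_meta <- function(voxel_size = 1, rotation_axis_offset = 0, notes = "") {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be strictly positive")
  }
  structure(
    list(
      voxel_size = voxel_size,
      rotation_axis_offset = as.numeric(rotation_axis_offset),
      notes = as.character(notes)
    ),
    class = "geometry_meta"
  )
}

#' An ordered sequence of scans
#'
#' Holds the scans of one specimen in ascending acquisition-day order.
#' `uniform_grid` is `TRUE` once every scan shares identical grid extents
#' (the state [trim_to_common()] establishes).
#'
#' @param scans List of [volume_scan()] objects with strictly increasing days.
#' @return An object of class `scan_sequence`.
#' @export
scan_sequence <- function(scans) {
  stopifnot(is.list(scans), length(scans) >= 1)
  if (!all(vapply(scans, inherits, logical(1), "volume_scan"))) {
    stop("all elements must be volume_scan objects")
  }
  days <- vapply(scans, function(s) as.numeric(s$day), numeric(1))
  if (!anyNA(days) && length(days) > 1 && any(diff(days) <= 0)) {
    stop("scan days must be strictly increasing")
  }
  dims <- vapply(scans, function(s) dim(s$intensities), integer(3))
  uniform <- all(dims == dims[, 1])
  structure(list(scans = scans, uniform_grid = uniform), class = "scan_sequence")
}

#' @export
length.scan_sequence <- function(x) length(x$scans)

#' @export
print.scan_sequence <- function(x, ...) {
  days <- vapply(x$scans, function(s) as.integer(s$day), integer(1))
  cat(sprintf(
    "<scan_sequence> %d timepoints (days %s), uniform grid: %s\n",
    length(x$scans), paste(days, collapse = ", "), x$uniform_grid
  ))
  invisible(x)
}

#' Summarize a scan sequence as a tibble
#'
#' One row per timepoint with grid extents, voxel size and label.
#'
#' @param x A [scan_sequence()].
#' @param ... Unused.
#' @return A tibble with one row per scan.
#' @method as_tibble scan_sequence
#' @export
as_tibble.scan_sequence <- function(x, ...) {
  tibble::tibble(
    timepoint = seq_along(x$scans) - 1L,
    day = vapply(x$scans, function(s) as.integer(s$day), integer(1)),
    scan_label = vapply(x$scans, function(s) s$scan_label, character(1)),
    nx = vapply(x$scans, function(s) dim(s$intensities)[1], integer(1)),
    ny = vapply(x$scans, function(s) dim(s$intensities)[2], integer(1)),
    nz = vapply(x$scans, function(s) dim(s$intensities)[3], integer(1)),
    voxel_size_mm = vapply(x$scans, function(s) s$voxel_size[1], numeric(1)),
    source_path = vapply(x$scans, function(s) s$source_path, character(1))
  )
}
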