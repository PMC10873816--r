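#' Common grid extents of a scan sequence
#'
#' The per-axis minimum extent over all scans: the largest grid every scan
#' can be cropped onto. Equals the shared extents when the sequence is
#' already uniform.
#'
#' @param seq A [scan_sequence()].
#' @return Integer vector of length 3 (nx, ny, nz).
#' @export
common_shape <- function(seq) {
  stopifnot(inherits(seq, "scan_sequence"), length(seq$scans) >= 1)
  dims <- vapply(seq$scans, function(s) dim(s$intensities), integer(3))
  apply(dims, 1, min)
}

#' Trim all scans onto a common grid
#'
#' Oversized scans arise when a specimen outgrows the detector's field of view
#' and sessions are reconstructed at different heights. This stage crops every
#' scan to the sequence's [common_shape()]: depth mismatches are resolved by
#' removing the highest-index (top) slices only — the container base is the
#' stable anatomical anchor and plants grow upward — while in-slice (x/y)
#' mismatches, which the acquisition protocol does not normally produce, are
#' resolved by a symmetric center-crop and logged as a deviation. Retained
#' voxels are never altered, and harmonizing an already-uniform sequence is
#' the identity.
#'
#' @param seq A [scan_sequence()].
#' @param log Optional run-log path.
#' @return A [scan_sequence()] with `uniform_grid = TRUE`.
#' @export
trim_to_common <- function(seq, log = NULL) {
  stopifnot(inherits(seq, "scan_sequence"))
  target <- common_shape(seq)
  if (any(target == 0)) {
    stop("degenerate harmonization: target extent 0 on axis ",
         paste(which(target == 0), collapse = ", "))
  }
  scans <- lapply(seq$scans, function(s) {
    d <- dim(s$intensities)
    if (all(d == target)) {
      return(s)
    }
    xs <- center_crop_range(d[1], target[1])
    ys <- center_crop_range(d[2], target[2])
    zs <- seq_len(target[3])  # top slices (highest z) dropped
    if (d[1] != target[1] || d[2] != target[2]) {
      run_log(log, "trim_to_common: in-slice center-crop ", d[1], "x", d[2],
              " -> ", target[1], "x", target[2], " for '", s$scan_label,
              "' (deviation: x/y extents differed)")
    }
    if (d[3] != target[3]) {
      run_log(log, "trim_to_common: removed ", d[3] - target[3],
              " top slice(s) from '", s$scan_label, "'")
    }
    s$intensities <- s$intensities[xs, ys, zs, drop = FALSE]
    s
  })
  out <- scan_sequence(scans)
  stopifnot(out$uniform_grid)
  out
}

center_crop_range <- function(n, target) {
  offset <- (n - target) %/% 2
  seq_len(target) + offset
}

#' Guarantee geometry metadata on every scan
#'
#' Attaches a [geometry_meta()] to each scan, repairing missing
#' `geometry.toml` files via [load_geometry()] defaults. Conflicting voxel
#' sizes across timepoints trigger a logged warning and the first scan's
#' value is adopted throughout (one specimen is scanned on one instrument
#' configuration; disagreement indicates a metadata error, not a physical
#' change).
#'
#' @param seq A [scan_sequence()].
#' @param default Defaults used for repair.
#' @param log Optional run-log path.
#' @return The sequence with `geometry` set on every scan.
#' @export
ensure_geometry <- function(seq, default = geometry_meta(), log = NULL) {
  stopifnot(inherits(seq, "scan_sequence"))
  scans <- lapply(seq$scans, function(s) {
    if (is.null(s$geometry)) {
      s$geometry <- if (nzchar(s$source_path) && dir.exists(s$source_path)) {
        load_geometry(s$source_path, default = default, log = log)
      } else {
        default
      }
      s$voxel_size <- s$geometry$voxel_size
    }
    s
  })
  ref <- scans[[1]]$geometry$voxel_size
  for (i in seq_along(scans)) {
    if (any(abs(scans[[i]]$geometry$voxel_size - ref) > 1e-12)) {
      warning("conflicting voxel sizes across timepoints (",
              paste(scans[[i]]$geometry$voxel_size, collapse = "x"), " vs ",
              paste(ref, collapse = "x"), " mm); adopting the first scan's value")
      run_log(log, "ensure_geometry: voxel size conflict at timepoint ", i,
              "; adopting first scan's ", paste(ref, collapse = "x"), " mm")
      scans[[i]]$geometry$voxel_size <- ref
      scans[[i]]$voxel_size <- ref
    }
  }
  scan_sequence(scans)
}
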