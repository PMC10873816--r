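#' Discover and order a scan dataset
#'
#' Scans `root_path` for per-timepoint subfolders of slice images and returns
#' a [scan_sequence()] ordered by acquisition day. The day is parsed as the
#' first integer in the folder name (scan sessions are commonly named by week
#' or day); folders without a number fall back to their lexicographic
#' position, which is flagged in the log. Volumes are read eagerly unless
#' `lazy = TRUE`, in which case each scan carries only its metadata and
#' `source_path` (read later with [read_volume_stack()]).
#'
#' @param root_path Directory containing one subfolder per timepoint.
#' @param lazy If `TRUE`, do not read voxel data; return placeholder scans.
#' @param log Optional run-log path (see [run_log()]).
#' @return A [scan_sequence()]; when `lazy = TRUE`, a tibble inventory with
#'   columns `folder`, `day`, `day_parsed` instead.
#' @export
scan_dataset <- function(root_path, lazy = FALSE, log = NULL) {
  if (!dir.exists(root_path)) {
    stop("dataset root does not exist: ", root_path)
  }
  subs <- list.dirs(root_path, full.names = TRUE, recursive = FALSE)
  if (length(subs) == 0) {
    stop("no timepoints found in ", root_path)
  }
  subs <- sort(subs)
  days <- parse_day_from_name(basename(subs))
  parsed <- !is.na(days)
  if (any(!parsed)) {
    days[!parsed] <- seq_along(subs)[!parsed]
    run_log(log, "scan_dataset: no day tag in folder(s) ",
            paste(basename(subs)[!parsed], collapse = ", "),
            "; using sequence position")
  }
  ord <- order(days, basename(subs))
  run_log(log, "scan_dataset: ", length(subs), " timepoints ordered by ",
          if (all(parsed)) "day parsed from folder name" else "mixed day/lexicographic rule",
          ": ", paste(basename(subs)[ord], collapse = ", "))
  inv <- tibble::tibble(
    folder = subs[ord],
    day = as.integer(days[ord]),
    day_parsed = parsed[ord]
  )
  if (lazy) {
    return(inv)
  }
  scans <- lapply(seq_len(nrow(inv)), function(i) {
    s <- read_volume_stack(inv$folder[[i]])
    s$day <- inv$day[[i]]
    s
  })
  scan_sequence(scans)
}

parse_day_from_name <- function(names) {
  m <- regmatches(names, regexpr("[0-9]+", names))
  out <- rep(NA_integer_, length(names))
  has <- grepl("[0-9]+", names)
  out[has] <- as.integer(m)
  out
}

#' Read a slice stack as a volume
#'
#' Reads every grayscale image in `folder` (TIFF or PNG) and stacks them in
#' ascending filename order as slices `z = 0 ... depth-1`, bottom-to-top.
#' Integer stacks are read at their stored bit depth (values `0 ... 2^bits-1`);
#' 32-bit float TIFFs are read as-is.
#'
#' @param folder Directory of slice images sharing one 2D shape.
#' @param voxel_size Fallback voxel size when no geometry file is present.
#' @return A [volume_scan()]; slice images are `[x, y]` in image order.
#' @export
read_volume_stack <- function(folder, voxel_size = 1) {
  if (!dir.exists(folder)) {
    stop("stack folder does not exist: ", folder)
  }
  files <- sort(list.files(folder, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("empty stack: no slice images in ", folder)
  }
  slices <- lapply(files, read_slice)
  shapes <- vapply(slices, dim, integer(2))
  if (any(shapes != shapes[, 1])) {
    stop("inconsistent slice shape in ", folder, ": ",
         paste(apply(unique(t(shapes)), 1, paste, collapse = "x"), collapse = " vs "))
  }
  bits <- max(vapply(slices, function(s) attr(s, "ct_bits"), numeric(1)))
  # slice matrices are [row, col] = [image y, image x]; volume axes are (x, y, z)
  vol <- array(0, c(shapes[2, 1], shapes[1, 1], length(slices)))
  for (k in seq_along(slices)) {
    vol[, , k] <- t(slices[[k]])
  }
  geom_path <- file.path(folder, "geometry.toml")
  vs <- voxel_size
  if (file.exists(geom_path)) {
    vs <- geometry_from_list(read_toml(geom_path))$voxel_size
  }
  scan <- volume_scan(vol, voxel_size = vs, scan_label = basename(folder),
                      source_path = folder, bit_depth = as.integer(bits))
  if (file.exists(geom_path)) {
    scan$geometry <- geometry_from_list(read_toml(geom_path))
  }
  scan
}

read_slice <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img <- round(img * 255)
    attr(img, "ct_bits") <- 8
    return(img)
  }
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- info$bits.per.sample[[1]]
  if (bits >= 32) {
    img <- tiff::readTIFF(path)  # float data: values as stored
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)  # integer sample values
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img <- img * 1.0
  attr(img, "ct_bits") <- bits
  img
}

#' Write a volume as a slice stack
#'
#' Inverse of [read_volume_stack()]: one image per z slice under zero-padded
#' numeric names (`slice_000.tif` upward), bottom slice first. Integer data
#' (`bit_depth` 8 or 16) round-trips bit-exactly; other data is written as
#' 32-bit float TIFF and round-trips at single precision (relative error
#' below 1e-6).
#'
#' @param scan A [volume_scan()].
#' @param folder Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_volume_stack <- function(scan, folder) {
  stopifnot(inherits(scan, "volume_scan"))
  ok <- dir.exists(folder) || dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(folder)) {
    stop("cannot create stack folder: ", folder)
  }
  d <- dim(scan$intensities)
  width <- max(3L, nchar(as.character(d[3] - 1)))
  paths <- file.path(folder, sprintf(paste0("slice_%0", width, "d.tif"), seq_len(d[3]) - 1L))
  bits <- scan$bit_depth
  for (k in seq_len(d[3])) {
    img <- t(scan$intensities[, , k])  # back to [row=y, col=x]
    if (bits %in% c(8L, 16L)) {
      maxval <- 2^bits - 1
      res <- tiff::writeTIFF(pmin(img, maxval) / maxval, paths[[k]], bits.per.sample = bits)
    } else {
      res <- tiff::writeTIFF(img, paths[[k]], bits.per.sample = 32)
    }
    if (!identical(res, 1L)) {
      stop("failed to write slice image: ", paths[[k]])
    }
  }
  if (!is.null(scan$geometry)) {
    write_geometry(scan$geometry, folder)
  }
  invisible(paths)
}

#' Load (or repair) geometry metadata for a timepoint folder
#'
#' Returns the contents of `geometry.toml` in `folder`. When the file is
#' missing, documented defaults (1 mm voxels, zero rotation-axis offset) are
#' returned and a default `geometry.toml` is written into the folder, so that
#' downstream stages always find one; the repair is logged.
#'
#' @param folder Timepoint folder.
#' @param default Defaults used for repair, a [geometry_meta()].
#' @param log Optional run-log path.
#' @return A [geometry_meta()].
#' @export
load_geometry <- function(folder, default = geometry_meta(), log = NULL) {
  path <- file.path(folder, "geometry.toml")
  if (!file.exists(path)) {
    if (dir.exists(folder)) {
      write_geometry(default, folder)
      run_log(log, "load_geometry: ", path, " missing; defaults written (voxel_size ",
              paste(default$voxel_size, collapse = "x"), " mm)")
    }
    return(default)
  }
  geometry_from_list(read_toml(path))
}

geometry_from_list <- function(x) {
  geometry_meta(
    voxel_size = if (!is.null(x$voxel_size)) x$voxel_size else 1,
    rotation_axis_offset = if (!is.null(x$rotation_axis_offset)) x$rotation_axis_offset else 0,
    notes = if (!is.null(x$notes)) x$notes else ""
  )
}

#' Write geometry metadata for a timepoint folder
#'
#' @param geometry A [geometry_meta()].
#' @param folder Timepoint folder.
#' @return Invisibly, the file path.
#' @export
write_geometry <- function(geometry, folder) {
  stopifnot(inherits(geometry, "geometry_meta"))
  write_toml(
    list(
      voxel_size = geometry$voxel_size,
      rotation_axis_offset = geometry$rotation_axis_offset,
      notes = geometry$notes
    ),
    file.path(folder, "geometry.toml")
  )
  invisible(file.path(folder, "geometry.toml"))
}
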