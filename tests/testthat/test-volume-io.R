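test_that("slice stacks round-trip bit-exactly at 8 and 16 bits", {
  root <- withr::local_tempdir()
  for (bits in c(8L, 16L)) {
    scan <- make_int_volume(c(6, 5, 3), bits = bits, seed = bits)
    dir <- write_stack_dir(scan, root, paste0("stack", bits))
    files <- list.files(dir, pattern = "\\.tif$")
    expect_length(files, 3)
    expect_equal(files, sprintf("slice_%03d.tif", 0:2))
    back <- read_volume_stack(dir)
    expect_identical(back$intensities, scan$intensities)
    expect_identical(dim(back$intensities), dim(scan$intensities))
    expect_equal(back$bit_depth, bits)
  }
})

test_that("float stacks round-trip at single precision", {
  root <- withr::local_tempdir()
  vals <- withr::with_seed(9, runif(4 * 4 * 2))
  scan <- volume_scan(array(vals, c(4, 4, 2)), bit_depth = 32L)
  dir <- write_stack_dir(scan, root, "float_stack")
  back <- read_volume_stack(dir)
  # values survive to single precision (the on-disk sample format)
  expect_equal(back$intensities, scan$intensities, tolerance = 1e-6)
  expect_equal(back$bit_depth, 32L)
  expect_identical(dim(back$intensities), dim(scan$intensities))
})

test_that("stacks of mixed slice shapes and empty folders are rejected", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "bad"))
  tiff::writeTIFF(matrix(0, 16, 16), file.path(root, "bad", "slice_000.tif"))
  tiff::writeTIFF(matrix(0, 16, 20), file.path(root, "bad", "slice_001.tif"))
  expect_error(read_volume_stack(file.path(root, "bad")), "inconsistent slice shape")
  dir.create(file.path(root, "empty"))
  expect_error(read_volume_stack(file.path(root, "empty")), "empty stack")
})

test_that("scan_dataset orders timepoints by day parsed from folder names", {
  root <- withr::local_tempdir()
  for (nm in c("week07", "week10", "week08")) {
    write_stack_dir(make_int_volume(c(4, 4, 2), seed = nchar(nm)), root, nm)
  }
  inv <- scan_dataset(root, lazy = TRUE)
  expect_equal(inv$day, c(7, 8, 10))
  expect_equal(basename(inv$folder), c("week07", "week08", "week10"))
  seq <- scan_dataset(root)
  expect_s3_class(seq, "scan_sequence")
  expect_equal(vapply(seq$scans, function(s) s$day, integer(1)), c(7L, 8L, 10L))
})

test_that("scan_dataset falls back to lexicographic order and errors on empty roots", {
  root <- withr::local_tempdir()
  expect_error(scan_dataset(root), "no timepoints found")
  for (nm in c("scanB", "scanA", "scanC")) {
    write_stack_dir(make_int_volume(c(4, 4, 2)), root, nm)
  }
  log <- file.path(root, "run.log")
  inv <- scan_dataset(root, lazy = TRUE, log = log)
  expect_equal(basename(inv$folder), c("scanA", "scanB", "scanC"))
  expect_false(any(inv$day_parsed))
  expect_match(paste(readLines(log), collapse = " "), "sequence position")
})

test_that("scan_dataset ordering is a permutation with non-decreasing days", {
  root <- withr::local_tempdir()
  names <- c("d012", "d003", "d021", "d008", "plainx")
  for (nm in names) write_stack_dir(make_int_volume(c(4, 4, 2)), root, nm)
  inv <- scan_dataset(root, lazy = TRUE)
  expect_setequal(basename(inv$folder), names)
  expect_true(all(diff(inv$day) >= 0))
})

test_that("load_geometry repairs missing files with logged defaults", {
  root <- withr::local_tempdir()
  dir <- file.path(root, "tp1")
  dir.create(dir)
  log <- file.path(root, "run.log")
  geom <- load_geometry(dir, log = log)
  expect_equal(geom$voxel_size, c(1, 1, 1))
  expect_true(file.exists(file.path(dir, "geometry.toml")))
  expect_match(paste(readLines(log), collapse = " "), "defaults written")
  # present file is passed through untouched
  write_geometry(geometry_meta(voxel_size = 0.02), dir)
  expect_equal(load_geometry(dir)$voxel_size, c(0.02, 0.02, 0.02))
})

test_that("malformed geometry files raise parse errors with line context", {
  root <- withr::local_tempdir()
  dir <- file.path(root, "tp1")
  dir.create(dir)
  writeLines(c("voxel_size = 0.02", "what even is this"),
             file.path(dir, "geometry.toml"))
  expect_error(load_geometry(dir), "line 2")
})

test_that("toml subset round-trips scalars, arrays, strings and booleans", {
  path <- withr::local_tempfile(fileext = ".toml")
  x <- list(voxel_size = c(0.02, 0.02, 0.025), rotation_axis_offset = 0,
            notes = "session 3", flag = TRUE)
  write_toml(x, path)
  back <- read_toml(path)
  expect_equal(back, x)
})
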