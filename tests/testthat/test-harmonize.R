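make_seq <- function(depths, base = c(8, 8), seed = 1) {
  scans <- lapply(seq_along(depths), function(i) {
    s <- make_int_volume(c(base, depths[i]), seed = seed + i)
    s$day <- 7L * i
    s
  })
  scan_sequence(scans)
}

test_that("common_shape is the per-axis minimum", {
  seq <- make_seq(c(10, 9, 8))
  expect_equal(common_shape(seq), c(8L, 8L, 8L))
  # already uniform: unchanged extents
  sequ <- make_seq(c(6, 6, 6))
  expect_equal(common_shape(sequ), c(8L, 8L, 6L))
  # x/y mismatch
  s1 <- make_int_volume(c(12, 8, 5))
  s2 <- make_int_volume(c(10, 8, 5))
  s2$day <- 14L
  expect_equal(common_shape(scan_sequence(list(s1, s2))), c(10L, 8L, 5L))
})

test_that("trim_to_common removes only top slices and keeps retained voxels bit-identical", {
  seq <- make_seq(c(10, 8))
  out <- trim_to_common(seq)
  expect_true(out$uniform_grid)
  expect_equal(dim(out$scans[[1]]$intensities)[3], 8)
  # kept region identical to input bottom slices; top slices dropped
  expect_identical(out$scans[[1]]$intensities,
                   seq$scans[[1]]$intensities[, , 1:8])
  expect_identical(out$scans[[2]]$intensities, seq$scans[[2]]$intensities)
  # retained-region voxel sums unchanged
  expect_identical(sum(out$scans[[1]]$intensities),
                   sum(seq$scans[[1]]$intensities[, , 1:8]))
})

test_that("harmonization is idempotent and the identity on uniform sequences", {
  seq <- make_seq(c(9, 7, 8))
  once <- trim_to_common(seq)
  twice <- trim_to_common(once)
  expect_identical(lapply(twice$scans, `[[`, "intensities"),
                   lapply(once$scans, `[[`, "intensities"))
  expect_equal(unname(dim(once$scans[[1]]$intensities)), unname(common_shape(seq)))
  uniform <- make_seq(c(5, 5))
  expect_identical(lapply(trim_to_common(uniform)$scans, `[[`, "intensities"),
                   lapply(uniform$scans, `[[`, "intensities"))
})

test_that("in-slice mismatches are center-cropped and logged as a deviation", {
  s1 <- make_int_volume(c(12, 10, 4), seed = 3)
  s2 <- make_int_volume(c(10, 10, 4), seed = 4)
  s2$day <- 14L
  log <- withr::local_tempfile()
  out <- trim_to_common(scan_sequence(list(s1, s2)), log = log)
  expect_equal(unname(dim(out$scans[[1]]$intensities)), c(10, 10, 4))
  expect_identical(out$scans[[1]]$intensities, s1$intensities[2:11, , ])
  expect_match(paste(readLines(log), collapse = " "), "center-crop")
})

test_that("ensure_geometry repairs missing metadata and reconciles conflicts", {
  root <- withr::local_tempdir()
  dirs <- character(3)
  scans <- list()
  for (i in 1:3) {
    s <- make_int_volume(c(6, 6, 3), seed = i)
    s$day <- 7L * i
    dirs[i] <- write_stack_dir(s, root, sprintf("wk%02d", i))
    scans[[i]] <- read_volume_stack(dirs[i])
    scans[[i]]$day <- 7L * i
  }
  write_geometry(geometry_meta(0.02), dirs[1])
  write_geometry(geometry_meta(0.02), dirs[3])
  unlink(file.path(dirs[2], "geometry.toml"))
  scans <- lapply(dirs, function(d) read_volume_stack(d))
  for (i in 1:3) scans[[i]]$day <- 7L * i
  out <- ensure_geometry(scan_sequence(scans), default = geometry_meta(0.02))
  expect_true(file.exists(file.path(dirs[2], "geometry.toml")))
  for (s in out$scans) expect_equal(s$geometry$voxel_size, rep(0.02, 3))
})

test_that("conflicting voxel sizes warn and adopt the first scan's value", {
  s1 <- make_int_volume(c(6, 6, 3), seed = 1); s1$day <- 7L
  s2 <- make_int_volume(c(6, 6, 3), seed = 2); s2$day <- 14L
  s1$geometry <- geometry_meta(0.02)
  s2$geometry <- geometry_meta(0.03)
  expect_warning(out <- ensure_geometry(scan_sequence(list(s1, s2))),
                 "conflicting voxel sizes")
  expect_equal(out$scans[[2]]$geometry$voxel_size, rep(0.02, 3))
})

test_that("degenerate harmonization targets are rejected", {
  s1 <- make_int_volume(c(6, 6, 3))
  s1$intensities <- s1$intensities[, , 1, drop = FALSE]
  s2 <- make_int_volume(c(6, 6, 3), seed = 2)
  s2$day <- 14L
  # force a zero-extent axis by constructing an impossible target
  expect_error(trim_to_common(structure(list(
    scans = list(), uniform_grid = FALSE), class = "scan_sequence")))
})
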