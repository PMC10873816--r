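point_volume <- function(dims = c(16, 16, 16), at = c(5, 9, 12), value = 255) {
  a <- array(0, dims)
  a[at[1], at[2], at[3]] <- value
  volume_scan(a, day = 7, scan_label = "wk1")
}

test_that("the projection of a single bright voxel keeps its maximum at all azimuths", {
  v <- point_volume()
  for (az in seq(0, 350, by = 35)) {
    fr <- project_mip(v, az)
    expect_equal(max(fr$pixels), 255, tolerance = 1e-6)
    expect_gte(fr$azimuth, 0)
    expect_lt(fr$azimuth, 360)
  }
})

test_that("projection is periodic in azimuth and deterministic", {
  v <- volume_scan(array(withr::with_seed(4, runif(16^3)), c(16, 16, 16)))
  expect_identical(project_mip(v, 0)$pixels, project_mip(v, 360)$pixels)
  expect_identical(project_mip(v, 123.4)$pixels, project_mip(v, 123.4)$pixels)
})

test_that("an axially symmetric cylinder projects alike at 0 and 90 degrees", {
  d <- c(24, 24, 24)
  cx <- (d[1] - 1) / 2
  r2 <- outer(0:(d[1] - 1), 0:(d[2] - 1),
              function(x, y) (x - cx)^2 + (y - cx)^2)
  slab <- exp(-r2 / 36)  # smooth radial falloff avoids rasterization edges
  v <- volume_scan(array(rep(slab, d[3]), d))
  f0 <- project_mip(v, 0)$pixels
  f90 <- project_mip(v, 90)$pixels
  expect_lt(max(abs(f0 - f90)), 0.02 * max(f0))
})

test_that("the image bottom corresponds to the volume bottom", {
  d <- c(10, 10, 10)
  a <- array(0, d)
  a[, , 1] <- 1  # bright bottom slice
  fr <- project_mip(volume_scan(a), 0)
  expect_equal(unname(fr$pixels[nrow(fr$pixels), ]), rep(1, d[1]))
  expect_equal(unname(fr$pixels[1, ]), rep(0, d[1]))
})

test_that("MIP is monotone: raising a voxel never darkens any pixel", {
  v <- volume_scan(array(withr::with_seed(3, runif(12^3)), c(12, 12, 12)))
  base <- project_mip(v, 40)$pixels
  v2 <- v
  v2$intensities[6, 7, 8] <- v2$intensities[6, 7, 8] + 5
  brighter <- project_mip(v2, 40)$pixels
  expect_true(all(brighter - base >= -1e-12))
})

test_that("annotation changes pixels only inside the label region", {
  v <- point_volume()
  fr <- project_mip(v, 0)
  ann <- annotate_frame(fr, label = "WK 1", value = 300)
  diff <- which(ann$pixels != fr$pixels, arr.ind = TRUE)
  expect_gt(nrow(diff), 0)
  # label region: bottom-left corner block
  bm_h <- 7; margin <- 2
  expect_true(all(diff[, 1] > nrow(fr$pixels) - margin - bm_h))
  expect_true(all(diff[, 2] <= margin + 6 * nchar("WK 1")))
})

test_that("turntable rendering yields n_timepoints x 360/step numbered frames", {
  seqs <- scan_sequence(list(
    point_volume(at = c(4, 4, 4)),
    local({ s <- point_volume(at = c(10, 10, 10)); s$day <- 14L; s })
  ))
  out <- withr::local_tempdir()
  frames <- render_turntable(seqs, azimuth_step = 90, out_dir = out)
  expect_length(frames, 2 * 4)
  inv <- attr(frames, "inventory")
  expect_equal(inv$frame, 0:7)
  expect_equal(inv$azimuth, rep(c(0, 90, 180, 270), 2))
  expect_equal(sort(list.files(out, pattern = "png$")),
               sprintf("capture_%05d.png", 0:7))
  expect_error(render_turntable(seqs, azimuth_step = 70), "invalid azimuth step")
  # three timepoints at the default 10-degree step give 108 frames
  s3 <- local({ s <- point_volume(at = c(8, 8, 8)); s$day <- 21L; s })
  seq3 <- scan_sequence(c(seqs$scans, list(s3)))
  expect_length(render_turntable(seq3), 108)
})

test_that("rendering identical inputs is bit-identical", {
  seqs <- scan_sequence(list(point_volume()))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  render_turntable(seqs, azimuth_step = 120, out_dir = out1)
  render_turntable(seqs, azimuth_step = 120, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), raw(), 1e6),
                     readBin(file.path(out2, f), raw(), 1e6))
  }
})

write_test_frames <- function(dir, n, w = 12, h = 10, start = 0) {
  dir.create(dir, showWarnings = FALSE)
  withr::with_seed(1, {
    for (i in seq_len(n) - 1L) {
      png::writePNG(matrix(runif(w * h), h, w),
                    file.path(dir, sprintf("capture_%05d.png", i + start)))
    }
  })
}

read_avi_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  avi <- readChar(con, 4)
  seek(con, 32)  # dwMicroSecPerFrame sits after LIST hdrl avih headers
  usec <- readBin(con, integer(), 1, 4, endian = "little")
  seek(con, 48)
  total <- readBin(con, integer(), 1, 4, endian = "little")
  list(riff = riff, avi = avi, usec_per_frame = usec, total_frames = total)
}

test_that("video assembly at 1/5 fps yields a container whose metadata spans 50 s", {
  frames <- file.path(withr::local_tempdir(), "frames")
  write_test_frames(frames, 10)
  out <- file.path(dirname(frames), "lapse.mp4")
  video <- assemble_video(frames, out, rate = "1/5", encoder = "avi")
  expect_equal(attr(video, "duration_s"), 50)
  hdr <- read_avi_header(as.character(video))
  expect_identical(hdr$riff, "RIFF")
  expect_identical(hdr$avi, "AVI ")
  expect_equal(hdr$total_frames * hdr$usec_per_frame / 1e6, 50)
})

test_that("video assembly rejects empty and gapped frame sequences", {
  dir <- file.path(withr::local_tempdir(), "frames")
  dir.create(dir)
  expect_error(assemble_video(dir, "x.avi"), "empty frame sequence")
  write_test_frames(dir, 5)
  unlink(file.path(dir, "capture_00002.png"))
  expect_error(assemble_video(dir, file.path(dirname(dir), "x.avi")),
               "capture_2")
})
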