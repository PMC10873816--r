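test_that("a transform composed with its inverse is the identity within tolerance", {
  withr::with_seed(5, {
    for (i in 1:20) {
      t1 <- rigid_transform(rotation = runif(3, -30, 30),
                            translation = runif(3, -10, 10))
      tid <- compose_transforms(invert_transform(t1), t1)
      expect_lt(max(abs(tid$rotation)), 0.1)
      expect_lt(max(abs(tid$translation)), 0.1)
    }
  })
})

test_that("euler angles round-trip through the rotation matrix", {
  withr::with_seed(6, {
    for (i in 1:20) {
      ang <- runif(3, -80, 80)
      R <- euler_to_matrix(ang)
      expect_equal(det(R), 1, tolerance = 1e-12)
      expect_equal(matrix_to_euler(R), ang, tolerance = 1e-9)
    }
  })
})

test_that("identity transforms leave volumes untouched", {
  v <- make_int_volume(c(6, 7, 5))
  out <- apply_transform(v, rigid_transform())
  expect_identical(out$intensities, v$intensities)
})

test_that("integer shifts are exact on interior voxels and invert cleanly", {
  v <- make_int_volume(c(12, 12, 12), seed = 3)
  s <- rigid_transform(translation = c(5, 0, 0))
  fwd <- apply_transform(v, s)
  # out(x) = v(x - t): interior voxels exact
  expect_identical(fwd$intensities[7, 4, 4], v$intensities[2, 4, 4])
  back <- apply_transform(fwd, rigid_transform(translation = c(-5, 0, 0)))
  # voxels that stayed in view through both shifts are recovered exactly
  expect_equal(back$intensities[1:7, , ], v$intensities[1:7, , ],
               tolerance = 1e-12)
})

test_that("shifts beyond the grid produce an all-zero volume", {
  v <- make_int_volume(c(6, 6, 6))
  out <- apply_transform(v, rigid_transform(translation = c(10, 0, 0)))
  expect_true(all(out$intensities == 0))
  expect_identical(dim(out$intensities), dim(v$intensities))
})

test_that("binning averages blocks, preserves constants and the global mean", {
  const <- volume_scan(array(3.5, c(16, 16, 16)))
  b <- bin_volume(const, 4)
  expect_true(all(b$intensities == 3.5))
  expect_equal(unname(dim(b$intensities)), c(4, 4, 4))
  expect_equal(b$voxel_size, const$voxel_size * 4)

  v <- volume_scan(array(withr::with_seed(8, runif(16^3)), c(16, 16, 16)))
  expect_equal(mean(bin_volume(v, 8)$intensities), mean(v$intensities),
               tolerance = 1e-9)
  expect_equal(unname(dim(bin_volume(v, 8)$intensities)), c(2, 2, 2))
})

test_that("binning with factor 1 is the identity and oversized factors fail", {
  v <- make_int_volume(c(6, 6, 4))
  expect_identical(bin_volume(v, 1)$intensities, v$intensities)
  expect_error(bin_volume(v, 8), "bin factor too large")
})

test_that("binning drops trailing remainder voxels", {
  v <- volume_scan(array(withr::with_seed(2, runif(7 * 6 * 5)), c(7, 6, 5)))
  b <- bin_volume(v, 2)
  expect_equal(unname(dim(b$intensities)), c(3, 3, 2))
  expect_equal(b$intensities[1, 1, 1], mean(v$intensities[1:2, 1:2, 1:2]))
})
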