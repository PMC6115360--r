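# Preprocessing primitives: ROI masking, thresholding, bit-depth
# rescaling, Butterworth smoothing and trilinear resampling.

test_that("cylindrical ROI masking follows the voxel-center rule", {
  vol <- ImageVolume(array(1, c(100, 100, 30)))
  roi <- CylindricalROI(c(49.5, 49.5, 14.5), diameter = 82, height = 20)
  m <- maskROI(vol, roi)
  n_in <- sum(!is.na(m@voxels))
  # analytic cylinder volume on a 1 mm grid: pi * 41^2 * 20 voxels
  expect_lt(abs(n_in - pi * 41^2 * 20) / (pi * 41^2 * 20), 0.01)
  # degenerate diameter: single voxel column nearest the axis
  tiny <- maskROI(vol, CylindricalROI(c(49.5, 49.5, 14.5),
                                      diameter = 1e-9, height = 20))
  expect_equal(dim(tiny@voxels)[1:2], c(1L, 1L))
  expect_equal(sum(!is.na(tiny@voxels)), 20)
  # ROI extending outside the volume is rejected
  expect_error(maskROI(vol, CylindricalROI(c(49.5, 49.5, 14.5),
                                           diameter = 150, height = 20)),
               "outside")
})

test_that("thresholding excludes (not clips) out-of-range values", {
  expect_equal(applyThreshold(c(-150, 0, 250), -100, 200),
               c(NA, 0, NA))
  expect_equal(applyThreshold(c(-150, 500), -100, NA), c(NA, 500))
  x <- c(-50, 0, 100)
  expect_equal(applyThreshold(x, -100, 200), x)  # all in range
  expect_warning(applyThreshold(c(-500, 300), -100, 200), "every")
  expect_error(applyThreshold(1:3, 10, 5), "below")
})

test_that("bit-depth rescaling maps [min, max] to 1..256", {
  expect_equal(rescaleBitDepth(c(0, 255)), c(1, 256))
  expect_equal(rescaleBitDepth(c(0, 100, 255)), c(1, 101, 256))
  expect_equal(rescaleBitDepth(rep(7.5, 5)), rep(1, 5))
  got <- rescaleBitDepth(c(NA, -100, 200))
  expect_equal(got, c(NA, 1, 256))
})

test_that("Butterworth filter preserves DC and attenuates Nyquist by the analytic gain", {
  const <- ImageVolume(array(42, c(16, 16, 2)))
  expect_equal(butterworthSmooth(const)@voxels, const@voxels,
               tolerance = 1e-10)
  # zero-mean checkerboard at Nyquist: gain = 1/(1 + (f/cutoff)^4),
  # f = 512 * sqrt(0.5^2 + 0.5^2) cycles per 512-equivalent matrix
  n <- 16
  cb <- outer(1:n, 1:n, function(i, j) (-1)^(i + j))
  vol <- ImageVolume(array(cb, c(n, n, 1)))
  f_nyq <- 512 * sqrt(0.5)
  gain <- 1 / (1 + (f_nyq / 125)^4)
  sm <- butterworthSmooth(vol)
  expect_equal(sm@voxels, vol@voxels * gain, tolerance = 1e-8)
  # cutoff -> infinity approaches the identity
  noisy <- ImageVolume(array(rnorm(16 * 16 * 2), c(16, 16, 2)))
  expect_equal(butterworthSmooth(noisy, cutoff = 1e9)@voxels,
               noisy@voxels, tolerance = 1e-6)
  # slice means always preserved
  set.seed(1)
  vol2 <- ImageVolume(array(rnorm(16 * 16 * 3, 100, 20), c(16, 16, 3)))
  sm2 <- butterworthSmooth(vol2)
  expect_equal(apply(sm2@voxels, 3, mean), apply(vol2@voxels, 3, mean),
               tolerance = 1e-10)
})

test_that("in-plane resampling reproduces affine fields and matches a 2D oracle", {
  # identity when already on the target grid
  vol <- ImageVolume(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  expect_identical(resampleXY(vol, 1), vol)
  # a linear ramp is reproduced exactly at the new grid points
  ramp <- ImageVolume(
    array(outer(0:15, 0:15, function(i, j) 2 * i + 3 * j), c(16, 16, 1)),
    spacing = c(0.5, 0.5, 1))
  rs <- resampleXY(ramp, 1)
  x_mm <- seq(0, by = 1, length.out = dim(rs@voxels)[1])
  y_mm <- seq(0, by = 1, length.out = dim(rs@voxels)[2])
  expected <- outer(x_mm / 0.5 * 2, y_mm / 0.5 * 3, "+")
  expect_equal(rs@voxels[, , 1], expected, tolerance = 1e-10)
  expect_equal(rs@spacing[1:2], c(1, 1))
  # random image vs independent bilinear oracle at probe points
  skip_if_not_installed("pracma")
  set.seed(9)
  img <- matrix(rnorm(20 * 20), 20, 20)
  vol2 <- ImageVolume(array(img, c(20, 20, 1)), spacing = c(0.5, 0.5, 1))
  rs2 <- resampleXY(vol2, 1)
  xg <- (0:19) * 0.5
  probes_x <- seq(0, 9, by = 1)[1 + (0:9)]
  for (p in 1:10) {
    xi <- probes_x[p]
    yi <- probes_x[11 - p]
    oracle <- pracma::interp2(xg, xg, t(img), xi, yi, method = "linear")
    got <- rs2@voxels[round(xi) + 1, round(yi) + 1, 1]
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("z resampling is exact on ramps and keeps enough slices", {
  vol <- ImageVolume(array(rnorm(4 * 4 * 10), c(4, 4, 10)))
  expect_identical(resampleZ(vol, 1), vol)
  ramp <- ImageVolume(array(rep(0:20, each = 16) * 5, c(4, 4, 21)))
  rs <- resampleZ(ramp, 2.5)
  expect_equal(rs@voxels[1, 1, ], seq(0, 100, by = 12.5),
               tolerance = 1e-10)
  # a 20 mm ROI resampled to dz = 7 retains >= 2 slices
  roi20 <- ImageVolume(array(0, c(4, 4, 21)))   # 20 mm z extent
  expect_gte(dim(resampleZ(roi20, 7)@voxels)[3], 2)
  expect_error(resampleZ(vol, -1), "positive")
})

test_that("preprocessing order is fixed and order matters on texture", {
  vol <- generateCartridgeVolume(materialSpec("m", 0, 50, 1.5),
                                 shape = c(24, 24, 8), seed = 5)
  roi <- CylindricalROI(c(11.5, 11.5, 3.5), diameter = 16, height = 5)
  canonical <- extractFeatureVector(vol, roi, chain = "tsb")
  # permuted pipeline: rescale before smoothing
  masked <- maskROI(vol, roi)
  lev_first <- rescaleBitDepth(masked@voxels)
  vol_lev <- vol
  vol_lev@voxels <- array(rescaleBitDepth(vol@voxels), dim(vol@voxels))
  sm <- maskROI(butterworthSmooth(vol_lev), roi)
  sm@voxels[is.na(masked@voxels)] <- NA
  permuted <- glcmFeatures(round(sm@voxels) -
                             min(round(sm@voxels), na.rm = TRUE) + 1)
  expect_false(isTRUE(all.equal(
    canonical[names(permuted)], permuted, tolerance = 1e-6)))
})
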