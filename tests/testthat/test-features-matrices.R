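# Texture-matrix features against brute-force enumeration oracles and
# their analytic degenerate limits.

test_that("constant ROI features take their analytic limits", {
  g <- array(3, c(4, 4, 3))
  glcm <- glcmFeatures(g)
  expect_equal(glcm[["glcm_contrast"]], 0)
  expect_equal(glcm[["glcm_dissimilarity"]], 0)
  expect_equal(glcm[["glcm_energy"]], 1)
  expect_equal(glcm[["glcm_entropy"]], 0)
  expect_equal(glcm[["glcm_max_probability"]], 1)
  expect_equal(glcm[["glcm_auto_correlation"]], 9)  # g^2 on a point mass
  expect_equal(glcm[["glcm_inverse_variance"]], 0)

  glrlm <- glrlmFeatures(g)
  expect_equal(glrlm[["glrlm_low_gray_level_run_emphasis"]], 1 / 9)
  expect_equal(glrlm[["glrlm_high_gray_level_run_emphasis"]], 9)
  expect_equal(glrlmFeatures(array(1, c(3, 3, 2)))[[
    "glrlm_low_gray_level_run_emphasis"]], 1)

  ng <- ngtdmFeatures(g)
  expect_equal(ng[["ngtdm_contrast"]], 0)
  expect_equal(ng[["ngtdm_coarseness"]], 1e6)  # capped maximum

  ih <- intensityFeatures(rep(5, 10))
  expect_equal(ih[["ih_standard_deviation"]], 0)
  expect_equal(ih[["ih_variance"]], 0)
  expect_equal(ih[["ih_minimum"]], ih[["ih_maximum"]])
  expect_equal(ih[["ih_mean"]], ih[["ih_median"]])
})

test_that("2x2 toy grid matches exhaustive pair enumeration", {
  g <- array(c(1, 2, 2, 1), c(2, 2, 1))
  expect_equal(glcmFeatures(g), oracle_glcm_features(g), tolerance = 1e-12)
})

test_that("alternating line is fully fragmented into unit runs", {
  g <- array(c(1, 2, 1, 2), c(4, 1, 1))
  got <- glrlmFeatures(g)
  # only the x direction produces multi-voxel lines; all runs length 1
  expect_equal(got, oracle_glrlm_features(g), tolerance = 1e-12)
  rp_x_only <- oracle_glrlm_features(g)[["glrlm_run_percentage"]]
  expect_equal(got[["glrlm_run_percentage"]], rp_x_only)
  expect_equal(got[["glrlm_short_run_emphasis"]], 1)  # every run length 1
})

test_that("NGTDM matches hand-computed s(i) on a 3x3x3 toy", {
  g <- array(1, c(3, 3, 3))
  g[2, 2, 2] <- 2
  # single interior voxel: level 2, neighborhood mean 1 -> s(2) = 1
  got <- ngtdmFeatures(g)
  expect_equal(got, oracle_ngtdm_features(g), tolerance = 1e-12)
  # N = 1 counted voxel of level 2: p = (0, 1), s = (0, 1)
  expect_equal(got[["ngtdm_coarseness"]], 1)         # 1 / (1 * 1)
  expect_equal(got[["ngtdm_contrast"]], 0)           # one occupied level
})

test_that("two-level checkerboard has positive NGTDM contrast", {
  g <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    g[i, j, k] <- 1 + (i + j + k) %% 2
  expect_gt(ngtdmFeatures(g)[["ngtdm_contrast"]], 0)
})

test_that("intensity moments match direct arithmetic", {
  x <- c(1, 2, 3, 4)
  got <- intensityFeatures(x)
  expect_equal(got[["ih_mean"]], 2.5)
  expect_equal(got[["ih_variance"]], 1.25)            # population m2
  expect_equal(got[["ih_kurtosis"]], (sum((x - 2.5)^4) / 4) / 1.25^2)
  expect_equal(got[["ih_skewness"]], 0)               # symmetric set
  expect_equal(got, oracle_intensity_features(x), tolerance = 1e-12)
})

test_that("all matrix features match oracles on random small grids", {
  set.seed(401)
  shapes <- list(c(2, 2, 1), c(3, 1, 1), c(3, 2, 1), c(2, 2, 2),
                 c(3, 3, 1), c(3, 3, 2))
  for (shape in shapes) for (n_lev in 2:3) for (rep in 1:4) {
    g <- random_level_grid(shape, n_lev,
                           na_frac = if (rep == 4) 0.2 else 0)
    if (sum(!is.na(g)) < 2) next
    expect_equal(glcmFeatures(g), oracle_glcm_features(g),
                 tolerance = 1e-10,
                 info = paste("glcm", paste(shape, collapse = "x")))
    expect_equal(glrlmFeatures(g), oracle_glrlm_features(g),
                 tolerance = 1e-10,
                 info = paste("glrlm", paste(shape, collapse = "x")))
    vals <- as.vector(g[!is.na(g)])
    expect_equal(intensityFeatures(vals), oracle_intensity_features(vals),
                 tolerance = 1e-10)
  }
})

test_that("NGTDM matches the oracle on grids with interior voxels", {
  set.seed(402)
  for (rep in 1:6) {
    g <- random_level_grid(c(3, 3, 3), 3)
    expect_equal(ngtdmFeatures(g), oracle_ngtdm_features(g),
                 tolerance = 1e-10)
  }
})

test_that("pooled matrices are normalized and consistent", {
  set.seed(403)
  g <- random_level_grid(c(4, 4, 3), 3)
  P <- radvar:::.buildGLCM(g)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  rl <- radvar:::.buildGLRLM(g)
  expect_equal(sum(rowSums(rl$p)), rl$n_runs)  # sum_i p_g(i) = n_r
  # every direction's run lengths account for every voxel once
  expect_equal(sum(rl$p %*% seq_len(ncol(rl$p))),
               13 * sum(!is.na(g)))
})

test_that("features are invariant to 90-degree in-plane rotation", {
  set.seed(404)
  g <- random_level_grid(c(4, 4, 3), 3)
  rot <- aperm(g, c(2, 1, 3))[dim(g)[2]:1, , , drop = FALSE]
  expect_equal(glcmFeatures(g), glcmFeatures(rot), tolerance = 1e-12)
  expect_equal(glrlmFeatures(g), glrlmFeatures(rot), tolerance = 1e-12)
  expect_equal(ngtdmFeatures(g), ngtdmFeatures(rot), tolerance = 1e-12)
})

test_that("feature registry covers 49 features in 4 categories", {
  fn <- featureNames()
  expect_length(fn, 49)
  expect_false(any(duplicated(fn)))
  expect_equal(as.vector(table(featureCategories())[
    c("glcm", "glrlm", "intensity", "ngtdm")]), c(22, 11, 11, 5))
})
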