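# Synthetic phantom and scanner simulator: determinism, Monte-Carlo
# moments, and the mean-scaled generative structure.

test_that("cartridge generation is deterministic and mean-accurate", {
  spec <- materialSpec("m", mean_hu = -50, texture_sd = 30,
                       correlation_length = 0.5)
  v1 <- generateCartridgeVolume(spec, shape = c(64, 64, 64), seed = 7)
  v2 <- generateCartridgeVolume(spec, shape = c(64, 64, 64), seed = 7)
  expect_identical(v1@voxels, v2@voxels)
  # short correlation length: mean SE ~ texture_sd/sqrt(N_eff); +-2 HU is
  # a wide multiple of it at 64^3
  expect_lt(abs(mean(v1@voxels) - (-50)), 2)
  expect_lt(abs(sd(as.vector(v1@voxels)) - 30), 2)
  # zero texture: exactly constant
  flat <- generateCartridgeVolume(materialSpec("f", -50, 0, 2),
                                  shape = c(8, 8, 4), seed = 1)
  expect_true(all(flat@voxels == -50))
  expect_error(generateCartridgeVolume(spec, shape = c(8, 8, 4),
                                       spacing = c(1, -1, 1)), "positive")
})

test_that("texture autocorrelation decays at the correlation length", {
  spec <- materialSpec("m", 0, 30, correlation_length = 3)
  v <- generateCartridgeVolume(spec, shape = c(96, 96, 16), seed = 3)
  x <- v@voxels
  lag_cor <- function(l) cor(as.vector(x[1:(96 - l), , ]),
                             as.vector(x[(1 + l):96, , ]))
  # Gaussian kernel of sd 3 voxels: field autocorrelation exp(-l^2/(4*3^2))
  expect_equal(lag_cor(3), exp(-9 / 36), tolerance = 0.1)
  expect_lt(lag_cor(12), 0.1)
})

test_that("acquisition simulation reduces to identity and obeys slab arithmetic", {
  vol <- generateCartridgeVolume(materialSpec("m", 0, 40, 2),
                                 shape = c(16, 16, 8), seed = 2)
  ident <- simulateAcquisition(vol, scannerSpec("V", "S", "controlled",
                                                thickness = 1,
                                                blur_fwhm = 0,
                                                noise_sd = 0))
  expect_equal(ident@voxels, vol@voxels, tolerance = 1e-12)
  two <- simulateAcquisition(vol, scannerSpec("V", "S", "controlled",
                                              thickness = 2, blur_fwhm = 0,
                                              noise_sd = 0))
  expect_equal(dim(two@voxels)[3], 4L)
  expect_equal(two@voxels[, , 1], (vol@voxels[, , 1] + vol@voxels[, , 2]) / 2)
  expect_equal(two@spacing[3], 2)
  thin <- ImageVolume(array(0, c(8, 8, 4)))   # 4 mm z extent
  expect_error(simulateAcquisition(
    thin, scannerSpec("V", "S", "controlled", thickness = 7)), "extent")
})

test_that("acquisition noise has the nominal SD and preserves the mean", {
  vol <- ImageVolume(array(0, c(50, 50, 40)))  # 1e5 voxels
  sc <- scannerSpec("V", "S", "controlled", thickness = 1, blur_fwhm = 0,
                    noise_sd = 10)
  acq <- simulateAcquisition(vol, sc, seed = 11)
  expect_lt(abs(sd(as.vector(acq@voxels)) - 10), 0.5)
  expect_lt(abs(mean(acq@voxels)), 3 * 10 / sqrt(5e4))
})

test_that("degenerate feature generator returns the material means exactly", {
  cfg <- featureSimConfig(sigma_gamma = 0, sigma_beta = 0, sigma_eps = 0,
                          thickness_slope = 0,
                          material_means = c(a = 100, b = 400),
                          n_manufacturers = 2,
                          scanners_per_manufacturer = 3)
  rec <- featureRecords(simulateFeatureTable(cfg, seed = 1))
  expect_equal(rec$value, unname(c(a = 100, b = 400)[rec$material]))
  expect_error(featureSimConfig(material_means = numeric(0)), "non-empty")
})

test_that("generator scaling: absolute SDs scale with the material mean", {
  cfg <- featureSimConfig(sigma_gamma = 0.04, sigma_beta = 0.03,
                          sigma_eps = 0.05, thickness_slope = 0,
                          material_means = c(small = 100, large = 1000),
                          n_manufacturers = 4,
                          scanners_per_manufacturer = 50)
  ratios <- vapply(1:10, function(r) {
    rec <- featureRecords(simulateFeatureTable(cfg, seed = 100 + r))
    sd(rec$value[rec$material == "large"]) /
      sd(rec$value[rec$material == "small"])
  }, numeric(1))
  expect_equal(mean(ratios), 10, tolerance = 0.25)
})

test_that("scanner-level relative SD matches the closed form", {
  cfg <- featureSimConfig(sigma_gamma = 0.04, sigma_beta = 0.03,
                          sigma_eps = 0.05, thickness_slope = 0,
                          material_means = c(a = 50, b = 100, c = 200,
                                             d = 400, e = 800, f = 1600),
                          n_manufacturers = 4,
                          scanners_per_manufacturer = 25)
  # scanner mean over the 6 materials (relative scale) has SD
  # sqrt(sg^2 + sb^2 + se^2/6); averaged over replicates to tame MC noise
  target <- sqrt(0.04^2 + 0.03^2)
  sds <- vapply(1:20, function(r) {
    rec <- featureRecords(simulateFeatureTable(cfg, seed = 200 + r))
    rel <- rec$value / c(a = 50, b = 100, c = 200, d = 400, e = 800,
                         f = 1600)[rec$material]
    sd(tapply(rel, rec$scanner, mean))
  }, numeric(1))
  expect_lt(abs(mean(sds) - target) / target, 0.25)
})

test_that("generating effects are recorded and reproducible", {
  cfg <- featureSimConfig(material_means = c(a = 100), seed = 31L)
  t1 <- simulateFeatureTable(cfg)
  t2 <- simulateFeatureTable(cfg)
  expect_identical(featureRecords(t1), featureRecords(t2))
  gen <- t1@metadata$generating
  expect_length(gen$gamma, 4)
  expect_length(gen$beta, 100)
})

test_that("patient cohort simulation converges to the configured moments", {
  fp <- data.frame(feature = c("f1", "f2"), mu_p = c(50, -10),
                   sigma_p = c(15, 2))
  cfg <- patientCohortConfig("NSCLC", 30, fp, seed = 5L)
  res <- simulatePatientCohort(cfg)
  st <- cohortStats(res$stats)
  expect_lt(abs(st$mu_p[st$feature == "f1"] - 50), 15 * 3 / sqrt(30))
  expect_equal(nrow(res$table), 60)
  # degenerate sigma: identical patients
  cfg0 <- patientCohortConfig("X", 5,
                              data.frame(feature = "f", mu_p = 3,
                                         sigma_p = 0), seed = 1L)
  st0 <- cohortStats(simulatePatientCohort(cfg0)$stats)
  expect_equal(st0$sigma_p, 0)
  expect_error(patientCohortConfig("X", 5,
                                   data.frame(feature = "f", mu_p = 1,
                                              sigma_p = -1)), "sigma_p")
})

test_that("thickness sampler respects the protocol ranges", {
  sc <- sprintf("S%02d", 1:40)
  ch <- sampleThickness("chest", sc, seed = 1)
  expect_true(all(ch >= 1 & ch <= 5))
  hd <- sampleThickness("head", sc, seed = 1)
  expect_true(all(hd >= 0.5 & hd <= 5))
  ct <- sampleThickness("controlled", sc,
                        manufacturers = rep(c("V1", "V2"), 20))
  expect_true(all(ct %in% c(2.5, 3)))
})
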