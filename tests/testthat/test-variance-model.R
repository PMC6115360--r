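# Mean-scaled variance decomposition: recovery, collapse, scale
# equivariance, variability summaries, IV metrics and protocol
# comparisons.

.sim_table <- function(sg, sb, se, slope = 0, seed = 1, protocol = "chest",
                       nm = 4, ns = 25,
                       means = c(a = 50, b = 100, c = 200, d = 400,
                                 e = 30, f = 800)) {
  cfg <- featureSimConfig(sigma_gamma = sg, sigma_beta = sb,
                          sigma_eps = se, thickness_slope = slope,
                          material_means = means, n_manufacturers = nm,
                          scanners_per_manufacturer = ns)
  scanners <- sprintf("V%d_S%02d", rep(seq_len(nm), each = ns),
                      rep(seq_len(ns), nm))
  th <- if (protocol == "controlled")
    setNames(rep(3, length(scanners)), scanners)
  else sampleThickness(protocol, scanners, seed = seed + 1000)
  simulateFeatureTable(cfg, thickness_per_scanner = th, seed = seed,
                       protocol = protocol)
}

test_that("null random components are collapsed and the residual is recovered", {
  tab <- .sim_table(0, 0, 0.05, seed = 4)
  fit <- fitVarianceModel(tab)
  expect_setequal(fit@collapsed, c("manufacturer", "scanner"))
  s <- relativeSigmas(fit)
  expect_equal(s[["sigma_gamma"]], 0)
  expect_equal(s[["sigma_beta"]], 0)
  expect_equal(s[["sigma_eps"]], 0.05, tolerance = 0.1)
})

test_that("components and slope are recovered from generated data", {
  tab <- .sim_table(0.04, 0.03, 0.05, slope = 0.02, seed = 8)
  fit <- fitVarianceModel(tab)
  s <- relativeSigmas(fit)
  expect_equal(s[["sigma_eps"]], 0.05, tolerance = 0.15)
  expect_equal(s[["sigma_beta"]], 0.03, tolerance = 0.4)
  expect_equal(fit@thickness_slope, 0.02,
               tolerance = 4 * fit@thickness_slope_se / 0.02)
  # material fixed effects vanish after mean scaling
  expect_true(all(abs(fit@material_effects) < 0.05))
})

test_that("the fit is scale equivariant in the material means", {
  tab <- .sim_table(0.03, 0.03, 0.04, seed = 5)
  rec2 <- featureRecords(tab)
  rec2$value[rec2$material == "a"] <- 10 * rec2$value[rec2$material == "a"]
  f1 <- fitVarianceModel(tab)
  f2 <- fitVarianceModel(FeatureTable(rec2))
  # equal up to optimizer convergence noise
  expect_equal(relativeSigmas(f1), relativeSigmas(f2), tolerance = 1e-4)
  expect_equal(materialMeans(f2@components)[["a"]],
               10 * materialMeans(f1@components)[["a"]], tolerance = 1e-10)
})

test_that("single-manufacturer data drop the manufacturer component", {
  tab <- .sim_table(0.04, 0.03, 0.05, seed = 6)
  rec <- featureRecords(tab)
  ge_only <- FeatureTable(rec[rec$manufacturer == "V1", ])
  fit <- fitVarianceModel(ge_only)
  expect_true("manufacturer" %in% fit@collapsed)
  expect_equal(relativeSigmas(fit)[["sigma_gamma"]], 0)
  expect_gt(relativeSigmas(fit)[["sigma_beta"]], 0)
})

test_that("variability summary follows the Pythagorean identity", {
  vc <- VarianceComponents(4, 3, 0, material_means = c(m = 1))
  sv <- summarizeVariability(vc)
  expect_equal(sv$sigma_total_m, 5)
  vc2 <- VarianceComponents(0.02, 0.02, 0.02,
                            material_means = c(m = 100))
  sv2 <- summarizeVariability(vc2)
  expect_equal(unname(sv2$proportions), rep(1 / 3, 3))
  expect_equal(sum(sv2$proportions), 1)
  # absolute SDs recover as sigma * f_hat
  expect_equal(sv2$sigma_eps_m, 2)
  set.seed(10)
  s <- runif(3)
  sv3 <- summarizeVariability(VarianceComponents(s[1], s[2], s[3],
                                                 c(m = 7)))
  expect_equal(unname(sv3$proportions), s^2 / sum(s^2), tolerance = 1e-12)
})

test_that("imaging variability ratios and strict cutoff flags", {
  cs <- PatientCohortStats("NSCLC", data.frame(feature = "f",
                                               mu_p = 200, sigma_p = 60))
  # relative total SD equals the cohort CoV -> IV_total = 1, flagged
  vc <- VarianceComponents(0.3 / sqrt(3), 0.3 / sqrt(3), 0.3 / sqrt(3),
                           c(m = 100))
  iv <- imagingVariability(vc, cs, feature = "f")
  expect_equal(iv$iv_total, 1, tolerance = 1e-12)
  expect_true(iv$above_cutoff_total)
  # zero residual
  iv0 <- imagingVariability(VarianceComponents(0.1, 0.1, 0, c(m = 1)),
                            cs, feature = "f")
  expect_equal(iv0$iv_residual, 0)
  expect_false(iv0$above_cutoff_residual)
  # boundary: exactly 1/3 is NOT flagged (strict >)
  ivb <- imagingVariability(VarianceComponents(0, 0, 0.1, c(m = 1)),
                            cs, feature = "f")
  expect_equal(ivb$iv_total, 1 / 3, tolerance = 1e-12)
  expect_false(ivb$above_cutoff_total)
  expect_gte(iv$iv_total, iv$iv_residual)
  # undefined for mu_p = 0
  cs0 <- PatientCohortStats("X", data.frame(feature = "f", mu_p = 0,
                                            sigma_p = 1))
  expect_true(is.na(imagingVariability(vc, cs0, feature = "f")$iv_total))
})

test_that("protocol comparison t-tests behave at the degenerate extremes", {
  sa <- data.frame(feature = paste0("f", 1:40),
                   sigma_gamma = rep(0.02, 40),
                   sigma_beta = rep(0.02, 40), sigma_eps = rep(0.03, 40))
  # identical vectors: p = 0.5 by convention
  same <- compareProtocolVariability(sa, sa)
  expect_equal(same$p_value, rep(0.5, 3))
  # controlled uniformly half of local: p very small
  sb <- sa
  sb[, 2:4] <- sa[, 2:4] * (2 + 0.05 * matrix(rnorm(120), 40, 3))
  cmp <- compareProtocolVariability(sa, sb)
  expect_true(all(cmp$p_value < 0.001))
  # reversed direction: p > 0.5
  rev <- compareProtocolVariability(sb, sa)
  expect_true(all(rev$p_value > 0.5))
  expect_error(compareProtocolVariability(sa[1, ], sb[1, ]), "paired")
})
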