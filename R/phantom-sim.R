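# Synthetic phantom and scanner simulator: textured cartridge volumes,
# scanner-affected acquisitions, generative feature tables with the
# nested manufacturer/scanner/residual structure, and patient cohorts.

#' Material specification for a textured phantom cartridge
#'
#' The texture model is a stationary Gaussian random field: white noise
#' convolved with an isotropic Gaussian kernel whose scale is the
#' material's correlation length, then standardized to \code{texture_sd}
#' around \code{mean_hu}.
#'
#' @param name Material label.
#' @param mean_hu Mean HU of the cartridge.
#' @param texture_sd Marginal SD of the texture in HU (>= 0).
#' @param correlation_length Isotropic correlation scale in mm (> 0).
#' @return A list of class \code{MaterialSpec}.
#' @export
materialSpec <- function(name, mean_hu, texture_sd, correlation_length) {
  .stopifnot1(texture_sd >= 0, "texture_sd must be >= 0")
  .stopifnot1(correlation_length > 0, "correlation_length must be > 0")
  structure(list(name = name, mean_hu = mean_hu, texture_sd = texture_sd,
                 correlation_length = correlation_length),
            class = "MaterialSpec")
}

#' Default six-cartridge material set
#'
#' Six textured materials spanning the HU / texture range of a
#' multi-material radiomics phantom (ABS blends, hemp seeds in
#' polyurethane, shredded rubber, dense cork). HU means and texture
#' scales are calibration choices producing NSCLC-tumor-like feature
#' ranges.
#'
#' @return Named list of six \code{MaterialSpec}s.
#' @export
defaultMaterials <- function() {
  specs <- list(
    materialSpec("abs_beads_pvc", mean_hu = 20, texture_sd = 60,
                 correlation_length = 1.5),
    materialSpec("abs_pvc", mean_hu = 60, texture_sd = 80,
                 correlation_length = 2.0),
    materialSpec("abs_beads", mean_hu = -20, texture_sd = 50,
                 correlation_length = 1.5),
    materialSpec("hemp_seed", mean_hu = -80, texture_sd = 90,
                 correlation_length = 2.5),
    materialSpec("rubber", mean_hu = -150, texture_sd = 70,
                 correlation_length = 2.0),
    materialSpec("dense_cork", mean_hu = -400, texture_sd = 50,
                 correlation_length = 3.0))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Scanner specification
#'
#' @param manufacturer_id Manufacturer label.
#' @param scanner_id Unique scanner label.
#' @param protocol One of "controlled", "chest", "head".
#' @param thickness Image (slice) thickness in mm, in [0.5, 7].
#' @param blur_fwhm In-plane Gaussian blur FWHM in mm (>= 0).
#' @param noise_sd Additive HU noise SD (>= 0).
#' @return A list of class \code{ScannerSpec}.
#' @export
scannerSpec <- function(manufacturer_id, scanner_id,
                        protocol = c("controlled", "chest", "head"),
                        thickness = 3, blur_fwhm = 1, noise_sd = 10) {
  protocol <- match.arg(protocol)
  .stopifnot1(thickness >= 0.5 && thickness <= 7,
              "thickness must be in [0.5, 7] mm")
  .stopifnot1(blur_fwhm >= 0, "blur_fwhm must be >= 0")
  .stopifnot1(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(manufacturer_id = manufacturer_id,
                 scanner_id = scanner_id, protocol = protocol,
                 thickness = thickness, blur_fwhm = blur_fwhm,
                 noise_sd = noise_sd),
            class = "ScannerSpec")
}

#' Generate a textured cartridge volume
#'
#' White Gaussian noise is convolved (periodically, via FFT) with an
#' isotropic Gaussian kernel of scale \code{correlation_length} and
#' standardized so the marginal texture SD equals \code{texture_sd}
#' exactly in distribution.
#'
#' @param spec A \code{\link{materialSpec}}.
#' @param shape Voxel counts (nx, ny, nz).
#' @param spacing Voxel spacing in mm.
#' @param seed RNG seed; identical seeds give identical volumes.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- generateCartridgeVolume(materialSpec("rubber", -150, 70, 2),
#'                                shape = c(32, 32, 8), seed = 1)
#' @export
generateCartridgeVolume <- function(spec, shape = c(96, 96, 24),
                                    spacing = c(1, 1, 1), seed = NULL) {
  .stopifnot1(all(shape > 0), "shape must be positive in all dims")
  .stopifnot1(all(spacing > 0), "spacing must be positive")
  shape <- as.integer(shape)
  if (spec$texture_sd == 0) {
    return(ImageVolume(array(spec$mean_hu, shape), spacing = spacing))
  }
  noise <- .withSeed(seed, array(rnorm(prod(shape)), dim = shape))
  sigma_vox <- spec$correlation_length / spacing
  filt <- .gaussianFilter3d(noise, sigma_vox)
  # white noise through |H|^2 has variance mean(H^2); standardize exactly
  tex <- filt$filtered / sqrt(filt$h2mean) * spec$texture_sd
  ImageVolume(spec$mean_hu + tex, spacing = spacing)
}

#' Simulate a scanner acquisition of a volume
#'
#' Models the protocol-driven image chain: slab averaging along z to the
#' scanner's image thickness, in-plane Gaussian blur of the stated FWHM,
#' and additive Gaussian HU noise. The HU mean is preserved in
#' expectation.
#'
#' @param volume Input \linkS4class{ImageVolume} (high-resolution ground
#'   truth).
#' @param scanner A \code{\link{scannerSpec}}.
#' @param seed RNG seed for the noise.
#' @return An \linkS4class{ImageVolume} with z-spacing equal to the
#'   scanner thickness.
#' @export
simulateAcquisition <- function(volume, scanner, seed = NULL) {
  d <- dim(volume@voxels)
  dz0 <- volume@spacing[3]
  tk <- scanner$thickness
  .stopifnot1(tk <= d[3] * dz0 + 1e-9,
              "scanner thickness exceeds volume z extent")
  per_slab <- tk / dz0
  n_out <- floor(d[3] / per_slab + 1e-9)
  .stopifnot1(n_out >= 1, "volume too thin for the requested thickness")
  out <- array(0, c(d[1], d[2], n_out))
  for (s in seq_len(n_out)) {
    k0 <- floor((s - 1) * per_slab + 1e-9) + 1
    k1 <- min(d[3], ceiling(s * per_slab - 1e-9))
    slab <- volume@voxels[, , k0:k1, drop = FALSE]
    out[, , s] <- rowMeans(slab, dims = 2)
  }
  vol <- ImageVolume(out, spacing = c(volume@spacing[1:2], tk),
                     origin = volume@origin +
                       c(0, 0, (tk - dz0) / 2))
  if (scanner$blur_fwhm > 0) {
    sigma_vox <- scanner$blur_fwhm / 2.354820045 / vol@spacing[1:2]
    filt <- .gaussianFilter3d(vol@voxels, c(sigma_vox, 0))
    vol <- ImageVolume(filt$filtered, spacing = vol@spacing,
                       origin = vol@origin)
  }
  if (scanner$noise_sd > 0) {
    dmo <- dim(vol@voxels)
    noise <- .withSeed(seed,
                       array(rnorm(prod(dmo), sd = scanner$noise_sd), dmo))
    vol <- ImageVolume(vol@voxels + noise, spacing = vol@spacing,
                       origin = vol@origin)
  }
  vol
}

#' Feature-level generative model configuration
#'
#' Parameters of the generative model
#' \deqn{f_{m,i} = \hat f_m (1 + \gamma_v + \beta_i +
#'   slope\,(t - t_{ref}) + \varepsilon)}
#' with \eqn{\gamma_v \sim N(0, \sigma_\gamma^2)} per manufacturer,
#' \eqn{\beta_i \sim N(0, \sigma_\beta^2)} per scanner and
#' \eqn{\varepsilon \sim N(0, \sigma_\varepsilon^2)} per record, so that
#' absolute-scale SDs equal \eqn{\sigma \hat f_m} (the mean-squared
#' variance scaling). The reference thickness is 3 mm, the controlled
#' protocol's nominal thickness.
#'
#' @param sigma_gamma,sigma_beta,sigma_eps Relative SDs (>= 0).
#' @param thickness_slope Relative change per mm of image thickness.
#' @param material_means Named numeric map material -> \eqn{\hat f_m}
#'   (non-zero).
#' @param n_manufacturers,scanners_per_manufacturer Design size.
#' @param feature Feature name written into the table.
#' @param t_ref Reference thickness (mm) for the slope term.
#' @param seed Default RNG seed.
#' @return A list of class \code{FeatureSimConfig}.
#' @export
featureSimConfig <- function(sigma_gamma = 0.04, sigma_beta = 0.03,
                             sigma_eps = 0.05, thickness_slope = 0.02,
                             material_means = c(material_1 = 100),
                             n_manufacturers = 4,
                             scanners_per_manufacturer = 25,
                             feature = "feature_1", t_ref = 3,
                             seed = NULL) {
  .stopifnot1(all(c(sigma_gamma, sigma_beta, sigma_eps) >= 0),
              "all relative SDs must be >= 0")
  .stopifnot1(length(material_means) >= 1 && all(material_means != 0),
              "material_means must be non-empty and non-zero")
  .stopifnot1(n_manufacturers >= 1 && scanners_per_manufacturer >= 1,
              "design must have >= 1 manufacturer and scanner")
  structure(list(sigma_gamma = sigma_gamma, sigma_beta = sigma_beta,
                 sigma_eps = sigma_eps, thickness_slope = thickness_slope,
                 material_means = material_means,
                 n_manufacturers = n_manufacturers,
                 scanners_per_manufacturer = scanners_per_manufacturer,
                 feature = feature, t_ref = t_ref, seed = seed),
            class = "FeatureSimConfig")
}

#' Simulate a feature table from the generative nested model
#'
#' Draws one record per (scanner, material): manufacturer effects
#' \eqn{\gamma_v}, scanner effects \eqn{\beta_i}, a linear thickness term
#' and residual noise, all on the relative scale and multiplied by the
#' per-material mean. The generating effects are recorded in the table's
#' metadata for parameter-recovery checks.
#'
#' @param config A \code{\link{featureSimConfig}}.
#' @param thickness_per_scanner Optional named numeric of per-scanner
#'   image thickness (mm); defaults to \code{t_ref} everywhere.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @param protocol Protocol label for the records.
#' @param preprocessing Preprocessing label for the records.
#' @return A \linkS4class{FeatureTable}.
#' @examples
#' cfg <- featureSimConfig(material_means = c(rubber = 100, cork = 1000))
#' tab <- simulateFeatureTable(cfg, seed = 1)
#' head(featureRecords(tab))
#' @export
simulateFeatureTable <- function(config, thickness_per_scanner = NULL,
                                 seed = config$seed,
                                 protocol = "controlled",
                                 preprocessing = "t") {
  nm <- config$n_manufacturers
  ns <- config$scanners_per_manufacturer
  manufacturers <- sprintf("V%d", seq_len(nm))
  scanners <- as.vector(vapply(seq_len(nm), function(v)
    sprintf("V%d_S%02d", v, seq_len(ns)), character(ns)))
  scanner_manu <- rep(manufacturers, each = ns)
  names(scanner_manu) <- scanners
  if (is.null(thickness_per_scanner)) {
    thickness_per_scanner <- setNames(rep(config$t_ref, length(scanners)),
                                      scanners)
  }
  .stopifnot1(all(scanners %in% names(thickness_per_scanner)),
              "thickness_per_scanner must cover every scanner")
  mats <- names(config$material_means)
  .withSeed(seed, {
    gamma <- setNames(rnorm(nm, 0, config$sigma_gamma), manufacturers)
    beta <- setNames(rnorm(length(scanners), 0, config$sigma_beta),
                     scanners)
    grid <- expand.grid(scanner = scanners, material = mats,
                        stringsAsFactors = FALSE)
    eps <- rnorm(nrow(grid), 0, config$sigma_eps)
    t <- thickness_per_scanner[grid$scanner]
    fm <- config$material_means[grid$material]
    value <- fm * (1 + gamma[scanner_manu[grid$scanner]] +
                     beta[grid$scanner] +
                     config$thickness_slope * (t - config$t_ref) + eps)
    rec <- data.frame(manufacturer = scanner_manu[grid$scanner],
                      scanner = grid$scanner, protocol = protocol,
                      material = grid$material, thickness_mm = as.numeric(t),
                      preprocessing = preprocessing,
                      feature = config$feature, value = as.numeric(value),
                      row.names = NULL)
    FeatureTable(rec, metadata = list(
      generating = list(gamma = gamma, beta = beta,
                        sigma_gamma = config$sigma_gamma,
                        sigma_beta = config$sigma_beta,
                        sigma_eps = config$sigma_eps,
                        thickness_slope = config$thickness_slope,
                        t_ref = config$t_ref)))
  })
}

#' Sample protocol-typical image thicknesses
#'
#' Controlled protocol: 3 mm, except manufacturer "V1" which uses 2.5 mm
#' (mirroring the one vendor whose controlled reconstruction is 2.5 mm).
#' Local chest: 1-5 mm; local head: 0.5-5 mm, drawn from discrete
#' clinical thickness menus with weights favoring the common
#' reconstructions.
#'
#' @param protocol "controlled", "chest" or "head".
#' @param scanners Character vector of scanner ids (named output).
#' @param manufacturers Optional manufacturer of each scanner (used for
#'   the controlled protocol).
#' @param seed RNG seed.
#' @return Named numeric vector of thicknesses (mm).
#' @export
sampleThickness <- function(protocol = c("controlled", "chest", "head"),
                            scanners, manufacturers = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  n <- length(scanners)
  t <- switch(protocol,
    controlled = {
      tt <- rep(3, n)
      if (!is.null(manufacturers)) tt[manufacturers == "V1"] <- 2.5
      tt
    },
    chest = .withSeed(seed, sample(
      c(1, 1.25, 2, 2.5, 3, 3.75, 4, 5), n, replace = TRUE,
      prob = c(0.05, 0.05, 0.10, 0.20, 0.15, 0.10, 0.05, 0.30))),
    head = .withSeed(seed, sample(
      c(0.5, 0.625, 1, 1.25, 2, 2.5, 3, 3.75, 5), n, replace = TRUE,
      prob = c(0.05, 0.05, 0.10, 0.15, 0.10, 0.25, 0.10, 0.05, 0.15))))
  setNames(t, scanners)
}

#' Patient cohort configuration
#'
#' @param cohort_name Label, e.g. "NSCLC".
#' @param n_patients Number of patients (>= 2).
#' @param feature_params data.frame with columns \code{feature, mu_p,
#'   sigma_p}.
#' @param seed RNG seed.
#' @return A list of class \code{PatientCohortConfig}.
#' @export
patientCohortConfig <- function(cohort_name, n_patients, feature_params,
                                seed = NULL) {
  feature_params <- as.data.frame(feature_params)
  .stopifnot1(all(c("feature", "mu_p", "sigma_p") %in%
                    names(feature_params)),
              "feature_params needs columns feature, mu_p, sigma_p")
  .stopifnot1(all(feature_params$sigma_p >= 0), "sigma_p must be >= 0")
  .stopifnot1(n_patients >= 2, "n_patients must be >= 2")
  structure(list(cohort_name = cohort_name, n_patients = n_patients,
                 feature_params = feature_params, seed = seed),
            class = "PatientCohortConfig")
}

#' Simulate a patient cohort feature table
#'
#' Per-patient feature values are drawn independently as
#' \eqn{N(\mu_p, \sigma_p^2)} per feature. Returns the long table and the
#' \linkS4class{PatientCohortStats} computed from it (sample mean / SD).
#'
#' @param config A \code{\link{patientCohortConfig}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return List with elements \code{table} (data.frame: cohort, patient,
#'   feature, value) and \code{stats} (\linkS4class{PatientCohortStats}).
#' @export
simulatePatientCohort <- function(config, seed = config$seed) {
  fp <- config$feature_params
  .withSeed(seed, {
    grid <- expand.grid(patient = sprintf("P%03d",
                                          seq_len(config$n_patients)),
                        feature = fp$feature, stringsAsFactors = FALSE)
    mu <- fp$mu_p[match(grid$feature, fp$feature)]
    sg <- fp$sigma_p[match(grid$feature, fp$feature)]
    grid$value <- rnorm(nrow(grid), mu, sg)
    grid$cohort <- config$cohort_name
    stats <- do.call(rbind, lapply(split(grid, grid$feature), function(d)
      data.frame(feature = d$feature[1], mu_p = mean(d$value),
                 sigma_p = sd(d$value))))
    rownames(stats) <- NULL
    list(table = grid[, c("cohort", "patient", "feature", "value")],
         stats = PatientCohortStats(config$cohort_name, stats))
  })
}
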