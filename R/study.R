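# End-to-end orchestration: simulate a multi-scanner phantom study,
# screen features, quantify thickness dependence, decompose variability,
# compare protocols and run the QA credentialing test.

#' Default feature parameters for feature-level simulation
#'
#' A panel of representative features spanning the four categories with
#' realistic magnitudes per material and thickness slopes (relative
#' change per mm). Magnitudes are calibration choices producing
#' feature/material scale ratios like those of a textured phantom.
#'
#' @param materials Material names (default: the six cartridge materials).
#' @return data.frame with columns \code{feature, slope} and one
#'   \code{mean_<material>} column per material.
#' @export
defaultFeatureParams <- function(materials = names(defaultMaterials())) {
  base <- c(glcm_auto_correlation = 8000, glcm_contrast = 150,
            glcm_entropy = 7.5, glcm_energy = 0.004,
            glcm_homogeneity = 0.35,
            glrlm_high_gray_level_run_emphasis = 8000,
            glrlm_low_gray_level_run_emphasis = 4e-4,
            glrlm_run_percentage = 0.85,
            ih_standard_deviation = 65, ih_entropy = 6.5,
            ngtdm_coarseness = 0.004, ngtdm_busyness = 4)
  slope <- c(0.030, -0.040, -0.010, 0.030, 0.020,
             0.030, 0.010, -0.010, -0.050, -0.010, 0.050, -0.020)
  # per-material multipliers around 1 (textures differ across cartridges)
  mult <- seq(0.55, 1.45, length.out = length(materials))
  out <- data.frame(feature = names(base), slope = slope,
                    row.names = NULL)
  for (i in seq_along(materials))
    out[[paste0("mean_", materials[i])]] <- as.numeric(base) * mult[i]
  out
}

#' Study configuration
#'
#' Collects the full design of a simulated phantom study: scanner fleet
#' size, per-protocol variance components, feature panel, patient
#' cohorts, and the analysis cutoffs. Per-protocol relative SDs default
#' to a controlled protocol with harmonized reconstruction (small
#' manufacturer component) and local protocols with a larger
#' manufacturer component and dispersed thicknesses.
#'
#' @param n_manufacturers,scanners_per_manufacturer Fleet design.
#' @param protocols Protocols to simulate.
#' @param sigmas Named list per protocol of
#'   \code{c(gamma, beta, eps)} relative SDs.
#' @param feature_params See \code{\link{defaultFeatureParams}}.
#' @param cohorts Named list of cohort definitions:
#'   \code{list(n_patients, rel_sd)} where \code{rel_sd} is the
#'   inter-patient coefficient of variation applied to every feature.
#' @param cov_cutoff,fail_fraction Stability screen cutoffs.
#' @param iv_cutoff IV flag cutoff; default 1/3.
#' @param bound_factor QA bound factor; default 1/3.
#' @param n_shifts ROI shifts in the stability stage.
#' @param shift_rel_sd,shift_abs_sd Relative / absolute SD of the
#'   feature-level ROI-shift noise.
#' @param resampling_rel_sd Relative SD of the z-resampling perturbation
#'   used for the ICC stage.
#' @param seed Master seed.
#' @return A list of class \code{StudyConfig}.
#' @export
studyConfig <- function(n_manufacturers = 4, scanners_per_manufacturer = 6,
                        protocols = c("controlled", "chest", "head"),
                        sigmas = list(
                          controlled = c(gamma = 0.0201, beta = 0.0225,
                                         eps = 0.0334),
                          chest = c(gamma = 0.055, beta = 0.050,
                                    eps = 0.065),
                          head = c(gamma = 0.055, beta = 0.050,
                                   eps = 0.065)),
                        feature_params = defaultFeatureParams(),
                        cohorts = list(
                          NSCLC = list(n_patients = 20, rel_sd = 0.35),
                          HNSCC = list(n_patients = 30, rel_sd = 0.25)),
                        cov_cutoff = 0.10, fail_fraction = 0.5,
                        iv_cutoff = 1 / 3, bound_factor = 1 / 3,
                        n_shifts = 10, shift_rel_sd = 0.02,
                        shift_abs_sd = 0, resampling_rel_sd = 0.01,
                        seed = 1L) {
  .stopifnot1(all(protocols %in% names(sigmas)),
              "sigmas must cover every protocol")
  .stopifnot1(all(c(cov_cutoff, fail_fraction, iv_cutoff, bound_factor) > 0) &&
                all(c(fail_fraction, iv_cutoff, bound_factor) <= 1),
              "cutoffs must be in (0, 1]")
  structure(list(n_manufacturers = n_manufacturers,
                 scanners_per_manufacturer = scanners_per_manufacturer,
                 protocols = protocols, sigmas = sigmas,
                 feature_params = as.data.frame(feature_params),
                 cohorts = cohorts, cov_cutoff = cov_cutoff,
                 fail_fraction = fail_fraction, iv_cutoff = iv_cutoff,
                 bound_factor = bound_factor, n_shifts = n_shifts,
                 shift_rel_sd = shift_rel_sd, shift_abs_sd = shift_abs_sd,
                 resampling_rel_sd = resampling_rel_sd,
                 seed = as.integer(seed)),
            class = "StudyConfig")
}

.materialMeansOf <- function(fp, feature) {
  row <- fp[fp$feature == feature, ]
  cols <- grep("^mean_", names(fp), value = TRUE)
  setNames(as.numeric(row[1, cols]), sub("^mean_", "", cols))
}

# Simulate one protocol's feature table across the whole feature panel,
# sharing the per-scanner thickness across features.
.simulateProtocolTable <- function(config, protocol, seed) {
  fp <- config$feature_params
  nm <- config$n_manufacturers; ns <- config$scanners_per_manufacturer
  scanners <- as.vector(vapply(seq_len(nm), function(v)
    sprintf("V%d_S%02d", v, seq_len(ns)), character(ns)))
  manufacturers <- rep(sprintf("V%d", seq_len(nm)), each = ns)
  seeds <- spawnSeeds(seed, nrow(fp) + 1)
  thick <- sampleThickness(protocol, scanners, manufacturers,
                           seed = seeds[1])
  s <- config$sigmas[[protocol]]
  tabs <- lapply(seq_len(nrow(fp)), function(i) {
    cfg <- featureSimConfig(
      sigma_gamma = s[["gamma"]], sigma_beta = s[["beta"]],
      sigma_eps = s[["eps"]], thickness_slope = fp$slope[i],
      material_means = .materialMeansOf(fp, fp$feature[i]),
      n_manufacturers = nm, scanners_per_manufacturer = ns,
      feature = fp$feature[i])
    simulateFeatureTable(cfg, thickness_per_scanner = thick,
                         seed = seeds[i + 1], protocol = protocol)@records
  })
  FeatureTable(do.call(rbind, tabs))
}

# Feature-level ROI-shift table: per (feature, material, preprocessing),
# n_shifts values with multiplicative + additive placement noise.
.simulateShiftTable <- function(config, seed) {
  fp <- config$feature_params
  mats <- sub("^mean_", "", grep("^mean_", names(fp), value = TRUE))
  chains <- c("t", "ts", "tb", "tsb")
  .withSeed(seed, {
    rows <- expand.grid(feature = fp$feature, material = mats,
                        preprocessing = chains, shift = seq_len(config$n_shifts),
                        stringsAsFactors = FALSE)
    fm <- mapply(function(f, m) .materialMeansOf(fp, f)[[m]],
                 rows$feature, rows$material)
    rows$value <- fm * (1 + rnorm(nrow(rows), 0, config$shift_rel_sd)) +
      rnorm(nrow(rows), 0, config$shift_abs_sd)
    rows$manufacturer <- "V1"; rows$scanner <- "V1_S01"
    rows$protocol <- "controlled"; rows$thickness_mm <- 3
    FeatureTable(rows[, c("manufacturer", "scanner", "protocol",
                          "material", "thickness_mm", "preprocessing",
                          "feature", "value", "shift")])
  })
}

#' Image-level ROI-shift stability study on the phantom simulator
#'
#' Generates one textured volume per material, samples shifted ROIs
#' within the cartridge's acceptable region, extracts the 49 features
#' under the four (threshold-free) preprocessing chains for every shift,
#' and returns the shift table ready for \code{\link{covScreen}}.
#'
#' @param materials List of \code{\link{materialSpec}}s (default all 6).
#' @param shape,spacing Cartridge volume geometry.
#' @param roi_diameter,roi_height ROI geometry in mm.
#' @param margin Acceptable-region margin around the ROI in mm (the shift
#'   freedom per axis is 2 x margin, z freedom margin).
#' @param n_shifts Number of ROI shifts; default 10.
#' @param chains Preprocessing chains.
#' @param seed Master seed.
#' @return A \linkS4class{FeatureTable} with a \code{shift} column.
#' @export
phantomStabilityStudy <- function(materials = defaultMaterials(),
                                  shape = c(36, 36, 10),
                                  spacing = c(1, 1, 1),
                                  roi_diameter = 24, roi_height = 6,
                                  margin = 4, n_shifts = 10,
                                  chains = c("t", "ts", "tb", "tsb"),
                                  seed = 1L) {
  seeds <- spawnSeeds(seed, 2 * length(materials))
  out <- vector("list", length(materials))
  for (i in seq_along(materials)) {
    mat <- materials[[i]]
    vol <- generateCartridgeVolume(mat, shape = shape, spacing = spacing,
                                   seed = seeds[2 * i - 1])
    ctr <- (shape - 1) * spacing / 2
    base <- CylindricalROI(ctr, diameter = roi_diameter,
                           height = roi_height)
    zfree <- min(margin / 2, (shape[3] - 1) * spacing[3] / 2 -
                   roi_height / 2 - spacing[3] / 2)
    region <- list(
      lower = ctr - c(roi_diameter / 2 + margin, roi_diameter / 2 + margin,
                      roi_height / 2 + zfree),
      upper = ctr + c(roi_diameter / 2 + margin, roi_diameter / 2 + margin,
                      roi_height / 2 + zfree))
    rois <- shiftROIs(base, region, n = n_shifts, seed = seeds[2 * i])
    tabs <- lapply(seq_along(rois), function(s) {
      md <- data.frame(manufacturer = "V1", scanner = "V1_S01",
                       protocol = "controlled", material = mat$name,
                       thickness_mm = spacing[3])
      rec <- extractFeatureTable(list(vol), rois[s], md, chains = chains,
                                 resample_inplane = FALSE)@records
      rec$shift <- s
      rec
    })
    out[[i]] <- do.call(rbind, tabs)
  }
  FeatureTable(do.call(rbind, out))
}

.cohortStatsFromConfig <- function(config, cohort_name) {
  fp <- config$feature_params
  co <- config$cohorts[[cohort_name]]
  mu <- vapply(fp$feature, function(f)
    mean(.materialMeansOf(fp, f)), numeric(1))
  PatientCohortStats(cohort_name, data.frame(
    feature = fp$feature, mu_p = as.numeric(mu),
    sigma_p = abs(as.numeric(mu)) * co$rel_sd))
}

#' Run a full simulated phantom study
#'
#' Sequences the pipeline: feature-table simulation per protocol,
#' stability screen (feature-level by default; image-level via
#' \code{stability_mode = "image"}), thickness correlation and
#' z-resampling ICC, per-feature variance decomposition with the
#' collapse rule, imaging-variability metrics against the configured
#' cohorts, protocol comparisons, and the QA tally. Fully reproducible
#' from the config's master seed.
#'
#' @param config A \code{\link{studyConfig}}.
#' @param outdir Optional directory; when given, all intermediate tables
#'   are persisted as CSV.
#' @param stability_mode "feature" (fast, default) or "image" (exercises
#'   volume generation and feature extraction).
#' @return List with elements \code{tables, stability, thickness, icc,
#'   fits, variability, iv, comparisons, qa, ratios}.
#' @export
runStudy <- function(config = studyConfig(), outdir = NULL,
                     stability_mode = c("feature", "image")) {
  stability_mode <- match.arg(stability_mode)
  seeds <- spawnSeeds(config$seed, length(config$protocols) + 3)
  names(seeds) <- c(config$protocols, "shifts", "cohorts", "icc")

  tables <- lapply(config$protocols, function(p)
    .simulateProtocolTable(config, p, seeds[[p]]))
  names(tables) <- config$protocols

  shift_tab <- if (stability_mode == "feature")
    .simulateShiftTable(config, seeds[["shifts"]])
  else phantomStabilityStudy(seed = seeds[["shifts"]],
                             n_shifts = config$n_shifts)
  stability <- covScreen(shift_tab, cov_cutoff = config$cov_cutoff,
                         fail_fraction = config$fail_fraction)
  retained <- intersect(retainedFeatures(stability),
                        unique(tables[[1]]@records$feature))
  if (!length(retained)) retained <- unique(tables[[1]]@records$feature)

  # thickness dependence on the local chest protocol
  local_prot <- intersect(c("chest", "head"), config$protocols)
  thick_cor <- if (length(local_prot))
    thicknessCorrelation(tables[[local_prot[1]]]) else NULL

  # ICC across 8 z-resampling options (values barely change on
  # resampling, emulating the finding that resampling does not undo the
  # thickness effect)
  icc_tab <- NULL
  if (length(local_prot)) {
    rec <- tables[[local_prot[1]]]@records
    icc_seeds <- spawnSeeds(seeds[["icc"]], length(retained))
    icc_tab <- do.call(rbind, lapply(seq_along(retained), function(i) {
      f <- retained[i]
      v <- rec$value[rec$feature == f]
      mat <- .withSeed(icc_seeds[i], {
        cbind(v, matrix(v * (1 + rnorm(length(v) * 7, 0,
                                       config$resampling_rel_sd)),
                        ncol = 7))
      })
      r <- iccAgreement(mat)
      data.frame(feature = f, icc_2_1 = r@icc_2_1, icc_3_1 = r@icc_3_1,
                 category_2_1 = r@category_2_1,
                 category_3_1 = r@category_3_1)
    }))
  }

  fits <- lapply(config$protocols, function(p) {
    fl <- lapply(retained, function(f)
      fitVarianceModel(tables[[p]], feature = f))
    names(fl) <- retained
    fl
  })
  names(fits) <- config$protocols

  variability <- do.call(rbind, lapply(config$protocols, function(p)
    do.call(rbind, lapply(retained, function(f) {
      sv <- summarizeVariability(fits[[p]][[f]])
      data.frame(protocol = p, feature = f,
                 sigma_total_rel = sv$sigma_total_rel,
                 prop_manufacturer = sv$proportions[["manufacturer"]],
                 prop_scanner = sv$proportions[["scanner"]],
                 prop_residual = sv$proportions[["residual"]])
    }))))

  cohort_stats <- lapply(names(config$cohorts), function(cn)
    .cohortStatsFromConfig(config, cn))
  names(cohort_stats) <- names(config$cohorts)

  iv <- do.call(rbind, lapply(config$protocols, function(p)
    do.call(rbind, lapply(names(cohort_stats), function(cn)
      do.call(rbind, lapply(retained, function(f) {
        r <- imagingVariability(fits[[p]][[f]], cohort_stats[[cn]],
                                cutoff = config$iv_cutoff)
        cbind(protocol = p, r)
      }))))))

  comparisons <- NULL
  if ("controlled" %in% config$protocols && length(local_prot)) {
    comparisons <- do.call(rbind, lapply(local_prot, function(p) {
      cmp <- compareProtocolVariability(fits[["controlled"]], fits[[p]])
      cbind(local_protocol = p, cmp)
    }))
  }

  ratios <- NULL
  if ("controlled" %in% config$protocols && length(local_prot)) {
    vc <- variability[variability$protocol == "controlled", ]
    ratios <- vapply(local_prot, function(p) {
      vl <- variability[variability$protocol == p, ]
      mean(vc$sigma_total_rel[match(retained, vc$feature)] /
             vl$sigma_total_rel[match(retained, vl$feature)])
    }, numeric(1))
  }

  qa <- NULL
  if ("controlled" %in% config$protocols) {
    fhat <- qaPopulationMeans(tables[["controlled"]],
                              preprocessing = "t")
    qa <- lapply(names(cohort_stats), function(cn) {
      b <- qaBounds(cohort_stats[[cn]],
                    merge(fhat, data.frame(feature = retained)),
                    bound_factor = config$bound_factor)
      qaTally(tables[["controlled"]], b, feature_subset = retained,
              subset_label = paste0("stable features (", cn, ")"))
    })
    names(qa) <- names(cohort_stats)
  }

  res <- list(tables = tables, stability = stability,
              thickness = thick_cor, icc = icc_tab, fits = fits,
              variability = variability, iv = iv,
              comparisons = comparisons, qa = qa, ratios = ratios,
              cohort_stats = cohort_stats, retained = retained,
              config = config)
  if (!is.null(outdir)) .persistStudy(res, outdir)
  res
}

.persistStudy <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(res$tables))
    writeFeatureTable(res$tables[[p]],
                      file.path(outdir, paste0("features_", p, ".csv")))
  write.csv(res$stability@summary,
            file.path(outdir, "stability_summary.csv"), row.names = FALSE)
  write.csv(res$stability@instances,
            file.path(outdir, "stability_instances.csv"),
            row.names = FALSE)
  if (!is.null(res$thickness))
    write.csv(res$thickness,
              file.path(outdir, "thickness_correlation.csv"),
              row.names = FALSE)
  if (!is.null(res$icc))
    write.csv(res$icc, file.path(outdir, "icc.csv"), row.names = FALSE)
  write.csv(res$variability, file.path(outdir, "variability.csv"),
            row.names = FALSE)
  write.csv(res$iv, file.path(outdir, "imaging_variability.csv"),
            row.names = FALSE)
  if (!is.null(res$comparisons))
    write.csv(res$comparisons,
              file.path(outdir, "protocol_comparisons.csv"),
              row.names = FALSE)
  if (!is.null(res$qa))
    for (cn in names(res$qa))
      write.csv(qaTallyTable(res$qa[[cn]]),
                file.path(outdir, paste0("qa_tally_", cn, ".csv")),
                row.names = FALSE)
  invisible(outdir)
}
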