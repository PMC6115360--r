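# Central S4 classes. Axis order is (x, y, z) throughout; spacing in mm;
# intensities in HU.

#' ImageVolume: a 3D HU voxel grid with physical spacing
#'
#' The unit consumed by preprocessing and feature extraction. Voxel
#' \code{[i, j, k]} (1-based array index) has its center at
#' \code{origin + (c(i, j, k) - 1) * spacing} in mm.
#'
#' @slot voxels 3D numeric array of HU values (may contain \code{NA} for
#'   voxels excluded from an ROI).
#' @slot spacing Numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @slot origin Numeric length-3, mm position of the first voxel center.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3)
      return("voxels must be a 3D array")
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3 || any(!is.finite(object@origin)))
      return("origin must be 3 finite values (mm)")
    TRUE
  })

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param origin mm position of the first voxel center.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- ImageVolume(array(0, c(8, 8, 4)), spacing = c(1, 1, 3))
#' voxelSpacing(vol)
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' CylindricalROI: a z-axis cylinder in physical coordinates
#'
#' @slot center mm triple, cylinder center.
#' @slot diameter mm.
#' @slot height mm (z extent).
#' @export
setClass("CylindricalROI",
  representation(center = "numeric", diameter = "numeric",
                 height = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3) return("center must be length 3 (mm)")
    if (object@diameter <= 0) return("diameter must be > 0")
    if (object@height <= 0) return("height must be > 0")
    TRUE
  })

#' Construct a CylindricalROI
#'
#' The default geometry mirrors the phantom analysis ROIs: 8.2 cm
#' diameter, 2 cm height, axis along z.
#'
#' @param center mm triple.
#' @param diameter mm; default 82.
#' @param height mm; default 20.
#' @return A \linkS4class{CylindricalROI}.
#' @export
CylindricalROI <- function(center, diameter = 82, height = 20) {
  new("CylindricalROI", center = as.numeric(center),
      diameter = as.numeric(diameter), height = as.numeric(height))
}

.FT_COLUMNS <- c("manufacturer", "scanner", "protocol", "material",
                 "thickness_mm", "preprocessing", "feature", "value")

#' FeatureTable: long-format feature records
#'
#' The pipeline's central exchange object: one row per (scanner, material,
#' preprocessing, feature) with the feature value and acquisition
#' metadata. Extra columns (e.g. \code{shift} for ROI-shift tables) are
#' allowed.
#'
#' @slot records data.frame with at least the canonical columns
#'   \code{manufacturer, scanner, protocol, material, thickness_mm,
#'   preprocessing, feature, value}.
#' @slot metadata Free-form list (e.g. the generating random effects of a
#'   simulated table, kept for parameter-recovery tests).
#' @export
setClass("FeatureTable",
  representation(records = "data.frame", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    missing <- setdiff(.FT_COLUMNS, names(object@records))
    if (length(missing))
      return(paste("records is missing columns:",
                   paste(missing, collapse = ", ")))
    if (!is.numeric(object@records$value))
      return("value column must be numeric")
    TRUE
  })

#' Construct a FeatureTable
#'
#' @param records data.frame of long-format feature records.
#' @param metadata Optional list of provenance metadata.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(records, metadata = list()) {
  new("FeatureTable", records = as.data.frame(records), metadata = metadata)
}

#' PatientCohortStats: per-feature patient mean and SD
#'
#' The denominator of the imaging-variability metrics and the source of
#' the QA bounds.
#'
#' @slot cohort Cohort label (e.g. "NSCLC").
#' @slot stats data.frame with columns \code{feature, mu_p, sigma_p}.
#' @export
setClass("PatientCohortStats",
  representation(cohort = "character", stats = "data.frame"),
  validity = function(object) {
    need <- c("feature", "mu_p", "sigma_p")
    if (!all(need %in% names(object@stats)))
      return("stats needs columns feature, mu_p, sigma_p")
    if (any(object@stats$sigma_p < 0, na.rm = TRUE))
      return("sigma_p must be >= 0")
    TRUE
  })

#' Construct PatientCohortStats
#'
#' @param cohort Cohort label.
#' @param stats data.frame with columns \code{feature, mu_p, sigma_p}.
#' @return A \linkS4class{PatientCohortStats}.
#' @export
PatientCohortStats <- function(cohort, stats) {
  new("PatientCohortStats", cohort = cohort, stats = as.data.frame(stats))
}

#' VarianceComponents: relative SDs of the variability sources
#'
#' Relative (mean-scaled) standard deviations: the absolute SD for
#' material m recovers as \code{sigma * materialMeans[m]}.
#'
#' @slot sigma_gamma Manufacturer-wise relative SD.
#' @slot sigma_beta Scanner-within-manufacturer relative SD.
#' @slot sigma_eps Residual relative SD.
#' @slot material_means Named numeric, per-material mean feature value
#'   \eqn{\hat f_m}.
#' @export
setClass("VarianceComponents",
  representation(sigma_gamma = "numeric", sigma_beta = "numeric",
                 sigma_eps = "numeric", material_means = "numeric"),
  validity = function(object) {
    s <- c(object@sigma_gamma, object@sigma_beta, object@sigma_eps)
    if (any(s < 0, na.rm = TRUE)) return("relative SDs must be >= 0")
    TRUE
  })

#' Construct VarianceComponents
#'
#' @param sigma_gamma,sigma_beta,sigma_eps Relative SDs (manufacturer,
#'   scanner, residual).
#' @param material_means Named numeric of per-material means.
#' @return A \linkS4class{VarianceComponents}.
#' @export
VarianceComponents <- function(sigma_gamma, sigma_beta, sigma_eps,
                               material_means = c(material = 1)) {
  new("VarianceComponents", sigma_gamma = sigma_gamma,
      sigma_beta = sigma_beta, sigma_eps = sigma_eps,
      material_means = material_means)
}

#' VarianceModelFit: fitted mean-scaled mixed-effects model
#'
#' @slot feature Feature name.
#' @slot protocol Protocol the fit used.
#' @slot mu Grand mean on the relative scale.
#' @slot material_effects Named numeric, per-material fixed effects
#'   (relative scale; ~0 by construction after mean scaling).
#' @slot thickness_slope Fixed-effect slope per mm (relative scale);
#'   \code{NA} when thickness was constant.
#' @slot thickness_slope_se Standard error of the slope.
#' @slot vendor_effects Named numeric, predicted manufacturer effects.
#' @slot components \linkS4class{VarianceComponents}.
#' @slot collapsed Character vector of components collapsed to 0
#'   ("manufacturer" and/or "scanner").
#' @slot n_obs Number of records used.
#' @slot fit The underlying lme4 / lm fit (or NULL).
#' @export
setClass("VarianceModelFit",
  representation(feature = "character", protocol = "character",
                 mu = "numeric", material_effects = "numeric",
                 thickness_slope = "numeric", thickness_slope_se = "numeric",
                 vendor_effects = "numeric",
                 components = "VarianceComponents",
                 collapsed = "character", n_obs = "integer", fit = "ANY"))

#' StabilityScreen: result of the ROI-shift CoV screen
#'
#' @slot instances data.frame with one row per (feature, preprocessing,
#'   material) instance: \code{cov}, \code{exceeds}.
#' @slot summary data.frame with one row per feature: \code{n_instances},
#'   \code{n_exceeding}, \code{pass}.
#' @slot cov_cutoff CoV threshold (default 0.10).
#' @slot fail_fraction Fraction of instances that must be exceeded
#'   (strictly) for removal (default 0.5).
#' @export
setClass("StabilityScreen",
  representation(instances = "data.frame", summary = "data.frame",
                 cov_cutoff = "numeric", fail_fraction = "numeric"),
  validity = function(object) {
    s <- object@summary
    if (nrow(s) && any(s$n_exceeding > s$n_instances))
      return("n_exceeding cannot exceed n_instances")
    TRUE
  })

#' ICCResult: intraclass correlation coefficients for one feature
#'
#' @slot icc_2_1 ICC(2,1): two-way random effects, absolute agreement,
#'   single measurement.
#' @slot icc_3_1 ICC(3,1): two-way random effects, consistency, single
#'   measurement.
#' @slot category_2_1,category_3_1 Reliability category
#'   (poor/moderate/good/excellent).
#' @slot degenerate TRUE when the between-subject variance vanished and
#'   the ICCs were reported as 0 by convention.
#' @export
setClass("ICCResult",
  representation(icc_2_1 = "numeric", icc_3_1 = "numeric",
                 category_2_1 = "character", category_3_1 = "character",
                 degenerate = "logical"),
  validity = function(object) {
    if (any(c(object@icc_2_1, object@icc_3_1) > 1 + 1e-8, na.rm = TRUE))
      return("ICC cannot exceed 1")
    TRUE
  })

#' QAReport: phantom-based credentialing tallies
#'
#' @slot bounds data.frame of per-feature (and optionally per-material)
#'   QA bounds: \code{feature, f_hat, sigma_scaled, lower, upper}.
#' @slot tally data.frame with one row per (scanner, material):
#'   \code{n_outside, n_eval, pct_outside}.
#' @slot feature_subset Label describing which feature subset was used.
#' @slot bound_factor The fraction of the scaled patient SD used for the
#'   bounds (default 1/3).
#' @export
setClass("QAReport",
  representation(bounds = "data.frame", tally = "data.frame",
                 feature_subset = "character", bound_factor = "numeric"),
  validity = function(object) {
    t <- object@tally
    if (nrow(t) && (any(t$pct_outside < 0) || any(t$pct_outside > 100)))
      return("pct_outside must be in [0, 100]")
    TRUE
  })
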