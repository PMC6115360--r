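# Generics and accessor/show methods for the core classes.

#' @rdname ImageVolume-class
#' @param x An object.
#' @export
setGeneric("voxelArray", function(x) standardGeneric("voxelArray"))
#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname ImageVolume-class
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))

#' @rdname ImageVolume-class
#' @aliases voxelArray,ImageVolume-method
setMethod("voxelArray", "ImageVolume", function(x) x@voxels)
#' @rdname ImageVolume-class
#' @aliases voxelSpacing,ImageVolume-method
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname ImageVolume-class
#' @aliases volumeOrigin,ImageVolume-method
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  v <- object@voxels[!is.na(object@voxels)]
  if (length(v))
    cat(sprintf("  HU range [%.1f, %.1f], mean %.1f (%d NA voxels)\n",
                min(v), max(v), mean(v), sum(is.na(object@voxels))))
})

setMethod("show", "CylindricalROI", function(object) {
  cat(sprintf(
    "CylindricalROI: center (%s) mm, diameter %.1f mm, height %.1f mm\n",
    paste(format(object@center, digits = 4), collapse = ", "),
    object@diameter, object@height))
})

#' @rdname FeatureTable-class
#' @param x An object.
#' @export
setGeneric("featureRecords", function(x) standardGeneric("featureRecords"))
#' @rdname FeatureTable-class
#' @aliases featureRecords,FeatureTable-method
setMethod("featureRecords", "FeatureTable", function(x) x@records)

#' @rdname FeatureTable-class
#' @param row.names,optional,... passed on per the generic.
#' @export
as.data.frame.FeatureTable <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  x@records
}

setMethod("show", "FeatureTable", function(object) {
  r <- object@records
  cat(sprintf(
    "FeatureTable: %d records | %d features | %d scanners | %d materials\n",
    nrow(r), length(unique(r$feature)), length(unique(r$scanner)),
    length(unique(r$material))))
  cat("  protocols:", paste(unique(r$protocol), collapse = ", "),
      "| preprocessing:", paste(unique(r$preprocessing), collapse = ", "),
      "\n")
})

setMethod("show", "PatientCohortStats", function(object) {
  cat(sprintf("PatientCohortStats '%s': %d features\n", object@cohort,
              nrow(object@stats)))
})

#' @rdname PatientCohortStats-class
#' @param x An object.
#' @export
setGeneric("cohortStats", function(x) standardGeneric("cohortStats"))
#' @rdname PatientCohortStats-class
#' @aliases cohortStats,PatientCohortStats-method
setMethod("cohortStats", "PatientCohortStats", function(x) x@stats)

#' @rdname VarianceModelFit-class
#' @param x An object.
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))
#' @rdname VarianceModelFit-class
#' @aliases varianceComponents,VarianceModelFit-method
setMethod("varianceComponents", "VarianceModelFit",
          function(x) x@components)

#' @rdname VarianceComponents-class
#' @param x An object.
#' @export
setGeneric("materialMeans", function(x) standardGeneric("materialMeans"))
#' @rdname VarianceComponents-class
#' @aliases materialMeans,VarianceComponents-method
setMethod("materialMeans", "VarianceComponents",
          function(x) x@material_means)

#' Relative SDs of a variance decomposition
#'
#' @param x A \linkS4class{VarianceComponents} or
#'   \linkS4class{VarianceModelFit}.
#' @return Named numeric \code{c(sigma_gamma, sigma_beta, sigma_eps)} on
#'   the relative (mean-scaled) scale.
#' @export
setGeneric("relativeSigmas", function(x) standardGeneric("relativeSigmas"))
#' @rdname relativeSigmas
#' @aliases relativeSigmas,VarianceComponents-method
setMethod("relativeSigmas", "VarianceComponents", function(x) {
  c(sigma_gamma = x@sigma_gamma, sigma_beta = x@sigma_beta,
    sigma_eps = x@sigma_eps)
})
#' @rdname relativeSigmas
#' @aliases relativeSigmas,VarianceModelFit-method
setMethod("relativeSigmas", "VarianceModelFit",
          function(x) relativeSigmas(x@components))

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents (relative scale): gamma=%.4g beta=%.4g eps=%.4g\n",
    object@sigma_gamma, object@sigma_beta, object@sigma_eps))
})

setMethod("show", "VarianceModelFit", function(object) {
  cat(sprintf("VarianceModelFit: feature '%s', protocol '%s', n=%d\n",
              object@feature, object@protocol, object@n_obs))
  show(object@components)
  if (length(object@collapsed))
    cat("  collapsed components:",
        paste(object@collapsed, collapse = ", "), "\n")
  if (!is.na(object@thickness_slope))
    cat(sprintf("  thickness slope: %.4g per mm (SE %.3g)\n",
                object@thickness_slope, object@thickness_slope_se))
})

#' Features removed / retained by a stability screen
#'
#' @param x A \linkS4class{StabilityScreen}.
#' @return Character vector of feature names.
#' @export
setGeneric("excludedFeatures",
           function(x) standardGeneric("excludedFeatures"))
#' @rdname excludedFeatures
#' @aliases excludedFeatures,StabilityScreen-method
setMethod("excludedFeatures", "StabilityScreen", function(x) {
  x@summary$feature[!x@summary$pass]
})

#' @rdname excludedFeatures
#' @export
setGeneric("retainedFeatures",
           function(x) standardGeneric("retainedFeatures"))
#' @rdname excludedFeatures
#' @aliases retainedFeatures,StabilityScreen-method
setMethod("retainedFeatures", "StabilityScreen", function(x) {
  x@summary$feature[x@summary$pass]
})

setMethod("show", "StabilityScreen", function(object) {
  cat(sprintf(
    "StabilityScreen: %d features, %d removed (CoV > %.0f%% in > %.0f%% of instances)\n",
    nrow(object@summary), sum(!object@summary$pass),
    100 * object@cov_cutoff, 100 * object@fail_fraction))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(2,1) = %.3f [%s]; ICC(3,1) = %.3f [%s]%s\n",
              object@icc_2_1, object@category_2_1, object@icc_3_1,
              object@category_3_1,
              if (object@degenerate) " (degenerate ANOVA)" else ""))
})

setMethod("show", "QAReport", function(object) {
  cat(sprintf(
    "QAReport: %d scanner x material tallies, %d feature bounds (subset: %s, factor %.3g)\n",
    nrow(object@tally), nrow(object@bounds), object@feature_subset,
    object@bound_factor))
})

#' @rdname QAReport-class
#' @param x An object.
#' @export
setGeneric("qaTallyTable", function(x) standardGeneric("qaTallyTable"))
#' @rdname QAReport-class
#' @aliases qaTallyTable,QAReport-method
setMethod("qaTallyTable", "QAReport", function(x) x@tally)

#' @rdname QAReport-class
#' @export
setGeneric("qaBoundsTable", function(x) standardGeneric("qaBoundsTable"))
#' @rdname QAReport-class
#' @aliases qaBoundsTable,QAReport-method
setMethod("qaBoundsTable", "QAReport", function(x) x@bounds)
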