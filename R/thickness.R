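# Image-thickness dependence: per-ROI-feature Pearson correlation with
# thickness, and intraclass correlation across z-resampling options.

#' Pearson correlation of feature values with image thickness
#'
#' For every (material ROI, feature) combination the absolute Pearson
#' correlation between the feature value and the image thickness across
#' scanners. Zero-variance features (or constant thickness) give
#' \code{NA}.
#'
#' @param table \linkS4class{FeatureTable} or data.frame of local-protocol
#'   records with varying \code{thickness_mm}.
#' @return data.frame with columns \code{material, feature, abs_rho, n};
#'   use \code{\link{meanAbsRho}} for the study-level summary.
#' @export
thicknessCorrelation <- function(table) {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  .stopifnot1(length(unique(rec$thickness_mm)) >= 3,
              "need >= 3 distinct thickness values")
  key <- interaction(rec$material, rec$feature, drop = TRUE)
  out <- do.call(rbind, lapply(split(rec, key), function(d) {
    rho <- if (sd(d$value) == 0 || sd(d$thickness_mm) == 0) NA_real_
      else abs(cor(d$value, d$thickness_mm))
    data.frame(material = d$material[1], feature = d$feature[1],
               abs_rho = rho, n = nrow(d), row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Mean absolute thickness correlation
#'
#' @param correlations Output of \code{\link{thicknessCorrelation}}.
#' @param exclude_glrlm Drop run-length features before averaging
#'   (the run-length family correlates with thickness differently, so a
#'   secondary summary without it is reported alongside).
#' @return Mean |rho| over the retained ROI-feature combinations.
#' @export
meanAbsRho <- function(correlations, exclude_glrlm = FALSE) {
  d <- correlations
  if (exclude_glrlm)
    d <- d[featureCategories(d$feature) != "glrlm", , drop = FALSE]
  mean(d$abs_rho, na.rm = TRUE)
}

#' Intraclass correlation coefficients ICC(2,1) and ICC(3,1)
#'
#' Shrout-Fleiss two-way random-effects single-measurement forms,
#' computed from the two-way ANOVA mean squares of a complete
#' subjects x raters matrix:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   k (MS_C - MS_E)/n}}
#' \deqn{ICC(3,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E}}
#' Here "raters" are the eight z-resampling options and "subjects" are
#' scanner x ROI combinations. A degenerate ANOVA (no between-subject
#' variance) reports both ICCs as 0 with the \code{degenerate} flag set.
#'
#' @param mat Numeric matrix, subjects in rows, raters/measurement
#'   conditions in columns; no missing cells.
#' @return An \linkS4class{ICCResult}.
#' @examples
#' m <- matrix(rnorm(48), 6, 8)
#' iccAgreement(m + 2 * rowMeans(m))
#' @export
iccAgreement <- function(mat) {
  mat <- as.matrix(mat)
  .stopifnot1(nrow(mat) >= 2 && ncol(mat) >= 2,
              "ICC needs >= 2 subjects and >= 2 raters")
  .stopifnot1(!anyNA(mat), "ICC input must have no missing cells")
  n <- nrow(mat); k <- ncol(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat); g <- mean(mat)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  mse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2) / ((n - 1) * (k - 1))
  tol <- 1e-12 * max(1, g^2)
  if (msr < tol && mse < tol) {
    return(new("ICCResult", icc_2_1 = 0, icc_3_1 = 0,
               category_2_1 = "poor", category_3_1 = "poor",
               degenerate = TRUE))
  }
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc31 <- (msr - mse) / (msr + (k - 1) * mse)
  new("ICCResult", icc_2_1 = icc21, icc_3_1 = icc31,
      category_2_1 = classifyReliability(icc21),
      category_3_1 = classifyReliability(icc31),
      degenerate = FALSE)
}

#' Classify ICC reliability
#'
#' Koo-Li style categories: below 0.5 poor, [0.5, 0.75) moderate,
#' [0.75, 0.9) good, 0.9 and above excellent (boundaries go to the upper
#' category).
#'
#' @param icc Numeric vector of ICC values (<= 1).
#' @return Character vector of categories.
#' @examples
#' classifyReliability(c(0.3, 0.6, 0.8, 0.95))
#' @export
classifyReliability <- function(icc) {
  .stopifnot1(all(icc <= 1 + 1e-8, na.rm = TRUE), "ICC cannot exceed 1")
  as.character(cut(icc, c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
                   labels = c("poor", "moderate", "good", "excellent")))
}

#' Feature values across z-resampling options
#'
#' Computes, for one masked phantom volume, the feature vector without z
#' resampling and after resampling to 1..7 mm, giving the
#' subjects x 8-options input for \code{\link{iccAgreement}} when stacked
#' over scanners/ROIs.
#'
#' @param volume \linkS4class{ImageVolume}.
#' @param roi \linkS4class{CylindricalROI}.
#' @param dz_values z spacings to resample to; default 1:7 mm.
#' @param chain Preprocessing chain (default "t", thresholding only).
#' @param ... Passed to \code{\link{extractFeatureVector}}.
#' @return Matrix: features x (1 + length(dz_values)) resampling options.
#' @export
resamplingFeatureMatrix <- function(volume, roi, dz_values = 1:7,
                                    chain = "t", ...) {
  base <- extractFeatureVector(volume, roi, chain = chain, ...)
  cols <- vapply(dz_values, function(dz) {
    extractFeatureVector(resampleZ(volume, dz), roi, chain = chain, ...)
  }, numeric(length(base)))
  out <- cbind(none = base, cols)
  colnames(out) <- c("none", paste0("dz", dz_values))
  out
}
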