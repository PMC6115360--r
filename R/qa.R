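# Phantom-based QA credentialing: scaled patient SD, bounds, and
# per-scanner out-of-bounds tallies.

#' QA bounds from scaled patient standard deviations
#'
#' For every feature the patient SD is scaled to the phantom scale,
#' \eqn{\sigma_{scaled} = (\sigma_p / \mu_p) \hat f}, and the bounds are
#' \eqn{\hat f \pm \sigma_{scaled} / 3} (the 1/3 factor is configurable).
#' Signed-mean features use \eqn{|\sigma_{scaled}|} so the bounds always
#' bracket \eqn{\hat f}. Features with \eqn{\mu_p = 0} are skipped with a
#' warning.
#'
#' @param cohort \linkS4class{PatientCohortStats}.
#' @param f_hat Named numeric of population mean feature values over the
#'   credentialed (controlled-protocol) scanners, or a data.frame with
#'   columns \code{feature, f_hat} and optionally \code{material}.
#' @param bound_factor Fraction of the scaled SD; default 1/3.
#' @return data.frame: \code{feature, (material,) f_hat, sigma_scaled,
#'   lower, upper}.
#' @examples
#' cs <- PatientCohortStats("NSCLC",
#'   data.frame(feature = "f", mu_p = 10, sigma_p = 3))
#' qaBounds(cs, c(f = 100))  # sigma_scaled 30, bounds (90, 110)
#' @export
qaBounds <- function(cohort, f_hat, bound_factor = 1 / 3) {
  st <- cohort@stats
  if (is.numeric(f_hat)) {
    fh <- data.frame(feature = names(f_hat), f_hat = as.numeric(f_hat))
  } else {
    fh <- as.data.frame(f_hat)
    .stopifnot1(all(c("feature", "f_hat") %in% names(fh)),
                "f_hat data.frame needs columns feature, f_hat")
  }
  m <- match(fh$feature, st$feature)
  .stopifnot1(!anyNA(m), "cohort stats missing some features")
  mu_p <- st$mu_p[m]; sigma_p <- st$sigma_p[m]
  zero <- mu_p == 0
  if (any(zero)) {
    warning("skipping features with mu_p = 0: ",
            paste(unique(fh$feature[zero]), collapse = ", "))
    fh <- fh[!zero, , drop = FALSE]
    mu_p <- mu_p[!zero]; sigma_p <- sigma_p[!zero]
  }
  sigma_scaled <- abs(sigma_p / mu_p * fh$f_hat)
  out <- fh
  out$sigma_scaled <- sigma_scaled
  out$lower <- fh$f_hat - bound_factor * sigma_scaled
  out$upper <- fh$f_hat + bound_factor * sigma_scaled
  out
}

#' Population mean feature values from controlled scans
#'
#' @param table \linkS4class{FeatureTable} of controlled-protocol
#'   records.
#' @param by_material Compute per (feature, material) means (default
#'   TRUE, matching the per-cartridge QA analysis).
#' @param preprocessing Optional preprocessing chain to subset to.
#' @return data.frame with columns \code{feature, (material,) f_hat}.
#' @export
qaPopulationMeans <- function(table, by_material = TRUE,
                              preprocessing = NULL) {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  if (!is.null(preprocessing))
    rec <- rec[rec$preprocessing %in% preprocessing, ]
  if (by_material) {
    out <- aggregate(value ~ feature + material, data = rec, FUN = mean)
  } else {
    out <- aggregate(value ~ feature, data = rec, FUN = mean)
  }
  names(out)[names(out) == "value"] <- "f_hat"
  out
}

#' Tally features outside the QA bounds per scanner and material
#'
#' For every scanner and material, counts the features whose
#' controlled-scan value falls strictly outside \code{[lower, upper]}
#' (boundary values count as inside). Missing feature values are counted
#' as missing, not as failures.
#'
#' @param table \linkS4class{FeatureTable} of controlled-protocol scans.
#' @param bounds Output of \code{\link{qaBounds}} (per feature, or per
#'   feature and material).
#' @param feature_subset Optional character vector restricting the tally
#'   (e.g. stable features, or a survival-correlated panel).
#' @param subset_label Label recorded in the report.
#' @return A \linkS4class{QAReport}.
#' @export
qaTally <- function(table, bounds, feature_subset = NULL,
                    subset_label = if (is.null(feature_subset)) "all"
                    else "subset") {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  if (!is.null(feature_subset)) {
    rec <- rec[rec$feature %in% feature_subset, ]
    .stopifnot1(all(feature_subset %in% bounds$feature),
                "bounds missing for some features in the subset")
  }
  rec <- rec[rec$feature %in% bounds$feature, ]
  .stopifnot1(nrow(rec) > 0, "no records to tally")
  by_material <- "material" %in% names(bounds)
  if (by_material) {
    m <- match(paste(rec$feature, rec$material),
               paste(bounds$feature, bounds$material))
  } else {
    m <- match(rec$feature, bounds$feature)
  }
  rec <- rec[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  outside <- !is.na(rec$value) &
    (rec$value < bounds$lower[m] | rec$value > bounds$upper[m])
  evaluable <- !is.na(rec$value)
  key <- interaction(rec$scanner, rec$material, drop = TRUE)
  tal <- do.call(rbind, lapply(split(seq_len(nrow(rec)), key), function(ii)
    data.frame(scanner = rec$scanner[ii[1]],
               material = rec$material[ii[1]],
               n_outside = sum(outside[ii]),
               n_eval = sum(evaluable[ii]),
               pct_outside = 100 * sum(outside[ii]) /
                 max(sum(evaluable[ii]), 1),
               row.names = NULL)))
  rownames(tal) <- NULL
  bf <- (bounds$upper[1] - bounds$f_hat[1]) /
    max(bounds$sigma_scaled[1], .Machine$double.eps)
  new("QAReport", bounds = bounds, tally = tal,
      feature_subset = subset_label,
      bound_factor = if (bounds$sigma_scaled[1] > 0) bf else 1 / 3)
}
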