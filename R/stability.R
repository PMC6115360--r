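# ROI-shift coefficient-of-variation stability screen: features whose
# value depends strongly on where the ROI sits inside the cartridge are
# removed before the variability analysis.

#' Randomly shifted copies of a cylindrical ROI
#'
#' Samples \code{n} ROIs whose centers are uniform in the largest box of
#' center positions that keeps the cylinder inside the allowed region.
#' When the region is exactly ROI-sized every shift equals the base ROI.
#'
#' @param base A \linkS4class{CylindricalROI}.
#' @param allowed_region List with mm triples \code{lower} and
#'   \code{upper}: the region the ROI must stay inside.
#' @param n Number of shifted ROIs (default 10).
#' @param seed RNG seed.
#' @return List of \code{n} \linkS4class{CylindricalROI}s.
#' @export
shiftROIs <- function(base, allowed_region, n = 10, seed = NULL) {
  lo <- allowed_region$lower; up <- allowed_region$upper
  .stopifnot1(length(lo) == 3 && length(up) == 3,
              "allowed_region needs mm triples lower and upper")
  half <- c(base@diameter / 2, base@diameter / 2, base@height / 2)
  cmin <- lo + half
  cmax <- up - half
  .stopifnot1(all(cmax - cmin >= -1e-9),
              "allowed region too small for the ROI")
  .stopifnot1(all(base@center >= cmin - 1e-9) &&
                all(base@center <= cmax + 1e-9),
              "allowed region does not contain the base ROI")
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      ctr <- cmin + runif(3) * pmax(cmax - cmin, 0)
      CylindricalROI(ctr, diameter = base@diameter, height = base@height)
    })
  })
}

#' Coefficient-of-variation stability screen over ROI shifts
#'
#' For every (feature, preprocessing, material) instance the CoV is the
#' sample SD over shifts divided by |sample mean|; an instance with
#' |mean| below the numeric floor is unstable by definition. A feature is
#' removed iff strictly more than \code{fail_fraction} of its instances
#' have CoV above \code{cov_cutoff} (the boundary case "exactly half"
#' passes).
#'
#' @param table \linkS4class{FeatureTable} (or data.frame) of feature
#'   values across ROI shifts; must contain >= 2 shifts per instance.
#' @param cov_cutoff CoV threshold; default 0.10.
#' @param fail_fraction Instance fraction that must be exceeded strictly;
#'   default 0.5.
#' @param mean_floor |mean| below this counts as unstable; default 1e-12.
#' @return A \linkS4class{StabilityScreen}.
#' @export
covScreen <- function(table, cov_cutoff = 0.10, fail_fraction = 0.5,
                      mean_floor = 1e-12) {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  key <- interaction(rec$feature, rec$preprocessing, rec$material,
                     drop = TRUE)
  pieces <- split(rec, key)
  .stopifnot1(all(vapply(pieces, nrow, 1L) >= 2),
              "every instance needs >= 2 shifts")
  inst <- do.call(rbind, lapply(pieces, function(d) {
    m <- mean(d$value)
    s <- sd(d$value)
    cv <- if (abs(m) < mean_floor) Inf else s / abs(m)
    data.frame(feature = d$feature[1], preprocessing = d$preprocessing[1],
               material = d$material[1], mean = m, sd = s, cov = cv,
               exceeds = cv > cov_cutoff, row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(split(inst, inst$feature), function(d)
    data.frame(feature = d$feature[1], n_instances = nrow(d),
               n_exceeding = sum(d$exceeds),
               pass = sum(d$exceeds) <= fail_fraction * nrow(d),
               row.names = NULL)))
  rownames(summ) <- NULL
  new("StabilityScreen", instances = inst, summary = summ,
      cov_cutoff = cov_cutoff, fail_fraction = fail_fraction)
}
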