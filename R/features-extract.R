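# Orchestrated feature extraction: preprocessing chains applied in the
# fixed order threshold -> smoothing -> bit-depth rescale, then the 49
# features per chain.

.PREPROCESS_CHAINS <- c("t", "ts", "tb", "tsb")

# Chain flags: every chain thresholds (a no-op when no thresholds are
# given, as for phantom scans); "s" adds Butterworth smoothing, "b" adds
# 8-bit depth rescaling.
.chainFlags <- function(chain) {
  .stopifnot1(chain %in% .PREPROCESS_CHAINS,
              paste("unknown preprocessing chain:", chain))
  list(smooth = grepl("s", chain), rescale = grepl("b", chain))
}

#' Extract the 49 features from one ROI under one preprocessing chain
#'
#' The preprocessing order is fixed: thresholding decides ROI-voxel
#' membership from the unsmoothed HU values, Butterworth smoothing is
#' applied to the full image, and 8-bit depth rescaling acts on the
#' (smoothed) values of the member voxels. Matrix features on
#' non-rescaled chains use 1-HU integer bins (rounded HU shifted to a
#' 1-based level scale).
#'
#' @param volume \linkS4class{ImageVolume} (already resampled in-plane if
#'   required).
#' @param roi \linkS4class{CylindricalROI}.
#' @param chain One of \code{"t"} (threshold only), \code{"ts"}
#'   (+ smoothing), \code{"tb"} (+ bit-depth rescale), \code{"tsb"}.
#' @param threshold_low,threshold_high HU thresholds (\code{NA} = none;
#'   phantom scans use none).
#' @param butterworth_order,butterworth_cutoff Smoothing parameters.
#' @return Named numeric vector of 49 features.
#' @export
extractFeatureVector <- function(volume, roi, chain = "t",
                                 threshold_low = NA, threshold_high = NA,
                                 butterworth_order = 2,
                                 butterworth_cutoff = 125) {
  fl <- .chainFlags(chain)
  masked_raw <- maskROI(volume, roi)
  member <- applyThreshold(masked_raw@voxels, threshold_low,
                           threshold_high)
  if (fl$smooth) {
    sm <- butterworthSmooth(volume, order = butterworth_order,
                            cutoff = butterworth_cutoff)
    vals <- maskROI(sm, roi)@voxels
    vals[is.na(member)] <- NA_real_
  } else {
    vals <- member
  }
  if (fl$rescale) {
    lev <- rescaleBitDepth(vals)
    ivals <- lev
  } else {
    r <- round(vals)
    lev <- r - min(r, na.rm = TRUE) + 1
    ivals <- vals
  }
  c(glcmFeatures(lev), glrlmFeatures(lev),
    intensityFeatures(as.vector(ivals[!is.na(ivals)]),
                      levels = as.vector(lev[!is.na(lev)])),
    ngtdmFeatures(lev))
}

#' Extract a long-format feature table from volumes and ROIs
#'
#' One record per (scanner, material, preprocessing, feature).
#' Local-protocol volumes (non-1 mm in-plane grids) are resampled
#' in-plane to 1 mm first; phantom extraction passes no thresholds.
#'
#' @param volumes List of \linkS4class{ImageVolume}s.
#' @param rois List of \linkS4class{CylindricalROI}s, one per volume.
#' @param metadata data.frame with one row per volume: columns
#'   \code{manufacturer, scanner, protocol, material, thickness_mm}.
#' @param chains Preprocessing chains to run (default all four).
#' @param threshold_low,threshold_high HU thresholds (\code{NA} = none).
#' @param resample_inplane Resample in-plane grids to 1 mm when they are
#'   not already (default TRUE).
#' @return A \linkS4class{FeatureTable}.
#' @export
extractFeatureTable <- function(volumes, rois, metadata,
                                chains = .PREPROCESS_CHAINS,
                                threshold_low = NA, threshold_high = NA,
                                resample_inplane = TRUE) {
  metadata <- as.data.frame(metadata)
  need <- c("manufacturer", "scanner", "protocol", "material",
            "thickness_mm")
  missing <- setdiff(need, names(metadata))
  .stopifnot1(length(missing) == 0,
              paste("metadata is missing fields:",
                    paste(missing, collapse = ", ")))
  .stopifnot1(length(volumes) == nrow(metadata) &&
                length(rois) == nrow(metadata),
              "volumes, rois and metadata rows must align")
  out <- vector("list", nrow(metadata) * length(chains))
  idx <- 1L
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    if (resample_inplane &&
        !isTRUE(all.equal(vol@spacing[1:2], c(1, 1)))) {
      vol <- resampleXY(vol, 1)
    }
    for (ch in chains) {
      fv <- extractFeatureVector(vol, rois[[v]], chain = ch,
                                 threshold_low = threshold_low,
                                 threshold_high = threshold_high)
      out[[idx]] <- data.frame(
        manufacturer = metadata$manufacturer[v],
        scanner = metadata$scanner[v],
        protocol = metadata$protocol[v],
        material = metadata$material[v],
        thickness_mm = metadata$thickness_mm[v],
        preprocessing = ch, feature = names(fv),
        value = as.numeric(fv), row.names = NULL)
      idx <- idx + 1L
    }
  }
  FeatureTable(do.call(rbind, out))
}
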