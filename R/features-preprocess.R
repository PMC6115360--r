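# ROI geometry and the preprocessing primitives applied before feature
# computation: thresholding, 8-bit depth rescaling, Butterworth smoothing
# and trilinear resampling.

# Voxel-center coordinates along one axis.
.axisCoords <- function(vol, a) {
  vol@origin[a] + (seq_len(dim(vol@voxels)[a]) - 1) * vol@spacing[a]
}

#' Mask a cylindrical ROI out of a volume
#'
#' Voxel membership is decided by the voxel center: a voxel belongs to
#' the ROI iff its in-plane distance from the cylinder axis is at most
#' \code{diameter/2} and its |z - center_z| is at most \code{height/2}.
#' The result is cropped to the ROI bounding box with \code{NA} outside
#' the mask.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param roi A \linkS4class{CylindricalROI}.
#' @return An \linkS4class{ImageVolume} cropped to the ROI bounding box,
#'   \code{NA} outside the cylinder.
#' @export
maskROI <- function(volume, roi) {
  x <- .axisCoords(volume, 1); y <- .axisCoords(volume, 2)
  z <- .axisCoords(volume, 3)
  c0 <- roi@center
  if (c0[1] - roi@diameter / 2 < min(x) - volume@spacing[1] / 2 ||
      c0[1] + roi@diameter / 2 > max(x) + volume@spacing[1] / 2 ||
      c0[2] - roi@diameter / 2 < min(y) - volume@spacing[2] / 2 ||
      c0[2] + roi@diameter / 2 > max(y) + volume@spacing[2] / 2 ||
      c0[3] - roi@height / 2 < min(z) - volume@spacing[3] / 2 ||
      c0[3] + roi@height / 2 > max(z) + volume@spacing[3] / 2)
    stop("ROI extends outside the volume", call. = FALSE)
  r2 <- outer((x - c0[1])^2, (y - c0[2])^2, "+")
  inplane <- r2 <= (roi@diameter / 2)^2
  inz <- abs(z - c0[3]) <= roi@height / 2
  if (!any(inplane) || !any(inz)) {
    # degenerate geometry: keep the voxel column / slice nearest the axis
    if (!any(inplane)) {
      nearest <- which(r2 == min(r2), arr.ind = TRUE)[1, ]
      inplane[nearest[1], nearest[2]] <- TRUE
    }
    if (!any(inz)) inz[which.min(abs(z - c0[3]))] <- TRUE
  }
  mask <- array(rep(inplane, sum(inz)),
                dim = c(length(x), length(y), sum(inz)))
  vox <- volume@voxels[, , inz, drop = FALSE]
  vox[!mask] <- NA_real_
  ix <- range(which(apply(inplane, 1, any)))
  iy <- range(which(apply(inplane, 2, any)))
  vox <- vox[ix[1]:ix[2], iy[1]:iy[2], , drop = FALSE]
  ImageVolume(vox, spacing = volume@spacing,
              origin = c(x[ix[1]], y[iy[1]], z[which(inz)[1]]))
}

#' Threshold an ROI voxel set
#'
#' Values outside \code{[low, high]} are excluded (set \code{NA}), not
#' clipped. \code{high = NA} (or \code{Inf}) means no upper bound;
#' likewise for \code{low}.
#'
#' @param values Numeric vector or array of HU values (NA allowed).
#' @param low,high HU bounds; \code{NA} disables a bound.
#' @return Same shape as \code{values} with out-of-range entries NA.
#' @examples
#' applyThreshold(c(-150, 0, 250), -100, 200)  # NA 0 NA
#' @export
applyThreshold <- function(values, low = NA, high = NA) {
  if (!is.na(low) && !is.na(high) && low >= high)
    stop("threshold_low must be below threshold_high", call. = FALSE)
  out <- values
  if (!is.na(low)) out[!is.na(out) & out < low] <- NA_real_
  if (!is.na(high)) out[!is.na(out) & out > high] <- NA_real_
  if (all(is.na(out)))
    warning("thresholding removed every ROI voxel")
  out
}

#' Rescale intensities to a fixed bit depth
#'
#' Linear map of the observed \code{[min, max]} onto the integer levels
#' \code{1 .. 2^bits}; a constant input maps to level 1.
#'
#' @param values Numeric vector or array (NA allowed).
#' @param bits Bit depth; default 8 (levels 1..256).
#' @return Integer levels, same shape as \code{values}.
#' @examples
#' rescaleBitDepth(c(0, 100, 255))  # 1 101 256
#' @export
rescaleBitDepth <- function(values, bits = 8) {
  .stopifnot1(any(!is.na(values)), "cannot rescale an empty voxel set")
  lo <- min(values, na.rm = TRUE); hi <- max(values, na.rm = TRUE)
  nlev <- 2^bits
  if (hi == lo) {
    out <- values
    out[!is.na(out)] <- 1
    return(out)
  }
  round(1 + (values - lo) / (hi - lo) * (nlev - 1))
}

#' Butterworth low-pass smoothing of axial slices
#'
#' Frequency-domain low-pass applied independently to every axial (x-y)
#' slice with gain \eqn{1 / (1 + (f / f_c)^{2 \cdot order})}. The cutoff
#' is expressed in cycles per matrix on a 512-pixel-equivalent grid, so a
#' slice of n pixels at frequency bin k sees \eqn{f = 512 k / n}. The DC
#' component is untouched: slice means are preserved exactly.
#'
#' @param volume An \linkS4class{ImageVolume} (no NAs).
#' @param order Filter order; default 2.
#' @param cutoff Cutoff frequency in cycles per 512-pixel matrix;
#'   default 125.
#' @return Smoothed \linkS4class{ImageVolume}.
#' @export
butterworthSmooth <- function(volume, order = 2, cutoff = 125) {
  d <- dim(volume@voxels)
  .stopifnot1(d[1] >= 4 && d[2] >= 4, "slice dimensions must be >= 4")
  fx <- .fftFreq(d[1]) * 512
  fy <- .fftFreq(d[2]) * 512
  f <- sqrt(outer(fx^2, fy^2, "+"))
  gain <- 1 / (1 + (f / cutoff)^(2 * order))
  out <- volume@voxels
  for (k in seq_len(d[3])) {
    s <- volume@voxels[, , k]
    out[, , k] <- Re(fft(fft(s) * gain, inverse = TRUE)) / (d[1] * d[2])
  }
  ImageVolume(out, spacing = volume@spacing, origin = volume@origin)
}

# Trilinear interpolation of a volume at the grid defined by coordinate
# vectors xs/ys/zs (mm). Coordinates are clamped to the volume extent.
.trilinearResample <- function(volume, xs, ys, zs) {
  arr <- volume@voxels
  d <- dim(arr)
  pos <- function(coords, a) {
    g <- (coords - volume@origin[a]) / volume@spacing[a]
    g <- pmin(pmax(g, 0), d[a] - 1)
    i0 <- pmin(floor(g), max(d[a] - 2, 0))
    list(i0 = i0 + 1, f = g - i0)       # 1-based lower index + fraction
  }
  px <- pos(xs, 1); py <- pos(ys, 2); pz <- pos(zs, 3)
  out <- array(0, c(length(xs), length(ys), length(zs)))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 1) px$f else 1 - px$f
    wy <- if (dy == 1) py$f else 1 - py$f
    wz <- if (dz == 1) pz$f else 1 - pz$f
    ix <- pmin(px$i0 + dx, d[1]); iy <- pmin(py$i0 + dy, d[2])
    iz <- pmin(pz$i0 + dz, d[3])
    w <- outer(outer(wx, wy), wz)
    if (all(w == 0)) next
    out <- out + arr[ix, iy, iz, drop = FALSE] * w
  }
  ImageVolume(out, spacing = c(
    if (length(xs) > 1) xs[2] - xs[1] else volume@spacing[1],
    if (length(ys) > 1) ys[2] - ys[1] else volume@spacing[2],
    if (length(zs) > 1) zs[2] - zs[1] else volume@spacing[3]),
    origin = c(xs[1], ys[1], zs[1]))
}

#' Resample the in-plane grid to an isotropic target spacing
#'
#' Trilinear interpolation onto a 1 mm x 1 mm (by default) in-plane grid
#' anchored at the volume origin; the z grid is untouched.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param target Target in-plane spacing in mm; default 1.
#' @return Resampled \linkS4class{ImageVolume}.
#' @export
resampleXY <- function(volume, target = 1) {
  d <- dim(volume@voxels)
  if (isTRUE(all.equal(volume@spacing[1:2], c(target, target))))
    return(volume)
  extx <- (d[1] - 1) * volume@spacing[1]
  exty <- (d[2] - 1) * volume@spacing[2]
  xs <- volume@origin[1] + seq(0, extx, by = target)
  ys <- volume@origin[2] + seq(0, exty, by = target)
  zs <- .axisCoords(volume, 3)
  .trilinearResample(volume, xs, ys, zs)
}

#' Resample the z grid to a target slice spacing
#'
#' Trilinear interpolation along z onto a grid of spacing \code{dz}
#' anchored at the volume origin; the in-plane grid is untouched.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param dz Target z spacing in mm.
#' @return Resampled \linkS4class{ImageVolume}.
#' @export
resampleZ <- function(volume, dz) {
  .stopifnot1(dz > 0, "dz must be positive")
  d <- dim(volume@voxels)
  if (isTRUE(all.equal(volume@spacing[3], dz))) return(volume)
  extz <- (d[3] - 1) * volume@spacing[3]
  zs <- volume@origin[3] + seq(0, extz, by = dz)
  .trilinearResample(volume, .axisCoords(volume, 1),
                     .axisCoords(volume, 2), zs)
}
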