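# Texture-matrix features. All matrix statistics are computed in 3D over
# the 13 unique direction offsets at distance 1, pooled into a single
# matrix. Gray levels are positive integers (1-based); NA marks voxels
# outside the ROI.

# 13 unique 3D directions (first non-zero component positive).
.DIRECTIONS3D <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

.GLCM_NAMES <- paste0("glcm_", c(
  "auto_correlation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_entropy",
  "dissimilarity", "energy", "entropy", "homogeneity", "homogeneity2",
  "imc1", "imc2", "idmn", "idn", "inverse_variance", "max_probability",
  "sum_average", "sum_entropy", "sum_variance", "variance"))

.GLRLM_NAMES <- paste0("glrlm_", c(
  "gray_level_nonuniformity", "high_gray_level_run_emphasis",
  "long_run_emphasis", "long_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "low_gray_level_run_emphasis",
  "run_length_nonuniformity", "run_percentage", "short_run_emphasis",
  "short_run_high_gray_level_emphasis",
  "short_run_low_gray_level_emphasis"))

.INTENSITY_NAMES <- paste0("ih_", c(
  "energy", "entropy", "kurtosis", "maximum", "mean", "median", "minimum",
  "skewness", "standard_deviation", "uniformity", "variance"))

.NGTDM_NAMES <- paste0("ngtdm_", c(
  "busyness", "coarseness", "complexity", "contrast", "texture_strength"))

#' Names and categories of the 49 radiomics features
#'
#' 22 gray level co-occurrence (GLCM), 11 gray level run length (GLRLM),
#' 11 intensity histogram and 5 neighborhood gray tone difference (NGTDM)
#' features.
#'
#' @return \code{featureNames()}: character vector of the 49 feature
#'   names; \code{featureCategories()}: named character vector mapping
#'   each feature to its category
#'   (\code{"glcm"}, \code{"glrlm"}, \code{"intensity"}, \code{"ngtdm"}).
#' @examples
#' table(featureCategories())
#' @export
featureNames <- function() {
  c(.GLCM_NAMES, .GLRLM_NAMES, .INTENSITY_NAMES, .NGTDM_NAMES)
}

#' @rdname featureNames
#' @param features Character vector of feature names (defaults to all 49).
#' @export
featureCategories <- function(features = featureNames()) {
  cat <- sub("_.*$", "", features)
  cat[cat == "ih"] <- "intensity"
  names(cat) <- features
  cat
}

# ---- GLCM -----------------------------------------------------------------

# Pooled, symmetrized, normalized co-occurrence matrix over the 13
# directions. Levels must be positive integers; NA breaks pairs.
.buildGLCM <- function(grid) {
  g <- .asGrid3d(grid)
  M <- max(g, na.rm = TRUE)
  counts <- matrix(0, M, M)
  dm <- dim(g)
  for (r in seq_len(nrow(.DIRECTIONS3D))) {
    d <- .DIRECTIONS3D[r, ]
    B <- .shift3d(g, d)
    ok <- !is.na(g) & !is.na(B)
    if (!any(ok)) next
    a <- g[ok]; b <- B[ok]
    tab <- tabulate(a + (b - 1L) * M, nbins = M * M)
    counts <- counts + matrix(tab, M, M)
  }
  counts <- counts + t(counts)  # symmetrize (adds reverse directions)
  s <- sum(counts)
  if (s == 0) stop("no co-occurring voxel pairs in ROI", call. = FALSE)
  counts / s
}

# The 22 Haralick-family statistics of a normalized symmetric GLCM.
.glcmStats <- function(P) {
  M <- nrow(P)
  lev <- seq_len(M)
  I <- row(P); J <- col(P)
  px <- rowSums(P)                      # == colSums(P) by symmetry
  mu <- sum(lev * px)
  sx <- sqrt(sum((lev - mu)^2 * px))
  pos <- P > 0
  ent <- -sum(P[pos] * log2(P[pos]))
  # sum / difference distributions (grouped sums over anti-/diagonals)
  psum <- numeric(2 * M - 1)
  tmp <- rowsum(as.vector(P), as.vector(I + J))
  psum[as.integer(rownames(tmp)) - 1L] <- tmp
  pdif <- numeric(M)
  tmp <- rowsum(as.vector(P), as.vector(abs(I - J)))
  pdif[as.integer(rownames(tmp)) + 1L] <- tmp
  sa <- sum((2:(2 * M)) * psum)
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  de <- -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  sv <- sum(((2:(2 * M)) - sa)^2 * psum)
  # information measures
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  PXY <- outer(px, px)
  hxy1 <- -sum(P[pos] * log2(PXY[pos]))
  okxy <- PXY > 0
  hxy2 <- -sum(PXY[okxy] * log2(PXY[okxy]))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  offd <- I != J
  corr <- if (sx > 0) (sum(I * J * P) - mu^2) / sx^2 else 1
  c(glcm_auto_correlation = sum(I * J * P),
    glcm_cluster_prominence = sum((I + J - 2 * mu)^4 * P),
    glcm_cluster_shade = sum((I + J - 2 * mu)^3 * P),
    glcm_cluster_tendency = sum((I + J - 2 * mu)^2 * P),
    glcm_contrast = sum((I - J)^2 * P),
    glcm_correlation = corr,
    glcm_difference_entropy = de,
    glcm_dissimilarity = sum(abs(I - J) * P),
    glcm_energy = sum(P^2),
    glcm_entropy = ent,
    glcm_homogeneity = sum(P / (1 + abs(I - J))),
    glcm_homogeneity2 = sum(P / (1 + (I - J)^2)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_idmn = sum(P / (1 + (I - J)^2 / M^2)),
    glcm_idn = sum(P / (1 + abs(I - J) / M)),
    glcm_inverse_variance = sum(P[offd] / (I[offd] - J[offd])^2),
    glcm_max_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = se,
    glcm_sum_variance = sv,
    glcm_variance = sum((I - mu)^2 * P))
}

#' Gray level co-occurrence matrix features
#'
#' Builds the 3D co-occurrence matrix pooled over the 13 unique direction
#' offsets at distance 1 (symmetrized, normalized) and computes the 22
#' Haralick-family features. On a single-level ROI the degenerate
#' features take their analytic limits (contrast 0, energy 1, entropy 0,
#' correlation 1 by convention).
#'
#' @param levels 3D array (or vector/matrix) of positive integer gray
#'   levels; \code{NA} marks voxels outside the ROI.
#' @return Named numeric vector of the 22 GLCM features.
#' @examples
#' g <- array(c(1, 2, 2, 1), c(2, 2, 1))
#' glcmFeatures(g)[c("glcm_contrast", "glcm_energy")]
#' @export
glcmFeatures <- function(levels) {
  g <- .asGrid3d(levels)
  .stopifnot1(sum(!is.na(g)) >= 2, "GLCM needs at least 2 in-ROI voxels")
  .glcmStats(.buildGLCM(g))
}

# ---- GLRLM ----------------------------------------------------------------

# Run list over the 13 directions: data.frame(level, length) of all runs.
.enumerateRuns <- function(grid) {
  g <- .asGrid3d(grid)
  dm <- dim(g)
  idx <- which(!is.na(g), arr.ind = TRUE)
  lev <- g[!is.na(g)]
  out_lev <- integer(0); out_len <- integer(0)
  for (r in seq_len(nrow(.DIRECTIONS3D))) {
    d <- .DIRECTIONS3D[r, ]
    axis <- which(d != 0)[1]           # d[axis] == +1 by construction
    t <- idx[, axis]
    key1 <- idx[, 1] - t * d[1]
    key2 <- idx[, 2] - t * d[2]
    key3 <- idx[, 3] - t * d[3]
    # encode the line id in a collision-free mixed radix; each component
    # lies in [1 - max(dm), dm_c + max(dm)]
    B <- 2 * sum(dm) + 2
    key <- (key1 + sum(dm)) + (key2 + sum(dm)) * B + (key3 + sum(dm)) * B^2
    o <- order(key, t)
    k2 <- key[o]; t2 <- t[o]; v2 <- lev[o]
    n <- length(o)
    newrun <- if (n > 1) {
      c(TRUE, k2[-1] != k2[-n] | t2[-1] != t2[-n] + 1L | v2[-1] != v2[-n])
    } else TRUE
    runid <- cumsum(newrun)
    out_len <- c(out_len, tabulate(runid))
    out_lev <- c(out_lev, v2[newrun])
  }
  data.frame(level = out_lev, length = out_len)
}

# Pooled run-length matrix p(i, j) with i = gray level, j = run length.
.buildGLRLM <- function(grid) {
  g <- .asGrid3d(grid)
  runs <- .enumerateRuns(g)
  M <- max(g, na.rm = TRUE)
  N <- max(runs$length)
  p <- matrix(tabulate(runs$level + (runs$length - 1L) * M, nbins = M * N),
              M, N)
  list(p = p, n_runs = nrow(runs), n_voxels = sum(!is.na(g)),
       n_directions = nrow(.DIRECTIONS3D))
}

#' Gray level run length matrix features
#'
#' Run-length matrices are built per direction (13 unique 3D offsets) and
#' pooled; runs are broken by ROI gaps and grid edges. Low gray level run
#' emphasis follows the classical definition
#' \eqn{LGRE = (1/n_r) \sum_i p_g(i) / i^2} with
#' \eqn{p_g(i) = \sum_j p(i,j)}. The two nonuniformity features use the
#' volume-independent variant (normalized by \eqn{n_r^2}); run percentage
#' is the run count over (voxels x directions), so a fully fragmented ROI
#' gives 1.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 11 GLRLM features.
#' @examples
#' g <- array(2, c(3, 3, 1))
#' glrlmFeatures(g)["glrlm_low_gray_level_run_emphasis"]  # 1/4
#' @export
glrlmFeatures <- function(levels) {
  g <- .asGrid3d(levels)
  .stopifnot1(sum(!is.na(g)) >= 1, "GLRLM needs at least 1 in-ROI voxel")
  rl <- .buildGLRLM(g)
  p <- rl$p; nr <- rl$n_runs
  M <- nrow(p); N <- ncol(p)
  i <- seq_len(M); j <- seq_len(N)
  pg <- rowSums(p)   # runs per gray level
  pr <- colSums(p)   # runs per length
  I <- row(p); J <- col(p)
  c(glrlm_gray_level_nonuniformity = sum(pg^2) / nr^2,
    glrlm_high_gray_level_run_emphasis = sum(pg * i^2) / nr,
    glrlm_long_run_emphasis = sum(pr * j^2) / nr,
    glrlm_long_run_high_gray_level_emphasis = sum(p * I^2 * J^2) / nr,
    glrlm_long_run_low_gray_level_emphasis = sum(p * J^2 / I^2) / nr,
    glrlm_low_gray_level_run_emphasis = sum(pg / i^2) / nr,
    glrlm_run_length_nonuniformity = sum(pr^2) / nr^2,
    glrlm_run_percentage = nr / (rl$n_voxels * rl$n_directions),
    glrlm_short_run_emphasis = sum(pr / j^2) / nr,
    glrlm_short_run_high_gray_level_emphasis = sum(p * I^2 / J^2) / nr,
    glrlm_short_run_low_gray_level_emphasis = sum(p / (I^2 * J^2)) / nr)
}

# ---- intensity histogram --------------------------------------------------

#' Intensity histogram features
#'
#' First-order statistics of the (preprocessed) ROI intensity
#' distribution. Moments use population conventions (variance
#' \eqn{m_2}, skewness \eqn{m_3/m_2^{3/2}}, kurtosis \eqn{m_4/m_2^2};
#' both 0 for a constant input). Entropy and uniformity are computed on
#' the discrete level distribution (\code{levels}; defaults to
#' 1-HU-wide bins, i.e. rounded values).
#'
#' @param values Numeric vector of ROI intensities (HU or rescaled
#'   levels); NAs dropped.
#' @param levels Optional integer vector of discretized levels matched to
#'   \code{values}; defaults to \code{round(values)}.
#' @return Named numeric vector of the 11 intensity features.
#' @examples
#' intensityFeatures(c(1, 2, 3, 4))[c("ih_mean", "ih_variance")]
#' @export
intensityFeatures <- function(values, levels = NULL) {
  x <- values[!is.na(values)]
  .stopifnot1(length(x) >= 1, "intensity features need a non-empty ROI")
  if (is.null(levels)) levels <- round(x) else levels <- levels[!is.na(levels)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  p <- as.numeric(table(levels)) / length(levels)
  c(ih_energy = sum(x^2),
    ih_entropy = -sum(p * log2(p)),
    ih_kurtosis = kurt,
    ih_maximum = max(x),
    ih_mean = m,
    ih_median = median(x),
    ih_minimum = min(x),
    ih_skewness = skew,
    ih_standard_deviation = sqrt(m2),
    ih_uniformity = sum(p^2),
    ih_variance = m2)
}

# ---- NGTDM ----------------------------------------------------------------

.NGTDM_COARSENESS_CAP <- 1e6

#' Neighborhood gray tone difference matrix features
#'
#' For every voxel with a complete 3x3x3 neighborhood inside the ROI, the
#' absolute difference between its level and the mean of its 26 neighbors
#' is accumulated per gray level (the NGTDM \eqn{s(i)} column). On a
#' constant ROI all \eqn{s(i) = 0}: coarseness is reported at its cap
#' (1e6) and contrast as 0.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 5 NGTDM features.
#' @export
ngtdmFeatures <- function(levels) {
  g <- .asGrid3d(levels)
  dm <- dim(g)
  S <- array(0, dm); Cn <- array(0L, dm)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- .shift3d(g, c(dx, dy, dz))
    ok <- !is.na(sh)
    S[ok] <- S[ok] + sh[ok]
    Cn <- Cn + ok
  }
  counted <- !is.na(g) & Cn == 26L
  .stopifnot1(any(counted),
              "NGTDM needs voxels with a complete 3x3x3 neighborhood")
  lev <- g[counted]
  diffs <- abs(lev - S[counted] / 26)
  M <- max(g, na.rm = TRUE)
  s <- vapply(seq_len(M), function(i) sum(diffs[lev == i]), numeric(1))
  n_i <- tabulate(lev, nbins = M)
  N <- sum(n_i)
  p <- n_i / N
  gl <- which(p > 0)          # gray levels present
  Ngp <- length(gl)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) min(1 / ps, .NGTDM_COARSENESS_CAP) else
    .NGTDM_COARSENESS_CAP
  contrast <- if (Ngp > 1) {
    (sum(outer(p[gl], p[gl]) * outer(gl, gl, "-")^2) / (Ngp * (Ngp - 1))) *
      (sum(s) / N)
  } else 0
  ipi <- gl * p[gl]
  busy_den <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  pi_ <- p[gl]; si <- s[gl]
  num <- outer(pi_ * si, pi_ * si, "+")
  complexity <- sum(abs(outer(gl, gl, "-")) * num /
                      outer(pi_, pi_, "+")) / N
  strength <- if (sum(s) > 0)
    sum(outer(pi_, pi_, "+") * outer(gl, gl, "-")^2) / sum(s) else 0
  c(ngtdm_busyness = busyness,
    ngtdm_coarseness = coarseness,
    ngtdm_complexity = complexity,
    ngtdm_contrast = contrast,
    ngtdm_texture_strength = strength)
}
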