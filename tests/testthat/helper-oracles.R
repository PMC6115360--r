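# Brute-force oracles for the texture-matrix features: explicit
# enumeration of voxel pairs, runs and neighborhoods with naive loops,
# plus independently coded feature formulas. Deliberately slow and
# simple; used only on tiny grids.

.oracle_dirs <- list(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

.in_grid <- function(p, dm) all(p >= 1) && all(p <= dm)

# Symmetric pooled co-occurrence matrix by explicit pair enumeration.
oracle_glcm_matrix <- function(g) {
  dm <- dim(g)
  M <- max(g, na.rm = TRUE)
  counts <- matrix(0, M, M)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      a <- g[i, j, k]
      if (is.na(a)) next
      for (d in .oracle_dirs) {
        q <- c(i, j, k) + d
        if (!.in_grid(q, dm)) next
        b <- g[q[1], q[2], q[3]]
        if (is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  counts / sum(counts)
}

oracle_glcm_features <- function(g) {
  P <- oracle_glcm_matrix(g)
  M <- nrow(P)
  px <- sapply(seq_len(M), function(i) sum(P[i, ]))
  py <- sapply(seq_len(M), function(j) sum(P[, j]))
  mux <- sum(seq_len(M) * px); muy <- sum(seq_len(M) * py)
  sx <- sqrt(sum((seq_len(M) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(M) - muy)^2 * py))
  f <- setNames(numeric(22), c(
    "glcm_auto_correlation", "glcm_cluster_prominence",
    "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast",
    "glcm_correlation", "glcm_difference_entropy", "glcm_dissimilarity",
    "glcm_energy", "glcm_entropy", "glcm_homogeneity",
    "glcm_homogeneity2", "glcm_imc1", "glcm_imc2", "glcm_idmn",
    "glcm_idn", "glcm_inverse_variance", "glcm_max_probability",
    "glcm_sum_average", "glcm_sum_entropy", "glcm_sum_variance",
    "glcm_variance"))
  hxy <- 0; hxy1 <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) {
    p <- P[i, j]
    f["glcm_auto_correlation"] <- f["glcm_auto_correlation"] + i * j * p
    f["glcm_cluster_prominence"] <-
      f["glcm_cluster_prominence"] + (i + j - mux - muy)^4 * p
    f["glcm_cluster_shade"] <-
      f["glcm_cluster_shade"] + (i + j - mux - muy)^3 * p
    f["glcm_cluster_tendency"] <-
      f["glcm_cluster_tendency"] + (i + j - mux - muy)^2 * p
    f["glcm_contrast"] <- f["glcm_contrast"] + (i - j)^2 * p
    f["glcm_dissimilarity"] <- f["glcm_dissimilarity"] + abs(i - j) * p
    f["glcm_energy"] <- f["glcm_energy"] + p^2
    f["glcm_homogeneity"] <- f["glcm_homogeneity"] + p / (1 + abs(i - j))
    f["glcm_homogeneity2"] <- f["glcm_homogeneity2"] + p / (1 + (i - j)^2)
    f["glcm_idmn"] <- f["glcm_idmn"] + p / (1 + (i - j)^2 / M^2)
    f["glcm_idn"] <- f["glcm_idn"] + p / (1 + abs(i - j) / M)
    if (i != j)
      f["glcm_inverse_variance"] <-
        f["glcm_inverse_variance"] + p / (i - j)^2
    f["glcm_variance"] <- f["glcm_variance"] + (i - mux)^2 * p
    if (p > 0) {
      hxy <- hxy - p * log2(p)
      hxy1 <- hxy1 - p * log2(px[i] * py[j])
    }
  }
  f["glcm_entropy"] <- hxy
  f["glcm_max_probability"] <- max(P)
  f["glcm_correlation"] <- if (sx > 0)
    (f[["glcm_auto_correlation"]] - mux * muy) / (sx * sy) else 1
  for (k in 2:(2 * M)) {
    pk <- 0
    for (i in seq_len(M)) for (j in seq_len(M))
      if (i + j == k) pk <- pk + P[i, j]
    f["glcm_sum_average"] <- f["glcm_sum_average"] + k * pk
    if (pk > 0)
      f["glcm_sum_entropy"] <- f["glcm_sum_entropy"] - pk * log2(pk)
  }
  for (k in 2:(2 * M)) {
    pk <- 0
    for (i in seq_len(M)) for (j in seq_len(M))
      if (i + j == k) pk <- pk + P[i, j]
    f["glcm_sum_variance"] <- f["glcm_sum_variance"] +
      (k - f[["glcm_sum_average"]])^2 * pk
  }
  for (k in 0:(M - 1)) {
    pk <- 0
    for (i in seq_len(M)) for (j in seq_len(M))
      if (abs(i - j) == k) pk <- pk + P[i, j]
    if (pk > 0)
      f["glcm_difference_entropy"] <-
        f["glcm_difference_entropy"] - pk * log2(pk)
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy2 <- 0
  for (i in seq_len(M)) for (j in seq_len(M))
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  f["glcm_imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  f["glcm_imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f
}

# All runs by explicit line walking per direction.
oracle_runs <- function(g) {
  dm <- dim(g)
  runs <- list()
  for (d in .oracle_dirs) {
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
      for (k in seq_len(dm[3])) {
        p <- c(i, j, k)
        if (.in_grid(p - d, dm)) next      # not a line start
        vals <- c()
        while (.in_grid(p, dm)) {
          vals <- c(vals, g[p[1], p[2], p[3]])
          p <- p + d
        }
        pos <- 1
        while (pos <= length(vals)) {
          if (is.na(vals[pos])) { pos <- pos + 1; next }
          len <- 1
          while (pos + len <= length(vals) &&
                 !is.na(vals[pos + len]) &&
                 vals[pos + len] == vals[pos]) len <- len + 1
          runs[[length(runs) + 1]] <- c(vals[pos], len)
          pos <- pos + len
        }
      }
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(g) {
  r <- oracle_runs(g)
  M <- max(g, na.rm = TRUE)
  N <- max(r[, 2])
  p <- matrix(0, M, N)
  for (q in seq_len(nrow(r))) p[r[q, 1], r[q, 2]] <- p[r[q, 1], r[q, 2]] + 1
  nr <- nrow(r)
  np <- sum(!is.na(g))
  f <- c(glrlm_gray_level_nonuniformity = 0,
         glrlm_high_gray_level_run_emphasis = 0,
         glrlm_long_run_emphasis = 0,
         glrlm_long_run_high_gray_level_emphasis = 0,
         glrlm_long_run_low_gray_level_emphasis = 0,
         glrlm_low_gray_level_run_emphasis = 0,
         glrlm_run_length_nonuniformity = 0,
         glrlm_run_percentage = nr / (np * 13),
         glrlm_short_run_emphasis = 0,
         glrlm_short_run_high_gray_level_emphasis = 0,
         glrlm_short_run_low_gray_level_emphasis = 0)
  for (i in seq_len(M)) {
    pg <- sum(p[i, ])
    f["glrlm_gray_level_nonuniformity"] <-
      f["glrlm_gray_level_nonuniformity"] + pg^2 / nr^2
    f["glrlm_high_gray_level_run_emphasis"] <-
      f["glrlm_high_gray_level_run_emphasis"] + pg * i^2 / nr
    f["glrlm_low_gray_level_run_emphasis"] <-
      f["glrlm_low_gray_level_run_emphasis"] + pg / i^2 / nr
  }
  for (j in seq_len(N)) {
    pr <- sum(p[, j])
    f["glrlm_run_length_nonuniformity"] <-
      f["glrlm_run_length_nonuniformity"] + pr^2 / nr^2
    f["glrlm_long_run_emphasis"] <-
      f["glrlm_long_run_emphasis"] + pr * j^2 / nr
    f["glrlm_short_run_emphasis"] <-
      f["glrlm_short_run_emphasis"] + pr / j^2 / nr
  }
  for (i in seq_len(M)) for (j in seq_len(N)) {
    f["glrlm_long_run_high_gray_level_emphasis"] <-
      f["glrlm_long_run_high_gray_level_emphasis"] + p[i, j] * i^2 * j^2 / nr
    f["glrlm_long_run_low_gray_level_emphasis"] <-
      f["glrlm_long_run_low_gray_level_emphasis"] + p[i, j] * j^2 / i^2 / nr
    f["glrlm_short_run_high_gray_level_emphasis"] <-
      f["glrlm_short_run_high_gray_level_emphasis"] + p[i, j] * i^2 / j^2 / nr
    f["glrlm_short_run_low_gray_level_emphasis"] <-
      f["glrlm_short_run_low_gray_level_emphasis"] + p[i, j] / (i^2 * j^2) / nr
  }
  f
}

oracle_ngtdm_features <- function(g) {
  dm <- dim(g)
  M <- max(g, na.rm = TRUE)
  s <- numeric(M); n_i <- numeric(M)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      if (is.na(g[i, j, k])) next
      nb <- c()
      complete <- TRUE
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        q <- c(i + di, j + dj, k + dk)
        if (!.in_grid(q, dm) || is.na(g[q[1], q[2], q[3]])) {
          complete <- FALSE
        } else nb <- c(nb, g[q[1], q[2], q[3]])
      }
      if (!complete) next
      lv <- g[i, j, k]
      s[lv] <- s[lv] + abs(lv - mean(nb))
      n_i[lv] <- n_i[lv] + 1
    }
  if (sum(n_i) == 0) return(NULL)
  N <- sum(n_i); p <- n_i / N
  gl <- which(p > 0); Ngp <- length(gl)
  ps <- sum(p * s)
  coarse <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contr <- 0; busy_den <- 0; compl <- 0; str_num <- 0
  for (i in gl) for (j in gl) {
    contr <- contr + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    compl <- compl + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (p[i] + p[j])
    str_num <- str_num + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (Ngp > 1) contr / (Ngp * (Ngp - 1)) * sum(s) / N else 0
  c(ngtdm_busyness = if (busy_den > 0) ps / busy_den else 0,
    ngtdm_coarseness = coarse,
    ngtdm_complexity = compl / N,
    ngtdm_contrast = contrast,
    ngtdm_texture_strength = if (sum(s) > 0) str_num / sum(s) else 0)
}

oracle_intensity_features <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  lv <- round(x)
  p <- table(lv) / n
  c(ih_energy = sum(x^2),
    ih_entropy = -sum(p * log2(p)),
    ih_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    ih_maximum = max(x),
    ih_mean = m,
    ih_median = median(x),
    ih_minimum = min(x),
    ih_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    ih_standard_deviation = sqrt(m2),
    ih_uniformity = sum(p^2),
    ih_variance = m2)
}

# Random level grid with optional NA holes.
random_level_grid <- function(shape, n_levels, na_frac = 0) {
  g <- array(sample.int(n_levels, prod(shape), replace = TRUE),
             dim = shape)
  if (na_frac > 0) {
    holes <- which(runif(prod(shape)) < na_frac)
    g[holes] <- NA
    if (all(is.na(g))) g[1] <- 1L
  }
  g
}
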