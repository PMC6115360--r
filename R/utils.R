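# Internal helpers: seeded evaluation, seed streams, FFT machinery.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL means "use the current stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible sub-seeds from one master seed
#'
#' One master seed spawns independent per-stage seeds so that every stage
#' of a study is reproducible in isolation.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds to draw.
#' @return Integer vector of length \code{n}, values in \code{[1, 2^31-2]}.
#' @export
spawnSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(2147483646L, n))
}

# Frequencies (cycles per sample) for an n-point DFT, in fft() bin order.
.fftFreq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Circular (periodic) Gaussian filtering of a 3D array; sigma in voxels
# per axis, 0 disables an axis. Returns list(filtered, h2mean) where
# h2mean = mean(|H|^2), the white-noise variance gain of the filter.
.gaussianFilter3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  H <- 1
  for (a in 1:3) {
    if (sigma_vox[a] <= 0) next
    f <- .fftFreq(d[a])
    ha <- exp(-2 * pi^2 * sigma_vox[a]^2 * f^2)
    shape <- c(1, 1, 1); shape[a] <- d[a]
    H <- H * array(rep(ha, each = prod(d[seq_len(a - 1)])), dim = d)
  }
  if (identical(H, 1)) return(list(filtered = arr, h2mean = 1))
  Fx <- fft(arr)
  filtered <- Re(fft(Fx * H, inverse = TRUE)) / prod(d)
  list(filtered = filtered, h2mean = mean(H^2))
}

# Shift a 3D array by integer offset d (length 3), NA-filling exposed
# edges: result[i] = arr[i + d] where defined.
.shift3d <- function(arr, d) {
  dm <- dim(arr)
  out <- array(NA_real_, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      if (d[a] >= dm[a]) return(out)
      dst[[a]] <- seq_len(dm[a] - d[a])
      src[[a]] <- seq_len(dm[a] - d[a]) + d[a]
    } else {
      if (-d[a] >= dm[a]) return(out)
      dst[[a]] <- seq_len(dm[a] + d[a]) - d[a]
      src[[a]] <- seq_len(dm[a] + d[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Coerce vector/matrix input to a 3D array of levels.
.asGrid3d <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  array(x, dim = c(length(x), 1L, 1L))
}

.stopifnot1 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
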