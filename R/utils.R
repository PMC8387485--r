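# Internal helpers: Gaussian (derivative) kernels, separable convolution with
# reflective borders, and deterministic seed substreams.

#' @useDynLib plexus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 1D Gaussian kernel or its first/second derivative, truncated at 3 sigma.
# Derivative kernels are moment-normalized so that constants map to exactly
# zero and a unit ramp / unit curvature is recovered exactly despite the
# truncation.
gauss_kernel1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)                     # zero response to constants
    k / sum(-x * k)                      # unit response to slope 1
  } else {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)                     # zero response to constants
    k <- k - x * sum(x * k) / sum(x^2)   # zero response to ramps
    k / sum(x^2 / 2 * k)                 # unit response to d2=1
  }
}

# Reflect-pad a matrix by (rr, rc) pixels on each side.
pad_reflect <- function(img, rr, rc) {
  nr <- nrow(img); nc <- ncol(img)
  if (2 * rr >= 2 * nr || 2 * rc >= 2 * nc)
    stop("image smaller than filter support")
  ri <- c(rev(seq_len(rr)), seq_len(nr), nr - seq_len(rr) + 1L)
  ci <- c(rev(seq_len(rc)), seq_len(nc), nc - seq_len(rc) + 1L)
  img[ri, ci, drop = FALSE]
}

# Separable convolution with reflective border handling. kr acts along rows
# (vertical), kc along columns (horizontal).
conv_sep <- function(img, kr, kc = kr) {
  rr <- (length(kr) - 1L) %/% 2L
  rc <- (length(kc) - 1L) %/% 2L
  if (rr >= nrow(img) || rc >= ncol(img))
    stop("image smaller than filter support")
  p <- pad_reflect(img, rr, rc)
  p <- EBImage::filter2(p, matrix(rev(kr), ncol = 1L), boundary = "circular")
  p <- EBImage::filter2(p, matrix(rev(kc), nrow = 1L), boundary = "circular")
  p[rr + seq_len(nrow(img)), rc + seq_len(ncol(img)), drop = FALSE]
}

# Gaussian smoothing of a 2D image (reflective borders).
gauss2d <- function(img, sigma) {
  k <- gauss_kernel1d(sigma, 0L)
  conv_sep(img, k, k)
}

# Convolve a 3D volume along z with a 1D kernel (reflective borders).
conv_z <- function(vol, k) {
  nz <- dim(vol)[3]
  r <- (length(k) - 1L) %/% 2L
  idx <- function(z) {
    z <- abs(z - 1L) + 1L              # reflect below
    z <- ifelse(z > nz, 2L * nz - z, z) # reflect above
    pmin(pmax(z, 1L), nz)
  }
  out <- array(0, dim(vol))
  for (t in seq_along(k)) {
    zs <- idx(seq_len(nz) + (t - 1L - r))
    out <- out + k[t] * vol[, , zs, drop = FALSE]
  }
  out
}

# Deterministic substream seed from a base seed and integer indices; always a
# positive integer below 2^31 so any scene is reproducible in isolation.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (i in seq_along(idx))
    s <- (s * 48271 + as.numeric(idx[i]) * 7919 + i * 104729) %% m
  as.integer(s %% (m - 2)) + 1L
}

# Run code under a local RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
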