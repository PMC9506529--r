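# Periodized orthogonal discrete wavelet transform (Daubechies family)
# and universal-threshold denoising. Written in-package; perfect
# reconstruction at zero threshold is asserted in the test suite.

.wavelet_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314453414, 0.83651630373780790,
            0.22414386804201339, -0.12940952255126037),
    db4 = c(0.23037781330889650, 0.71484657055291564,
            0.63088076792985890, -0.02798376941685985,
            -0.18703481171909309, 0.03084138183556076,
            0.03288301166688520, -0.01059740178506903),
    stop("unknown wavelet '", wavelet, "'; available: haar, db2, db4")
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror filter
  list(h = h, g = g, L = L)
}

# One analysis step on an even-length vector, periodic extension.
.dwt_step <- function(x, f) {
  N <- length(x)
  half <- N %/% 2L
  n0 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(f$L)) {
    xi <- x[(n0 + (k - 1L)) %% N + 1L]
    a <- a + f$h[k] * xi
    d <- d + f$g[k] * xi
  }
  list(a = a, d = d)
}

# Inverse of .dwt_step: adjoint of the orthogonal analysis operator.
.idwt_step <- function(a, d, f) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  n0 <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(f$L)) {
    idx <- (n0 + (k - 1L)) %% N + 1L
    x[idx] <- x[idx] + f$h[k] * a + f$g[k] * d
  }
  x
}

# Multilevel decomposition; x length must be divisible by 2^level.
.dwt <- function(x, f, level) {
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a, f)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

.idwt <- function(dec, f) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- .idwt_step(a, dec$details[[j]], f)
  a
}

.soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)
.hard_threshold <- function(d, thr) d * (abs(d) > thr)

# Denoise one vector: symmetric-pad to a multiple of 2^level, decompose,
# estimate sigma from the finest detail (MAD/0.6745), threshold all
# detail levels, reconstruct, trim.
.wavelet_denoise_vec <- function(x, f, level, mode, threshold) {
  n0 <- length(x)
  block <- 2L^level
  N <- as.integer(ceiling(n0 / block) * block)
  if (N > n0) {
    pad <- N - n0
    x <- c(x, x[n0 - seq_len(pad) + 1L])  # mirror the tail
  }
  dec <- .dwt(x, f, level)
  if (is.null(threshold)) {
    sigma <- median(abs(dec$details[[1L]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(N))
  }
  shrink <- if (mode == "soft") .soft_threshold else .hard_threshold
  dec$details <- lapply(dec$details, shrink, thr = threshold)
  .idwt(dec, f)[seq_len(n0)]
}
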