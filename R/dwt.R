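# Periodized orthogonal discrete wavelet transform (Mallat pyramid).
# Used by the motion-artifact correction, which thresholds detail
# coefficients level-by-level and needs exact perfect reconstruction
# after modification.

# One analysis step of the periodized DWT.
# x: even-length numeric vector. Returns list(approx, detail), each n/2.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0, n >= 2)
  L <- length(lo)
  k <- seq_len(n / 2) - 1L                       # 0-indexed output position
  idx <- outer(2L * k + 1L, 0:(L - 1L), `-`) %% n + 1L  # (2k + 1 - l) mod n
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = drop(xm %*% lo), detail = drop(xm %*% hi))
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
# For fixed filter tap l the target indices (2k + 1 - l) mod n are distinct,
# so the accumulation vectorizes per tap.
idwt_step <- function(approx, detail, lo, hi) {
  nh <- length(approx)
  n <- 2L * nh
  x <- numeric(n)
  k <- seq_len(nh) - 1L
  for (l in seq_along(lo)) {
    m <- (2L * k + 1L - (l - 1L)) %% n + 1L
    x[m] <- x[m] + approx * lo[l] + detail * hi[l]
  }
  x
}

# Multi-level periodized DWT. length(x) must be a multiple of 2^levels.
dwt_pyramid <- function(x, levels, lo, hi) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, lo, hi)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details)
}

idwt_pyramid <- function(pyr, lo, hi) {
  a <- pyr$approx
  for (j in rev(seq_along(pyr$details))) {
    a <- idwt_step(a, pyr$details[[j]], lo, hi)
  }
  a
}

# Reflect-pad x (without repeating the edge sample) to a multiple of `block`;
# returns the padded vector and the index range of the original samples.
reflect_pad <- function(x, block) {
  n <- length(x)
  pad <- (block - n %% block) %% block
  if (pad == 0L) return(list(x = x, first = 1L, last = n))
  stopifnot(n > pad)                      # enough samples to reflect from
  pl <- pad %/% 2L
  pr <- pad - pl
  left <- if (pl > 0L) rev(x[2L:(pl + 1L)]) else numeric(0)
  right <- if (pr > 0L) rev(x[(n - pr):(n - 1L)]) else numeric(0)
  list(x = c(left, x, right), first = pl + 1L, last = pl + n)
}
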