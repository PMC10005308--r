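# Internal numeric helpers shared across modules.

# Clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Minimum-image displacement for (possibly vector) separations under period L
min_image <- function(d, L) d - L * round(d / L)

# Row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize rows of an n x 3 matrix to unit length
normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-300)) stop("cannot normalize zero-length vector")
  m / n
}

# Row-wise cross product of two n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Second Legendre polynomial of x = cos(theta)
p2 <- function(x) 0.5 * (3 * x * x - 1)

# Rotation matrix taking the z axis onto unit vector `axis`
rotation_z_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * axis)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Sum over time origins of x(s) * x(s + lag), lags 0..n-1, via FFT.
# Returns a vector of raw sums; divide by (n - lag) for the origin mean.
acf_sums_fft <- function(x) {
  n <- length(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  s[seq_len(n)]
}

# 95% confidence half-width from a vector of (approximately) independent
# unit means; 0 for a single unit.
ci95 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0)
  1.96 * stats::sd(x) / sqrt(length(x))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
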