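# internal numerical helpers

# distance of index 0..n-1 from the origin on a circle of length n
wrap_dist <- function(n) pmin(0:(n - 1), n - 0:(n - 1))

# circular 2-D convolution via FFT; kernel must already be wrapped so its
# centre sits at [1, 1]
conv2d_circular <- function(x, kernel_wrapped) {
  Re(stats::fft(stats::fft(x) * stats::fft(kernel_wrapped), inverse = TRUE)) /
    length(x)
}

# zero-padded "same"-size convolution with an odd-sized kernel; used for
# moving-window class counts where edges must see a truncated window
conv2d_same <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(x) + 2L * kr
  nc <- ncol(x) + 2L * kc
  xp <- matrix(0, nr, nc)
  xp[kr + seq_len(nrow(x)), kc + seq_len(ncol(x))] <- x
  kw <- matrix(0, nr, nc)
  kw[(( -kr:kr) %% nr) + 1L, ((-kc:kc) %% nc) + 1L] <- kernel
  out <- conv2d_circular(xp, kw)
  out[kr + seq_len(nrow(x)), kc + seq_len(ncol(x))]
}

# standardized (mean 0, sd 1) spatially autocorrelated field: white noise
# smoothed with a Gaussian kernel of scale range_cells/2 on a padded torus,
# then cropped so opposite edges are not artificially correlated
gaussian_random_field <- function(n_rows, n_cols, range_cells) {
  f <- if (range_cells <= 0) {
    matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  } else {
    pad <- ceiling(3 * range_cells)
    nr <- n_rows + 2L * pad
    nc <- n_cols + 2L * pad
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    sigma <- range_cells / 2
    kern <- exp(-outer(wrap_dist(nr)^2, wrap_dist(nc)^2, "+") / (2 * sigma^2))
    sm <- conv2d_circular(noise, kern)
    sm[pad + seq_len(n_rows), pad + seq_len(n_cols)]
  }
  if (stats::sd(f) < .Machine$double.eps) {
    return(matrix(0, n_rows, n_cols))
  }
  (f - mean(f)) / stats::sd(f)
}

# affine rescale of a field onto [lo, hi]
rescale_range <- function(f, lo, hi) {
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) {
    return(array((lo + hi) / 2, dim = dim(f) %||% length(f)))
  }
  lo + (hi - lo) * (f - rng[1]) / diff(rng)
}

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(z, dr, dc) {
  nr <- nrow(z)
  nc <- ncol(z)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  z[ri, ci, drop = FALSE]
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number %s %s.",
      name, if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}
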