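# Sampled Gaussian (derivative) kernels and separable 3D filtering.
# Kernels are built at physical scale sigma (mm) on the voxel lattice and
# corrected to satisfy the exact discrete moment conditions: order 0 sums to
# one, order 1 reproduces the slope of a linear ramp, order 2 reproduces the
# second derivative of a parabola. Truncation at 4 sigma.

gaussian_kernel <- function(sigma, spacing, order = 0L, truncate = 4) {
  stopifnot(sigma > 0, spacing > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma / spacing)))
  x <- (-r:r) * spacing
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    w <- -x / sigma^2 * g
    w <- w - mean(w)
    w / sum(w * x)
  } else if (order == 2L) {
    w <- (x^2 / sigma^4 - 1 / sigma^2) * g
    w <- w - mean(w)
    2 * w / sum(w * x^2)
  } else stop("order must be 0, 1, or 2")
}

# Apply separable Gaussian-derivative filtering to a 3D array with per-axis
# derivative orders. spacing may be anisotropic; sigma is physical (mm).
filter_gaussian <- function(arr, sigma, spacing, orders = c(0L, 0L, 0L),
                            truncate = 4) {
  d <- dim(arr)
  out <- as.numeric(arr)
  dim(out) <- d
  for (axis in 1:3) {
    if (d[axis] == 1L && orders[axis] == 0L) next
    k <- gaussian_kernel(sigma, spacing[axis], orders[axis], truncate)
    out <- .sep_convolve(out, d, k, axis - 1L)
  }
  out
}
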