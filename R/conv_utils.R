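# Separable Gaussian filtering with reflected (edge-duplicating) borders.
# Shared by unsharp masking and the phantom's background texture.

# Fold an arbitrary index onto 1..n by reflection with edge duplication:
# ... 2 1 | 1 2 ... n-1 n | n n-1 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

gaussian_kernel1d <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

conv1d_axis <- function(m, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  n <- if (axis == 1L) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    idx <- reflect_index(seq_len(n) + (t - 1L - r), n)
    out <- out + k[t] * (if (axis == 1L) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

#' Gaussian blur of a 2D plane (separable, reflected borders)
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels.
#' @param truncate kernel support radius in sigmas (default 4).
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma, truncate = 4) {
  k <- gaussian_kernel1d(sigma, truncate)
  conv1d_axis(conv1d_axis(m, k, 1L), k, 2L)
}
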