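# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::fft) so they can arbitrate them.

# direct 2D DFT by explicit summation over all (u, v): O(N^4)
dft2_direct <- function(x, inverse = FALSE) {
  m <- nrow(x); n <- ncol(x)
  sgn <- if (inverse) 2i else -2i
  out <- matrix(0 + 0i, m, n)
  ys <- seq_len(m) - 1; xs <- seq_len(n) - 1
  for (u in ys) {
    for (v in xs) {
      phase <- exp(sgn * pi * outer(ys * u / m, xs * v / n, `+`))
      out[u + 1L, v + 1L] <- sum(x * phase)
    }
  }
  out
}

# centred -> unshifted spectrum index map (DC at centre -> index 1)
unshift_idx <- function(n) ((seq_len(n) - 1L + n %/% 2L) %% n) + 1L

# frequency-domain filtering via the direct DFT
filter_direct <- function(plane, centered_mask) {
  m <- nrow(plane); n <- ncol(plane)
  f <- dft2_direct(plane)
  f <- f * centered_mask[unshift_idx(m), unshift_idx(n)]
  dft2_direct(f, inverse = TRUE) / (m * n)
}

# brute-force global histogram equalization via a cumulative histogram
global_he_oracle <- function(plane, n_bins, bit_depth) {
  L <- 2^bit_depth
  counts <- numeric(n_bins)
  for (v in as.vector(plane)) {
    b <- min(floor(v / L * n_bins), n_bins - 1) + 1
    counts[b] <- counts[b] + 1
  }
  cdf <- numeric(n_bins)
  acc <- 0
  for (b in seq_len(n_bins)) {
    acc <- acc + counts[b]
    cdf[b] <- acc
  }
  mapping <- round(cdf / length(plane) * (L - 1))
  out <- plane
  for (i in seq_along(plane)) {
    b <- min(floor(plane[i] / L * n_bins), n_bins - 1) + 1
    out[i] <- mapping[b]
  }
  out
}

# direct 2D convolution with a full Gaussian kernel, reflected borders
# (edge-duplicating reflection, matching the documented border contract)
conv2_gauss_direct <- function(plane, sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    if (j < n) j + 1 else 2 * n - j
  }
  ny <- nrow(plane); nx <- ncol(plane)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      acc <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          acc <- acc + k2[dy + r + 1, dx + r + 1] *
            plane[refl(y + dy, ny), refl(x + dx, nx)]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

unsharp_direct <- function(plane, sigma, amount, threshold, bit_depth) {
  blur <- conv2_gauss_direct(plane, sigma)
  detail <- plane - blur
  out <- ifelse(abs(detail) > threshold, plane + amount * detail, plane)
  pmin(pmax(round(out), 0), 2^bit_depth - 1)
}

# sort-based percentile (linear interpolation of the order statistics)
percentile_direct <- function(x, p) {
  s <- sort(as.vector(x))
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# small deterministic 16-bit test plane with mixed content
fixture_plane <- function(ny = 32, nx = 32, seed = 1, lo = 0, hi = 65535) {
  set.seed(seed)
  # stored as doubles, matching the package's plane representation
  matrix(as.numeric(sample(lo:hi, ny * nx, replace = TRUE)), ny, nx)
}
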