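#' Pie-slice destriping filter geometry
#'
#' Shadow stripes cast by light-absorbing particles run along the light-sheet
#' propagation axis and make an angle `alpha` with the horizontal image edge.
#' In the centred 2D power spectrum their energy concentrates along a ray at
#' `90 - alpha` degrees, and is removed by attenuating a pie-slice (wedge)
#' shaped region there. The wedge is a symmetric trapezoid in
#' (radius, transverse-offset) coordinates: it spans radii `d1..d2` and its
#' full transverse width interpolates linearly from `w1` at `d1` to `w2` at
#' `d2`; the point-mirrored wedge is always included. A Gaussian transition
#' profile (`edge_sigma`) softens the wedge edges to avoid ringing from a
#' hard frequency cutoff.
#'
#' @param alpha_deg spatial stripe angle in degrees from the horizontal
#'   image edge, stored mod 180 (stripes are undirected).
#' @param d1,d2 inner/outer radial bounds in frequency-pixels
#'   (`1 <= d1 < d2`); `d2` may be the token `"nyquist"`, resolved per plane
#'   shape.
#' @param w1,w2 full transverse wedge widths (frequency-pixels) at `d1`/`d2`.
#' @param edge_sigma Gaussian transition standard deviation
#'   (frequency-pixels), `>= 0`.
#' @param attenuation suppression depth in `[0, 1]`; 1 removes the wedge
#'   band completely, 0 leaves the image untouched.
#' @return a validated `pie_filter_spec`.
#' @export
pie_filter_spec <- function(alpha_deg, d1 = 5, d2 = "nyquist", w1 = 3,
                            w2 = 9, edge_sigma = 2, attenuation = 1) {
  alpha_deg <- as.numeric(alpha_deg) %% 180
  d1 <- as.numeric(d1)
  if (!(identical(d2, "nyquist"))) {
    d2 <- as.numeric(d2)
    if (!(d1 >= 1 && d1 < d2)) stop("need 1 <= d1 < d2")
  } else if (d1 < 1) stop("need d1 >= 1")
  if (w1 <= 0 || w2 <= 0) stop("wedge widths w1, w2 must be positive")
  if (edge_sigma < 0) stop("edge_sigma must be >= 0")
  if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0,1]")
  structure(list(alpha_deg = alpha_deg, d1 = d1, d2 = d2, w1 = w1, w2 = w2,
                 edge_sigma = edge_sigma, attenuation = attenuation),
            class = "pie_filter_spec")
}

# resolve the "nyquist" token and clamp an over-large d2, per plane shape
resolve_d2 <- function(spec, shape) {
  nyq <- min(shape %/% 2L)
  if (identical(spec$d2, "nyquist")) return(max(nyq, spec$d1 + 1))
  max_r <- sqrt(sum((shape / 2)^2))
  if (spec$d2 > max_r) {
    lp_log("warn", "destripe", sprintf(
      "d2 = %g exceeds the largest representable radius %.1f; clamped to Nyquist (%d)",
      spec$d2, max_r, nyq))
    return(max(nyq, spec$d1 + 1))
  }
  spec$d2
}

# binary trapezoidal wedge (plus its point mirror) on the centred grid
pie_wedge_region <- function(shape, spec) {
  d2 <- resolve_d2(spec, shape)
  fc <- freq_coords(shape)
  a <- (90 - spec$alpha_deg) * pi / 180     # spectral axis angle
  axis_y <- sin(a); axis_x <- cos(a)
  r <- sqrt(fc$uy^2 + fc$ux^2)
  p <- abs(fc$uy * axis_x - fc$ux * axis_y) # perpendicular distance to axis
  h <- spec$w1 + (spec$w2 - spec$w1) * (r - spec$d1) / (d2 - spec$d1)
  r >= spec$d1 & r <= d2 & p <= h / 2
}

#' Build the pie-slice frequency mask for a plane shape
#'
#' The returned gain field lives on the centred spectrum (zero frequency at
#' the array centre), takes values in `[0, 1]`, is point-symmetric about DC
#' (so the filtered image stays real), and has gain exactly 1 at DC so the
#' mean intensity is preserved.
#'
#' @param shape integer `(rows, cols)`, each `>= 4`.
#' @param spec a [pie_filter_spec()].
#' @return a `frequency_mask` with fields `values` (matrix of gains) and
#'   `shape`.
#' @export
build_pie_mask <- function(shape, spec) {
  stopifnot(inherits(spec, "pie_filter_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L))
    stop("shape must be (rows, cols) with both >= 4")
  w <- pie_wedge_region(shape, spec) * 1
  if (spec$edge_sigma > 0)
    w <- gaussian_blur(w, spec$edge_sigma)
  w <- pmin(pmax(w, 0), 1)
  m <- 1 - spec$attenuation * w
  # enforce exact point symmetry (Hermitian-compatible), then DC gain 1
  m <- (m + m[mirror_indices(shape[1L]), mirror_indices(shape[2L])]) / 2
  fc <- freq_coords(shape)
  m[fc$center[1L], fc$center[2L]] <- 1
  structure(list(values = m, shape = shape), class = "frequency_mask")
}

#' Apply a centred frequency mask to one plane
#'
#' Forward FFT, element-wise multiplication by the mask (re-aligned to the
#' unshifted spectrum), inverse FFT. The imaginary residual of the inverse
#' transform must stay below `1e-6 * dtype max` (a larger residual signals a
#' non-symmetric mask and is an error). Rescaling back to integers:
#' `"clip"` truncates to `[0, 2^bit_depth - 1]`; `"minmax"` affinely maps
#' the raw result onto the input's own min/max range.
#'
#' @param plane integer-valued matrix.
#' @param mask a `frequency_mask` from [build_pie_mask()].
#' @param rescale_mode `"clip"` (default) or `"minmax"`.
#' @param bit_depth 8 or 16.
#' @return integer-valued matrix, same shape and dtype range as the input.
#' @export
apply_frequency_filter <- function(plane, mask, rescale_mode = "clip",
                                   bit_depth = 16L) {
  stopifnot(inherits(mask, "frequency_mask"))
  if (!identical(dim(plane), as.integer(mask$shape)))
    stop(sprintf("mask shape %dx%d does not match plane %dx%d",
                 mask$shape[1L], mask$shape[2L], nrow(plane), ncol(plane)))
  rescale_mode <- match.arg(rescale_mode, c("clip", "minmax"))
  dmax <- 2^as.integer(bit_depth) - 1
  inv <- filter_plane_raw(plane, mask)
  im_max <- max(abs(Im(inv)))
  if (im_max >= 1e-6 * dmax)
    stop(sprintf(
      "imaginary residual %.3g exceeds 1e-6 of dtype max (non-symmetric mask?)",
      im_max))
  out <- Re(inv)
  if (rescale_mode == "clip") {
    out <- pmin(pmax(out, 0), dmax)
  } else {
    lo <- min(plane); hi <- max(plane)
    rlo <- min(out); rhi <- max(out)
    out <- if (rhi > rlo) lo + (out - rlo) / (rhi - rlo) * (hi - lo)
           else matrix(lo, nrow(plane), ncol(plane))
  }
  matrix(round(out), nrow(plane), ncol(plane))
}

# pre-rescale filtered plane (complex); the rescaling contract lives in
# apply_frequency_filter
filter_plane_raw <- function(plane, mask) {
  f <- stats::fft(plane) * ifftshift2(mask$values)
  stats::fft(f, inverse = TRUE) / length(plane)
}

.mask_cache <- new.env(parent = emptyenv())

#' Remove directional stripes from one plane
#'
#' Composition of [build_pie_mask()] and [apply_frequency_filter()]; masks
#' are memoized per `(shape, spec)` so whole-stack runs build each mask
#' once.
#'
#' @inheritParams apply_frequency_filter
#' @param spec a [pie_filter_spec()].
#' @return filtered integer-valued matrix.
#' @export
destripe_plane <- function(plane, spec, rescale_mode = "clip",
                           bit_depth = 16L) {
  if (any(dim(plane) < 4L)) stop("plane must be at least 4x4")
  key <- digest::digest(list(dim(plane), unclass(spec)))
  mask <- .mask_cache[[key]]
  if (is.null(mask)) {
    mask <- build_pie_mask(dim(plane), spec)
    .mask_cache[[key]] <- mask
  }
  apply_frequency_filter(plane, mask, rescale_mode, bit_depth)
}

#' Estimate the stripe angle from the power spectrum
#'
#' Computes the median centred log-power spectrum over the supplied planes
#' (each plane is Hann-windowed first to suppress the boundary-discontinuity
#' cross along the spectral axes), converts back to power, sums it over
#' angular direction bins of width `180 / n_theta` degrees restricted to the
#' radial band, excluding a 3-pixel guard block around DC, and converts the
#' peak direction
#' `theta*` back to the spatial stripe angle `alpha = (90 - theta*) mod 180`.
#'
#' @param planes a matrix, a list of matrices, or an [image_stack()].
#' @param radial_band `(d1, d2)` radii in frequency-pixels; `d2 = NA` means
#'   Nyquist, and `radial_band = NULL` (default) resolves to
#'   `(Nyquist / 4, Nyquist)`. Stripe shadows are thin, so their energy
#'   extends to high spatial frequencies where thick anatomical structures
#'   no longer contribute; estimating in the upper band separates the two.
#' @param n_theta number of direction bins over 180 degrees (default 180,
#'   i.e. 1-degree bins).
#' @param confidence_ratio flag threshold: when peak bin power is less than
#'   this multiple of the median bin power the estimate is marked
#'   low-confidence (attribute `low_confidence`, plus a warning).
#' @return the estimated angle in degrees (`[0, 180)`), with attributes
#'   `theta_power` (per-bin sums) and `low_confidence`.
#' @export
estimate_stripe_angle <- function(planes, radial_band = NULL,
                                  n_theta = 180L, confidence_ratio = 2) {
  if (inherits(planes, "image_stack")) {
    stk <- planes
    planes <- lapply(seq_len(dim(stk$planes)[1L]), function(z) get_plane(stk, z))
  }
  if (is.matrix(planes)) planes <- list(planes)
  if (length(planes) == 0L) stop("need at least one plane")
  shape <- dim(planes[[1L]])
  if (is.null(radial_band))
    radial_band <- c(max(5, min(shape %/% 2L) / 4), NA)
  # radial Hann window: isotropic spectral leakage (a separable window's
  # cross-shaped sidelobes would bias the 0/90-degree direction bins)
  rn <- sqrt(outer(((seq_len(shape[1L]) - (shape[1L] + 1) / 2) /
                      (shape[1L] / 2))^2,
                   ((seq_len(shape[2L]) - (shape[2L] + 1) / 2) /
                      (shape[2L] / 2))^2, `+`))
  win <- 0.5 + 0.5 * cos(pi * pmin(rn, 1))
  logp <- lapply(planes, function(p) {
    p <- (p - mean(p)) * win
    log1p(fftshift2(Mod(stats::fft(p))^2))
  })
  # median across planes in log space (robust to per-plane outliers), then
  # back to power so genuinely dominant directions dominate the bin sums
  med <- expm1(apply(simplify2array(logp), c(1L, 2L), stats::median))

  fc <- freq_coords(shape)
  r <- sqrt(fc$uy^2 + fc$ux^2)
  d1 <- radial_band[1L]
  d2 <- if (is.na(radial_band[2L])) min(shape %/% 2L) else radial_band[2L]
  if (d2 > min(shape %/% 2L)) d2 <- min(shape %/% 2L)
  guard <- pmax(abs(fc$uy), abs(fc$ux)) <= 3    # DC cross guard
  sel <- r >= d1 & r <= d2 & !guard
  if (sum(med[sel]) <= 0)
    stop("no spectral energy in the radial band (constant planes?)")

  dtheta <- 180 / n_theta
  theta <- (atan2(fc$uy, fc$ux) * 180 / pi) %% 180
  bin <- (round(theta / dtheta) %% n_theta) + 1L   # bins centred on k*dtheta
  sums <- vapply(seq_len(n_theta), function(b) sum(med[sel & bin == b]),
                 numeric(1L))
  b_star <- which.max(sums)
  theta_star <- (b_star - 1L) * dtheta
  low <- max(sums) < confidence_ratio * stats::median(sums)
  if (low)
    warning("no dominant stripe direction (peak/median bin power < ",
            confidence_ratio, "); estimate is low-confidence")
  structure((90 - theta_star) %% 180,
            theta_power = sums, low_confidence = low)
}

#' Spectral energy inside the binary wedge band
#'
#' Sum of squared spectrum magnitudes over the un-smoothed trapezoidal
#' wedge region of `spec` (DC excluded). Together with the complement and
#' the DC term this partitions the plane's total spectral energy
#' (Parseval).
#'
#' @param plane integer-valued matrix.
#' @param spec a [pie_filter_spec()].
#' @return nonnegative scalar.
#' @export
stripe_band_energy <- function(plane, spec) {
  stopifnot(inherits(spec, "pie_filter_spec"))
  p <- fftshift2(Mod(stats::fft(plane))^2)
  w <- pie_wedge_region(dim(plane), spec)
  fc <- freq_coords(dim(plane))
  w[fc$center[1L], fc$center[2L]] <- FALSE
  sum(p[w])
}
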