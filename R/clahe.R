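#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization works on a grid of
#' contextual tiles: each tile's histogram is clipped at
#' `clip_limit * tile_pixels`, the clipped excess is redistributed uniformly
#' over all bins, and each tile's cumulative mapping is blended into its
#' neighbours' by bilinear interpolation. For high-bit-depth recordings the
#' bin count should match the dynamic range (65536 bins for 16-bit) so that
#' barely perceptible brightness differences are preserved and expanded
#' rather than quantized away; `n_bins = NULL` resolves to `2^bit_depth` at
#' run time.
#'
#' @param tile_rows,tile_cols contextual tile grid (>= 1 each).
#' @param clip_limit clip fraction in `(0, 1]`; 1 disables clipping.
#' @param n_bins histogram bin count (>= 2), or `NULL` for `2^bit_depth`.
#' @return a validated `clahe_params` list.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_limit = 0.01,
                         n_bins = NULL) {
  tile_rows <- as.integer(tile_rows); tile_cols <- as.integer(tile_cols)
  if (tile_rows < 1L || tile_cols < 1L)
    stop("tile grid dimensions must be >= 1")
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1)
    stop("clip_limit must be in (0, 1]")
  if (!is.null(n_bins)) {
    n_bins <- as.integer(n_bins)
    if (n_bins < 2L) stop("n_bins must be >= 2")
  }
  structure(list(tile_rows = tile_rows, tile_cols = tile_cols,
                 clip_limit = clip_limit, n_bins = n_bins),
            class = "clahe_params")
}

# near-equal integer partition of n into k contiguous runs
tile_bounds <- function(n, k) {
  cuts <- round(seq(0, n, length.out = k + 1L))
  cbind(lo = cuts[-(k + 1L)] + 1L, hi = cuts[-1L])
}

# clipped + uniformly redistributed histogram -> intensity mapping.
# Redistribution is real-valued single-pass (excess/n_bins to every bin),
# which conserves histogram mass exactly.
clahe_tile_mapping <- function(counts, clip_limit, n_pixels, out_max) {
  clip <- clip_limit * n_pixels
  excess <- sum(pmax(counts - clip, 0))
  h <- pmin(counts, clip) + excess / n_bins_of(counts)
  stopifnot(abs(sum(h) - n_pixels) <= 1e-6 * max(1, n_pixels))
  round(cumsum(h) / n_pixels * out_max)
}

n_bins_of <- function(counts) length(counts)

#' Contrast-limited adaptive histogram equalization of one plane
#'
#' With `tile_rows = tile_cols = 1` and `clip_limit = 1` this reduces to
#' plain global histogram equalization. Interior pixels are blended from the
#' four surrounding tile mappings (bilinear, on tile centres); border pixels
#' clamp the tile coordinate (replicate), i.e. the half-tile frame around
#' the plane uses the nearest tile's mapping directly.
#'
#' @param plane numeric matrix `(y, x)` of integers in
#'   `[0, 2^bit_depth - 1]`.
#' @param params a [clahe_params()].
#' @param bit_depth 8 or 16.
#' @return integer-valued matrix of the same shape and range.
#' @export
equalize_clahe <- function(plane, params = clahe_params(), bit_depth = 16L) {
  stopifnot(inherits(params, "clahe_params"))
  L <- 2^as.integer(bit_depth)
  ny <- nrow(plane); nx <- ncol(plane)
  tr <- params$tile_rows; tc <- params$tile_cols
  if (tr > ny || tc > nx)
    stop(sprintf("tile grid %dx%d exceeds plane %dx%d", tr, tc, ny, nx))
  n_bins <- if (is.null(params$n_bins)) L else params$n_bins
  if (n_bins > L)
    stop(sprintf("n_bins (%d) exceeds dtype capacity (%d)", n_bins, L))

  bins <- pmin(floor(plane / L * n_bins), n_bins - 1) + 1L  # 1..n_bins
  yb <- tile_bounds(ny, tr); xb <- tile_bounds(nx, tc)

  maps <- matrix(0, n_bins, tr * tc)  # one cumulative mapping per tile
  for (j in seq_len(tc)) {
    for (i in seq_len(tr)) {
      sub <- bins[yb[i, "lo"]:yb[i, "hi"], xb[j, "lo"]:xb[j, "hi"]]
      counts <- tabulate(sub, nbins = n_bins)
      maps[, (j - 1L) * tr + i] <-
        clahe_tile_mapping(counts, params$clip_limit, length(sub), L - 1)
    }
  }

  blend <- function(pos, bounds, k) {
    centers <- (bounds[, "lo"] + bounds[, "hi"]) / 2
    i0 <- findInterval(pos, centers)
    i1 <- pmin(i0 + 1L, k)
    i0 <- pmax(i0, 1L)
    span <- centers[i1] - centers[i0]
    w <- ifelse(span > 0, (pos - centers[i0]) / span, 0)
    w[pos <= centers[1L]] <- 0
    list(lo = i0, hi = i1, w = w)
  }
  by <- blend(seq_len(ny), yb, tr)
  bx <- blend(seq_len(nx), xb, tc)

  wy <- matrix(by$w, ny, nx)            # weight toward the lower tile row
  wx <- matrix(bx$w, ny, nx, byrow = TRUE)
  tile_col <- function(iy, jx) {
    # linear index into maps for tile (iy, jx), expanded to the plane
    matrix(iy, ny, nx) + (matrix(jx, ny, nx, byrow = TRUE) - 1L) * tr
  }
  gather <- function(tiles) maps[bins + (tiles - 1L) * n_bins]
  out <- (1 - wy) * (1 - wx) * gather(tile_col(by$lo, bx$lo)) +
         (1 - wy) * wx       * gather(tile_col(by$lo, bx$hi)) +
         wy       * (1 - wx) * gather(tile_col(by$hi, bx$lo)) +
         wy       * wx       * gather(tile_col(by$hi, bx$hi))
  matrix(round(out), ny, nx)
}
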