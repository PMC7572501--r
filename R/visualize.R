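#' Intensity threshold scheme
#'
#' Tissue types in monochrome autofluorescence recordings are distinguished
#' by characteristic intensity: the brightest voxels correspond to
#' erythrocytes, microcalcifications, vessels and collagen; nuclei and fat
#' appear dark. A scheme is an ordered list of half-open intensity intervals
#' `[lower, upper)`, each carrying a label; voxels covered by no interval
#' get the background label.
#'
#' @param intervals named list; each element `c(lower, upper)` with
#'   `lower < upper`, bounds within the dtype range, intervals pairwise
#'   non-overlapping.
#' @param background label name for uncovered intensities.
#' @return a validated `threshold_scheme`.
#' @export
threshold_scheme <- function(intervals, background = "background") {
  if (length(intervals) == 0L || is.null(names(intervals)))
    stop("intervals must be a non-empty named list")
  b <- t(vapply(intervals, function(iv) {
    if (length(iv) != 2L || iv[1L] >= iv[2L])
      stop("each interval must be c(lower, upper) with lower < upper")
    as.numeric(iv)
  }, numeric(2L)))
  o <- order(b[, 1L])
  if (any(b[o, 2L][-nrow(b)] > b[o, 1L][-1L] + 1e-12))
    stop("intervals overlap")
  structure(list(labels = names(intervals), lower = b[, 1L],
                 upper = b[, 2L], background = background),
            class = "threshold_scheme")
}

#' Intensity-based threshold segmentation of a stack
#'
#' @param stack an [image_stack()].
#' @param scheme a [threshold_scheme()]; bounds must lie within the stack's
#'   dtype range.
#' @return list with `labels` (integer volume, 0 = background, i = i-th
#'   interval) and `legend` (data.frame: code, label, lower, upper).
#' @export
threshold_segment <- function(stack, scheme) {
  stopifnot(inherits(stack, "image_stack"), inherits(scheme, "threshold_scheme"))
  if (any(scheme$upper > dtype_max(stack) + 1) || any(scheme$lower < 0))
    stop("scheme bounds outside the stack's dtype range")
  lab <- array(0L, dim = dim(stack$planes))
  for (i in seq_along(scheme$labels)) {
    sel <- stack$planes >= scheme$lower[i] & stack$planes < scheme$upper[i]
    lab[sel] <- i
  }
  legend <- data.frame(code = c(0L, seq_along(scheme$labels)),
                       label = c(scheme$background, scheme$labels),
                       lower = c(NA, scheme$lower),
                       upper = c(NA, scheme$upper))
  list(labels = lab, legend = legend)
}

#' Piecewise-linear colour map
#'
#' @param name map name.
#' @param points data.frame/matrix with columns `frac, r, g, b`: intensity
#'   fraction (strictly increasing, first 0, last 1) and RGB in `[0, 255]`.
#' @return a `lumipipe_colormap`.
#' @export
colormap <- function(name, points) {
  points <- as.data.frame(points)
  stopifnot(all(c("frac", "r", "g", "b") %in% names(points)))
  f <- points$frac
  if (f[1L] != 0 || f[length(f)] != 1 || any(diff(f) <= 0))
    stop("control points must start at 0, end at 1, strictly increasing")
  if (any(points[, c("r", "g", "b")] < 0 | points[, c("r", "g", "b")] > 255))
    stop("RGB components must be in [0, 255]")
  structure(list(name = name, points = points), class = "lumipipe_colormap")
}

#' Built-in colour maps
#'
#' `"grayscale"` and `"hotbody"` (black-red-yellow-white) are monotone in
#' luminance; `"diverging"` (blue-white-red) is not (bright midpoint) and
#' is meant for signed/centred quantities.
#'
#' @param name one of `"grayscale"`, `"hotbody"`, `"diverging"`.
#' @return a [colormap()].
#' @export
builtin_colormap <- function(name = c("grayscale", "hotbody", "diverging")) {
  name <- match.arg(name)
  pts <- switch(name,
    grayscale = data.frame(frac = c(0, 1), r = c(0, 255), g = c(0, 255),
                           b = c(0, 255)),
    hotbody = data.frame(frac = c(0, 0.4, 0.8, 1),
                         r = c(0, 230, 255, 255), g = c(0, 0, 210, 255),
                         b = c(0, 0, 0, 255)),
    diverging = data.frame(frac = c(0, 0.5, 1), r = c(40, 255, 200),
                           g = c(60, 255, 30), b = c(200, 255, 40)))
  colormap(name, pts)
}

#' Map stack intensities to RGB through a colour map
#'
#' Intensities are affinely mapped through `display_range` onto `[0, 1]`
#' (values outside are clamped), then piecewise-linearly interpolated
#' through the map's control points. `display_range = "auto"` uses the
#' stack's 1st/99th intensity percentiles.
#'
#' @param stack an [image_stack()].
#' @param cmap a [colormap()] or a built-in map name.
#' @param display_range `c(lo, hi)` with `lo < hi`, or `"auto"`.
#' @return 4D numeric array `(z, y, x, channel)` of 8-bit RGB values.
#' @export
apply_colormap <- function(stack, cmap = "grayscale",
                           display_range = "auto") {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(cmap)) cmap <- builtin_colormap(cmap)
  if (identical(display_range, "auto")) {
    display_range <- intensity_percentiles(stack$planes, c(0.01, 0.99))
    if (display_range[1L] >= display_range[2L])
      display_range <- range(stack$planes) + c(0, 1)
  }
  lo <- display_range[1L]; hi <- display_range[2L]
  if (!(lo < hi)) stop("degenerate display range (need lo < hi)")
  fr <- pmin(pmax((stack$planes - lo) / (hi - lo), 0), 1)
  d <- dim(stack$planes)
  out <- array(0, dim = c(d, 3L))
  p <- cmap$points
  for (ch in 1:3) {
    v <- stats::approx(p$frac, p[[c("r", "g", "b")[ch]]], xout = as.vector(fr),
                       rule = 2)$y
    out[, , , ch] <- round(v)
  }
  out
}

# linearly interpolated percentiles of a sorted sample (quantile type 7)
intensity_percentiles <- function(x, probs) {
  s <- sort(as.vector(x))
  n <- length(s)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }, numeric(1L))
}

#' Extract one orthogonal virtual slice
#'
#' @param stack an [image_stack()].
#' @param axis `"z"` (stored plane), `"y"` or `"x"`.
#' @param index 1-based index along the chosen axis.
#' @return 2D numeric matrix (for `axis = "z"`: `(y, x)`; `"y"`: `(z, x)`;
#'   `"x"`: `(z, y)`).
#' @export
extract_virtual_slice <- function(stack, axis = c("z", "y", "x"), index) {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  d <- dim(stack$planes)
  n <- d[match(axis, c("z", "y", "x"))]
  if (index < 1L || index > n)
    stop(sprintf("index %d out of 1..%d along axis %s", index, n, axis))
  switch(axis,
         z = stack$planes[index, , ],
         y = stack$planes[, index, ],
         x = stack$planes[, , index])
}
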