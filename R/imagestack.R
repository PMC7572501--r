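#' Grayscale image stack
#'
#' The unit of pipeline processing: an ordered set of 2D grayscale planes
#' sharing dimensions and bit depth, stored as a 3D integer array indexed
#' `(z, y, x)` with `y` increasing downward (row-major image convention).
#'
#' @param planes 3D numeric array indexed `(z, y, x)`, or a list of equally
#'   sized 2D matrices (converted). Values must be integers in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @param voxel_size optional numeric triple, micrometres per voxel along
#'   `(z, y, x)`; all components strictly positive.
#' @param name free-text identifier carried through processing.
#'
#' @return An object of class `image_stack` with fields `planes`,
#'   `bit_depth`, `voxel_size`, `name`.
#' @export
image_stack <- function(planes, bit_depth = 16L, voxel_size = NULL,
                        name = "stack") {
  if (is.list(planes)) {
    dims <- unique(lapply(planes, dim))
    if (length(dims) != 1L)
      stop("all planes must share identical (y, x) dimensions")
    arr <- array(0, dim = c(length(planes), dims[[1L]]))
    for (i in seq_along(planes)) arr[i, , ] <- planes[[i]]
    planes <- arr
  }
  if (!is.array(planes) || length(dim(planes)) != 3L)
    stop("planes must be a 3D array indexed (z, y, x)")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  if (dim(planes)[1L] < 1L)
    stop("plane count must be >= 1")
  rng <- range(planes)
  if (is.na(rng[1L]))
    stop("planes contain NA")
  if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1)
    stop(sprintf("intensities outside [0, %d]", 2L^bit_depth - 1L))
  if (any(planes != round(planes)))
    stop("intensities must be integers")
  if (!is.null(voxel_size)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("voxel_size must be a strictly positive (z, y, x) triple")
  }
  structure(
    list(planes = planes, bit_depth = bit_depth,
         voxel_size = voxel_size, name = as.character(name)[1L]),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<image_stack '%s': %d plane(s) of %d x %d, %d-bit", x$name,
              d[1L], d[2L], d[3L], x$bit_depth))
  if (!is.null(x$voxel_size))
    cat(sprintf(", voxel %.3g x %.3g x %.3g um", x$voxel_size[1L],
                x$voxel_size[2L], x$voxel_size[3L]))
  cat(">\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$planes)

#' Maximum representable grey value of a stack or bit depth
#'
#' For 16-bit stacks this is 65535 grey levels above zero, the full dynamic
#' range the pipeline preserves end to end.
#'
#' @param x an `image_stack` or an integer bit depth.
#' @return integer, `2^bit_depth - 1`.
#' @export
dtype_max <- function(x) {
  bd <- if (inherits(x, "image_stack")) x$bit_depth else as.integer(x)
  as.integer(2^bd - 1)
}

#' Extract one plane as a matrix
#' @param stack an `image_stack`.
#' @param z plane index (1-based).
#' @return numeric matrix `(y, x)`.
#' @export
get_plane <- function(stack, z) {
  nz <- dim(stack$planes)[1L]
  if (z < 1L || z > nz) stop(sprintf("plane index %d out of 1..%d", z, nz))
  stack$planes[z, , ]
}

#' Replace one plane
#' @inheritParams get_plane
#' @param value numeric matrix of matching `(y, x)` shape.
#' @return the modified stack.
#' @export
set_plane <- function(stack, z, value) {
  stack$planes[z, , ] <- value
  stack
}
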