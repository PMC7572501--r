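#' Unsharp-masking parameters
#'
#' Sharpening adds back a scaled high-frequency detail layer,
#' `detail = plane - Gaussian_sigma(plane)`, wherever `|detail|` exceeds
#' `threshold`. Defaults give a slight sharpening suitable as the last
#' stage of the chain.
#'
#' @param sigma Gaussian blur standard deviation in pixels (> 0).
#' @param amount detail gain (>= 0); 0 is the exact identity.
#' @param threshold integer intensity difference below which a pixel is
#'   left untouched.
#' @return a validated `unsharp_params` list.
#' @export
unsharp_params <- function(sigma = 1.5, amount = 0.5, threshold = 0) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(amount) || amount < 0) stop("amount must be >= 0")
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be >= 0")
  structure(list(sigma = sigma, amount = amount, threshold = threshold),
            class = "unsharp_params")
}

#' Unsharp masking of one plane
#'
#' The Gaussian blur uses reflected borders (no halo at plane edges); the
#' result is rounded and clipped to the dtype range.
#'
#' @param plane integer-valued matrix.
#' @param params an [unsharp_params()].
#' @param bit_depth 8 or 16.
#' @return integer-valued matrix, same shape.
#' @export
unsharp_mask <- function(plane, params = unsharp_params(), bit_depth = 16L) {
  stopifnot(inherits(params, "unsharp_params"))
  if (length(plane) == 0L) stop("plane must be nonempty")
  if (params$threshold > dtype_max(bit_depth))
    stop("threshold exceeds dtype max")
  if (params$amount == 0) return(plane)
  detail <- plane - gaussian_blur(plane, params$sigma)
  out <- ifelse(abs(detail) > params$threshold,
                plane + params$amount * detail, plane)
  matrix(pmin(pmax(round(out), 0), dtype_max(bit_depth)),
         nrow(plane), ncol(plane))
}
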