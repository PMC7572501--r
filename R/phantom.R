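#' Synthetic cleared-tissue phantom specification
#'
#' The phantom emulates the intensity structure of autofluorescence
#' ultramicroscopy recordings of cleared tumour tissue: a textured
#' background, bright tubular vessels (vascular structures and collagen
#' fibres carry the highest autofluorescence), dark ellipsoidal nuclei,
#' multiplicative occluder shadows at a known stripe angle (pigmented
#' particles obstructing the light sheet), and sensor noise. Ground-truth
#' masks are recorded before shadows and noise so every pipeline stage can
#' be scored against a known answer.
#'
#' @param shape integer `(z, y, x)`.
#' @param bit_depth 8 or 16.
#' @param background_level mean background intensity.
#' @param texture_sigma low-pass scale of the background texture in pixels;
#'   0 disables texture.
#' @param n_vessels,vessel_radius,vessel_intensity bright tube count,
#'   radius range (pixels) and intensity.
#' @param n_nuclei,nucleus_radius,nucleus_intensity dark ellipsoid count,
#'   radius range and (low) intensity.
#' @param stripe_angle_deg spatial stripe angle `alpha` in degrees.
#' @param occluders_per_plane shadow-casting occluders per plane.
#' @param shadow_width shadow band width in pixels.
#' @param shadow_attenuation fractional intensity loss in the shadow,
#'   `[0, 1]`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param poisson apply Poisson (shot) noise before the Gaussian term.
#' @param seed integer RNG seed; a fixed seed gives bit-identical stacks.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(16L, 256L, 256L), bit_depth = 16L,
                         background_level = 8000, texture_sigma = 8,
                         n_vessels = 4L, vessel_radius = c(3, 6),
                         vessel_intensity = 50000,
                         n_nuclei = 30L, nucleus_radius = c(2, 4),
                         nucleus_intensity = 2000,
                         stripe_angle_deg = 25, occluders_per_plane = 20L,
                         shadow_width = 3, shadow_attenuation = 0.5,
                         noise_sigma = 200, poisson = FALSE, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be (z, y, x)")
  dmax <- dtype_max(bit_depth)
  for (v in c(background_level, vessel_intensity, nucleus_intensity))
    if (v < 0 || v > dmax) stop("structure intensity outside dtype range")
  if (shadow_attenuation < 0 || shadow_attenuation > 1)
    stop("shadow_attenuation must be in [0, 1]")
  if (texture_sigma < 0 || noise_sigma < 0 || shadow_width <= 0)
    stop("invalid texture/noise/shadow parameter")
  structure(list(shape = shape, bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 texture_sigma = texture_sigma,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = as.numeric(vessel_radius),
                 vessel_intensity = vessel_intensity,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = as.numeric(nucleus_radius),
                 nucleus_intensity = nucleus_intensity,
                 stripe_angle_deg = as.numeric(stripe_angle_deg) %% 180,
                 occluders_per_plane = as.integer(occluders_per_plane),
                 shadow_width = shadow_width,
                 shadow_attenuation = shadow_attenuation,
                 noise_sigma = noise_sigma, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# stamp a soft-edged ball into `vol` (z, y, x); returns list(vol, coverage)
# coverage is distance-based partial coverage: clamp(R + 0.5 - d, 0, 1),
# the package's anti-aliasing rule; truth masks use coverage >= 0.5.
stamp_ball <- function(vol, cov, center, radius, zscale = 1) {
  d <- dim(vol)
  rz <- ceiling(radius / zscale) + 1; rxy <- ceiling(radius) + 1
  lo <- pmax(1, floor(center - c(rz, rxy, rxy)))
  hi <- pmin(d, ceiling(center + c(rz, rxy, rxy)))
  if (any(lo > hi)) return(cov)   # ball entirely outside the volume
  zr <- lo[1L]:hi[1L]; yr <- lo[2L]:hi[2L]; xr <- lo[3L]:hi[3L]
  dz2 <- ((zr - center[1L]) * zscale)^2
  dy2 <- (yr - center[2L])^2
  dx2 <- (xr - center[3L])^2
  dist <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
  c_new <- pmin(pmax(radius + 0.5 - dist, 0), 1)
  cov[zr, yr, xr] <- pmax(cov[zr, yr, xr], c_new)
  cov
}

#' Multiplicative occluder-shadow field for one plane
#'
#' Each occluder casts a half-line shadow downstream along the stripe
#' direction `alpha` (measured counter-clockwise on screen from the
#' horizontal image edge): pixels within perpendicular distance `width / 2`
#' of the half-line get gain `1 - attenuation`; overlapping shadows are
#' floor-bounded at `1 - attenuation`.
#'
#' @param shape integer `(y, x)`.
#' @param angle_deg stripe angle alpha in degrees.
#' @param occluders matrix or data.frame with columns `(y, x)`, one row per
#'   occluder position (may have zero rows).
#' @param width shadow band width in pixels.
#' @param attenuation fractional loss in `[0, 1]`.
#' @return numeric gain matrix in `[1 - attenuation, 1]`.
#' @export
generate_shadow_field <- function(shape, angle_deg, occluders, width,
                                  attenuation) {
  shape <- as.integer(shape)
  gain <- matrix(1, shape[1L], shape[2L])
  occluders <- as.matrix(occluders)
  if (nrow(occluders) == 0L || attenuation == 0) return(gain)
  if (any(occluders[, 1L] < 1 | occluders[, 1L] > shape[1L] |
          occluders[, 2L] < 1 | occluders[, 2L] > shape[2L]))
    stop("occluder positions must lie within the plane")
  a <- angle_deg * pi / 180
  # screen-CCW angle with y increasing downward: direction (dy, dx)
  dy <- -sin(a); dx <- cos(a)
  yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  for (i in seq_len(nrow(occluders))) {
    ry <- yy - occluders[i, 1L]; rx <- xx - occluders[i, 2L]
    t <- ry * dy + rx * dx            # along-ray coordinate
    p <- abs(ry * dx - rx * dy)       # perpendicular distance
    shadow <- t >= 0 & p <= width / 2
    gain[shadow] <- gain[shadow] * (1 - attenuation)
  }
  pmax(gain, 1 - attenuation)
}

#' Generate a synthetic phantom stack with ground truth
#'
#' Deterministic for a fixed seed. Internally three sub-seeds (`seed`,
#' `seed + 1`, `seed + 2`) drive structures/texture, occluder placement and
#' noise respectively, so the stripe-free twin of a phantom
#' (`occluders_per_plane = 0`, same seed) differs from it only through the
#' shadow field — structures and noise draws are shared.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (an [image_stack()]) and `truth` (list:
#'   `vessel_mask`, `nuclei_mask` boolean volumes; `stripe_mask` boolean
#'   volume, TRUE where a shadow attenuates; `occluders` per-plane list of
#'   position matrices).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # --- structures & texture ------------------------------------------------
  set.seed(spec$seed)
  vol <- array(spec$background_level, dim = d)
  if (spec$texture_sigma > 0) {
    amp <- 0.1 * spec$background_level    # fixed texture contrast: 10% of bg
    for (z in seq_len(d[1L])) {
      tex <- gaussian_blur(matrix(stats::rnorm(d[2L] * d[3L]), d[2L], d[3L]),
                           spec$texture_sigma, truncate = 3)
      tex <- tex / max(stats::sd(tex), 1e-12)
      vol[z, , ] <- vol[z, , ] + amp * tex
    }
  }

  vcov <- array(0, dim = d)
  if (spec$n_vessels > 0) {
    for (v in seq_len(spec$n_vessels)) {
      radius <- stats::runif(1, spec$vessel_radius[1L], spec$vessel_radius[2L])
      pos <- c(stats::runif(1, 1, d[1L]), stats::runif(1, 1, d[2L]),
               stats::runif(1, 1, d[3L]))
      theta <- stats::runif(1, 0, 2 * pi)
      dir <- c(stats::runif(1, -0.2, 0.2), sin(theta), cos(theta))
      dir <- dir / sqrt(sum(dir^2))
      n_steps <- ceiling(1.5 * max(d[2L], d[3L]))
      for (s in seq_len(n_steps)) {   # random-walk centreline, unit steps
        vcov <- stamp_ball(vol, vcov, pos, radius,
                           zscale = max(1, d[2L] / max(d[1L], 1) / 4))
        turn <- stats::rnorm(3, 0, 0.08)
        dir <- dir + turn; dir <- dir / sqrt(sum(dir^2))
        pos <- pos + dir
        if (any(pos < -radius) || any(pos > d + radius)) break
      }
    }
  }

  ncov <- array(0, dim = d)
  if (spec$n_nuclei > 0) {
    for (k in seq_len(spec$n_nuclei)) {
      radius <- stats::runif(1, spec$nucleus_radius[1L],
                             spec$nucleus_radius[2L])
      pos <- c(stats::runif(1, 1, d[1L]), stats::runif(1, 1, d[2L]),
               stats::runif(1, 1, d[3L]))
      ncov <- stamp_ball(vol, ncov, pos, radius, zscale = 1)
    }
  }
  # nuclei override background, vessels override nuclei (brightest wins)
  vol <- vol * (1 - ncov) + spec$nucleus_intensity * ncov
  vol <- vol * (1 - vcov) + spec$vessel_intensity * vcov
  vessel_mask <- vcov >= 0.5
  nuclei_mask <- ncov >= 0.5 & !vessel_mask

  # --- occluder shadows ----------------------------------------------------
  set.seed(spec$seed + 1L)
  stripe_mask <- array(FALSE, dim = d)
  occluders <- vector("list", d[1L])
  for (z in seq_len(d[1L])) {
    if (spec$occluders_per_plane > 0L) {
      occ <- cbind(y = stats::runif(spec$occluders_per_plane, 1, d[2L]),
                   x = stats::runif(spec$occluders_per_plane, 1, d[3L]))
    } else {
      occ <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("y", "x")))
    }
    occluders[[z]] <- occ
    gain <- generate_shadow_field(d[2:3], spec$stripe_angle_deg, occ,
                                  spec$shadow_width, spec$shadow_attenuation)
    stripe_mask[z, , ] <- gain < 1
    vol[z, , ] <- vol[z, , ] * gain
  }

  # --- noise & quantization ------------------------------------------------
  set.seed(spec$seed + 2L)
  if (spec$poisson)
    vol[] <- stats::rpois(length(vol), lambda = pmax(vol, 0))
  if (spec$noise_sigma > 0)
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sigma)
  vol <- array(pmin(pmax(round(vol), 0), dtype_max(spec$bit_depth)), dim = d)

  list(stack = image_stack(vol, bit_depth = spec$bit_depth,
                           name = sprintf("phantom-seed%d", spec$seed)),
       truth = list(vessel_mask = vessel_mask, nuclei_mask = nuclei_mask,
                    stripe_mask = stripe_mask, occluders = occluders))
}
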