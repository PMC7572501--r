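test_that("spec validation", {
  expect_error(pie_filter_spec(30, d1 = 5, d2 = 3), "d1 < d2")
  expect_error(pie_filter_spec(30, w1 = 0), "widths")
  expect_error(pie_filter_spec(30, edge_sigma = -1), "edge_sigma")
  expect_error(pie_filter_spec(30, attenuation = 1.2), "attenuation")
  expect_equal(pie_filter_spec(200)$alpha_deg, 20)  # stored mod 180
})

test_that("mask invariants hold for randomized specs (property)", {
  set.seed(10)
  for (i in 1:12) {
    shape <- sample(c(16L, 17L, 24L, 33L), 2, replace = TRUE)
    d1 <- runif(1, 1, 4)
    spec <- pie_filter_spec(runif(1, 0, 180), d1 = d1,
                            d2 = d1 + runif(1, 2, 6),
                            w1 = runif(1, 0.5, 4), w2 = runif(1, 0.5, 8),
                            edge_sigma = sample(c(0, 0.8, 2), 1),
                            attenuation = runif(1))
    m <- build_pie_mask(shape, spec)$values
    expect_true(all(m >= 0 & m <= 1))
    mirrored <- m[lumipipe:::mirror_indices(shape[1]),
                  lumipipe:::mirror_indices(shape[2])]
    expect_lt(max(abs(m - mirrored)), 1e-9)
    ctr <- shape %/% 2L + 1L
    expect_identical(m[ctr[1], ctr[2]], 1)
  }
})

test_that("attenuation 0 gives the all-ones mask", {
  m <- build_pie_mask(c(32, 32), pie_filter_spec(40, attenuation = 0))
  expect_equal(m$values, matrix(1, 32, 32))
})

test_that("stripes at 30 degrees map to the 60-degree spectral ray", {
  # wedge axis must lie at 90 - alpha in the spectrum: sample the mask
  # along the 60- and 150-degree rays between d1 and d2
  spec <- pie_filter_spec(30, d1 = 4, d2 = 14, w1 = 3, w2 = 5,
                          edge_sigma = 1, attenuation = 1)
  m <- build_pie_mask(c(65, 65), spec)$values
  ctr <- c(33, 33)
  ray <- function(theta_deg) {
    r <- 5:13
    uy <- round(r * sin(theta_deg * pi / 180))
    ux <- round(r * cos(theta_deg * pi / 180))
    m[cbind(ctr[1] + uy, ctr[2] + ux)]
  }
  expect_lt(min(ray(60)), min(ray(150)))
  expect_lt(min(ray(60)), 0.05)      # deep attenuation on the wedge axis
  expect_gt(min(ray(150)), 0.95)     # perpendicular ray untouched
})

test_that("all-ones mask filtering is the exact identity (clip mode)", {
  p <- fixture_plane(20, 24, seed = 2)
  mask <- build_pie_mask(c(20, 24), pie_filter_spec(10, attenuation = 0))
  expect_identical(apply_frequency_filter(p, mask, "clip", 16L), p)
})

test_that("FFT filtering equals the direct-DFT oracle (16x16 and 32x32)", {
  set.seed(3)
  for (n in c(16L, 32L)) {
    p <- fixture_plane(n, n, seed = n)
    spec <- pie_filter_spec(35, d1 = 2, d2 = n %/% 2 - 1, w1 = 2, w2 = 5,
                            edge_sigma = 1, attenuation = 0.8)
    mask <- build_pie_mask(c(n, n), spec)
    got <- lumipipe:::filter_plane_raw(p, mask)
    want <- filter_direct(p, mask$values)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-6)
  }
})

test_that("a grating inside the wedge is suppressed by >= 95%", {
  n <- 64
  # grating along the wedge axis for alpha = 30: spectral direction 60 deg,
  # radius 16 -> frequency indices (uy, ux) = (14, 8)
  ky <- 14; kx <- 8
  yy <- matrix(0:(n - 1), n, n); xx <- t(yy)
  grating <- cos(2 * pi * (ky * yy + kx * xx) / n)
  p <- round(5000 + 2000 * grating)
  spec <- pie_filter_spec(30, d1 = 10, d2 = 24, w1 = 8, w2 = 10,
                          edge_sigma = 1, attenuation = 1)
  mask <- build_pie_mask(c(n, n), spec)
  out <- Re(lumipipe:::filter_plane_raw(p, mask))
  amp_in <- 2 * mean((p - mean(p)) * grating)
  amp_out <- 2 * mean((out - mean(out)) * grating)
  expect_lt(abs(amp_out), 0.05 * abs(amp_in))
})

test_that("destripe_plane limits: attenuation 0 identity, gentle on clean", {
  # 256^2: at realistic plane sizes the wedge is a small spectrum fraction
  ph <- generate_phantom(phantom_spec(shape = c(1, 256, 256),
                                      occluders_per_plane = 0L, seed = 5))
  p <- ph$stack$planes[1, , ]
  expect_identical(destripe_plane(p, pie_filter_spec(25, attenuation = 0)), p)
  # stripe-free plane, d1 >= 3: output within 2% RMS of dtype range
  out <- destripe_plane(p, pie_filter_spec(25, d1 = 3))
  expect_lt(sqrt(mean((out - p)^2)), 0.02 * 65535)
})

test_that("matched destriping removes band energy, spares the rest", {
  sp <- phantom_spec(shape = c(1, 128, 128), stripe_angle_deg = 25,
                     seed = 8)
  p <- generate_phantom(sp)$stack$planes[1, , ]
  spec <- pie_filter_spec(25, d1 = 5, d2 = "nyquist", w1 = 3, w2 = 9,
                          edge_sigma = 0.5, attenuation = 1)
  q <- destripe_plane(p, spec)
  expect_lt(stripe_band_energy(q, spec), 0.1 * stripe_band_energy(p, spec))
  # energy outside the wedge band changes by <= 5%
  tot <- function(x) {
    f <- Mod(stats::fft(x))^2
    sum(f) - f[1, 1]              # AC energy
  }
  out_before <- tot(p) - stripe_band_energy(p, spec)
  out_after <- tot(q) - stripe_band_energy(q, spec)
  expect_lt(abs(out_after - out_before) / out_before, 0.05)
})

test_that("Parseval partition: wedge + complement + DC = total", {
  p <- fixture_plane(33, 32, seed = 12)
  spec <- pie_filter_spec(70, d1 = 3, d2 = 12, w1 = 2, w2 = 6)
  pw <- lumipipe:::fftshift2(Mod(stats::fft(p))^2)
  fc <- lumipipe:::freq_coords(dim(p))
  wedge <- lumipipe:::pie_wedge_region(dim(p), spec)
  wedge[fc$center[1], fc$center[2]] <- FALSE
  dc <- pw[fc$center[1], fc$center[2]]
  complement <- sum(pw) - dc - sum(pw[wedge])
  expect_equal(stripe_band_energy(p, spec) + complement + dc, sum(pw),
               tolerance = 1e-9)
  # constant plane: all energy at DC, band energy zero
  expect_identical(stripe_band_energy(matrix(7, 16, 16), spec), 0)
})

test_that("energy is conserved under the attenuation-0 filter", {
  p <- fixture_plane(24, 24, seed = 6)
  q <- destripe_plane(p, pie_filter_spec(12, attenuation = 0))
  e <- function(x) sum(Mod(stats::fft(x))^2)
  expect_equal(e(q), e(p), tolerance = 1e-9)
})

test_that("angle recovery within 1 degree across the circle (property)", {
  for (ang in c(0, 15, 30, 45, 60, 75, 90, 120, 150)) {
    sp <- phantom_spec(shape = c(4, 128, 128), stripe_angle_deg = ang,
                       seed = 3)
    est <- as.numeric(estimate_stripe_angle(generate_phantom(sp)$stack))
    delta <- min(abs(est - ang), 180 - abs(est - ang))
    expect_lte(delta, 1)
  }
})

test_that("degenerate and isotropic inputs are flagged", {
  expect_error(estimate_stripe_angle(matrix(5, 32, 32)), "no spectral energy")
  set.seed(2)
  wn <- matrix(sample(0:65535, 128 * 128, TRUE), 128, 128)
  expect_warning(est <- estimate_stripe_angle(wn), "low-confidence")
  expect_true(attr(est, "low_confidence"))
})

test_that("oversized d2 is clamped with a warning log", {
  spec <- pie_filter_spec(30, d1 = 2, d2 = 500)
  withr::local_options(lumipipe.log_level = "warn")
  expect_message(m <- build_pie_mask(c(32, 32), spec), "clamped")
  expect_true(all(m$values >= 0 & m$values <= 1))
})
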