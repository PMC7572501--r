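test_that("scheme validation", {
  expect_error(threshold_scheme(list()), "non-empty")
  expect_error(threshold_scheme(list(a = c(5, 5))), "lower < upper")
  expect_error(threshold_scheme(list(a = c(0, 10), b = c(5, 20))), "overlap")
})

test_that("vessel segmentation matches the generator mask (Jaccard)", {
  sp <- phantom_spec(shape = c(6, 96, 96), seed = 13,
                     occluders_per_plane = 0, noise_sigma = 100)
  ph <- generate_phantom(sp)
  # threshold at the half-intensity between background (8000) and vessel
  # (50000): the generator's truth masks use the 50%-coverage rule, so the
  # matched intensity cut is the midpoint, 29000
  seg <- threshold_segment(ph$stack,
                           threshold_scheme(list(vessel = c(29000, 65536))))
  got <- seg$labels == 1L
  expect_gte(jaccard(got, ph$truth$vessel_mask), 0.95)
})

test_that("segmentation partitions the volume", {
  s <- image_stack(array(sample(0:255, 2 * 8 * 8, TRUE), c(2, 8, 8)), 8L)
  seg <- threshold_segment(s, threshold_scheme(list(lo = c(0, 100),
                                                    hi = c(200, 256))))
  counts <- table(factor(seg$labels, levels = 0:2))
  expect_equal(sum(counts), length(s$planes))
  # full-range single interval: everything labelled
  seg2 <- threshold_segment(s, threshold_scheme(list(all = c(0, 256))))
  expect_true(all(seg2$labels == 1L))
  # empty intersection: all background (16-bit plane capped at 1000)
  s16 <- image_stack(array(sample(0:1000, 2 * 8 * 8, TRUE), c(2, 8, 8)), 16L)
  seg3 <- threshold_segment(s16, threshold_scheme(list(x = c(60000, 65536))))
  expect_true(all(seg3$labels == 0L))
})

test_that("legend describes the scheme", {
  s <- image_stack(array(0L, c(1, 4, 4)), 8L)
  seg <- threshold_segment(s, threshold_scheme(list(a = c(0, 10))))
  expect_identical(seg$legend$label, c("background", "a"))
  expect_identical(seg$legend$code, c(0L, 1L))
})

test_that("grayscale identity map reproduces input up to 8-bit quantization", {
  arr <- array(sample(0:65535, 4 * 8 * 8, TRUE), c(4, 8, 8))
  s <- image_stack(arr, 16L)
  rgb <- apply_colormap(s, "grayscale", display_range = c(0, 65535))
  expect_identical(dim(rgb), c(4L, 8L, 8L, 3L))
  expect_true(all(abs(rgb[, , , 1] - arr / 65535 * 255) <= 0.5 + 1e-9))
  # equal intensities -> identical RGB
  expect_identical(rgb[, , , 1], rgb[, , , 2])
  expect_identical(rgb[, , , 1], rgb[, , , 3])
})

test_that("auto display range matches the sort-based percentile oracle", {
  set.seed(14)
  arr <- array(sample(0:65535, 5000, TRUE), c(5, 100, 10))
  got <- lumipipe:::intensity_percentiles(arr, c(0.01, 0.99))
  expect_equal(got, c(percentile_direct(arr, 0.01),
                      percentile_direct(arr, 0.99)))
  expect_error(apply_colormap(image_stack(arr, 16L), "grayscale",
                              display_range = c(10, 10)), "degenerate")
})

test_that("shipped monotone maps are monotone in luminance", {
  for (nm in c("grayscale", "hotbody")) {
    p <- builtin_colormap(nm)$points
    lum <- 0.299 * p$r + 0.587 * p$g + 0.114 * p$b
    expect_true(all(diff(lum) > 0), info = nm)
  }
  # the diverging map is documented as non-monotone (bright midpoint)
  p <- builtin_colormap("diverging")$points
  lum <- 0.299 * p$r + 0.587 * p$g + 0.114 * p$b
  expect_false(all(diff(lum) > 0))
})

test_that("virtual slices agree with the transposition oracle", {
  arr <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  s <- image_stack(array(arr %% 256, dim(arr)), 8L)
  expect_identical(extract_virtual_slice(s, "z", 1), s$planes[1, , ])
  expect_identical(extract_virtual_slice(s, "y", 2), s$planes[, 2, ])
  expect_identical(extract_virtual_slice(s, "x", 5), s$planes[, , 5])
  # y-slice of the z-transposed volume equals z-slice of original, etc.
  tr <- image_stack(aperm(s$planes, c(2, 1, 3)), 8L)
  expect_identical(extract_virtual_slice(tr, "z", 2),
                   extract_virtual_slice(s, "y", 2))
  expect_error(extract_virtual_slice(s, "z", 4), "out of")
})
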