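test_that("image_stack validates its invariants", {
  arr <- array(0:7, dim = c(2, 2, 2))
  s <- image_stack(arr, bit_depth = 8L)
  expect_s3_class(s, "image_stack")
  expect_identical(dim(s), c(2L, 2L, 2L))
  expect_error(image_stack(array(-1, c(1, 2, 2)), 8L), "outside")
  expect_error(image_stack(array(256, c(1, 2, 2)), 8L), "outside")
  expect_error(image_stack(array(0.5, c(1, 2, 2)), 8L), "integers")
  expect_error(image_stack(arr, 12L), "8 or 16")
  expect_error(image_stack(arr, 8L, voxel_size = c(1, 0, 1)), "positive")
  expect_identical(dtype_max(image_stack(arr, 16L)), 65535L)
  expect_identical(dtype_max(8L), 255L)
})

test_that("multi-page TIFF round trip is the identity (8 and 16 bit)", {
  for (bd in c(8L, 16L)) {
    arr <- array(sample(0:(2^bd - 1), 3 * 16 * 12, TRUE), dim = c(3, 16, 12))
    s <- image_stack(arr, bd)
    path <- file.path(withr::local_tempdir(), "stack.tif")
    write_stack(s, path)
    r <- read_stack(path)
    expect_identical(r$planes, s$planes * 1)
    expect_identical(r$bit_depth, bd)
  }
})

test_that("slice-sequence round trip and naming contract", {
  arr <- array(sample(0:65535, 3 * 8 * 8, TRUE), dim = c(3, 8, 8))
  s <- image_stack(arr, 16L)
  dir <- file.path(withr::local_tempdir(), "seq")
  files <- write_stack(s, dir, as_sequence = TRUE)
  expect_identical(basename(files),
                   c("slice_000.tif", "slice_001.tif", "slice_002.tif"))
  r <- read_stack(dir)
  expect_identical(r$planes, s$planes * 1)
  # second read after re-writing with overwrite
  expect_error(write_stack(s, dir, as_sequence = TRUE), "overwrite")
  write_stack(s, dir, as_sequence = TRUE, overwrite = TRUE)
  expect_identical(read_stack(dir)$planes, s$planes * 1)
})

test_that("directory ordering follows trailing numbers, not padding", {
  dir <- withr::local_tempdir()
  # inconsistent zero padding: lexicographic order would be s10, s2, s9
  vals <- c(2L, 9L, 10L)
  for (v in vals) {
    pl <- matrix(v, 4, 4)
    lumipipe:::write_tiff_pages(file.path(dir, sprintf("s%d.tif", v)),
                                list(pl), 8L)
  }
  r <- read_stack(dir)
  expect_equal(r$planes[, 1, 1], c(2, 9, 10))
})

test_that("write refuses to clobber and read rejects bad inputs", {
  d <- withr::local_tempdir()
  s <- image_stack(array(1, c(1, 4, 4)), 8L)
  p <- file.path(d, "a.tif")
  write_stack(s, p)
  expect_error(write_stack(s, p), "overwrite")
  expect_error(read_stack(file.path(d, "nope.tif")), "does not exist")
  # mixed dimensions across slices in a directory
  d2 <- file.path(d, "mix"); dir.create(d2)
  lumipipe:::write_tiff_pages(file.path(d2, "s1.tif"), list(matrix(0, 4, 4)), 8L)
  lumipipe:::write_tiff_pages(file.path(d2, "s2.tif"), list(matrix(0, 5, 4)), 8L)
  expect_error(read_stack(d2), "differ")
  # mixed bit depth
  d3 <- file.path(d, "mixbd"); dir.create(d3)
  lumipipe:::write_tiff_pages(file.path(d3, "s1.tif"), list(matrix(0, 4, 4)), 8L)
  lumipipe:::write_tiff_pages(file.path(d3, "s2.tif"), list(matrix(0, 4, 4)), 16L)
  expect_error(read_stack(d3), "bit depth")
})

test_that("codec interoperates with an independent TIFF implementation", {
  # tifffile (Python) both reads our output and produces input we read;
  # it also supplies float32 and RGB files that must be rejected by name
  d <- withr::local_tempdir()
  arr <- array(sample(0:65535, 2 * 6 * 5, TRUE), dim = c(2, 6, 5))
  write_stack(image_stack(arr, 16L), file.path(d, "ours.tif"))
  script <- sprintf('
import tifffile, numpy as np, sys
a = tifffile.imread(%s)
assert a.shape == (2, 6, 5) and a.dtype == np.uint16
np.save(%s, a)
tifffile.imwrite(%s, np.arange(12, dtype=np.float32).reshape(3, 4))
tifffile.imwrite(%s, np.zeros((4, 4, 3), dtype=np.uint8), photometric="rgb")
tifffile.imwrite(%s, np.arange(20, dtype=np.uint16).reshape(4, 5))
print("OK")
', shQuote(file.path(d, "ours.tif")), shQuote(file.path(d, "back.npy")),
   shQuote(file.path(d, "f32.tif")), shQuote(file.path(d, "rgb.tif")),
   shQuote(file.path(d, "theirs.tif")))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  expect_true(any(grepl("OK", out)))
  expect_error(read_stack(file.path(d, "f32.tif")), "floating-point")
  expect_error(read_stack(file.path(d, "rgb.tif")), "grayscale|samples")
  theirs <- read_stack(file.path(d, "theirs.tif"))
  expect_equal(theirs$planes[1, , ],
               matrix(0:19, 4, 5, byrow = TRUE))
})

test_that("load_config validates stages and fills defaults", {
  d <- withr::local_tempdir()
  cfg <- file.path(d, "cfg.yaml")
  writeLines(c("schema_version: 1",
               "stages:",
               "  - clahe:",
               "      clip_limit: 0.02",
               "  - destripe:",
               "      alpha: 25",
               "  - unsharp:"), cfg)
  pc <- load_config(cfg)
  expect_identical(names(pc$stages), c("clahe", "destripe", "unsharp"))
  expect_equal(pc$stages$clahe$clip_limit, 0.02)
  expect_equal(pc$stages$clahe$tile_rows, 8L)      # default filled
  expect_equal(pc$stages$destripe$alpha, 25)
  expect_equal(pc$stages$unsharp$sigma, 1.5)

  writeLines(c("stages:", "  - deconvolve:"), cfg)
  expect_error(load_config(cfg), "deconvolve")
  writeLines(c("stages: []"), cfg)
  expect_error(load_config(cfg), "at least one stage")
  writeLines(c("stages:", "  - clahe:", "  - clahe:"), cfg)
  expect_error(load_config(cfg), "more than once")
  writeLines(c("stages:", "  - unsharp:", "  - clahe:"), cfg)
  expect_error(load_config(cfg), "canonical")
  writeLines(c("wibble: 1", "stages:", "  - clahe:"), cfg)
  expect_error(load_config(cfg), "wibble")
  writeLines(c("stages:", "  - clahe:", "      banana: 1"), cfg)
  expect_error(load_config(cfg), "banana")
})
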