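test_that("PNG/TIFF intensities are rescaled by the dtype maximum", {
  d <- withr::local_tempdir()
  p8 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 4, 4), p8)          # encodes as 8-bit 255
  img <- read_image(p8)
  expect_true(all(img == 1.0))

  p16 <- file.path(d, "white16.tif")
  tiff::writeTIFF(matrix(1, 4, 4), p16, bits.per.sample = 16L)
  expect_true(all(read_image(p16) == 1.0))

  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  ramp <- round(ramp * 255) / 255             # representable at 8 bit
  pr <- file.path(d, "ramp.png")
  write_image(ramp, pr)
  back <- read_image(pr)
  expect_identical(back, ramp)                # bit-exact 8-bit round trip
  expect_identical(order(back), order(ramp))  # monotone normalization
})

test_that("RGB input is converted with BT.601 luminance weights", {
  d <- withr::local_tempdir()
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, 1] <- 1                            # pure red pixel
  p <- file.path(d, "rgb.png")
  png::writePNG(arr, p)
  img <- read_image(p)
  expect_equal(img[1, 1], 0.2989, tolerance = 1e-6)
  expect_equal(img[2, 2], 0)
})

test_that("unreadable or unsupported files raise a format error naming the path", {
  expect_error(read_image("no/such/file.png"), "no/such/file.png")
  d <- withr::local_tempdir()
  bad <- file.path(d, "notimage.txt")
  writeLines("hello", bad)
  expect_error(read_image(bad), "notimage.txt")
})

test_that("region stats survive a CSV round trip", {
  d <- withr::local_tempdir()
  p <- file.path(d, "stats.csv")

  empty <- data.frame(label = integer(), area_px = integer(),
                      perimeter_px = integer(), fractal_dimension = numeric())
  write_region_stats(empty, p)
  expect_identical(readLines(p), "label,area_px,perimeter_px,fractal_dimension")
  expect_equal(nrow(read_region_stats(p)), 0L)

  one <- data.frame(label = 1L, area_px = 100L, perimeter_px = 36L,
                    fractal_dimension = 1.0)
  write_region_stats(one, p)
  expect_equal(read_region_stats(p), one)

  set.seed(11)
  many <- data.frame(label = 1:50,
                     area_px = sample.int(10000, 50),
                     perimeter_px = sample.int(500, 50),
                     fractal_dimension = runif(50, 1, 2))
  write_region_stats(many, p)
  back <- read_region_stats(p)
  expect_identical(back$label, many$label)
  expect_identical(back$area_px, many$area_px)
  expect_identical(back$perimeter_px, many$perimeter_px)
  expect_equal(back$fractal_dimension, many$fractal_dimension,
               tolerance = 1e-6)              # 6 significant digits
})

test_that("pipeline configuration validates its fields", {
  expect_s3_class(pipeline_config(), "curvseg_config")
  expect_equal(pipeline_config()$entropy_window, 9L)
  expect_error(pipeline_config(entropy_window = 8), "odd")
  expect_error(pipeline_config(wiener_window = 4), "odd")
  expect_error(pipeline_config(curvelet_angles_coarse = 12), "8, 16 or 32")
  expect_error(pipeline_config(box_sizes = c(4, 4, 8)), "increasing")
  expect_error(pipeline_config(box_sizes = c(1, 2)), "increasing")
})

test_that("configurations round-trip through JSON", {
  d <- withr::local_tempdir()
  p <- file.path(d, "cfg.json")
  cfg <- pipeline_config(entropy_window = 7L, texture_threshold_mode = "fixed",
                         texture_threshold = 2.5, box_sizes = c(2L, 4L, 8L))
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back, cfg)
})
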