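test_that("box counts handle exact tilings, single pixels and ragged edges", {
  ones <- matrix(1L, 4, 4)
  expect_equal(box_counts(ones, 2L)$N, 4L)

  single <- matrix(0L, 8, 8); single[3, 5] <- 1L
  expect_equal(box_counts(single, c(2L, 4L, 8L))$N, c(1L, 1L, 1L))

  # ragged tiling: 5x5 frame with r = 2 has 9 boxes
  expect_equal(box_counts(matrix(1L, 5, 5), c(2L, 4L))$N, c(9L, 4L))

  expect_error(box_counts(matrix(0L, 8, 8), 2L), "empty")
  expect_error(box_counts(ones, c(4L, 2L)), "increasing")
})

test_that("box counts equal the brute-force tiling oracle on random masks", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rbinom(64 * 64, 1L, runif(1, 0.05, 0.5)), 64, 64)
    bc <- box_counts(m, c(2L, 4L, 8L, 16L))
    for (i in seq_len(nrow(bc)))
      expect_identical(bc$N[i], oracle_box_count(m, bc$r[i]))
  }
})

test_that("the strict occupancy variant needs two pixels per box", {
  single <- matrix(0L, 8, 8); single[3, 5] <- 1L
  expect_equal(box_counts(single, c(2L, 4L), occupancy = "gt1")$N, c(0L, 0L))
  pair <- single; pair[4, 5] <- 1L
  expect_equal(box_counts(pair, c(2L, 4L), occupancy = "gt1")$N, c(1L, 1L))
})

test_that("fractal dimension recovers plane, line and Sierpinski scaling", {
  full <- matrix(1L, 256, 256)
  fd_full <- fractal_dimension(box_counts(full, dyadic_box_sizes(c(256, 256))))
  expect_equal(as.numeric(fd_full), 2, tolerance = 0.05)

  line <- matrix(0L, 256, 256); line[128, ] <- 1L
  fd_line <- fractal_dimension(box_counts(line, dyadic_box_sizes(c(256, 256))))
  expect_equal(as.numeric(fd_line), 1, tolerance = 0.05)

  carpet <- matrix(as.integer(sierpinski_mask(5L)), 243, 243)
  bc <- box_counts(carpet, c(3L, 9L, 27L, 81L))
  expect_equal(bc$N, as.integer(8^(4:1)))    # exact by construction
  fd_carpet <- fractal_dimension(bc)
  expect_equal(as.numeric(fd_carpet), log(8) / log(3), tolerance = 0.03)
  expect_lt(attr(fd_carpet, "residual"), 1e-10)

  expect_error(fractal_dimension(data.frame(r = c(2, 4), N = c(8, 4))),
               "at least 3")
})

test_that("fractal dimension is stable under small translations", {
  base <- matrix(0L, 256, 256)
  base[79:179, 79:179] <- disk_mask(101, 101, c(51, 51), 50)
  fd0 <- as.numeric(fractal_dimension(box_counts(base, c(2L, 4L, 8L, 16L, 32L))))
  for (sh in list(c(3, 3), c(-3, 3), c(3, -3), c(-3, -3))) {
    shifted <- matrix(0L, 256, 256)
    shifted[79:179 + sh[1], 79:179 + sh[2]] <- disk_mask(101, 101, c(51, 51), 50)
    fdt <- as.numeric(fractal_dimension(box_counts(shifted,
                                                   c(2L, 4L, 8L, 16L, 32L))))
    expect_equal(fdt, fd0, tolerance = 0.02)
    expect_identical(sum(shifted), sum(base))  # area conserved exactly
  }
})

test_that("region area counts pixels and partitions the foreground", {
  lab <- matrix(0L, 64, 64)
  lab[5:24, 5:24] <- 1L
  lab[40:49, 40:49] <- 2L
  expect_equal(region_area(lab, 1L), 400L)
  expect_equal(region_area(lab, 2L), 100L)
  expect_equal(region_area(lab, 1L) + region_area(lab, 2L), sum(lab > 0L))
  expect_error(region_area(lab, 3L), "not present")

  disk <- disk_mask(128, 128, c(64, 64), 50)
  expect_lt(abs(sum(disk) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("boundary-box perimeter matches hand counts and circle scaling", {
  one <- matrix(0L, 8, 8); one[4, 4] <- 1L
  expect_equal(region_perimeter(one, 1L), 1L)

  sq <- square_mask(32, 32, 10, 10, 10)
  expect_equal(region_perimeter(sq, 1L), 36L)

  disk <- disk_mask(128, 128, c(64, 64), 50)
  p <- region_perimeter(disk, 1L)
  expect_lt(abs(p - 2 * pi * 50) / (2 * pi * 50), 0.15)

  # perimeter measures the filled shape: punching holes changes nothing
  holey <- disk
  holey[60:68, 60:68] <- 0L
  expect_equal(region_perimeter(holey, 1L), p)

  poly <- region_perimeter_polygon(disk, 1L)
  expect_lt(abs(poly - 2 * pi * 50) / (2 * pi * 50), 0.15)
})

test_that("relative error reproduces the reference arithmetic", {
  expect_equal(relative_error(123.4, 123.4), 0)
  expect_equal(round(relative_error(9647, 10864), 2), 11.20)
  expect_equal(round(relative_error(427, 399), 2), 7.02)
  expect_error(relative_error(1, 0), "positive")
})

test_that("quantify_all measures every region independently", {
  lab <- matrix(0L, 64, 64)
  lab[21:40, 21:40] <- 1L
  st <- quantify_all(lab)
  expect_equal(nrow(st), 1L)
  expect_equal(st$area_px, 400L)
  expect_equal(st$perimeter_px, 76L)
  # frozen from the brute-force tiling oracle on the 32x32 canvas,
  # r in {2, 4, 8}: N = 100, 25, 9
  fd_expected <- as.numeric(fractal_dimension(data.frame(r = c(2, 4, 8),
                                                         N = c(100, 25, 9))))
  expect_equal(st$fractal_dimension, fd_expected, tolerance = 1e-10)
  expect_gt(st$fractal_dimension, 1)
  expect_lt(st$fractal_dimension, 2.1)
  expect_equal(unlist(st[, c("row0", "col0", "row1", "col1")], use.names = FALSE),
               c(20L, 20L, 40L, 40L))        # 0-based, half-open

  expect_equal(nrow(quantify_all(matrix(0L, 16, 16))), 0L)

  # permutation invariance: swapping labels permutes rows, not values
  lab2 <- matrix(0L, 64, 64)
  lab2[21:40, 21:40] <- 2L
  lab2[5:8, 5:8] <- 1L
  lab1 <- matrix(0L, 64, 64)
  lab1[21:40, 21:40] <- 1L
  lab1[5:8, 5:8] <- 2L
  s1 <- quantify_all(lab1); s2 <- quantify_all(lab2)
  key <- function(s) {
    k <- s[order(s$area_px), c("area_px", "perimeter_px", "fractal_dimension")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(s1), key(s2))
})
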