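test_that("entropy of a constant image is zero everywhere", {
  img <- matrix(0.37, 24, 24)
  for (w in c(3L, 9L)) expect_true(all(entropy_filter(img, w) == 0))
})

test_that("a two-level checkerboard scores the exact binomial entropy", {
  img <- checkerboard_image(32, 32)
  ent <- entropy_filter(img, 9L)
  # interior window holds counts {41, 40} of the two levels out of 81
  expected <- -(41 / 81) * log2(41 / 81) - (40 / 81) * log2(40 / 81)
  expect_equal(ent[16, 16], expected, tolerance = 1e-12)
  expect_equal(expected, 0.9999, tolerance = 1e-4)
})

test_that("entropy filter agrees exactly with the brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    img <- random_image(32)
    for (w in c(3L, 9L)) {
      expect_lt(max(abs(entropy_filter(img, w) - oracle_entropy(img, w))),
                1e-12)
    }
  }
})

test_that("entropy windows must be odd", {
  expect_error(entropy_filter(random_image(16), 4L), "odd")
})

test_that("thresholding splits a two-valued entropy image at the modes", {
  ent <- matrix(c(0, 2), 16, 16)           # half 0, half 2 bits
  mask <- threshold_texture(ent, mode = "otsu")
  expect_identical(sort(unique(as.vector(mask))), c(0L, 1L))
  expect_identical(unname(mask == 1L), unname(ent == 2))
})

test_that("fixed thresholds behave and constant entropy degenerates safely", {
  ent <- matrix(0.5, 8, 8)
  expect_warning(m <- threshold_texture(ent, mode = "otsu"), "constant")
  expect_true(all(m == 0L))
  expect_error(threshold_texture(ent, mode = "fixed", T = 2), "range")
  ent2 <- matrix(seq(0, 3, length.out = 64), 8, 8)
  m2 <- threshold_texture(ent2, mode = "fixed", T = 1.5)
  expect_identical(unname(m2 == 1L), unname(ent2 >= 1.5))
})

test_that("mask refinement removes specks, keeps solids, trims protrusions", {
  specks <- matrix(0L, 32, 32)
  specks[cbind(c(3, 10, 20, 29), c(5, 14, 7, 30))] <- 1L
  expect_true(all(refine_mask(specks, min_size = 10L, radius = 1L) == 0L))

  # disk opening preserves the square body; only the 4 convex corner pixels
  # round off (a square is not open with respect to a disk)
  solid <- square_mask(64, 64, 8, 8, 50)
  ref_solid <- refine_mask(solid, min_size = 10L, radius = 2L)
  expect_true(all(ref_solid <= solid))
  expect_lte(sum(solid) - sum(ref_solid), 4L)

  spur <- square_mask(64, 64, 20, 20, 20)
  spur[25, 40:42] <- 1L                     # 3-pixel-thin protrusion
  refined <- refine_mask(spur, min_size = 10L, radius = 2L)
  expect_identical(refined,
                   refine_mask(square_mask(64, 64, 20, 20, 20),
                               min_size = 10L, radius = 2L))
  expect_true(all(refined[25, 40:42] == 0L))
})

test_that("mask refinement is idempotent and monotone in min_size", {
  set.seed(22)
  sc <- single_disk_scene(radius = 30, size = c(128L, 128L),
                          noise_sigma = 0.05, seed = 3L)
  ent <- entropy_filter(sc$image, 9L)
  raw <- threshold_texture(ent, "otsu")
  m1 <- refine_mask(raw, min_size = 64L, radius = 2L)
  expect_identical(refine_mask(m1, min_size = 64L, radius = 2L), m1)
  n_regions <- vapply(c(0L, 16L, 64L, 256L, 1024L), function(ms)
    max(label_regions(refine_mask(raw, min_size = ms, radius = 2L))),
    integer(1))
  expect_true(all(diff(n_regions) <= 0L))
})

test_that("boundary overlay marks exactly the mask-to-background frontier", {
  img <- matrix(0.4, 32, 32)
  empty <- matrix(0L, 32, 32)
  expect_identical(boundary_overlay(img, empty), img)

  full <- matrix(1L, 32, 32)
  ov <- boundary_overlay(img, full)
  border <- matrix(FALSE, 32, 32)
  border[c(1, 32), ] <- TRUE; border[, c(1, 32)] <- TRUE
  expect_true(all(ov[border] == 1.0))
  expect_true(all(ov[!border] == 0.4))

  sq <- square_mask(32, 32, 10, 10, 10)
  ov2 <- boundary_overlay(img, sq)
  expect_equal(sum(ov2 == 1.0), 36L)       # 4*10 - 4 boundary pixels
})

test_that("region labelling is 8-connected, ordered by area, oracle-exact", {
  empty <- matrix(0L, 8, 8)
  expect_true(all(label_regions(empty) == 0L))

  two <- square_mask(64, 64, 2, 2, 10)
  two[40:59, 30:49] <- 1L                   # larger 20x20 square
  lab <- label_regions(two)
  expect_equal(max(lab), 2L)
  expect_equal(lab[45, 35], 1L)             # bigger square labelled first
  expect_equal(lab[5, 5], 2L)

  diag <- matrix(0L, 6, 6)
  diag[cbind(1:5, 1:5)] <- 1L
  expect_equal(max(label_regions(diag)), 1L)

  set.seed(23)
  for (rep in 1:6) {
    m <- matrix(rbinom(30 * 30, 1L, 0.4), 30, 30)
    ours <- curvseg:::label_components(m, 8L)
    ref <- oracle_label(m, 8L)
    # same partition: labels must be a relabelling of each other
    expect_equal(max(ours), max(ref))
    expect_true(all(tapply(ref[m == 1L], ours[m == 1L],
                           function(v) length(unique(v))) == 1L))
    # 4-connected variant cross-checked against EBImage's labelling
    ours4 <- curvseg:::label_components(m, 4L)
    eb <- EBImage::imageData(EBImage::bwlabel(m))
    expect_equal(max(ours4), max(eb))
  }
})

test_that("watershed baseline finds separate bright disks and merges necks", {
  two <- generate_scene(scene_spec(list(
    list(kind = "disk", center = c(60, 60), radius = 25, intensity = 0.8),
    list(kind = "disk", center = c(160, 160), radius = 25, intensity = 0.8)),
    size = c(224L, 224L), texture_amplitude = 0.05, noise_sigma = 0.01,
    seed = 9L))
  lab <- watershed_baseline(two$image)
  expect_equal(max(lab), 2L)

  expect_equal(max(watershed_baseline(matrix(0.5, 64, 64))), 0L)

  # broad contact neck: the gradient saddle is too shallow to separate
  merged <- generate_scene(scene_spec(list(
    list(kind = "disk", center = c(100, 85), radius = 30, intensity = 0.75),
    list(kind = "disk", center = c(100, 125), radius = 30, intensity = 0.75)),
    size = c(200L, 200L), texture_amplitude = 0.05, noise_sigma = 0.01,
    blur_sigma = 2, seed = 10L))
  lab2 <- watershed_baseline(merged$image)
  expect_equal(max(lab2), 1L)
})

test_that("well-separated particles are recovered with IoU >= 0.7", {
  sc <- generate_scene(scene_spec(list(
    list(kind = "disk", center = c(60, 64), radius = 28, intensity = 0.7),
    list(kind = "disk", center = c(160, 150), radius = 35, intensity = 0.7)),
    size = c(224L, 224L), noise_sigma = 0.05, seed = 14L))
  seg <- segment_image(sc$image, pipeline_config())
  m <- match_regions(sc$truth$label_image, seg$labels)
  expect_true(all(m$iou >= 0.7))
})
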