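test_that("nuclear mask: thresholding, area filter, hole filling", {
  blue <- matrix(10, 5, 5)
  blue[2:4, 2:4] <- 200
  m <- compute_nuclear_mask(blue, threshold_config(100, 0, min_nucleus_area = 1))
  expect_identical(m$n_nuclei, 1L)
  expect_identical(sum(m$nucleus_labels == 1L), 9L)

  m2 <- compute_nuclear_mask(blue, threshold_config(100, 0, min_nucleus_area = 10))
  expect_identical(m2$n_nuclei, 0L)

  # ring of bright pixels around one dim pixel: hole filling claims it
  ring <- matrix(0, 5, 5)
  ring[2:4, 2:4] <- 200; ring[3, 3] <- 5
  mf <- compute_nuclear_mask(ring, threshold_config(100, 0, min_nucleus_area = 1,
                                                    fill_holes = TRUE))
  expect_true(mf$nucleus_labels[3, 3] == 1L)
  mn <- compute_nuclear_mask(ring, threshold_config(100, 0, min_nucleus_area = 1,
                                                    fill_holes = FALSE))
  expect_true(mn$nucleus_labels[3, 3] == 0L)

  # pixels exactly at the threshold are excluded (strictly greater-than)
  at <- matrix(100, 2, 2)
  expect_identical(
    compute_nuclear_mask(at, threshold_config(100, 0, 0))$n_nuclei, 0L)

  # all-zero plane is a valid empty result, not an error
  expect_identical(
    compute_nuclear_mask(matrix(0, 4, 4), threshold_config(10, 0))$n_nuclei, 0L)
})

test_that("labels are assigned in top-left-first scan order", {
  blue <- matrix(0, 7, 7)
  blue[6:7, 1:2] <- 255 # placed first in the matrix but scanned later
  blue[1:2, 5:6] <- 255
  m <- compute_nuclear_mask(blue, threshold_config(1, 0, min_nucleus_area = 1))
  expect_identical(m$nucleus_labels[1, 5], 1L)
  expect_identical(m$nucleus_labels[6, 1], 2L)
})

test_that("three-way classification follows the two threshold rules", {
  # worked 3x3 example: center nucleus, corners above threshold, edges below
  tm <- tiny_map()
  cls <- tm$map$classes
  expect_identical(sum(cls == COMPARTMENTS[["NUCLEUS"]]), 1L)
  expect_identical(sum(cls == COMPARTMENTS[["CYTOSOL"]]), 4L)
  expect_identical(sum(cls == COMPARTMENTS[["BACKGROUND"]]), 4L)

  # degenerate planes
  none <- matrix(0L, 2, 2)
  allbg <- classify_compartments(matrix(0, 2, 2), none, threshold_config(0, 10))
  expect_true(all(allbg$classes == COMPARTMENTS[["BACKGROUND"]]))
  allcy <- classify_compartments(matrix(50, 2, 2), none, threshold_config(0, 10))
  expect_true(all(allcy$classes == COMPARTMENTS[["CYTOSOL"]]))
  expect_error(classify_compartments(matrix(0, 2, 3), none,
                                     threshold_config(0, 10)), "shape")
})

test_that("compartments always partition the image and respond monotonically", {
  for (seed in 1:5) {
    sc <- generate_scene(small_scene_params(seed = seed))
    img <- sc$image
    npix <- img$height * img$width
    prev_cyt <- Inf
    for (bt in c(5, 15, 40, 120)) {
      map <- segment_image(img, threshold_config(90, bt))
      counts <- tabulate(map$classes + 1L, 3L)
      expect_identical(sum(counts), npix)
      cyt <- counts[COMPARTMENTS[["CYTOSOL"]] + 1L]
      expect_lte(cyt, prev_cyt)
      prev_cyt <- cyt
    }
    prev_area <- Inf
    for (dt in c(40, 90, 150, 250)) {
      map <- segment_image(img, threshold_config(dt, 15))
      area <- sum(map$nucleus_labels > 0L)
      expect_lte(area, prev_area)
      prev_area <- area
    }
  }
})

test_that("recovered nuclear mask overlaps ground truth (Jaccard >= 0.9)", {
  for (seed in 1:5) {
    sc <- generate_scene(small_scene_params(seed = 100 + seed))
    map <- segment_image(sc$image, default_thresholds())
    truth <- sc$truth$nucleus_labels > 0L
    rec <- map$nucleus_labels > 0L
    expect_gte(sum(truth & rec) / sum(truth | rec), 0.9)
  }
})

test_that("threshold propagation has value semantics and rejects empty series", {
  ref <- threshold_config(50, 25)
  out <- propagate_threshold(ref, c("a", "b", "c"))
  expect_length(out, 3L)
  expect_identical(out$b$background_threshold, 25)
  # two distinct series never share thresholds
  out2 <- propagate_threshold(threshold_config(80, 40), c("x", "y"))
  expect_identical(out$a$background_threshold, 25)
  expect_identical(out2$x$background_threshold, 40)
  # changing the reference afterwards does not alter issued configs
  ref$background_threshold <- 99
  expect_identical(out$a$background_threshold, 25)
  expect_error(propagate_threshold(ref, character()), "empty")
})

test_that("Otsu suggestion lands between the two modes of a bimodal plane", {
  sc <- generate_scene(small_scene_params(seed = 3))
  t <- otsu_threshold(sc$image$channels$blue, bit_depth = 8L)
  expect_gt(t, 20)
  expect_lt(t, 180)
})
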