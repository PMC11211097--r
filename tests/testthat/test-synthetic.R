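test_that("noise-free scene is piecewise constant with the stated levels", {
  p <- small_scene_params(seed = 1, noise_sd = 0, foci_per_nucleus = 0,
                          n_nuclei = 1L)
  sc <- generate_scene(p)
  g <- sc$image$channels$green
  expect_setequal(unique(as.vector(g)), c(5, 30, 60))
  b <- sc$image$channels$blue
  expect_setequal(unique(as.vector(b)), c(0, 180))
  # nuclear pixels carry the nuclear level exactly
  expect_true(all(g[sc$truth$nucleus_labels > 0L] == 60))
})

test_that("a planted focus peaks at nuclear level + amplitude", {
  p <- small_scene_params(seed = 2, noise_sd = 0, foci_per_nucleus = 1,
                          n_nuclei = 1L)
  sc <- generate_scene(p)
  if (nrow(sc$truth$foci) == 0L) skip("Poisson draw placed no focus")
  g <- sc$image$channels$green
  expect_equal(max(g), 60 + 90)
  pk <- which(g == max(g), arr.ind = TRUE)
  expect_true(any(pk[, 1] %in% sc$truth$foci$row &
                    pk[, 2] %in% sc$truth$foci$col))
})

test_that("identical seeds give bit-identical scenes and ground truth", {
  a <- generate_scene(small_scene_params(seed = 33))
  b <- generate_scene(small_scene_params(seed = 33))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(small_scene_params(seed = 34))
  expect_false(identical(a$image$channels$green, c$image$channels$green))
})

test_that("ground-truth invariants hold across seeds", {
  for (seed in 1:5) {
    sc <- generate_scene(small_scene_params(seed = 300 + seed))
    tr <- sc$truth
    if (nrow(tr$foci))
      expect_true(all(tr$nucleus_labels[cbind(tr$foci$row, tr$foci$col)] ==
                        tr$foci$nucleus))
    expect_equal(tr$true_foci_density, nrow(tr$foci) / tr$nuclear_area)
    expect_identical(max(tr$nucleus_labels), tr$n_nuclei)
  }
})

test_that("segmentation with oracle thresholds recovers a noise-free mask exactly", {
  sc <- generate_scene(small_scene_params(seed = 8, noise_sd = 0))
  map <- segment_image(sc$image, default_thresholds())
  expect_identical(map$nucleus_labels > 0L, sc$truth$nucleus_labels > 0L)
  expect_identical(map$n_nuclei, sc$truth$n_nuclei)
})

test_that("infeasible placement raises a placement error", {
  p <- scene_params(width = 64L, height = 64L, n_nuclei = 40L, seed = 1)
  expect_error(generate_scene(p), "placement")
})

test_that("experiment generation applies multipliers and writes a manifest", {
  p <- small_scene_params()
  ex <- generate_experiment(p, effect = c(nuclear = 1.5, foci = 3),
                            n_images_per_group = 2L, seed = 5L)
  expect_identical(nrow(ex$manifest), 4L)
  expect_setequal(unique(ex$manifest$group), c("control", "treated"))
  expect_true(all(ex$manifest$is_control == (ex$manifest$group == "control")))
  expect_error(generate_experiment(p, effect = c(nuclear = -1, foci = 1),
                                   n_images_per_group = 1L), "parameter")

  # on-disk variant round-trips through the image reader
  d <- file.path(tempdir(), "exp_io")
  ex2 <- generate_experiment(p, n_images_per_group = 1L, seed = 6L, dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  img <- load_image(ex2$manifest$path[1])
  expect_identical(img$channels$green,
                   ex2$scenes[[ex2$manifest$image_id[1]]]$image$channels$green)
})

test_that("planted foci-density contrast is recovered at the stated multiplier", {
  p <- small_scene_params()
  ex <- generate_experiment(p, effect = c(nuclear = 1, foci = 3),
                            n_images_per_group = 6L, seed = 9L)
  dens <- function(grp) {
    mean(vapply(ex$scenes[ex$manifest$image_id[ex$manifest$group == grp]],
                function(s) s$truth$true_foci_density, 1))
  }
  expect_lt(abs(dens("treated") / dens("control") - 3), 3 * 0.2)
})
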