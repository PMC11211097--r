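test_that("isolated peaks, merging peaks, ramps and flat planes", {
  # single bright pixel
  pl <- matrix(0, 7, 7); pl[4, 4] <- 100
  fx <- find_maxima(pl, maxima_params(10))
  expect_identical(nrow(fx), 1L)
  expect_identical(c(fx$row, fx$col), c(4L, 4L))

  # two peaks (100 and 90) joined through a valley at 50: the 90-peak can
  # reach the higher one without descending by 60, but not by 30
  pl2 <- matrix(0, 5, 9)
  pl2[3, 2] <- 100; pl2[3, 8] <- 90; pl2[3, 3:7] <- 50
  expect_identical(nrow(find_maxima(pl2, maxima_params(30))), 2L)
  expect_identical(nrow(find_maxima(pl2, maxima_params(60))), 1L)
  # ordering: descending intensity
  both <- find_maxima(pl2, maxima_params(30))
  expect_equal(both$intensity, c(100, 90))

  # strictly increasing ramp: unique global maximum only
  ramp <- matrix(rep(1:9, each = 5), 5, 9)
  fx3 <- find_maxima(ramp, maxima_params(0))
  expect_identical(nrow(fx3), 1L)
  expect_identical(fx3$col, 9L)

  # globally constant plane: no summit, no maxima
  expect_identical(nrow(find_maxima(matrix(5, 6, 6), maxima_params(0))), 0L)

  # summit plateau: one centroid-snapped representative
  plat <- matrix(0, 7, 7); plat[3:5, 3:5] <- 8
  fx4 <- find_maxima(plat, maxima_params(2))
  expect_identical(nrow(fx4), 1L)
  expect_identical(c(fx4$row, fx4$col), c(4L, 4L))

  # equal-height twin peaks over a deep valley: both kept
  twin <- matrix(0, 5, 9); twin[3, 2] <- 70; twin[3, 8] <- 70; twin[3, 5] <- 10
  expect_identical(nrow(find_maxima(twin, maxima_params(20))), 2L)
})

test_that("find_maxima equals the brute-force path oracle on random planes", {
  set.seed(77)
  tols <- c(0, 7, 25)
  for (i in 1:40) {
    pl <- matrix(sample(0:50, 144, replace = TRUE), 12, 12)
    for (tol in tols) {
      a <- find_maxima(pl, maxima_params(tol))
      b <- brute_force_maxima_oracle(pl, maxima_params(tol))
      expect_identical(a$row, b$row)
      expect_identical(a$col, b$col)
      expect_identical(a$intensity, b$intensity)
    }
  }
  expect_error(brute_force_maxima_oracle(matrix(0, 40, 40), maxima_params(1)),
               "size guard")
})

test_that("tolerance monotonicity and shift/scale robustness", {
  set.seed(5)
  pl <- matrix(sample(0:100, 225, replace = TRUE), 15, 15)
  prev <- Inf
  for (tol in c(0, 5, 15, 40, 100)) {
    k <- nrow(find_maxima(pl, maxima_params(tol)))
    expect_lte(k, prev)
    prev <- k
  }
  base <- find_maxima(pl, maxima_params(12))
  shifted <- find_maxima(pl + 37, maxima_params(12))
  scaled <- find_maxima(pl * 3, maxima_params(36))
  expect_identical(base[c("row", "col")], shifted[c("row", "col")])
  expect_identical(base[c("row", "col")], scaled[c("row", "col")])
})

test_that("mask restriction: foci and merge paths cannot leave the nucleus", {
  # two bright spots in one image; only the one inside the mask is counted
  g <- matrix(0, 12, 12)
  g[3, 3] <- 200; g[9, 9] <- 200
  labels <- matrix(0L, 12, 12)
  labels[2:4, 2:4] <- 1L
  map <- classify_compartments(g, labels, threshold_config(0, 10))
  fr <- find_nuclear_foci(g, map, maxima_params(20))
  expect_identical(fr$foci_count, 1L)
  expect_identical(fr$foci$nucleus, 1L)
  expect_true(all(map$nucleus_labels[cbind(fr$foci$row, fr$foci$col)] >= 1L))

  # outside = bottomless: a merge path that would run through non-nuclear
  # territory does not exist, so two blobs sharing a bright bridge outside
  # the mask keep separate peaks
  g2 <- matrix(0, 5, 9)
  g2[3, 2] <- 100; g2[3, 8] <- 90; g2[3, 3:7] <- 50
  lab2 <- matrix(0L, 5, 9)
  lab2[2:4, 1:3] <- 1L; lab2[2:4, 7:9] <- 1L # bridge cols 4:6 not nucleus
  expect_identical(nrow(find_maxima(g2, maxima_params(60))), 1L)
  map2 <- classify_compartments(g2, lab2, threshold_config(0, 10))
  fr2 <- find_nuclear_foci(g2, map2, maxima_params(60))
  expect_identical(fr2$foci_count, 2L)
})

test_that("foci bookkeeping: counts, density, per-nucleus assignment", {
  g <- matrix(0, 20, 20)
  labels <- matrix(0L, 20, 20)
  labels[3:12, 3:12] <- 1L # one 10x10 nucleus
  g[labels == 1L] <- 20
  g[5, 5] <- 120; g[10, 10] <- 110
  map <- classify_compartments(g, labels, threshold_config(0, 10))
  fr <- find_nuclear_foci(g, map, maxima_params(30))
  expect_identical(fr$foci_count, 2L)
  expect_identical(fr$nuclear_area, 100L)
  expect_equal(fr$foci_density, 0.02)
  expect_identical(sum(fr$per_nucleus_counts), fr$foci_count)

  # no nuclei: zero count, flagged-undefined density
  none <- classify_compartments(g, matrix(0L, 20, 20), threshold_config(0, 10))
  fr0 <- find_nuclear_foci(g, none, maxima_params(30))
  expect_identical(fr0$foci_count, 0L)
  expect_true(is.na(fr0$foci_density))
})

test_that("planted foci are recovered on default synthetic scenes", {
  rec <- prec <- dens_ratio <- numeric()
  for (seed in 1:5) {
    sc <- generate_scene(scene_params(seed = 200 + seed))
    map <- segment_image(sc$image, default_thresholds())
    tol <- suggest_noise_tolerance(sc$image$channels$green, map)
    fr <- find_nuclear_foci(sc$image$channels$green, map, maxima_params(tol))
    s <- score_foci_detection(fr$foci, sc$truth$foci, radius = 2)
    rec <- c(rec, s$recall); prec <- c(prec, s$precision)
    dens_ratio <- c(dens_ratio, fr$foci_density / sc$truth$true_foci_density)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
  expect_lt(abs(mean(dens_ratio) - 1), 0.15)
})
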