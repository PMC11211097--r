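#' Parameters of a synthetic fluorescence scene
#'
#' The generator emulates a confocal field of adherent cultured cells imaged
#' in two channels: bright elliptical nuclei on the blue (DAPI) channel, and
#' on the green (marker) channel a dark background, a diffuse cytosolic halo
#' around each nucleus, an elevated nuclear level, and punctate intranuclear
#' foci modeled as isotropic Gaussian spots, all degraded by additive
#' Gaussian read noise and clipped to the representable range.
#'
#' Defaults describe an 8-bit confocal field at moderate cell density:
#' 256 x 256 px, 8 non-overlapping nuclei of 9-14 px semi-axes, DAPI level
#' 180, nuclear green 60 over a cytosolic 30 and background 5, a 6 px
#' cytosolic halo, on average 3 resolvable foci per nucleus (amplitude 90,
#' sigma 1.5 px, minimum separation 4 px), and read noise of sd 4.
#'
#' @param width,height scene size in pixels.
#' @param n_nuclei number of nuclei to place (rejection-sampled without
#'   overlap).
#' @param nucleus_axes length-2 numeric, (min, max) semi-axis length in px.
#' @param nucleus_blue_level DAPI intensity of nuclear pixels.
#' @param nuclear_green_level marker intensity added inside nuclei.
#' @param cytosol_green_level marker intensity of the perinuclear halo.
#' @param cytosol_halo_width halo width in px beyond the nuclear boundary.
#' @param background_green_level marker intensity elsewhere.
#' @param foci_per_nucleus Poisson mean of planted foci per nucleus.
#' @param focus_amplitude peak intensity added by one focus.
#' @param focus_sigma Gaussian width of a focus in px.
#' @param min_focus_separation minimum center distance between planted foci
#'   of one nucleus, in px; keeps puncta resolvable by maxima counting.
#' @param noise_sd sd of the additive Gaussian noise (both channels).
#' @param bit_depth 8 or 16.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(width = 256L, height = 256L, n_nuclei = 8L,
                         nucleus_axes = c(9, 14), nucleus_blue_level = 180,
                         nuclear_green_level = 60, cytosol_green_level = 30,
                         cytosol_halo_width = 6, background_green_level = 5,
                         foci_per_nucleus = 3, focus_amplitude = 90,
                         focus_sigma = 1.5, min_focus_separation = 4,
                         noise_sd = 4, bit_depth = 8L, seed = NULL) {
  p <- list(width = as.integer(width), height = as.integer(height),
            n_nuclei = as.integer(n_nuclei), nucleus_axes = nucleus_axes,
            nucleus_blue_level = nucleus_blue_level,
            nuclear_green_level = nuclear_green_level,
            cytosol_green_level = cytosol_green_level,
            cytosol_halo_width = cytosol_halo_width,
            background_green_level = background_green_level,
            foci_per_nucleus = foci_per_nucleus,
            focus_amplitude = focus_amplitude, focus_sigma = focus_sigma,
            min_focus_separation = min_focus_separation,
            noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
            seed = seed)
  maxv <- 2^p$bit_depth - 1
  stopifnot(p$width > 0, p$height > 0, p$n_nuclei >= 0,
            length(nucleus_axes) == 2L, nucleus_axes[1] <= nucleus_axes[2],
            nuclear_green_level >= background_green_level,
            nucleus_blue_level <= maxv, noise_sd >= 0,
            nuclear_green_level + focus_amplitude <= maxv)
  structure(p, class = "scene_params")
}

#' Generate one synthetic fluorescence scene with ground truth
#'
#' @param params a [scene_params].
#' @param source_id identifier for the generated image.
#' @return list with `image` (an [mc_image] with `blue` and `green`
#'   channels) and `truth`: `nucleus_labels` (label matrix in placement
#'   order), `foci` (data.frame `row`, `col`, `nucleus`), `true_nc_ratio`
#'   (nuclear over cytosolic mean of the noise-free green plane, foci
#'   included), `true_foci_density` (planted foci per pixel of true nuclear
#'   area), `n_nuclei`, `nuclear_area`.
#' @export
generate_scene <- function(params, source_id = "scene") {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    halo <- params$cytosol_halo_width
    rowg <- matrix(seq_len(h), h, w)
    colg <- matrix(seq_len(w), h, w, byrow = TRUE)

    # --- place non-overlapping ellipses by rejection sampling -------------
    centers <- matrix(numeric(0), ncol = 2)
    axes <- matrix(numeric(0), ncol = 2)
    theta <- numeric(0)
    tries <- 0L
    amax <- params$nucleus_axes[2]
    while (nrow(centers) < params$n_nuclei) {
      tries <- tries + 1L
      if (tries > 200L * max(params$n_nuclei, 1L))
        stop("placement error: cannot place non-overlapping nuclei; ",
             "reduce n_nuclei or nucleus_axes")
      a <- runif(1, params$nucleus_axes[1], params$nucleus_axes[2])
      b <- runif(1, params$nucleus_axes[1], params$nucleus_axes[2])
      margin <- amax + halo + 2
      cy <- runif(1, margin, h - margin)
      cx <- runif(1, margin, w - margin)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        # conservative bounding-circle test keeps halos from merging too
        if (any(d < (pmax(axes[, 1], axes[, 2]) + max(a, b) + halo + 2)))
          next
      }
      centers <- rbind(centers, c(cy, cx))
      axes <- rbind(axes, c(a, b))
      theta <- c(theta, runif(1, 0, pi))
    }

    labels <- matrix(0L, h, w)
    cytosol <- matrix(FALSE, h, w)
    inside_frac <- matrix(Inf, h, w) # normalized ellipse radius^2 per pixel
    for (k in seq_len(nrow(centers))) {
      dy <- rowg - centers[k, 1]; dx <- colg - centers[k, 2]
      u <- dy * cos(theta[k]) + dx * sin(theta[k])
      v <- -dy * sin(theta[k]) + dx * cos(theta[k])
      r2 <- (u / axes[k, 1])^2 + (v / axes[k, 2])^2
      nucpix <- r2 <= 1
      labels[nucpix] <- k
      inside_frac[nucpix] <- pmin(inside_frac[nucpix], r2[nucpix])
      r2h <- (u / (axes[k, 1] + halo))^2 + (v / (axes[k, 2] + halo))^2
      cytosol <- cytosol | (r2h <= 1)
    }
    cytosol <- cytosol & labels == 0L

    # --- clean (noise-free) planes ----------------------------------------
    blue <- matrix(0, h, w)
    blue[labels > 0L] <- params$nucleus_blue_level
    green <- matrix(params$background_green_level, h, w)
    green[cytosol] <- params$cytosol_green_level
    green[labels > 0L] <- params$nuclear_green_level

    # --- plant foci: Poisson count per nucleus, uniform inside the inner
    #     85% of the ellipse, minimum pairwise separation -------------------
    foci <- NULL
    for (k in seq_len(nrow(centers))) {
      nk <- rpois(1, params$foci_per_nucleus)
      if (nk == 0L) next
      cand <- which(labels == k & inside_frac <= 0.85^2)
      if (!length(cand)) next
      placed <- matrix(numeric(0), ncol = 2)
      attempts <- 0L
      while (nrow(placed) < nk && attempts < 50L * nk) {
        attempts <- attempts + 1L
        pick <- cand[sample.int(length(cand), 1L)]
        pr <- (pick - 1L) %% h + 1L
        pc <- (pick - 1L) %/% h + 1L
        if (nrow(placed)) {
          d <- sqrt((placed[, 1] - pr)^2 + (placed[, 2] - pc)^2)
          if (any(d < params$min_focus_separation)) next
        }
        placed <- rbind(placed, c(pr, pc))
      }
      if (nrow(placed))
        foci <- rbind(foci, data.frame(row = placed[, 1], col = placed[, 2],
                                       nucleus = k))
    }
    if (is.null(foci))
      foci <- data.frame(row = integer(), col = integer(),
                         nucleus = integer())

    if (nrow(foci)) {
      s2 <- 2 * params$focus_sigma^2
      win <- ceiling(4 * params$focus_sigma)
      for (k in seq_len(nrow(foci))) {
        r0 <- foci$row[k]; c0 <- foci$col[k]
        rr <- max(1, r0 - win):min(h, r0 + win)
        cc <- max(1, c0 - win):min(w, c0 + win)
        dy <- outer(rr - r0, rep(1, length(cc)))
        dx <- outer(rep(1, length(rr)), cc - c0)
        green[rr, cc] <- green[rr, cc] +
          params$focus_amplitude * exp(-(dy^2 + dx^2) / s2)
      }
    }

    nuc_area <- sum(labels > 0L)
    true_nc <- if (nuc_area && any(cytosol))
      mean(green[labels > 0L]) / mean(green[cytosol]) else NA_real_
    true_density <- if (nuc_area) nrow(foci) / nuc_area else NA_real_

    # --- noise and quantization ------------------------------------------
    maxv <- 2^params$bit_depth - 1
    clipq <- function(m) {
      if (params$noise_sd > 0) m <- m + rnorm(length(m), 0, params$noise_sd)
      matrix(pmin(pmax(round(m), 0), maxv), h, w)
    }
    img <- mc_image(list(blue = clipq(blue), green = clipq(green)),
                    bit_depth = params$bit_depth, source_id = source_id)
    list(image = img,
         truth = list(nucleus_labels = labels, foci = foci,
                      true_nc_ratio = true_nc,
                      true_foci_density = true_density,
                      n_nuclei = nrow(centers), nuclear_area = nuc_area))
  })
}

#' Generate a two-group synthetic experiment
#'
#' Emulates a redox-challenge experiment at the data level: a "control" group
#' and a "treated" group of scenes that differ only by multipliers on the
#' nuclear green level and the expected foci load. The menadione-like preset
#' (nuclear x1.5, foci x3) mirrors the direction of the oxidative-damage
#' response the pipeline is built to detect; multipliers of 1 give an
#' exchangeable null experiment.
#'
#' @param control_params a [scene_params] describing the control condition.
#' @param effect named numeric vector `c(nuclear = ..., foci = ...)`,
#'   multipliers applied to `nuclear_green_level` and `foci_per_nucleus`.
#' @param n_images_per_group number of scenes per group.
#' @param seed integer master seed; per-scene seeds are derived from it.
#' @param dir if non-NULL, scenes are written there as RGB TIFFs together
#'   with `manifest.csv` (columns `image_id`, `path`, `group`, `is_control`)
#'   and a ground-truth foci table `truth_foci.csv`.
#' @return list with `scenes` (named list: `image`, `truth`, `group` each),
#'   `manifest` (data.frame), and `dir`.
#' @export
generate_experiment <- function(control_params,
                                effect = c(nuclear = 1.5, foci = 3),
                                n_images_per_group = 20L, seed = 1L,
                                dir = NULL) {
  stopifnot(inherits(control_params, "scene_params"),
            n_images_per_group >= 1L)
  if (any(effect <= 0)) stop("parameter error: effect multipliers must be > 0")
  eff_nuc <- if ("nuclear" %in% names(effect)) effect[["nuclear"]] else 1
  eff_foc <- if ("foci" %in% names(effect)) effect[["foci"]] else 1
  treated_params <- control_params
  treated_params$nuclear_green_level <-
    control_params$nuclear_green_level * eff_nuc
  treated_params$foci_per_nucleus <-
    control_params$foci_per_nucleus * eff_foc
  maxv <- 2^control_params$bit_depth - 1
  if (treated_params$nuclear_green_level +
      treated_params$focus_amplitude > maxv)
    stop("parameter error: treated nuclear level + focus amplitude exceeds ",
         "the representable range")

  scenes <- list()
  manifest <- NULL
  idx <- 0L
  for (grp in c("control", "treated")) {
    par_g <- if (grp == "control") control_params else treated_params
    for (i in seq_len(n_images_per_group)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", grp, i)
      par_g$seed <- (seed * 1000L + idx) %% .Machine$integer.max
      sc <- generate_scene(par_g, source_id = id)
      sc$group <- grp
      scenes[[id]] <- sc
      path <- if (!is.null(dir)) file.path(dir, paste0(id, ".tif")) else NA
      manifest <- rbind(manifest, data.frame(
        image_id = id, path = path, group = grp,
        is_control = grp == "control", stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in names(scenes))
      write_image(scenes[[id]]$image, manifest$path[manifest$image_id == id])
    write_results_table(manifest, file.path(dir, "manifest.csv"))
    tf <- do.call(rbind, lapply(names(scenes), function(id) {
      f <- scenes[[id]]$truth$foci
      if (nrow(f)) cbind(image_id = id, f) else NULL
    }))
    if (is.null(tf))
      tf <- data.frame(image_id = character(), row = integer(),
                       col = integer(), nucleus = integer())
    write_results_table(tf, file.path(dir, "truth_foci.csv"))
  }
  list(scenes = scenes, manifest = manifest, dir = dir)
}
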