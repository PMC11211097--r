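#' Analyze one image: segment, quantify, detect foci
#'
#' Applies the full single-image chain — DAPI mask, three-way
#' compartmentalization, per-compartment and per-nucleus intensity
#' quantification, nuclear foci detection — with one series-level threshold
#' and maxima configuration.
#'
#' @param img an [mc_image].
#' @param thresholds a [threshold_config] (propagated from the series
#'   reference).
#' @param maxima a [maxima_params].
#' @param image_id identifier; defaults to the image's `source_id`.
#' @return list with `per_image` (one-row data.frame joining the intensity
#'   report with `foci_count`, `foci_density`, `n_nuclei`), `per_nucleus`
#'   (data.frame with per-object `area`, `mean_green`, `total_green`,
#'   `foci_count`, `foci_density`), `foci` (data.frame of detected maxima),
#'   `map` (the `compartment_map`), `foci_result`.
#' @export
analyze_image <- function(img, thresholds, maxima,
                          image_id = img$source_id) {
  map <- segment_image(img, thresholds)
  green <- img$channels$green
  rep1 <- compartment_intensities(green, map, image_id = image_id)
  pernuc <- per_nucleus_intensities(green, map, image_id = image_id)
  fr <- find_nuclear_foci(green, map, maxima, image_id = image_id)
  rep1$foci_count <- fr$foci_count
  rep1$foci_density <- fr$foci_density
  rep1$n_nuclei <- map$n_nuclei
  if (nrow(pernuc)) {
    pernuc$foci_count <- as.integer(fr$per_nucleus_counts[pernuc$nucleus])
    pernuc$foci_density <- pernuc$foci_count / pernuc$area
  } else {
    pernuc$foci_count <- integer()
    pernuc$foci_density <- numeric()
  }
  foci <- fr$foci
  if (nrow(foci)) foci <- cbind(image_id = image_id, foci)
  else foci <- data.frame(image_id = character(), row = integer(),
                          col = integer(), intensity = numeric(),
                          nucleus = integer())
  list(per_image = rep1, per_nucleus = pernuc, foci = foci, map = map,
       foci_result = fr)
}

#' Run configuration for a batch analysis
#'
#' @param manifest path to a manifest CSV (columns `image_id`, `path`,
#'   `group`, `is_control`) or an equivalent data.frame.
#' @param thresholds a [threshold_config] set on the series' reference image.
#' @param maxima a [maxima_params]; `NULL` derives the noise tolerance from
#'   the first control image via [suggest_noise_tolerance].
#' @param unit analysis unit pooled per condition for the statistics:
#'   `"per_nucleus"` (default) or `"per_image"`. The nuclear-to-cytosolic
#'   ratio is always compared per image (cytosol is not assigned to cells).
#' @param control control group name; `NULL` takes the manifest's
#'   `is_control` column.
#' @param alpha significance level.
#' @param rule normality combination rule, see [assess_normality].
#' @param out_dir output directory for tables and the run summary; `NULL`
#'   keeps everything in memory.
#' @param channel_order RGB plane naming passed to [load_image].
#' @return object of class `run_config`.
#' @export
run_config <- function(manifest, thresholds, maxima = NULL,
                       unit = c("per_nucleus", "per_image"), control = NULL,
                       alpha = 0.05, rule = "all", out_dir = NULL,
                       channel_order = c("red", "green", "blue")) {
  unit <- match.arg(unit)
  if (is.character(manifest)) manifest <- read_results_table(manifest)
  need <- c("image_id", "group")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns image_id and group")
  if (is.null(control)) {
    if (!"is_control" %in% names(manifest))
      stop("configuration error: no control designated")
    control <- unique(manifest$group[as.logical(manifest$is_control)])
    if (length(control) != 1L)
      stop("configuration error: manifest must designate exactly one ",
           "control group")
  }
  if (!(control %in% manifest$group))
    stop("configuration error: control group absent from manifest")
  structure(list(manifest = manifest, thresholds = thresholds,
                 maxima = maxima, unit = unit, control = control,
                 alpha = alpha, rule = rule, out_dir = out_dir,
                 channel_order = channel_order),
            class = "run_config")
}

# Group-comparison statistics over collected per-image / per-nucleus tables.
# Returns the comparisons plus the tables with the control-relative
# percentage column attached.
experiment_stats <- function(per_image, per_nucleus, config) {
  unit_tab <- if (config$unit == "per_nucleus" && nrow(per_nucleus))
    per_nucleus else per_image
  val_col <- if (config$unit == "per_nucleus" && nrow(per_nucleus))
    "mean_green" else "nuclear_mean"
  grp_of <- function(tab) {
    config$manifest$group[match(tab$image_id, config$manifest$image_id)]
  }
  unit_tab$group <- grp_of(unit_tab)
  per_image$group <- grp_of(per_image)

  ctrl_vals <- unit_tab[[val_col]][unit_tab$group == config$control]
  unit_tab$relative_intensity <-
    normalize_to_control(unit_tab[[val_col]], ctrl_vals)

  split_by_group <- function(tab, col) {
    v <- split(tab[[col]][!is.na(tab[[col]])],
               tab$group[!is.na(tab[[col]])])
    v[vapply(v, length, 1L) > 0L]
  }
  comparisons <- list()
  run_metric <- function(tab, col) {
    g <- split_by_group(tab, col)
    if (length(g) < 2L) return(NULL)
    # a metric whose groups are too small for the battery is reported as
    # missing rather than aborting the whole run
    tryCatch(select_and_run(g, control = config$control,
                            alpha = config$alpha, rule = config$rule),
             error = function(e) {
               warning("comparison for '", col, "' skipped: ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  }
  comparisons$relative_nuclear_intensity <-
    run_metric(unit_tab, "relative_intensity")
  comparisons$foci_density <- run_metric(unit_tab, "foci_density")
  comparisons$nc_ratio <- run_metric(per_image, "nc_ratio")
  list(comparisons = comparisons, unit_table = unit_tab,
       per_image = per_image)
}

#' Run the full batch pipeline
#'
#' For every image of the manifest: load, build the DAPI mask, classify
#' compartments, quantify intensities, detect foci. Then pool measurements
#' per condition, normalize nuclear intensities to the control (control mean
#' = 100%), and run the normality-gated group comparison for relative
#' nuclear intensity, foci density and nuclear-to-cytosolic ratio. With an
#' `out_dir`, writes `per_image.csv`, `per_nucleus.csv`, `foci.csv`,
#' `stats.csv` and a machine-readable `summary.json`. Identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param config a [run_config].
#' @param images optional named list of [mc_image]s keyed by `image_id`,
#'   bypassing file loading (used for in-memory synthetic experiments).
#' @return run summary list: `groups` (per-group image/nucleus/foci counts),
#'   `thresholds`, `noise_tolerance`, `unit`, `comparisons` (per metric:
#'   chosen test, per-group normality p-values, comparisons table), plus the
#'   collected `tables`.
#' @export
run_pipeline <- function(config, images = NULL) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  if (!nrow(man)) stop("configuration error: empty manifest")
  if (any(!nzchar(man$group)))
    stop("configuration error: image with empty group")

  get_image <- function(i) {
    id <- man$image_id[i]
    if (!is.null(images)) {
      img <- images[[id]]
      if (is.null(img)) stop("image '", id, "' missing from supplied images")
      return(img)
    }
    tryCatch(load_image(man$path[i], channel_order = config$channel_order,
                        source_id = id),
             error = function(e) stop("while processing image '", id, "': ",
                                      conditionMessage(e)))
  }

  # series policy: one reference configuration, propagated verbatim
  series_cfg <- propagate_threshold(config$thresholds, man$image_id)
  maxima <- config$maxima
  if (is.null(maxima)) {
    ref_i <- which(man$group == config$control)[1L]
    ref_img <- get_image(ref_i)
    ref_map <- segment_image(ref_img, config$thresholds)
    maxima <- maxima_params(
      suggest_noise_tolerance(ref_img$channels$green, ref_map))
  }

  per_image <- NULL; per_nucleus <- NULL; foci <- NULL
  for (i in seq_len(nrow(man))) {
    id <- man$image_id[i]
    res <- analyze_image(get_image(i), series_cfg[[id]], maxima,
                         image_id = id)
    per_image <- rbind(per_image, res$per_image)
    per_nucleus <- rbind(per_nucleus, res$per_nucleus)
    foci <- rbind(foci, res$foci)
  }

  st <- experiment_stats(per_image, per_nucleus, config)

  groups <- lapply(split(st$per_image, st$per_image$group), function(g)
    list(n_images = nrow(g), n_nuclei = sum(g$n_nuclei),
         n_foci = sum(g$foci_count)))
  cmp_summary <- lapply(st$comparisons, function(x) {
    if (is.null(x)) return(NULL)
    list(chosen_test = x$chosen_test,
         normality = lapply(x$normality, function(v)
           list(gaussian = v$gaussian,
                p = as.list(round(v$per_test_p, 10)))),
         overall_p = x$overall_p,
         comparisons = x$comparisons)
  })
  summary <- list(
    n_images = nrow(man),
    unit = config$unit,
    control = config$control,
    thresholds = unclass(config$thresholds),
    noise_tolerance = maxima$noise_tolerance,
    groups = groups,
    comparisons = cmp_summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(per_image, file.path(config$out_dir,
                                             "per_image.csv"))
    write_results_table(per_nucleus, file.path(config$out_dir,
                                               "per_nucleus.csv"))
    write_results_table(foci, file.path(config$out_dir, "foci.csv"))
    stats_tab <- do.call(rbind, lapply(names(st$comparisons), function(m) {
      x <- st$comparisons[[m]]
      if (is.null(x)) return(NULL)
      cbind(metric = m, chosen_test = x$chosen_test, x$comparisons)
    }))
    if (!is.null(stats_tab))
      write_results_table(stats_tab, file.path(config$out_dir, "stats.csv"))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE, na = "null"),
               con = file.path(config$out_dir, "summary.json"))
  }
  invisible(c(summary,
              list(tables = list(per_image = per_image,
                                 per_nucleus = per_nucleus, foci = foci,
                                 unit_table = st$unit_table),
                   stats = st$comparisons)))
}

#' Export audit overlays for one image
#'
#' Writes the visual quality-control images that stand in for the manual
#' threshold check of the original workflow: a compartment-mask PNG
#' (background 0, cytosol 85, nucleus 170) and a foci-overlay PNG (green
#' channel in grey, detected foci marked by red crosses).
#'
#' @param config a [run_config].
#' @param image_id identifier of an image listed in the manifest.
#' @param dir output directory.
#' @param images optional in-memory image list as in [run_pipeline].
#' @return invisibly, the two file paths written.
#' @export
audit_export <- function(config, image_id, dir, images = NULL) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  i <- match(image_id, man$image_id)
  if (is.na(i)) stop("lookup error: unknown image id '", image_id, "'")
  img <- if (!is.null(images)) images[[image_id]]
  else load_image(man$path[i], channel_order = config$channel_order,
                  source_id = image_id)
  maxima <- config$maxima
  if (is.null(maxima)) {
    map0 <- segment_image(img, config$thresholds)
    maxima <- maxima_params(
      suggest_noise_tolerance(img$channels$green, map0))
  }
  res <- analyze_image(img, config$thresholds, maxima, image_id = image_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  mask_path <- file.path(dir, paste0(image_id, "_mask.png"))
  enc <- matrix(0, img$height, img$width)
  enc[res$map$classes == COMPARTMENTS[["CYTOSOL"]]] <- 85
  enc[res$map$classes == COMPARTMENTS[["NUCLEUS"]]] <- 170
  png::writePNG(enc / 255, mask_path)

  overlay_path <- file.path(dir, paste0(image_id, "_foci.png"))
  g <- img$channels$green / (2^img$bit_depth - 1)
  rgb <- array(0, dim = c(img$height, img$width, 3L))
  rgb[, , 1] <- g; rgb[, , 2] <- g; rgb[, , 3] <- g
  fx <- res$foci
  for (k in seq_len(nrow(fx))) {
    rr <- pmin(pmax(fx$row[k] + (-2:2), 1L), img$height)
    cc <- pmin(pmax(fx$col[k] + (-2:2), 1L), img$width)
    rgb[rr, fx$col[k], 1] <- 1; rgb[rr, fx$col[k], 2:3] <- 0
    rgb[fx$row[k], cc, 1] <- 1; rgb[fx$row[k], cc, 2:3] <- 0
  }
  png::writePNG(rgb, overlay_path)
  invisible(c(mask_path, overlay_path))
}
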