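#' Per-compartment intensity summary of one image
#'
#' Means and areas of the green (marker) channel over the three compartments,
#' plus the nuclear-to-cytosolic mean-intensity ratio. The background is
#' measured but never subtracted: the workflow thresholds background away
#' rather than correcting for it. Compartments with zero pixels yield `NA`
#' means, and `nc_ratio` is `NA` whenever the cytosolic area is zero.
#'
#' @param green numeric matrix, marker-channel intensities.
#' @param map a `compartment_map` from [classify_compartments].
#' @param image_id identifier copied into the report.
#'
#' @return one-row data.frame: `image_id`, `nuclear_mean`, `cytosolic_mean`,
#'   `background_mean`, `nuclear_total`, `nuclear_area`, `cytosolic_area`,
#'   `background_area`, `nc_ratio`.
#' @export
compartment_intensities <- function(green, map, image_id = "image") {
  if (!all(dim(green) == dim(map$classes)))
    stop("shape mismatch between green plane and compartment map")
  cls <- map$classes
  nuc <- green[cls == COMPARTMENTS[["NUCLEUS"]]]
  cyt <- green[cls == COMPARTMENTS[["CYTOSOL"]]]
  bg  <- green[cls == COMPARTMENTS[["BACKGROUND"]]]
  m <- function(v) if (length(v)) mean(v) else NA_real_
  nc <- if (length(cyt) && length(nuc)) m(nuc) / m(cyt) else NA_real_
  data.frame(image_id = image_id,
             nuclear_mean = m(nuc), cytosolic_mean = m(cyt),
             background_mean = m(bg),
             nuclear_total = sum(nuc),
             nuclear_area = length(nuc), cytosolic_area = length(cyt),
             background_area = length(bg),
             nc_ratio = nc, stringsAsFactors = FALSE)
}

#' Per-nucleus intensity summary
#'
#' Mean and total green intensity over each labeled nuclear object. These are
#' the per-cell measurements pooled within a condition when the analysis unit
#' is `per_nucleus`.
#'
#' @inheritParams compartment_intensities
#' @return data.frame with one row per nucleus: `image_id`, `nucleus`,
#'   `area`, `mean_green`, `total_green`.
#' @export
per_nucleus_intensities <- function(green, map, image_id = "image") {
  if (!all(dim(green) == dim(map$nucleus_labels)))
    stop("shape mismatch between green plane and nucleus labels")
  lab <- map$nucleus_labels
  n <- map$n_nuclei
  if (n == 0L)
    return(data.frame(image_id = character(), nucleus = integer(),
                      area = integer(), mean_green = numeric(),
                      total_green = numeric(), stringsAsFactors = FALSE))
  idx <- lab > 0L
  sums <- as.vector(tapply(green[idx], lab[idx], sum))
  areas <- tabulate(lab[idx], n)
  data.frame(image_id = image_id, nucleus = seq_len(n), area = areas,
             mean_green = sums / areas, total_green = sums,
             stringsAsFactors = FALSE)
}

#' Express measurements relative to the control group
#'
#' Every value is mapped to `100 * v / mean(control_values)`, so the control
#' group's transformed mean is exactly 100 (the control is defined as 100%).
#'
#' @param sample_values numeric vector of measurements (e.g. per-image or
#'   per-nucleus nuclear means).
#' @param control_values numeric vector of the control group's measurements;
#'   must be non-empty with a positive mean.
#' @return numeric vector of relative percentages.
#' @export
normalize_to_control <- function(sample_values, control_values) {
  if (!length(control_values))
    stop("normalization error: empty control group")
  cm <- mean(control_values)
  if (!is.finite(cm) || cm <= 0)
    stop("normalization error: control mean must be positive")
  100 * sample_values / cm
}
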