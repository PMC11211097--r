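#' Threshold configuration for a sample series
#'
#' Per the manual-threshold policy of the underlying workflow, thresholds are
#' set once on a reference image of a stained series and propagated unchanged
#' to every other image of that series ([propagate_threshold]). Pixels exactly
#' at a threshold count as background (strictly-greater-than semantics).
#'
#' @param dapi_threshold blue-channel intensity on the native scale; pixels
#'   with DAPI signal strictly above it are nucleus candidates.
#' @param background_threshold green-channel intensity on the native scale;
#'   non-nuclear pixels strictly above it are cytosol, the rest background.
#' @param min_nucleus_area smallest connected nuclear object kept, in pixels.
#' @param fill_holes fill interior holes of each nuclear component.
#'
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(dapi_threshold, background_threshold,
                             min_nucleus_area = 50L, fill_holes = TRUE) {
  stopifnot(dapi_threshold >= 0, background_threshold >= 0,
            min_nucleus_area >= 0)
  structure(list(dapi_threshold = dapi_threshold,
                 background_threshold = background_threshold,
                 min_nucleus_area = as.integer(min_nucleus_area),
                 fill_holes = isTRUE(fill_holes)),
            class = "threshold_config")
}

#' Compute the DAPI-derived nuclear mask
#'
#' Binarizes the blue (DAPI) plane at `config$dapi_threshold` (strictly
#' greater-than), optionally fills interior holes of each 8-connected
#' component, removes components smaller than `config$min_nucleus_area`
#' (measured after hole filling), and labels the survivors `1..n` in
#' top-left-first row-major scan order.
#'
#' @param blue numeric matrix, DAPI intensities on the native scale.
#' @param config a [threshold_config].
#'
#' @return list with `nucleus_labels` (integer matrix, 0 = not nucleus) and
#'   `n_nuclei`. An all-background plane is a valid result with `n_nuclei = 0`.
#' @export
compute_nuclear_mask <- function(blue, config) {
  stopifnot(is.matrix(blue), inherits(config, "threshold_config"))
  mask <- blue > config$dapi_threshold
  if (config$fill_holes) mask <- cpp_fill_holes(mask)
  lab <- cpp_label_components(mask, 8L)
  if (config$min_nucleus_area > 0L && any(lab > 0L)) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= config$min_nucleus_area)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep) # survivors keep scan-order ranks
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  list(nucleus_labels = lab, n_nuclei = max(lab))
}

#' Classify every pixel as nucleus, cytosol or background
#'
#' Nucleus wherever the nuclear mask is set; outside the mask, pixels with
#' green signal strictly above `background_threshold` are cytosol ("not
#' nucleus, but brighter than the background") and the rest are background.
#'
#' @param green numeric matrix, marker-channel intensities.
#' @param nucleus_labels integer label matrix from [compute_nuclear_mask].
#' @param config a [threshold_config].
#'
#' @return A `compartment_map`: list with `classes` (integer matrix coded by
#'   [COMPARTMENTS]), `nucleus_labels`, and `n_nuclei`. The three classes
#'   partition the image.
#' @export
classify_compartments <- function(green, nucleus_labels, config) {
  if (!all(dim(green) == dim(nucleus_labels)))
    stop("shape mismatch between green plane and nucleus labels")
  classes <- matrix(COMPARTMENTS[["BACKGROUND"]], nrow(green), ncol(green))
  classes[nucleus_labels == 0L & green > config$background_threshold] <-
    COMPARTMENTS[["CYTOSOL"]]
  classes[nucleus_labels >= 1L] <- COMPARTMENTS[["NUCLEUS"]]
  structure(list(classes = classes, nucleus_labels = nucleus_labels,
                 n_nuclei = max(nucleus_labels)),
            class = "compartment_map")
}

#' Segment an image into compartments in one call
#'
#' Convenience wrapper: nuclear mask from the blue channel, then three-way
#' classification of the green channel.
#'
#' @param img an [mc_image] with `blue` and `green` channels.
#' @param config a [threshold_config].
#' @return a `compartment_map` (see [classify_compartments]).
#' @export
segment_image <- function(img, config) {
  m <- compute_nuclear_mask(img$channels$blue, config)
  classify_compartments(img$channels$green, m$nucleus_labels, config)
}

#' Propagate a reference threshold configuration across a series
#'
#' The thresholds are set manually on a single reference image of a test
#' series and every remaining image of the series is evaluated with the same
#' values; there is no per-image adaptation. Configurations have value
#' semantics: later changes to the reference do not alter issued copies.
#'
#' @param reference a [threshold_config] fixed on the series' reference image.
#' @param series character vector of image identifiers.
#' @return named list mapping each image id to an identical copy of
#'   `reference`.
#' @export
propagate_threshold <- function(reference, series) {
  if (!inherits(reference, "threshold_config"))
    stop("'reference' must be a threshold_config")
  if (!length(series)) stop("configuration error: empty image series")
  stats::setNames(rep(list(reference), length(series)), series)
}

#' Otsu threshold suggestion
#'
#' Histogram-based two-class variance maximization on the native integer
#' scale; offered as a logged starting point for the manual threshold choice,
#' never applied silently.
#'
#' @param plane numeric matrix of integer intensities.
#' @param bit_depth 8 or 16.
#' @return suggested threshold (pixels strictly above it are foreground).
#' @export
otsu_threshold <- function(plane, bit_depth = 8L) {
  v <- as.integer(round(plane))
  nbins <- 2^bit_depth
  h <- tabulate(v + 1L, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 1))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # a bimodal histogram with an empty gap maximizes the criterion on a
  # plateau of thresholds; take the plateau midpoint
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  as.integer(round(mean(range(best)))) - 1L
}
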