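#' Parameters for noise-tolerance maxima detection
#'
#' `noise_tolerance` is the prominence a peak must have over its merging
#' saddle: a candidate maximum at intensity `I` is discarded when a strictly
#' higher pixel can be reached from it along an 8-connected path that never
#' drops to `I - noise_tolerance` or below. Like the compartment thresholds
#' it is fixed once per stained series on a reference image.
#'
#' @param noise_tolerance non-negative intensity difference on the native
#'   scale.
#' @param exclude_edge drop maxima whose representative pixel lies on the
#'   image border.
#' @return object of class `maxima_params`.
#' @export
maxima_params <- function(noise_tolerance, exclude_edge = FALSE) {
  stopifnot(noise_tolerance >= 0)
  structure(list(noise_tolerance = noise_tolerance,
                 exclude_edge = isTRUE(exclude_edge)),
            class = "maxima_params")
}

#' Find noise-tolerance local maxima
#'
#' Detects intensity peaks under the prominence rule described in
#' [maxima_params]. Connected plateaus of equal intensity count as a single
#' candidate, represented by the plateau pixel nearest the plateau centroid.
#' A fully flat region — in particular a globally constant plane — contains
#' no summit and yields no maxima. Maxima are returned sorted by descending
#' intensity, ties broken by row-major scan order.
#'
#' @param plane numeric intensity matrix.
#' @param params a [maxima_params].
#' @param mask optional logical matrix; pixels outside the mask are treated
#'   as bottomless (-Inf) so that peaks and their merge paths cannot cross
#'   non-masked territory.
#' @return data.frame with columns `row`, `col` (1-based) and `intensity`.
#' @export
find_maxima <- function(plane, params, mask = NULL) {
  stopifnot(is.matrix(plane), inherits(params, "maxima_params"))
  if (!length(plane)) stop("empty intensity plane")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(plane), ncol(plane))
  if (!all(dim(mask) == dim(plane)))
    stop("shape mismatch between plane and mask")
  cpp_find_maxima(plane, mask, params$noise_tolerance, params$exclude_edge)
}

#' Brute-force reference implementation of the maxima rule
#'
#' Independent oracle for testing [find_maxima]: pure-R exhaustive graph
#' search applying the identical acceptance rule by iterated neighborhood
#' expansion. Guarded to small planes.
#'
#' @inheritParams find_maxima
#' @return data.frame with columns `row`, `col`, `intensity`, same contract
#'   as [find_maxima].
#' @export
brute_force_maxima_oracle <- function(plane, params, mask = NULL) {
  stopifnot(is.matrix(plane), inherits(params, "maxima_params"))
  h <- nrow(plane); w <- ncol(plane)
  if (h * w > 1024L) stop("oracle size guard: plane larger than 32 x 32")
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  tol <- params$noise_tolerance

  nb <- function(r, c) {
    d <- expand.grid(dr = -1:1, dc = -1:1)
    d <- d[!(d$dr == 0 & d$dc == 0), ]
    rr <- r + d$dr; cc <- c + d$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    cbind(rr[ok], cc[ok])
  }

  # plateau labels by repeated merging of equal-value masked neighbors
  plab <- matrix(0L, h, w)
  nextl <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c] || plab[r, c] > 0L) next
    nextl <- nextl + 1L
    frontier <- matrix(c(r, c), ncol = 2)
    plab[r, c] <- nextl
    v <- plane[r, c]
    while (nrow(frontier)) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        for (j in seq_len(nrow(nbk <- nb(frontier[k, 1], frontier[k, 2])))) {
          rr <- nbk[j, 1]; cc <- nbk[j, 2]
          if (mask[rr, cc] && plab[rr, cc] == 0L && plane[rr, cc] == v) {
            plab[rr, cc] <- nextl
            nxt <- rbind(nxt, c(rr, cc))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
    }
  }

  res <- NULL
  for (id in seq_len(nextl)) {
    px <- which(plab == id, arr.ind = TRUE)
    I <- plane[px[1, 1], px[1, 2]]
    # neighbor relations of the plateau
    higher <- FALSE; lower <- FALSE
    for (k in seq_len(nrow(px))) {
      nbk <- nb(px[k, 1], px[k, 2])
      for (j in seq_len(nrow(nbk))) {
        rr <- nbk[j, 1]; cc <- nbk[j, 2]
        if (!mask[rr, cc]) next
        if (plane[rr, cc] > I) higher <- TRUE
        if (plane[rr, cc] < I) lower <- TRUE
      }
    }
    if (higher || !lower) next
    # reachability flood: iterate to fixpoint over pixels with value > I - tol
    reach <- plab == id
    repeat {
      grew <- FALSE
      for (r in seq_len(h)) for (c in seq_len(w)) {
        if (!reach[r, c]) next
        nbk <- nb(r, c)
        for (j in seq_len(nrow(nbk))) {
          rr <- nbk[j, 1]; cc <- nbk[j, 2]
          if (mask[rr, cc] && !reach[rr, cc] && plane[rr, cc] > I - tol) {
            reach[rr, cc] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    if (any(plane[reach & mask] > I)) next
    mr <- mean(px[, 1]); mc <- mean(px[, 2])
    d2 <- (px[, 1] - mr)^2 + (px[, 2] - mc)^2
    scan <- (px[, 1] - 1) * w + px[, 2]
    cand <- which(abs(d2 - min(d2)) <= 1e-12)
    best <- cand[which.min(scan[cand])]
    br <- px[best, 1]; bc <- px[best, 2]
    if (params$exclude_edge && (br == 1 || br == h || bc == 1 || bc == w))
      next
    res <- rbind(res, data.frame(row = as.integer(br), col = as.integer(bc),
                                 intensity = as.numeric(I)))
  }
  if (is.null(res))
    return(data.frame(row = integer(), col = integer(),
                      intensity = numeric()))
  scan <- (res$row - 1) * w + res$col
  res <- res[order(-res$intensity, scan), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Suggested noise tolerance for a series
#'
#' Mirrors the manual per-series threshold policy: on a reference image, the
#' suggestion is twice the robust standard deviation (MAD) of the green
#' intensities inside the nuclear mask — large enough to step over pixel
#' noise, small enough to keep genuine puncta.
#'
#' @param green numeric matrix, marker-channel intensities.
#' @param map a `compartment_map` of the reference image.
#' @return suggested `noise_tolerance` value.
#' @export
suggest_noise_tolerance <- function(green, map) {
  v <- green[map$nucleus_labels > 0L]
  if (!length(v)) stop("reference image has no nuclear pixels")
  2 * mad(v)
}

#' Detect nuclear foci and their density per nuclear area
#'
#' Runs noise-tolerance maxima detection on the green plane restricted to the
#' nuclear mask (non-nuclear pixels are bottomless, so two nuclei merged into
#' one label cannot share a focus across a background gap), assigns each
#' focus to its nucleus, and reports the foci count divided by the total
#' nuclear area in pixels.
#'
#' @param green numeric matrix, marker-channel intensities.
#' @param map a `compartment_map`.
#' @param params a [maxima_params].
#' @param image_id identifier copied into the result.
#' @return object of class `foci_result`: list with `image_id`, `foci`
#'   (data.frame `row`, `col`, `intensity`, `nucleus`), `foci_count`,
#'   `nuclear_area`, `foci_density` (`NA` when the nuclear area is zero), and
#'   `per_nucleus_counts` (named integer vector over labels `1..n_nuclei`).
#' @export
find_nuclear_foci <- function(green, map, params, image_id = "image") {
  if (!all(dim(green) == dim(map$nucleus_labels)))
    stop("shape mismatch between green plane and nucleus labels")
  mask <- map$nucleus_labels > 0L
  area <- sum(mask)
  fx <- find_maxima(green, params, mask = mask)
  lab <- map$nucleus_labels[cbind(fx$row, fx$col)]
  fx$nucleus <- if (length(lab)) as.integer(lab) else integer()
  counts <- tabulate(fx$nucleus, nbins = max(map$n_nuclei, 0L))
  names(counts) <- if (map$n_nuclei > 0L) seq_len(map$n_nuclei)
  structure(list(image_id = image_id, foci = fx, foci_count = nrow(fx),
                 nuclear_area = area,
                 foci_density = if (area > 0L) nrow(fx) / area else NA_real_,
                 per_nucleus_counts = counts),
            class = "foci_result")
}

#' Score detected foci against ground-truth coordinates
#'
#' Greedy one-to-one matching by increasing distance within a match radius,
#' for benchmarking detection on synthetic scenes.
#'
#' @param detected data.frame with `row`, `col` (e.g. `foci` of a
#'   `foci_result`).
#' @param truth data.frame with `row`, `col` of planted foci.
#' @param radius maximum center distance (pixels) for a match.
#' @return list with `n_matched`, `recall`, `precision`.
#' @export
score_foci_detection <- function(detected, truth, radius = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  dmat <- outer(detected$row, truth$row, "-")^2 +
    outer(detected$col, truth$col, "-")^2
  pairs <- which(dmat <= radius^2, arr.ind = TRUE)
  if (!nrow(pairs))
    return(list(n_matched = 0L, recall = 0, precision = 0))
  pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); m <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE; m <- m + 1L
    }
  }
  list(n_matched = m, recall = m / nt, precision = m / nd)
}
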