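# Forward radiography: polychromatic Beer-Lambert imaging through a filter,
# Poisson counting noise, and image conditioning (flat-field, pedestal,
# frame averaging).

.detector_weights <- function(spectrum, filter, response) {
  S <- if (is.null(filter)) spectrum else filter_transmission(filter, spectrum)
  D <- switch(response, counting = 1, energy = S$energy)
  S$counts * D
}

# Evaluate sum_E w(E) exp(-sum_el mu_el(E) t_el) for every pixel, exploiting
# repeated thickness combinations (piecewise-constant phantoms collapse to a
# handful of unique rows).
.poly_transmission <- function(thick_um, elements, energy, weights) {
  npx <- nrow(thick_um)
  if (length(elements) == 0) {
    return(rep(sum(weights), npx))
  }
  keep <- weights > 0  # skip empty bins (below cut-off / above kVp)
  energy <- energy[keep]
  weights <- weights[keep]
  mu_mat <- matrix(0, length(energy), length(elements))
  for (j in seq_along(elements)) mu_mat[, j] <- mu(elements[j], energy)
  key <- do.call(paste, c(lapply(seq_len(ncol(thick_um)),
                                 function(j) thick_um[, j]), sep = "\r"))
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  u_thick <- thick_um[uniq, , drop = FALSE] * 1e-4  # um -> cm
  vals <- beer_lambert_counts(u_thick, mu_mat, weights)
  vals[idx]
}

#' Simulate a filtered radiograph of a 2D phantom
#'
#' Per pixel, detected counts are the spectrum summed over energy after the
#' filter's and the sample's Beer-Lambert transmission, weighted by the
#' detector response (`counting`: D(E) = 1; `energy`: D(E) = E, mimicking
#' an energy-integrating scintillator/CCD).  The paired flat-field image is
#' computed with the same model at zero sample thickness.  Poisson counting
#' noise is applied iff `noise_seed` is given; the flat uses an independent
#' stream seeded with `noise_seed + 1`.
#'
#' @param phantom A [phantom2d()].
#' @param spectrum An [xr_spectrum].
#' @param filter A [filter_spec()], or `NULL` for the naked beam.
#' @param flat_counts Mean flat-field counts per pixel at `exposure_scale =
#'   1` (exposure calibration).
#' @param exposure_scale Relative exposure.
#' @param noise_seed Integer seed for Poisson sampling, or `NULL` for a
#'   noise-free image.
#' @param response Detector weighting, `"counting"` (default) or
#'   `"energy"`.
#' @return An object of class `radiograph` with fields `counts`, `flat`,
#'   `filter`, `shape`, `pixel_um`, `exposure` and `n_frames`.
#' @export
simulate_radiograph <- function(phantom, spectrum, filter = NULL,
                                flat_counts = 1e4, exposure_scale = 1,
                                noise_seed = NULL,
                                response = c("counting", "energy")) {
  stopifnot(inherits(phantom, "phantom2d"), inherits(spectrum, "xr_spectrum"))
  response <- match.arg(response)
  w <- .detector_weights(spectrum, filter, response)
  if (sum(w) <= 0) stop("filtered spectrum has no flux", call. = FALSE)
  # exposure calibration: the naked (unfiltered) beam gives `flat_counts`
  # mean counts/pixel, shared by all filters of an acquisition
  w <- w * flat_counts * exposure_scale /
    sum(.detector_weights(spectrum, NULL, response))
  shape <- phantom$shape
  npx <- prod(shape)
  elements <- names(phantom$thickness)
  thick <- if (length(elements)) {
    vapply(elements, function(el) as.numeric(phantom$thickness[[el]]),
           numeric(npx))
  } else {
    matrix(0, npx, 0)
  }
  sample_px <- .poly_transmission(thick, elements, spectrum$energy, w)
  flat_px <- rep(sum(w), npx)
  if (!is.null(noise_seed)) {
    set.seed(as.integer(noise_seed))
    sample_px <- as.numeric(stats::rpois(npx, sample_px))
    set.seed(as.integer(noise_seed) + 1L)
    flat_px <- as.numeric(stats::rpois(npx, flat_px))
  }
  structure(list(counts = matrix(sample_px, shape[1], shape[2]),
                 flat = matrix(flat_px, shape[1], shape[2]),
                 filter = filter, shape = shape, pixel_um = phantom$pixel_um,
                 exposure = flat_counts * exposure_scale, n_frames = 1L),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px, filter %s, mean counts %.4g (flat %.4g), %d frame(s)\n",
              x$shape[1], x$shape[2],
              if (is.null(x$filter)) "none"
              else sprintf("%s %.1f um", x$filter$element, x$filter$thickness_um),
              mean(x$counts), mean(x$flat), x$n_frames))
  invisible(x)
}

#' Flat-field correction
#'
#' Per-pixel ratio of the sample image to its no-sample reference image,
#' removing illumination and filter non-uniformity.  Values can exceed 1
#' under noise.
#'
#' @param radiograph A [simulate_radiograph()] result (or any list with
#'   `counts` and `flat` matrices).
#' @return Transmission image (matrix).
#' @export
flat_correct <- function(radiograph) {
  counts <- radiograph$counts
  flat <- radiograph$flat
  bad <- which(flat == 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(flat))
    stop(sprintf("flat field has %d zero pixel(s); first at (row %d, col %d)",
                 length(bad), rc[1], rc[2]), call. = FALSE)
  }
  counts / flat
}

#' Pedestal threshold
#'
#' Sets pixels below `fraction` of the image maximum to zero, suppressing
#' stray scattered background; all other pixels are unchanged.
#'
#' @param image Numeric matrix.
#' @param fraction Threshold as a fraction of `max(image)`, in `[0, 1]`.
#' @return Thresholded matrix.
#' @export
pedestal_threshold <- function(image, fraction = 0.02) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (fraction == 0) return(image)
  thr <- fraction * max(image)
  image[image < thr] <- 0
  image
}

#' Average repeated radiographs
#'
#' Pixel-wise arithmetic mean of the sample and of the flat images of
#' repeated frames taken with the same filter.
#'
#' @param frames List of `radiograph` objects with identical shape and
#'   filter.
#' @return A `radiograph` whose `n_frames` records the count.
#' @export
average_frames <- function(frames) {
  stopifnot(length(frames) >= 1)
  ref <- frames[[1]]
  same_filter <- function(a, b) {
    (is.null(a) && is.null(b)) ||
      (!is.null(a) && !is.null(b) && a$element == b$element &&
         a$thickness_um == b$thickness_um)
  }
  for (f in frames[-1]) {
    if (!all(f$shape == ref$shape)) stop("frame shapes differ", call. = FALSE)
    if (!same_filter(f$filter, ref$filter)) {
      stop("cannot average frames taken with different filters", call. = FALSE)
    }
  }
  n <- length(frames)
  out <- ref
  out$counts <- Reduce(`+`, lapply(frames, `[[`, "counts")) / n
  out$flat <- Reduce(`+`, lapply(frames, `[[`, "flat")) / n
  out$n_frames <- sum(vapply(frames, `[[`, integer(1), "n_frames"))
  out
}
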