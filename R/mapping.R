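# Elemental mapping: band absorbances from filter-pair image subtraction,
# the final elemental distribution map, and its quality metrics.

#' Flux-weighted centre of a pair's passband
#'
#' Mean energy of the in-band difference flux `S(E) (T_high - T_low)`, the
#' effective energy the subtracted image probes.
#'
#' @param spectrum An [xr_spectrum].
#' @param pair A [ross_pair()].
#' @return Energy in keV.
#' @export
band_centre <- function(spectrum, pair) {
  stopifnot(inherits(spectrum, "xr_spectrum"), inherits(pair, "ross_pair"))
  E <- spectrum$energy
  inband <- E >= pair$E_lo & E <= pair$E_hi
  w <- spectrum$counts[inband] *
    (transmission_curve(pair$high, E[inband]) -
       transmission_curve(pair$low, E[inband]))
  if (sum(w) <= 0) stop("no in-band difference flux", call. = FALSE)
  sum(E[inband] * w) / sum(w)
}

#' Matrix-cancellation weight for combining the two band absorbances
#'
#' Weight `w = (Ebar_minus / Ebar_plus)^exponent` applied to the low-band
#' absorbance before subtraction.  With the photoelectric scaling exponent
#' (3), the contribution of any element whose attenuation varies smoothly
#' as ~E^-3 across both bands cancels from the final map, which is what
#' lets two bands separated by several keV emulate a narrow K-edge
#' subtraction.  `exponent = 0` gives the plain difference.
#'
#' @param spectrum An [xr_spectrum].
#' @param pairs List with `minus` and `plus` [ross_pair()]s.
#' @param exponent Power-law exponent of the attenuation model being
#'   cancelled.
#' @return Scalar weight.
#' @export
map_weight <- function(spectrum, pairs, exponent = 3) {
  (band_centre(spectrum, pairs$minus) / band_centre(spectrum, pairs$plus))^exponent
}

#' Out-of-band flux ratio of a pair
#'
#' Ratio of the two filtered out-of-band fluxes,
#' `c = sum_out S T_high / sum_out S T_low`.  Scaling the low-edge image by
#' `c` before subtraction cancels the residual out-of-band leakage of a
#' slightly mismatched (e.g. stock-foil) pair for any sample, because both
#' filters transmit the same sample spectrum outside the band.
#'
#' @param spectrum An [xr_spectrum].
#' @param pair A [ross_pair()].
#' @param response Detector weighting, as in [simulate_radiograph()].
#' @return Scalar ratio, close to 1 for a well-matched pair.
#' @export
out_of_band_ratio <- function(spectrum, pair,
                              response = c("counting", "energy")) {
  stopifnot(inherits(spectrum, "xr_spectrum"), inherits(pair, "ross_pair"))
  response <- match.arg(response)
  E <- spectrum$energy
  w <- spectrum$counts * switch(response, counting = 1, energy = E)
  out <- w > 0 & (E < pair$E_lo | E > pair$E_hi)
  if (!any(out)) stop("no out-of-band flux", call. = FALSE)
  sum(w[out] * transmission_curve(pair$high, E[out])) /
    sum(w[out] * transmission_curve(pair$low, E[out]))
}

#' Band absorbance from a filter pair's two radiographs
#'
#' Default `"band-intensity"` mode subtracts the two filtered images and
#' takes the logarithm of the normalised difference:
#' `A = -ln((I_high - I_low) / (I0_high - I0_low))`, where `I` are detected
#' counts and `I0` the flats.  Because the pair is balanced outside its
#' passband, the numerator isolates the in-band flux and `A` approximates
#' `mu_band * t`.  Pixels whose intensity difference falls below
#' `clamp_frac` of the mean flat difference are clamped before the log and
#' flagged in the returned mask.  `"log-difference"` mode instead returns
#' the difference of broadband absorbances,
#' `A = ln(T_high) - ln(T_low)` on flat-corrected images.
#'
#' @param rg_high Radiograph taken with the pair's high-K-edge filter (the
#'   one transmitting more inside the band).
#' @param rg_low Radiograph taken with the low-K-edge filter.
#' @param band Band label, `"minus"` or `"plus"`.
#' @param mode `"band-intensity"` (default) or `"log-difference"`.
#' @param clamp_frac Clamp level as a fraction of the mean flat band
#'   intensity.
#' @param rebalance Scalar applied to the low-edge image before
#'   subtraction (see [out_of_band_ratio()]); 1 leaves the raw images as
#'   acquired.  Ignored in `"log-difference"` mode.
#' @return An object of class `band_absorbance` with fields `A`, `band`,
#'   `mask`, `filters`.
#' @export
band_absorbance <- function(rg_high, rg_low, band = c("minus", "plus"),
                            mode = c("band-intensity", "log-difference"),
                            clamp_frac = 1e-6, rebalance = 1) {
  band <- match.arg(band)
  mode <- match.arg(mode)
  if (!all(rg_high$shape == rg_low$shape)) {
    stop("band images have different shapes", call. = FALSE)
  }
  fh <- rg_high$filter; fl <- rg_low$filter
  if (is.null(fh) || is.null(fl) ||
      (fh$element == fl$element && fh$thickness_um == fl$thickness_um)) {
    stop("band absorbance needs two distinct filters", call. = FALSE)
  }
  if (kedge(fh$element) <= kedge(fl$element)) {
    stop("rg_high must use the higher-K-edge filter of the pair", call. = FALSE)
  }
  if (mode == "band-intensity") {
    num <- rg_high$counts - rebalance * rg_low$counts
    den <- rg_high$flat - rebalance * rg_low$flat
    eps <- clamp_frac * mean(den)
    if (eps <= 0) stop("flat band intensity is not positive", call. = FALSE)
    mask <- num < eps | den < eps
    A <- -log(pmax(num, eps) / pmax(den, eps))
  } else {
    Th <- flat_correct(rg_high)
    Tl <- flat_correct(rg_low)
    mask <- Th <= 0 | Tl <= 0
    eps <- clamp_frac
    A <- log(pmax(Th, eps)) - log(pmax(Tl, eps))
  }
  structure(list(A = A, band = band, mask = mask,
                 filters = list(low = fl, high = fh)),
            class = "band_absorbance")
}

#' @export
print.band_absorbance <- function(x, ...) {
  cat(sprintf("<band_absorbance> band %s (%s/%s), %d x %d px, %d clamped\n",
              x$band, x$filters$low$element, x$filters$high$element,
              nrow(x$A), ncol(x$A), sum(x$mask)))
  invisible(x)
}

#' Final elemental distribution map
#'
#' Combines the two band absorbances as `F = A_plus - weight * A_minus`.
#' The sign convention makes the target element - the one whose K-edge lies
#' between the two bands, so its absorbance jumps from the low band to the
#' high band - come out positive.  `weight = 1` is the plain difference;
#' see [map_weight()] for the matrix-cancelling default used by the
#' pipeline.
#'
#' @param A_minus Band absorbance of the low-energy pair (`band ==
#'   "minus"`).
#' @param A_plus Band absorbance of the high-energy pair (`band ==
#'   "plus"`).
#' @param weight Scalar weight on `A_minus`.
#' @return An object of class `elemental_map` with fields `F`, `mask`,
#'   `weight`.
#' @export
elemental_map <- function(A_minus, A_plus, weight = 1) {
  stopifnot(inherits(A_minus, "band_absorbance"),
            inherits(A_plus, "band_absorbance"))
  if (A_minus$band != "minus" || A_plus$band != "plus") {
    stop("band mismatch: expected a 'minus' and a 'plus' absorbance",
         call. = FALSE)
  }
  if (!all(dim(A_minus$A) == dim(A_plus$A))) {
    stop("band absorbances have different shapes", call. = FALSE)
  }
  structure(list(F = A_plus$A - weight * A_minus$A,
                 mask = A_minus$mask | A_plus$mask,
                 weight = weight),
            class = "elemental_map")
}

#' @export
print.elemental_map <- function(x, ...) {
  cat(sprintf("<elemental_map> %d x %d px, weight %.4f, range [%.4g, %.4g]\n",
              nrow(x$F), ncol(x$F), x$weight, min(x$F), max(x$F)))
  invisible(x)
}

#' @export
plot.elemental_map <- function(x, ...) {
  graphics::image(t(x$F[nrow(x$F):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

.roi_values <- function(map, roi) {
  if (inherits(map, "elemental_map")) {
    img <- map$F; mask <- map$mask
  } else {
    img <- map; mask <- NULL
  }
  r <- as.integer(roi)
  if (length(r) != 4 || r[1] < 1 || r[3] < 1 || r[2] > nrow(img) ||
      r[4] > ncol(img)) {
    stop("ROI outside the map", call. = FALSE)
  }
  vals <- as.numeric(img[r[1]:r[2], r[3]:r[4]])
  if (!is.null(mask)) vals <- vals[!as.logical(mask[r[1]:r[2], r[3]:r[4]])]
  if (length(vals) == 0) stop("ROI is empty (all pixels clamped)", call. = FALSE)
  vals
}

.check_disjoint <- function(a, b) {
  overlap <- max(a[1], b[1]) <= min(a[2], b[2]) &&
    max(a[3], b[3]) <= min(a[4], b[4])
  if (overlap) stop("ROIs must be disjoint", call. = FALSE)
}

#' Signal-to-noise ratio between two regions
#'
#' `SNR = |mean(signal) - mean(background)| / sqrt(var(signal) +
#' var(background))`, variances taken over the ROI pixels.
#'
#' @param map An `elemental_map` (clamped pixels are excluded) or plain
#'   matrix.
#' @param signal_roi,background_roi Disjoint [roi_rect()]s.
#' @return Dimensionless SNR.
#' @export
snr <- function(map, signal_roi, background_roi) {
  .check_disjoint(signal_roi, background_roi)
  s <- .roi_values(map, signal_roi)
  b <- .roi_values(map, background_roi)
  abs(mean(s) - mean(b)) / sqrt(stats::var(s) + stats::var(b))
}

#' Residue error of the smooth element
#'
#' `eps_res = 100 |mean(residue)| / mean(target)`: the magnitude the
#' non-target foil leaves in the final map, relative to the target signal.
#'
#' @param map An `elemental_map` or matrix.
#' @param residue_roi ROI over the non-target element only.
#' @param rh_roi ROI over the target element only.
#' @return Percentage.
#' @export
eps_res <- function(map, residue_roi, rh_roi) {
  .check_disjoint(residue_roi, rh_roi)
  m_rh <- mean(.roi_values(map, rh_roi))
  if (m_rh == 0) stop("degenerate map: target ROI mean is zero", call. = FALSE)
  100 * abs(mean(.roi_values(map, residue_roi))) / m_rh
}

#' Overlap error of the target signal
#'
#' `eps_over = 100 (mean(target-only) - mean(overlap)) / mean(target-only)`
#' (signed): how much the target element's recovered signal changes where a
#' second element lies on top of it.
#'
#' @param map An `elemental_map` or matrix.
#' @param rh_roi ROI over the target element alone.
#' @param overlap_roi ROI where both elements overlap.
#' @return Signed percentage.
#' @export
eps_over <- function(map, rh_roi, overlap_roi) {
  .check_disjoint(rh_roi, overlap_roi)
  m_rh <- mean(.roi_values(map, rh_roi))
  if (m_rh == 0) stop("degenerate map: target ROI mean is zero", call. = FALSE)
  100 * (m_rh - mean(.roi_values(map, overlap_roi))) / m_rh
}

#' Run the four-filter imaging pipeline on a 2D phantom
#'
#' Simulates the four filtered radiographs (optionally averaging repeated
#' noisy frames), applies the pedestal threshold to the high-band pair's
#' raw images, forms the two band absorbances and the final map.
#'
#' @param phantom A [phantom2d()].
#' @param spectrum An [xr_spectrum].
#' @param pairs List with `minus` and `plus` [ross_pair()]s.
#' @param flat_counts,exposure_scale,response Passed to
#'   [simulate_radiograph()].
#' @param n_frames Frames to average per filter.
#' @param noise_seed Base seed; each filter/frame uses a distinct derived
#'   seed.  `NULL` for noise-free.
#' @param pedestal_fraction 2% by default.
#' @param pedestal_filters Which pair's raw images get the pedestal:
#'   `"plus"` (default), `"minus"`, `"both"` or `"none"`.
#' @param mode Subtraction mode, see [band_absorbance()].
#' @param subtraction `"weighted"` (default) applies [map_weight()];
#'   `"plain"` uses weight 1.
#' @param weight_exponent Exponent for [map_weight()].
#' @param rebalance Cancel residual out-of-band mismatch of stock foils by
#'   scaling each pair's low-edge image with [out_of_band_ratio()]
#'   (default `TRUE`).
#' @return List with `radiographs`, `A_minus`, `A_plus`, `map`, `weight`
#'   and `band_centres`.
#' @export
ross_map_pipeline <- function(phantom, spectrum,
                              pairs = default_filter_pairs(),
                              flat_counts = 1e4, exposure_scale = 1,
                              n_frames = 1, noise_seed = NULL,
                              pedestal_fraction = 0.02,
                              pedestal_filters = c("plus", "minus", "both", "none"),
                              mode = c("band-intensity", "log-difference"),
                              subtraction = c("weighted", "plain"),
                              weight_exponent = 3, rebalance = TRUE,
                              response = "counting") {
  pedestal_filters <- match.arg(pedestal_filters)
  mode <- match.arg(mode)
  subtraction <- match.arg(subtraction)
  filters <- list(minus_low = pairs$minus$low, minus_high = pairs$minus$high,
                  plus_low = pairs$plus$low, plus_high = pairs$plus$high)
  rgs <- vector("list", length(filters))
  names(rgs) <- names(filters)
  for (i in seq_along(filters)) {
    frames <- lapply(seq_len(n_frames), function(j) {
      seed <- if (is.null(noise_seed)) NULL
              else as.integer(noise_seed) + 10000L * i + 100L * (j - 1L)
      simulate_radiograph(phantom, spectrum, filters[[i]],
                          flat_counts = flat_counts,
                          exposure_scale = exposure_scale,
                          noise_seed = seed, response = response)
    })
    rgs[[i]] <- if (n_frames == 1) frames[[1]] else average_frames(frames)
  }
  ped <- function(rg) {
    rg$counts <- pedestal_threshold(rg$counts, pedestal_fraction)
    rg
  }
  if (pedestal_fraction > 0 && pedestal_filters %in% c("plus", "both")) {
    rgs$plus_low <- ped(rgs$plus_low); rgs$plus_high <- ped(rgs$plus_high)
  }
  if (pedestal_fraction > 0 && pedestal_filters %in% c("minus", "both")) {
    rgs$minus_low <- ped(rgs$minus_low); rgs$minus_high <- ped(rgs$minus_high)
  }
  c_minus <- if (isTRUE(rebalance)) {
    out_of_band_ratio(spectrum, pairs$minus, response)
  } else 1
  c_plus <- if (isTRUE(rebalance)) {
    out_of_band_ratio(spectrum, pairs$plus, response)
  } else 1
  A_minus <- band_absorbance(rgs$minus_high, rgs$minus_low, "minus", mode,
                             rebalance = c_minus)
  A_plus <- band_absorbance(rgs$plus_high, rgs$plus_low, "plus", mode,
                            rebalance = c_plus)
  w <- if (subtraction == "weighted") {
    map_weight(spectrum, pairs, weight_exponent)
  } else 1
  centres <- c(minus = band_centre(spectrum, pairs$minus),
               plus = band_centre(spectrum, pairs$plus))
  list(radiographs = rgs, A_minus = A_minus, A_plus = A_plus,
       map = elemental_map(A_minus, A_plus, w), weight = w,
       band_centres = centres)
}

#' Recover foil thickness from the map value
#'
#' For a pure foil of the target element, `F = (mu(E_plus) - w mu(E_minus))
#' t`, so dividing the map by that coefficient estimates the thickness.
#'
#' @param F_value Map value(s) (dimensionless).
#' @param element Target element.
#' @param spectrum,pairs Define the band centres.
#' @param weight The weight used in the map (see [elemental_map()]).
#' @return Thickness estimate(s), micrometres.
#' @export
recover_thickness <- function(F_value, element, spectrum,
                              pairs = default_filter_pairs(), weight = 1) {
  e_minus <- band_centre(spectrum, pairs$minus)
  e_plus <- band_centre(spectrum, pairs$plus)
  coef_cm <- mu(element, e_plus) - weight * mu(element, e_minus)
  F_value / coef_cm * 1e4
}

#' Overlap error as a function of the second element's thickness
#'
#' Runs the noise-free pipeline on a small two-block phantom (target foil
#' alone next to target + overlayer) for each thickness and reports the
#' resulting signed overlap error.
#'
#' @param overlap_element Element layered on top of the target foil.
#' @param thickness_grid_um Thicknesses to evaluate, micrometres.
#' @param spectrum An [xr_spectrum].
#' @param pairs Filter pairs.
#' @param target_element,target_um The foil being mapped (default Rh
#'   12 um).
#' @param shape Phantom size used for the sweep.
#' @param ... Further arguments to [ross_map_pipeline()].
#' @return `data.frame(thickness_um, eps_over)`.
#' @export
eps_over_curve <- function(overlap_element, thickness_grid_um,
                           spectrum, pairs = default_filter_pairs(),
                           target_element = "Rh", target_um = 12,
                           shape = c(32, 32), ...) {
  element_info(overlap_element)
  n <- shape[1]
  rh_roi <- roi_rect(2, n - 1, 2, n %/% 2 - 1)
  ov_roi <- roi_rect(2, n - 1, n %/% 2 + 2, n - 1)
  vals <- vapply(thickness_grid_um, function(t_um) {
    foils <- list(list(element = target_element, thickness_um = target_um,
                       region = c(1, n, 1, n)))
    if (t_um > 0) {
      foils <- c(foils, list(list(element = overlap_element,
                                  thickness_um = t_um,
                                  region = c(1, n, n %/% 2 + 1, n))))
    }
    ph <- make_foil_phantom(shape, 11, foils)
    res <- ross_map_pipeline(ph, spectrum, pairs, noise_seed = NULL, ...)
    eps_over(res$map, rh_roi, ov_roi)
  }, numeric(1))
  data.frame(thickness_um = thickness_grid_um, eps_over = vals)
}
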