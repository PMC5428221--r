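# Parallel-beam CT: polychromatic forward projection of 3D phantoms,
# ramp-filtered back-projection, and per-projection elemental subtraction.

#' Default CT angle set
#'
#' Equiangular projections in 1 degree steps over 0-180 degrees inclusive
#' (181 angles).  The 180 degree projection duplicates 0 degrees in
#' parallel geometry and is dropped during reconstruction.
#'
#' @param step Angular step, degrees.
#' @param n Number of angles.
#' @return Numeric vector of angles, degrees.
#' @export
ct_angles <- function(step = 1, n = 181) seq(0, by = step, length.out = n)

#' Element path lengths of a phantom over a set of projection angles
#'
#' Computes, for every (angle, detector pixel, slice) ray, the areal
#' thickness each element presents to the beam, by rotating the phantom
#' slice-wise (bilinear interpolation) and summing occupancy along rays.
#' The result is filter-independent and can be passed to
#' [forward_project()] to avoid recomputation across the four filters.
#'
#' @param phantom A [phantom3d()].
#' @param angles Projection angles, degrees.
#' @return List with `paths` (named per element, arrays `(n_angles,
#'   n_detector, n_slices)` in um), `angles` and `voxel_um`.
#' @export
radon_paths <- function(phantom, angles = ct_angles()) {
  stopifnot(inherits(phantom, "phantom3d"))
  paths <- lapply(phantom$occupancy, .radon_paths, angles = angles,
                  voxel_um = phantom$voxel_um)
  list(paths = paths, angles = angles, voxel_um = phantom$voxel_um)
}

# Single-element worker for radon_paths().
# occupancy: array (nz, ny, nx).  Returns array (n_angles, nx, nz) in um.
.radon_paths <- function(occupancy, angles, voxel_um) {
  d <- dim(occupancy)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  stack <- matrix(aperm(occupancy, c(2, 3, 1)), ny * nx, nz)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  xg <- rep(seq_len(nx) - 1, each = ny) - cx
  yg <- rep(seq_len(ny) - 1, times = nx) - cy
  out <- array(0, c(length(angles), nx, nz))
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    xs <- cos(th) * xg - sin(th) * yg + cx
    ys <- sin(th) * xg + cos(th) * yg + cy
    g <- bilinear_gather(stack, xs, ys, ny, nx)
    dim(g) <- c(ny, nx, nz)
    out[i, , ] <- colSums(g)  # integrate along y (the ray direction)
  }
  out * voxel_um
}

#' Forward-project a 3D phantom through a filter
#'
#' For every slice and angle, element path lengths are computed by rotating
#' the phantom (bilinear interpolation) and summing occupancy along rays;
#' detected intensities then follow the polychromatic Beer-Lambert model of
#' [simulate_radiograph()].  Poisson noise is applied iff `noise_seed` is
#' given; the flat field is the uniform noise-free beam intensity.
#'
#' @param phantom A [phantom3d()].
#' @param angles Projection angles in degrees, within `[0, 360)`.
#' @param spectrum An [xr_spectrum].
#' @param filter A [filter_spec()] or `NULL`.
#' @param flat_counts,exposure_scale,response As in
#'   [simulate_radiograph()].
#' @param noise_seed Integer seed or `NULL`.
#' @param paths Optional precomputed [radon_paths()] for this phantom and
#'   angle set.
#' @return An object of class `ct_sinogram`: `counts` array `(n_angles,
#'   n_detector, n_slices)`, scalar `flat`, `angles`, `pixel_um`,
#'   `filter`.
#' @export
forward_project <- function(phantom, angles = ct_angles(), spectrum,
                            filter = NULL, flat_counts = 1e4,
                            exposure_scale = 1, noise_seed = NULL,
                            response = "counting", paths = NULL) {
  stopifnot(inherits(phantom, "phantom3d"), inherits(spectrum, "xr_spectrum"))
  if (any(angles < 0 | angles >= 360)) {
    stop("projection angles must lie in [0, 360) degrees", call. = FALSE)
  }
  if (any(diff(angles) <= 0)) {
    stop("projection angles must be strictly increasing", call. = FALSE)
  }
  w <- .detector_weights(spectrum, filter, response)
  if (sum(w) <= 0) stop("filtered spectrum has no flux", call. = FALSE)
  # naked-beam exposure calibration, as in simulate_radiograph()
  w <- w * flat_counts * exposure_scale /
    sum(.detector_weights(spectrum, NULL, response))
  elements <- names(phantom$occupancy)
  nray <- length(angles) * phantom$shape[3] * phantom$shape[1]
  if (is.null(paths)) paths <- radon_paths(phantom, angles)
  if (!isTRUE(all.equal(paths$angles, angles))) {
    stop("precomputed paths were built for different angles", call. = FALSE)
  }
  thick <- vapply(elements, function(el) as.numeric(paths$paths[[el]]),
                  numeric(nray))
  keep <- w > 0
  mu_mat <- matrix(0, sum(keep), length(elements))
  for (j in seq_along(elements)) {
    mu_mat[, j] <- mu(elements[j], spectrum$energy[keep])
  }
  counts <- beer_lambert_counts(thick * 1e-4, mu_mat, w[keep])  # um -> cm
  if (!is.null(noise_seed)) {
    set.seed(as.integer(noise_seed))
    counts <- as.numeric(stats::rpois(length(counts), counts))
  }
  structure(list(counts = array(counts, c(length(angles), phantom$shape[3],
                                          phantom$shape[1])),
                 flat = sum(w), angles = angles, pixel_um = phantom$voxel_um,
                 filter = filter),
            class = "ct_sinogram")
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf("<ct_sinogram> %d angles x %d detector px x %d slices, filter %s\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              if (is.null(x$filter)) "none"
              else sprintf("%s %.1f um", x$filter$element, x$filter$thickness_um)))
  invisible(x)
}

#' Absorbance of an intensity sinogram
#'
#' @param sino A `ct_sinogram`.
#' @return Array of `-ln(counts/flat)` with the sinogram's geometry
#'   attributes (`angles`, `pixel_um`) attached.
#' @export
sinogram_absorbance <- function(sino) {
  stopifnot(inherits(sino, "ct_sinogram"))
  A <- -log(pmax(sino$counts, 1e-12) / sino$flat)
  attr(A, "angles") <- sino$angles
  attr(A, "pixel_um") <- sino$pixel_um
  A
}

#' Band-absorbance sinogram from a filter pair
#'
#' The sinogram analogue of [band_absorbance()] (band-intensity mode):
#' `A = -ln((I_high - I_low) / (flat_high - flat_low))` per ray.
#'
#' @param sino_high,sino_low `ct_sinogram`s taken with the pair's high- and
#'   low-K-edge filters under identical geometry.
#' @param clamp_frac Clamp level as a fraction of the flat band intensity.
#' @param rebalance Scalar scaling of the low-edge sinogram, see
#'   [out_of_band_ratio()].
#' @return Absorbance array `(n_angles, n_detector, n_slices)` with
#'   geometry attributes and a `"mask"` attribute marking clamped rays.
#' @export
band_absorbance_sinogram <- function(sino_high, sino_low, clamp_frac = 1e-6,
                                     rebalance = 1) {
  stopifnot(inherits(sino_high, "ct_sinogram"), inherits(sino_low, "ct_sinogram"))
  if (!all(dim(sino_high$counts) == dim(sino_low$counts)) ||
      !isTRUE(all.equal(sino_high$angles, sino_low$angles))) {
    stop("sinogram geometries differ", call. = FALSE)
  }
  den <- sino_high$flat - rebalance * sino_low$flat
  if (den <= 0) stop("flat band intensity is not positive", call. = FALSE)
  num <- sino_high$counts - rebalance * sino_low$counts
  eps <- clamp_frac * den
  A <- -log(pmax(num, eps) / den)
  attr(A, "angles") <- sino_high$angles
  attr(A, "pixel_um") <- sino_high$pixel_um
  attr(A, "mask") <- num < eps
  A
}

.ramp_filter <- function(np, window = c("ram-lak", "hann")) {
  window <- match.arg(window)
  # frequency response of the band-limited spatial-domain ramp
  # (h[0] = 1/4, h[n odd] = -1/(pi n)^2, h[n even] = 0), which avoids the
  # DC bias of sampling |nu| directly
  n <- c(0:(np / 2), (-np / 2 + 1):-1)
  h <- numeric(np)
  h[1] <- 0.25
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd])^2
  H <- Re(stats::fft(h))
  if (window == "hann") {
    nu <- n / np
    H <- H * 0.5 * (1 + cos(2 * pi * nu))
  }
  H
}

#' Filtered back-projection reconstruction
#'
#' Standard parallel-beam FBP: each projection is ramp-filtered in the
#' frequency domain (Ram-Lak by default, optional Hann apodisation) and
#' back-projected with linear interpolation.  Input absorbances are
#' dimensionless per ray; the output is divided by the detector pixel size
#' so that reconstructed values are linear attenuation in 1/cm.
#'
#' @param absorbance Array `(n_angles, n_detector)` or `(n_angles,
#'   n_detector, n_slices)`, e.g. from [sinogram_absorbance()] or
#'   [band_absorbance_sinogram()].
#' @param angles Projection angles, degrees; defaults to the array's
#'   `"angles"` attribute.  Angles >= 180 are dropped as duplicates.
#' @param pixel_um Detector pixel size; defaults to the `"pixel_um"`
#'   attribute.
#' @param window Ramp filter window.
#' @return Reconstructed slice (matrix `n_det x n_det`) or volume
#'   (`n_det x n_det x n_slices`), units 1/cm.
#' @export
fbp <- function(absorbance, angles = NULL, pixel_um = NULL,
                window = c("ram-lak", "hann")) {
  window <- match.arg(window)
  if (is.null(angles)) angles <- attr(absorbance, "angles")
  if (is.null(pixel_um)) pixel_um <- attr(absorbance, "pixel_um")
  if (is.null(angles) || is.null(pixel_um)) {
    stop("angles and pixel_um must be supplied (or attached as attributes)",
         call. = FALSE)
  }
  d <- dim(absorbance)
  if (length(d) == 2) {
    dim(absorbance) <- c(d, 1L)
    d <- dim(absorbance)
  }
  keep <- angles < 180
  angles_use <- angles[keep]
  if (length(angles_use) < 3) {
    stop("reconstruction needs at least 3 angles below 180 degrees",
         call. = FALSE)
  }
  na <- length(angles_use); ndet <- d[2]; nz <- d[3]
  np <- 2^ceiling(log2(2 * ndet))
  H <- .ramp_filter(np, window)
  c_det <- (ndet - 1) / 2
  xg <- rep(seq_len(ndet) - 1, each = ndet) - c_det   # x = col
  yg <- rep(seq_len(ndet) - 1, times = ndet) - c_det  # y = row (fastest)
  accum <- matrix(0, ndet * ndet, nz)
  ai <- which(keep)
  for (k in seq_len(na)) {
    p <- matrix(0, np, nz)
    p[seq_len(ndet), ] <- absorbance[ai[k], , ]
    q <- Re(stats::mvfft(stats::mvfft(p) * H, inverse = TRUE)) / np
    th <- angles_use[k] * pi / 180
    svals <- cos(th) * xg + sin(th) * yg + c_det
    backproject_accum(accum, q[seq_len(ndet), , drop = FALSE], svals)
  }
  out <- accum * pi / na / (pixel_um * 1e-4)
  dim(out) <- c(ndet, ndet, nz)
  if (nz == 1) out[, , 1] else out
}

#' Elemental CT: subtract per projection, then reconstruct
#'
#' Runs the band subtraction on each of the 181 (or however many)
#' projection angles of the four filtered sinogram stacks, reconstructs the
#' final-map sinograms slice by slice with [fbp()], and stacks the slices
#' into the elemental volume.
#'
#' @param sinos List with components `minus_low`, `minus_high`, `plus_low`,
#'   `plus_high` (`ct_sinogram`s with consistent geometry).
#' @param spectrum,pairs Used to compute the matrix-cancellation weight.
#' @param subtraction `"weighted"` (default) or `"plain"`.
#' @param weight_exponent Exponent for [map_weight()].
#' @param rebalance Apply [out_of_band_ratio()] rebalancing per pair
#'   (default `TRUE`).
#' @param window Ramp filter window.
#' @param keep_bands Also return the reconstructed band volumes?
#' @return List with `volume` (`n_det x n_det x n_slices`, 1/cm), `weight`,
#'   and if requested `band_minus` / `band_plus` volumes.
#' @export
elemental_ct <- function(sinos, spectrum, pairs = default_filter_pairs(),
                         subtraction = c("weighted", "plain"),
                         weight_exponent = 3, rebalance = TRUE,
                         window = "ram-lak", keep_bands = FALSE) {
  subtraction <- match.arg(subtraction)
  need <- c("minus_low", "minus_high", "plus_low", "plus_high")
  if (!all(need %in% names(sinos))) {
    stop("sinos must contain minus_low, minus_high, plus_low, plus_high",
         call. = FALSE)
  }
  dims <- lapply(sinos[need], function(s) dim(s$counts))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("sinogram geometries are inconsistent", call. = FALSE)
  }
  c_minus <- if (isTRUE(rebalance)) out_of_band_ratio(spectrum, pairs$minus) else 1
  c_plus <- if (isTRUE(rebalance)) out_of_band_ratio(spectrum, pairs$plus) else 1
  A_minus <- band_absorbance_sinogram(sinos$minus_high, sinos$minus_low,
                                      rebalance = c_minus)
  A_plus <- band_absorbance_sinogram(sinos$plus_high, sinos$plus_low,
                                     rebalance = c_plus)
  w <- if (subtraction == "weighted") {
    map_weight(spectrum, pairs, weight_exponent)
  } else 1
  Fsino <- A_plus - w * A_minus
  attr(Fsino, "angles") <- attr(A_plus, "angles")
  attr(Fsino, "pixel_um") <- attr(A_plus, "pixel_um")
  out <- list(volume = fbp(Fsino, window = window), weight = w)
  if (keep_bands) {
    out$band_minus <- fbp(A_minus, window = window)
    out$band_plus <- fbp(A_plus, window = window)
  }
  out
}
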