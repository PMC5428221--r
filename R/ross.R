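# Balanced (Ross) filter pair design: passband from adjacent K-edges,
# thickness matching so out-of-band transmission is equalised, band flux.

#' Passband of a Ross filter pair
#'
#' The pass band of a pair of adjacent-Z filters runs from the lower
#' K-edge to the higher one.
#'
#' @param element_low,element_high Element symbols of the two foils (in any
#'   order).
#' @return List with `E_lo`, `E_hi` and `bandwidth`, all in keV.
#' @export
passband <- function(element_low, element_high) {
  k1 <- kedge(element_low)
  k2 <- kedge(element_high)
  if (identical(element_low, element_high) || k1 == k2) {
    stop("degenerate Ross pair: identical elements or equal K-edges",
         call. = FALSE)
  }
  list(E_lo = min(k1, k2), E_hi = max(k1, k2), bandwidth = abs(k2 - k1))
}

#' Construct a Ross filter pair
#'
#' The two foils are ordered so that `low` is the smaller-K-edge element;
#' the derived passband spans the two K-edges.
#'
#' @param filter_a,filter_b Two [filter_spec()] objects with distinct
#'   K-edges.
#' @return An object of class `ross_pair` with fields `low`, `high`,
#'   `E_lo`, `E_hi`, `bandwidth`.
#' @export
ross_pair <- function(filter_a, filter_b) {
  stopifnot(inherits(filter_a, "xr_filter"), inherits(filter_b, "xr_filter"))
  band <- passband(filter_a$element, filter_b$element)
  if (kedge(filter_a$element) > kedge(filter_b$element)) {
    tmp <- filter_a; filter_a <- filter_b; filter_b <- tmp
  }
  structure(list(low = filter_a, high = filter_b, E_lo = band$E_lo,
                 E_hi = band$E_hi, bandwidth = band$bandwidth),
            class = "ross_pair")
}

#' @export
print.ross_pair <- function(x, ...) {
  cat(sprintf("<ross_pair> %s %.1f um / %s %.1f um, passband [%.3f, %.3f] keV (%.3f keV)\n",
              x$low$element, x$low$thickness_um, x$high$element,
              x$high$thickness_um, x$E_lo, x$E_hi, x$bandwidth))
  invisible(x)
}

# Out-of-band bin mask for a pair on a spectrum grid: every bin inside the
# spectrum's support excluding the passband.
.out_of_band <- function(spectrum, E_lo, E_hi) {
  spectrum$counts > 0 & (spectrum$energy < E_lo | spectrum$energy > E_hi)
}

#' Match the partner thickness of a Ross pair
#'
#' Finds the partner foil thickness minimising the spectrum-weighted squared
#' difference of the two transmission curves over all bins outside the
#' passband, i.e. making the two filtered spectra essentially equal except
#' between the two K-edges.  Deterministic bounded (Brent) scalar search.
#'
#' @param fixed A [filter_spec()] for the foil held fixed.
#' @param partner_element Element symbol of the foil to be matched.
#' @param spectrum An [xr_spectrum] providing the weights.
#' @param bounds Search interval for the thickness, micrometres.
#' @param tol Optimiser tolerance, micrometres.
#' @return Matched thickness in micrometres, reported to 0.1 um.
#' @export
match_thickness <- function(fixed, partner_element, spectrum,
                            bounds = c(0.1, 500), tol = 0.01) {
  stopifnot(inherits(fixed, "xr_filter"), inherits(spectrum, "xr_spectrum"))
  band <- passband(fixed$element, partner_element)
  out <- .out_of_band(spectrum, band$E_lo, band$E_hi)
  if (!any(out)) stop("no out-of-band bins with flux", call. = FALSE)
  E <- spectrum$energy[out]
  w <- spectrum$counts[out]
  T1 <- transmission_curve(fixed, E)
  mu2 <- mu(partner_element, E)
  obj <- function(t_um) sum(w * (T1 - exp(-mu2 * t_um * 1e-4))^2)
  opt <- stats::optimize(obj, interval = bounds, tol = tol)
  t_hat <- opt$minimum
  if (t_hat <= bounds[1] + 10 * tol || t_hat >= bounds[2] - 10 * tol) {
    stop("thickness matching failed: optimum at the search bound",
         call. = FALSE)
  }
  round(t_hat, 1)
}

#' Out-of-band balance residual of a pair
#'
#' Spectrum-weighted root-mean-square relative difference of the two
#' filtered spectra over bins outside the passband.  Zero for identical
#' foils; small (well under 0.05) for a properly matched pair.
#'
#' @param pair A [ross_pair()].
#' @param spectrum An [xr_spectrum].
#' @return Dimensionless mismatch.
#' @export
balance_residual <- function(pair, spectrum) {
  stopifnot(inherits(pair, "ross_pair"), inherits(spectrum, "xr_spectrum"))
  out <- .out_of_band(spectrum, pair$E_lo, pair$E_hi)
  E <- spectrum$energy[out]
  w <- spectrum$counts[out]
  T1 <- transmission_curve(pair$low, E)
  T2 <- transmission_curve(pair$high, E)
  rel <- 2 * (T1 - T2) / (T1 + T2)
  sqrt(sum(w * rel^2) / sum(w))
}

#' Photon flux inside the passband
#'
#' Trapezoidal integral of the source spectral density over the passband
#' `[E_lo, E_hi]`, with partial-bin weighting at the band edges.  This is
#' the number of photons a perfectly subtracted pair isolates.
#'
#' @param spectrum An [xr_spectrum]; counts per bin are converted to a
#'   density (counts/keV) using the bin width.
#' @param pair A [ross_pair()] (or any list with `E_lo`, `E_hi`).
#' @return Photon count inside the band.
#' @export
band_flux <- function(spectrum, pair) {
  stopifnot(inherits(spectrum, "xr_spectrum"))
  E_lo <- pair$E_lo; E_hi <- pair$E_hi
  half <- spectrum$bin_width / 2
  grid_lo <- spectrum$energy[1] - half
  grid_hi <- spectrum$energy[length(spectrum$energy)] + half
  if (E_lo < grid_lo || E_hi > grid_hi) {
    stop("passband outside the spectrum grid", call. = FALSE)
  }
  lo_edges <- spectrum$energy - half
  hi_edges <- spectrum$energy + half
  overlap <- pmax(0, pmin(hi_edges, E_hi) - pmax(lo_edges, E_lo))
  sum(spectrum$counts / spectrum$bin_width * overlap)
}

#' Default Ross pairs for rhodium mapping
#'
#' Nb 30 / Mo 24 um isolating the 18.99-20.00 keV band below the Rh edge,
#' and Pd 25 / Ag 27 um isolating 24.35-25.52 keV above it.
#'
#' @return List with components `minus` and `plus`, each a [ross_pair()].
#' @export
default_filter_pairs <- function() {
  list(minus = ross_pair(filter_spec("Nb", 30), filter_spec("Mo", 24)),
       plus  = ross_pair(filter_spec("Pd", 25), filter_spec("Ag", 27)))
}
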