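# Metal foil filters and their transmission applied to spectra.

#' Specify a metal foil filter
#'
#' @param element Element symbol; must exist in the attenuation database.
#' @param thickness_um Foil thickness in micrometres, > 0.
#' @return An object of class `xr_filter`.
#' @export
filter_spec <- function(element, thickness_um) {
  element_info(element)  # errors for unknown elements
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 ||
      !is.finite(thickness_um) || thickness_um <= 0) {
    stop("thickness_um must be a single positive number", call. = FALSE)
  }
  structure(list(element = element, thickness_um = as.numeric(thickness_um)),
            class = "xr_filter")
}

#' @export
print.xr_filter <- function(x, ...) {
  cat(sprintf("<xr_filter> %s %.1f um (K-edge %.3f keV)\n",
              x$element, x$thickness_um, kedge(x$element)))
  invisible(x)
}

#' Filter transmission curve
#'
#' Beer-Lambert transmission `exp(-mu(E) * t)` of a foil, with the
#' micrometre thickness converted internally to cm.
#'
#' @param filter An [filter_spec()] object.
#' @param energy_keV Energies at which to evaluate, keV.
#' @return Transmission values in (0, 1].
#' @export
transmission_curve <- function(filter, energy_keV) {
  stopifnot(inherits(filter, "xr_filter"))
  exp(-mu(filter$element, energy_keV) * filter$thickness_um * 1e-4)
}

#' Apply a filter to a spectrum
#'
#' Per-bin counts are multiplied by the foil's Beer-Lambert transmission;
#' the energy grid is unchanged.
#'
#' @param filter An [filter_spec()] object.
#' @param spectrum An [xr_spectrum].
#' @return The filtered [xr_spectrum].
#' @export
filter_transmission <- function(filter, spectrum) {
  stopifnot(inherits(spectrum, "xr_spectrum"))
  xr_spectrum(spectrum$energy,
              spectrum$counts * transmission_curve(filter, spectrum$energy))
}
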