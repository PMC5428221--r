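# Polychromatic source spectra: binned photon fluence on a uniform keV grid.

#' Construct a binned photon spectrum
#'
#' @param energy Strictly increasing, uniformly spaced bin centres, keV.
#' @param counts Non-negative photon counts per bin.
#' @return An object of class `xr_spectrum` with fields `energy`, `counts`
#'   and `bin_width` (keV).
#' @export
xr_spectrum <- function(energy, counts) {
  if (length(energy) < 2 || length(energy) != length(counts)) {
    stop("energy and counts must be equal-length vectors (>= 2 bins)", call. = FALSE)
  }
  dE <- diff(energy)
  if (any(dE <= 0) || diff(range(dE)) > 1e-8 * mean(dE)) {
    stop("energy bin centres must be strictly increasing and uniform", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  structure(list(energy = as.numeric(energy), counts = as.numeric(counts),
                 bin_width = mean(dE)),
            class = "xr_spectrum")
}

#' Default energy grid
#'
#' Bin centres from 5 to 60 keV in 0.05 keV steps: fine enough to resolve a
#' 1 keV Ross passband with more than 20 bins.
#'
#' @param bin_width Bin width in keV.
#' @param emin,emax Grid limits in keV.
#' @return Numeric vector of bin centres.
#' @export
default_energy_grid <- function(bin_width = 0.05, emin = 5, emax = 60) {
  seq(emin, emax, by = bin_width)
}

#' Simulate a tungsten-anode tube spectrum
#'
#' Kramers-form bremsstrahlung continuum, `S(E) ~ (kVp - E)/E`, zero above
#' the tube voltage and below a detector-induced low-energy cut-off, with
#' optional tungsten L fluorescence lines superposed as Gaussian peaks.
#'
#' @param tube_kVp Tube voltage (spectrum end point), keV.
#' @param bin_width_keV Energy bin width, keV.
#' @param low_cutoff_keV Low-energy cut-off, keV (counts are zero below it).
#' @param exposure_scale Linear scale factor on all counts.
#' @param l_lines Include tungsten L lines (8.40 and 9.67 keV)?
#' @param l_line_frac Areas of the two L lines as fractions of the continuum
#'   total.
#' @param emin,emax Extent of the energy grid, keV.
#' @return An [xr_spectrum].
#' @export
simulate_spectrum <- function(tube_kVp = 40, bin_width_keV = 0.05,
                              low_cutoff_keV = 8, exposure_scale = 1,
                              l_lines = TRUE, l_line_frac = c(0.10, 0.06),
                              emin = 5, emax = 60) {
  if (!is.numeric(tube_kVp) || tube_kVp <= 0 || !is.numeric(bin_width_keV) ||
      bin_width_keV <= 0) {
    stop("tube_kVp and bin_width_keV must be positive", call. = FALSE)
  }
  if (low_cutoff_keV <= 0 || low_cutoff_keV >= tube_kVp) {
    stop("low_cutoff_keV must lie in (0, tube_kVp)", call. = FALSE)
  }
  E <- default_energy_grid(bin_width_keV, emin, emax)
  inside <- E >= low_cutoff_keV & E < tube_kVp
  S <- ifelse(inside, pmax(tube_kVp - E, 0) / E, 0)
  if (l_lines) {
    centres <- c(8.40, 9.67)
    sigma <- 0.15
    area <- sum(S)
    for (i in seq_along(centres)) {
      line <- exp(-0.5 * ((E - centres[i]) / sigma)^2)
      line <- line / sum(line) * area * l_line_frac[i]
      S <- S + ifelse(inside, line, 0)
    }
  }
  xr_spectrum(E, S * exposure_scale)
}

#' Load a measured spectrum from CSV
#'
#' Reads a two-column CSV (`energy_keV,counts`) and rebins it onto the
#' uniform internal grid.  Each input row's counts are assigned to the
#' covering output bin, which conserves total counts exactly.
#'
#' @param path CSV file path.
#' @param bin_width Output bin width, keV.
#' @param emin,emax Output grid limits, keV.
#' @return An [xr_spectrum].
#' @export
load_spectrum <- function(path, bin_width = 0.05, emin = 5, emax = 60) {
  tab <- utils::read.csv(path)
  if (!all(c("energy_keV", "counts") %in% names(tab))) {
    stop("spectrum CSV must have columns 'energy_keV,counts'", call. = FALSE)
  }
  E_in <- tab$energy_keV
  c_in <- tab$counts
  if (any(diff(E_in) <= 0)) {
    stop("spectrum CSV energies must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(c_in)) || any(c_in < 0)) {
    stop("spectrum CSV counts must be finite and non-negative", call. = FALSE)
  }
  E <- default_energy_grid(bin_width, emin, emax)
  half <- bin_width / 2
  if (any(E_in < emin - half) || any(E_in > emax + half)) {
    stop(sprintf("spectrum energies outside the [%g, %g] keV grid", emin, emax),
         call. = FALSE)
  }
  idx <- pmin(pmax(round((E_in - emin) / bin_width) + 1L, 1L), length(E))
  counts <- numeric(length(E))
  agg <- tapply(c_in, idx, sum)
  counts[as.integer(names(agg))] <- agg
  xr_spectrum(E, counts)
}

#' Write a spectrum to CSV
#'
#' @param spectrum An [xr_spectrum].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xr_spectrum"))
  utils::write.csv(data.frame(energy_keV = spectrum$energy,
                              counts = spectrum$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total photon fluence of a spectrum
#'
#' @param spectrum An [xr_spectrum].
#' @return Sum of per-bin counts.
#' @export
total_fluence <- function(spectrum) sum(spectrum$counts)

#' @export
print.xr_spectrum <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<xr_spectrum> %d bins of %.3g keV over [%.4g, %.4g] keV\n",
              length(x$energy), x$bin_width, min(x$energy), max(x$energy)))
  if (length(nz)) {
    cat(sprintf("  support [%.4g, %.4g] keV, total fluence %.4g\n",
                x$energy[min(nz)], x$energy[max(nz)], sum(x$counts)))
  } else {
    cat("  empty spectrum\n")
  }
  invisible(x)
}

#' @export
plot.xr_spectrum <- function(x, ...) {
  graphics::plot(x$energy, x$counts, type = "l", xlab = "energy (keV)",
                 ylab = "counts / bin", ...)
  invisible(x)
}
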