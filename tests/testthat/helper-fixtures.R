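# Shared fixtures: built once per test run.

spec40 <- simulate_spectrum()                      # default 40 kVp model
spec40_plain <- simulate_spectrum(l_lines = FALSE) # continuum only

# 1 eV evaluation of the Kramers continuum (independent of the binned path)
kramers_1ev <- function(emin, emax, kvp = 40, cutoff = 8) {
  E <- seq(emin, emax, by = 0.001)
  S <- ifelse(E >= cutoff & E < kvp, (kvp - E) / E, 0)
  list(E = E, S = S)
}

# uniform foil phantom covering the whole (small) image
uniform_foil <- function(elements, thicknesses, n = 4, pixel_um = 11) {
  foils <- Map(function(el, t) list(element = el, thickness_um = t,
                                    region = c(1, n, 1, n)),
               elements, thicknesses)
  make_foil_phantom(c(n, n), pixel_um, unname(foils))
}

# noise-free polychromatic transmission of a stack of foils under a filter,
# by 1 eV quadrature of the same physical integrand
quadrature_transmission <- function(elements, thicknesses_um, filter_el,
                                    filter_um, kvp = 40, cutoff = 8) {
  g <- kramers_1ev(5, 59.999, kvp, cutoff)
  Tf <- exp(-mu(filter_el, g$E) * filter_um * 1e-4)
  Ts <- rep(1, length(g$E))
  for (i in seq_along(elements)) {
    Ts <- Ts * exp(-mu(elements[i], g$E) * thicknesses_um[i] * 1e-4)
  }
  sum(g$S * Tf * Ts) / sum(g$S * Tf)
}
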