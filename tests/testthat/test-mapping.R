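test_that("no sample gives zero band absorbance and a zero map", {
  ph <- make_foil_phantom(c(5, 5), 11, list())
  res <- ross_map_pipeline(ph, spec40)
  expect_equal(max(abs(res$A_minus$A)), 0, tolerance = 1e-12)
  expect_equal(max(abs(res$A_plus$A)), 0, tolerance = 1e-12)
  expect_equal(max(abs(res$map$F)), 0, tolerance = 1e-12)
})

test_that("band absorbance approximates mu * t at the band centre for a pure foil", {
  # computed-matched pairs: the approximation A ~ mu(Ebar) t presumes the
  # out-of-band transmissions are properly balanced
  t_mo <- match_thickness(filter_spec("Nb", 30), "Mo", spec40)
  t_ag <- match_thickness(filter_spec("Pd", 25), "Ag", spec40)
  pairs <- list(minus = ross_pair(filter_spec("Nb", 30), filter_spec("Mo", t_mo)),
                plus = ross_pair(filter_spec("Pd", 25), filter_spec("Ag", t_ag)))
  ph <- uniform_foil("Rh", 12)
  res <- ross_map_pipeline(ph, spec40, pairs = pairs, pedestal_fraction = 0)
  e_minus <- band_centre(spec40, pairs$minus)
  e_plus <- band_centre(spec40, pairs$plus)
  expect_equal(res$A_minus$A[1, 1], mu("Rh", e_minus) * 12e-4, tolerance = 0.1)
  expect_equal(res$A_plus$A[1, 1], mu("Rh", e_plus) * 12e-4, tolerance = 0.1)
})

test_that("pixels with non-positive band difference are clamped and masked", {
  ph <- make_foil_phantom(c(4, 4), 11, list())
  rg_h <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24))
  rg_l <- simulate_radiograph(ph, spec40, filter_spec("Nb", 30))
  rg_h$counts[2, 2] <- 0   # force T_high < T_low at one pixel
  A <- band_absorbance(rg_h, rg_l, "minus")
  expect_true(A$mask[2, 2])
  expect_true(all(!A$mask[-2, -2]))
  expect_true(all(is.finite(A$A)))

  expect_error(band_absorbance(rg_l, rg_l, "minus"), "distinct")
  expect_error(band_absorbance(rg_l, rg_h, "minus"), "higher-K-edge")
})

test_that("the map isolates the K-edge element with the documented sign", {
  rh <- uniform_foil("Rh", 12, n = 6)
  ni <- uniform_foil("Ni", 18, n = 6)
  F_rh <- ross_map_pipeline(rh, spec40)$map$F
  F_ni <- ross_map_pipeline(ni, spec40)$map$F
  expect_gt(min(F_rh), 0)                       # target element positive
  expect_gt(mean(F_rh) / max(abs(F_ni)), 5)     # Rh dominates Ni
  expect_lt(max(abs(F_ni)), 0.1 * max(F_rh))    # Ni-only map is nearly empty
})

test_that("identical bands subtract to an identically zero map", {
  ph <- uniform_foil("Rh", 12)
  rgs <- ross_map_pipeline(ph, spec40)$radiographs
  A1 <- band_absorbance(rgs$minus_high, rgs$minus_low, "minus")
  A2 <- band_absorbance(rgs$minus_high, rgs$minus_low, "plus")
  expect_equal(elemental_map(A1, A2, weight = 1)$F, 0 * A1$A)
  # band labels are enforced
  expect_error(elemental_map(A2, A1), "band mismatch")
})

test_that("quality metrics match their closed forms", {
  set.seed(5)
  m <- matrix(rnorm(200 * 200), 200, 200)
  m[1:100, 1:100] <- m[1:100, 1:100] + 10
  s_roi <- roi_rect(1, 100, 1, 100)
  b_roi <- roi_rect(101, 200, 101, 200)
  expect_equal(snr(m, s_roi, b_roi), 10 / sqrt(2), tolerance = 0.02)

  # two ROIs from the same distribution: SNR ~ 0
  null_snr <- snr(m, roi_rect(101, 200, 1, 100), b_roi)
  expect_lt(null_snr, 0.2)

  flat2 <- matrix(1, 50, 50); flat2[1:10, 1:10] <- 0.02
  expect_equal(eps_res(flat2, roi_rect(1, 10, 1, 10), roi_rect(20, 40, 20, 40)),
               2)
  expect_equal(eps_over(flat2, roi_rect(20, 40, 20, 40), roi_rect(45, 50, 45, 50)),
               0)
  expect_error(snr(m, s_roi, roi_rect(50, 150, 50, 150)), "disjoint")
  expect_error(eps_res(matrix(0, 4, 4), roi_rect(1, 2, 1, 2),
                       roi_rect(3, 4, 3, 4)), "degenerate")
  expect_error(snr(m, roi_rect(1, 300, 1, 10), b_roi), "outside")
})

test_that("noise-free overlap and residue errors are small on the foil fixture", {
  fx <- foil_fixture(shape = c(96, 96))
  res <- ross_map_pipeline(fx$phantom, spec40)
  expect_lt(abs(eps_over(res$map, fx$rois$rh, fx$rois$overlap)), 3)
  expect_lt(eps_res(res$map, fx$rois$residue, fx$rois$rh), 10)
})

test_that("overlap-error curves separate edge-adjacent from smooth elements", {
  th <- c(0, 10, 18, 30)
  zr <- eps_over_curve("Zr", th, spec40)
  ni <- eps_over_curve("Ni", th, spec40)
  sn <- eps_over_curve("Sn", th, spec40)
  expect_equal(zr$eps_over[1], 0)
  # Zr's K-edge sits against the filter edges: strong, monotone effect
  expect_true(all(diff(abs(zr$eps_over)) > 0))
  # smooth absorbers nearly cancel
  expect_lt(max(abs(ni$eps_over)), 5)
  expect_lt(max(abs(sn$eps_over)), 5)
  expect_gt(abs(zr$eps_over[3]), abs(ni$eps_over[3]))
  expect_gt(abs(zr$eps_over[3]), abs(sn$eps_over[3]))
})

test_that("the map is linear in foil thickness and recovers it", {
  ratios <- vapply(c(4, 12, 20), function(t) {
    ph <- uniform_foil("Rh", t)
    mean(ross_map_pipeline(ph, spec40)$map$F) / t
  }, numeric(1))
  expect_lt(max(abs(ratios / ratios[2] - 1)), 0.05)

  ph <- uniform_foil("Rh", 12)
  res <- ross_map_pipeline(ph, spec40)
  t_hat <- recover_thickness(mean(res$map$F), "Rh", spec40,
                             weight = res$weight)
  expect_lt(abs(t_hat - 12) / 12, 0.15)
})
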