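test_that("the default geometry is 181 one-degree steps over the half turn", {
  a <- ct_angles()
  expect_length(a, 181)
  expect_equal(a[1], 0)
  expect_equal(a[181], 180)
  expect_equal(unique(diff(a)), 1)
})

test_that("a zero-degree projection reproduces the 2D forward model", {
  ph <- make_foam_phantom(shape = c(6, 32, 32), voxel_um = 11,
                          porosity = 0.3, seed = 3)
  sino <- forward_project(ph, c(0, 30, 60), spec40, filter_spec("Mo", 24))
  paths <- project_thickness(ph, axis = 2)
  z <- 3
  slab <- phantom2d(c(1, 32), 11,
                    lapply(paths, function(m) matrix(m[z, ], 1, 32)))
  rg <- simulate_radiograph(slab, spec40, filter_spec("Mo", 24))
  expect_equal(sino$counts[1, , z], rg$counts[1, ], tolerance = 0.005)
  expect_equal(sino$flat, rg$flat[1, 1])
})

test_that("ray absorbance of a uniform disk equals mu times the chord", {
  n <- 64
  occ <- array(0, c(1, n, n))
  c0 <- (n + 1) / 2; r0 <- 20
  ss <- seq(-0.375, 0.375, by = 0.25)   # 4x4 partial-volume supersampling
  for (y in 1:n) for (x in 1:n) {
    occ[1, y, x] <- mean(outer((y + ss - c0)^2, (x + ss - c0)^2, "+") <= r0^2)
  }
  ph <- phantom3d(c(1, n, n), 11, list(Al = occ))
  # single-energy beam: one populated bin at 30 keV
  E <- default_energy_grid()
  mono <- xr_spectrum(E, as.numeric(abs(E - 30) < 0.026))
  sino <- forward_project(ph, c(0, 45), mono, NULL)
  A <- sinogram_absorbance(sino)
  det <- seq_len(n) - c0
  chord_cm <- 2 * sqrt(pmax(r0^2 - det^2, 0)) * 11e-4
  oracle <- mu("Al", 30) * chord_cm
  expect_lt(max(abs(A[1, , 1] - oracle)), 0.02 * max(oracle))
})

test_that("geometry preconditions are enforced", {
  ph <- make_foam_phantom(shape = c(4, 16, 16), porosity = 0, seed = 1)
  expect_error(forward_project(ph, c(-5, 0), spec40), "0, 360")
  expect_error(forward_project(ph, c(10, 5), spec40), "increasing")
  sino <- array(0, c(2, 16, 1))
  expect_error(fbp(sino, angles = c(0, 90), pixel_um = 11), "at least 3")
})

test_that("filtered back-projection recovers a disk and is linear", {
  n <- 64; ang <- ct_angles(step = 2, n = 91)
  c0 <- (n - 1) / 2; r0 <- 18; muv <- 3.0; px_cm <- 11e-4
  det <- (0:(n - 1)) - c0
  sino <- array(0, c(length(ang), n, 1))
  chord <- muv * 2 * sqrt(pmax(r0^2 - det^2, 0)) * px_cm
  for (i in seq_along(ang)) sino[i, , 1] <- chord
  rec <- fbp(sino, angles = ang, pixel_um = 11)
  xg <- rep(det, each = n); yg <- rep(det, times = n)
  inside <- matrix(sqrt(xg^2 + yg^2) <= 0.8 * r0, n, n)
  expect_lt(abs(mean(rec[inside]) / muv - 1), 0.03)

  rec_scaled <- fbp(3 * sino, angles = ang, pixel_um = 11)
  expect_equal(rec_scaled, 3 * rec, tolerance = 1e-12)

  # a central impulse back-projects to a point response at the centre
  m <- 65; cm <- (m + 1) / 2
  imp <- array(0, c(length(ang), m, 1)); imp[, cm, 1] <- 1
  rimp <- fbp(imp, angles = ang, pixel_um = 11)
  peak <- which(rimp == max(rimp), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, 1:2]), c(cm, cm))
})

test_that("projection mass is conserved across angles", {
  # the sample must lie inside the inscribed circle of the field of view;
  # absorbance is linear in path length only for a monochromatic beam
  # (beam hardening breaks strict conservation for broad spectra)
  ph <- make_foam_phantom(shape = c(6, 48, 48), porosity = 0.3,
                          cube_frac = 0.55, seed = 5)
  angles <- c(0, 33, 61, 90, 147)
  paths <- radon_paths(ph, angles)
  psums <- apply(paths$paths$Al, 1, sum)
  expect_lt(diff(range(psums)) / mean(psums), 0.01)

  E <- default_energy_grid()
  mono <- xr_spectrum(E, as.numeric(abs(E - 30) < 0.026))
  sino <- forward_project(ph, angles, mono, NULL, paths = paths)
  sums <- apply(sinogram_absorbance(sino), 1, sum)
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("elemental CT isolates the insert and the two subtraction orders agree", {
  pairs <- default_filter_pairs()
  ph <- make_foam_phantom(shape = c(24, 48, 48), porosity = 0.4, seed = 2)
  ang <- ct_angles(step = 6, n = 31)
  paths <- radon_paths(ph, ang)
  filters <- list(minus_low = pairs$minus$low, minus_high = pairs$minus$high,
                  plus_low = pairs$plus$low, plus_high = pairs$plus$high)
  sinos <- lapply(filters, function(f) {
    forward_project(ph, ang, spec40, f, paths = paths)
  })
  rec <- elemental_ct(sinos, spec40, pairs, keep_bands = TRUE)
  vol <- aperm(rec$volume, c(3, 1, 2))   # (y, x, z) -> (z, y, x)
  rh <- ph$occupancy$Rh > 0.5
  al <- attr(ph, "cube_mask") & ph$occupancy$Al > 0.5
  expect_gt(mean(vol[rh]) / mean(abs(vol[al])), 10)

  # subtract-then-reconstruct vs reconstruct-then-subtract
  alt <- rec$band_plus - rec$weight * rec$band_minus
  expect_lt(max(abs(alt - rec$volume)) / max(abs(rec$volume)), 0.01)

  # without the insert the map is nearly empty
  ph0 <- make_foam_phantom(shape = c(24, 48, 48), porosity = 0.4,
                           insert = NULL, seed = 2)
  sinos0 <- lapply(filters, function(f) forward_project(ph0, ang, spec40, f))
  rec0 <- elemental_ct(sinos0, spec40, pairs)
  expect_lt(max(abs(rec0$volume)), 0.1 * mean(vol[rh]))

  expect_error(elemental_ct(sinos[1:3], spec40, pairs), "must contain")
})

test_that("reconstructed contrast degrades monotonically as exposure drops", {
  pairs <- default_filter_pairs()
  ph <- make_foam_phantom(shape = c(12, 40, 40), porosity = 0.4, seed = 2)
  ang <- ct_angles(step = 9, n = 21)
  paths <- radon_paths(ph, ang)
  filters <- list(minus_low = pairs$minus$low, minus_high = pairs$minus$high,
                  plus_low = pairs$plus$low, plus_high = pairs$plus$high)
  rh <- ph$occupancy$Rh > 0.5
  al <- attr(ph, "cube_mask") & ph$occupancy$Al > 0.5
  contrast <- vapply(c(1, 0.1, 0.01), function(ex) {
    sinos <- lapply(seq_along(filters), function(i) {
      forward_project(ph, ang, spec40, filters[[i]], exposure_scale = ex,
                      noise_seed = 300 + i, paths = paths)
    })
    names(sinos) <- names(filters)
    vol <- aperm(elemental_ct(sinos, spec40, pairs)$volume, c(3, 1, 2))
    mean(vol[rh]) / mean(abs(vol[al]))
  }, numeric(1))
  expect_true(all(diff(contrast) < 0))
})
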