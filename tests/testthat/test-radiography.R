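test_that("an empty phantom images identically to its flat field", {
  ph <- make_foil_phantom(c(6, 6), 11, list())
  rg <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24))
  expect_identical(rg$counts, rg$flat)
  expect_equal(flat_correct(rg), matrix(1, 6, 6))
})

test_that("noise-free transmissions match 1 eV quadrature of the same integrand", {
  # 18 um Ni under the Mo filter
  ph <- uniform_foil("Ni", 18)
  rg <- simulate_radiograph(ph, spec40_plain, filter_spec("Mo", 24))
  got <- flat_correct(rg)[1, 1]
  oracle <- quadrature_transmission("Ni", 18, "Mo", 24)
  expect_equal(got, oracle, tolerance = 0.002)

  # 12 um Rh under the Nb filter
  ph2 <- uniform_foil("Rh", 12)
  rg2 <- simulate_radiograph(ph2, spec40_plain, filter_spec("Nb", 30))
  expect_equal(flat_correct(rg2)[1, 1],
               quadrature_transmission("Rh", 12, "Nb", 30),
               tolerance = 0.005)

  # transmissions never exceed 1 noise-free
  t <- flat_correct(rg)
  expect_true(all(t > 0 & t <= 1))
})

test_that("Poisson sampling gives variance close to the mean", {
  ph <- make_foil_phantom(c(100, 100), 11, list())
  rg <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24),
                            noise_seed = 99)
  # uniform region: across-pixel variance estimates the per-pixel variance
  expect_lt(abs(var(as.numeric(rg$counts)) / mean(rg$counts) - 1), 0.1)
  # sample and flat use different streams
  expect_false(identical(rg$counts, rg$flat))
})

test_that("flat-field correction validates its reference image", {
  ph <- make_foil_phantom(c(4, 4), 11, list())
  rg <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24))
  rg$flat[2, 3] <- 0
  expect_error(flat_correct(rg), "row 2, col 3")
})

test_that("pedestal threshold zeroes stray background only", {
  img <- matrix(100, 10, 10)
  img[1, ] <- 5   # 5% uniform stray background
  out <- pedestal_threshold(img, 0.06)
  expect_true(all(out[1, ] == 0))
  expect_true(all(out[-1, ] == 100))

  expect_identical(pedestal_threshold(img, 0), img)
  only_max <- pedestal_threshold(img, 1)
  expect_true(all(only_max[1, ] == 0) && all(only_max[-1, ] == 100))
  expect_error(pedestal_threshold(img, 1.5), "0, 1")
})

test_that("frame averaging preserves means and enforces consistency", {
  ph <- make_foil_phantom(c(8, 8), 11, list())
  frames <- lapply(1:4, function(i) {
    simulate_radiograph(ph, spec40, filter_spec("Mo", 24), noise_seed = i * 10)
  })
  avg <- average_frames(frames)
  expect_equal(mean(avg$counts),
               mean(vapply(frames, function(f) mean(f$counts), numeric(1))))
  expect_equal(avg$n_frames, 4L)

  expect_identical(average_frames(list(frames[[1]], frames[[1]]))$counts,
                   frames[[1]]$counts)

  other <- simulate_radiograph(ph, spec40, filter_spec("Nb", 30))
  expect_error(average_frames(list(frames[[1]], other)), "different filters")
})

test_that("detector energy weighting changes counts but not band transmissions", {
  ph <- uniform_foil("Ni", 18)
  rg_c <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24))
  rg_e <- simulate_radiograph(ph, spec40, filter_spec("Mo", 24),
                              response = "energy")
  expect_false(isTRUE(all.equal(rg_c$flat[1, 1], rg_e$flat[1, 1])))

  tr <- vapply(c("counting", "energy"), function(resp) {
    r <- ross_map_pipeline(ph, spec40, response = resp, pedestal_fraction = 0)
    c(exp(-r$A_minus$A[1, 1]), exp(-r$A_plus$A[1, 1]))
  }, numeric(2))
  expect_lt(abs(tr[1, 2] / tr[1, 1] - 1), 0.02)
  expect_lt(abs(tr[2, 2] / tr[2, 1] - 1), 0.02)
})
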