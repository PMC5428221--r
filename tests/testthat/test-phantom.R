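test_that("foil phantoms accumulate thicknesses and validate geometry", {
  ph <- make_foil_phantom(c(20, 20), 11, list(
    list(element = "Rh", thickness_um = 12, region = c(1, 10, 1, 10)),
    list(element = "Ni", thickness_um = 18, region = c(5, 15, 5, 15)),
    list(element = "Rh", thickness_um = 5, region = c(8, 12, 8, 12))))
  expect_equal(ph$thickness$Rh[6, 6], 12)       # Rh only
  expect_equal(ph$thickness$Ni[6, 6], 18)       # overlap carries both
  expect_equal(ph$thickness$Rh[9, 9], 17)       # same-element regions add
  expect_equal(ph$thickness$Rh[18, 18], 0)

  empty <- make_foil_phantom(c(8, 8), 11, list())
  expect_length(empty$thickness, 0)

  expect_error(make_foil_phantom(c(8, 8), 11, list(
    list(element = "Rh", thickness_um = 1, region = c(1, 9, 1, 8)))),
    "outside")
})

test_that("the default two-foil fixture carries the reference thicknesses", {
  fx <- foil_fixture()
  expect_equal(fx$phantom$shape, c(512L, 512L))
  expect_equal(fx$phantom$pixel_um, 11)
  ov <- fx$rois$overlap
  expect_true(all(fx$phantom$thickness$Rh[ov[1]:ov[2], ov[3]:ov[4]] == 12))
  expect_true(all(fx$phantom$thickness$Ni[ov[1]:ov[2], ov[3]:ov[4]] == 18))
  bg <- fx$rois$background
  expect_true(all(fx$phantom$thickness$Rh[bg[1]:bg[2], bg[3]:bg[4]] == 0))
})

test_that("foam phantoms reach the requested porosity deterministically", {
  solid <- make_foam_phantom(shape = c(24, 24, 24), porosity = 0,
                             insert = NULL, seed = 1)
  cube <- attr(solid, "cube_mask")
  expect_true(all(solid$occupancy$Al[cube] == 1))
  expect_true(all(solid$occupancy$Al[!cube] == 0))

  a <- make_foam_phantom(shape = c(48, 48, 48), porosity = 0.3, seed = 7)
  b <- make_foam_phantom(shape = c(48, 48, 48), porosity = 0.3, seed = 7)
  expect_identical(a$occupancy, b$occupancy)

  big <- make_foam_phantom(porosity = 0.4, seed = 11)   # 128^3 study size
  expect_lt(abs(attr(big, "achieved_porosity") - 0.4), 0.01)

  expect_error(make_foam_phantom(shape = c(16, 16, 16),
                                 insert = list(element = "Rh",
                                               region = c(1, 20, 1, 8, 1, 8)),
                                 seed = 1),
               "outside")
})

test_that("projected areal thickness conserves total occupancy", {
  ph <- make_foam_phantom(shape = c(16, 24, 24), porosity = 0.3, seed = 2)
  for (ax in 1:3) {
    p <- project_thickness(ph, ax)
    expect_equal(sum(p$Al) / ph$voxel_um, sum(ph$occupancy$Al))
    expect_equal(sum(p$Rh) / ph$voxel_um, sum(ph$occupancy$Rh))
  }
})

test_that("phantoms round-trip through TIFF + JSON serialisation", {
  d2 <- tempfile()
  fx <- foil_fixture(shape = c(32, 32))
  write_phantom(fx$phantom, d2)
  back <- read_phantom(d2)
  expect_equal(back$thickness$Rh, fx$phantom$thickness$Rh, tolerance = 1e-5)
  expect_equal(back$pixel_um, 11)

  d3 <- tempfile()
  ph <- make_foam_phantom(shape = c(8, 16, 16), porosity = 0.2, seed = 4)
  write_phantom(ph, d3)
  back3 <- read_phantom(d3)
  expect_equal(back3$occupancy$Al, ph$occupancy$Al, tolerance = 1e-5)
  expect_equal(back3$shape, ph$shape)
})
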