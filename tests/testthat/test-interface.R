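small_cfg <- function(seed = NULL) {
  experiment_config(phantom = list(shape = c(64, 64)),
                    source = list(seed = seed))
}

test_that("run_experiment produces the full artefact bundle", {
  out <- tempfile()
  res <- run_experiment(small_cfg(seed = 3), out)
  files <- list.files(out)
  for (f in c("minus_low.tif", "minus_high.tif", "plus_low.tif",
              "plus_high.tif", "minus_low_flat.tif", "band_minus.tif",
              "band_plus.tif", "elemental_map.tif", "metrics.json",
              "config.yaml", "log.txt")) {
    expect_true(f %in% files, label = paste("wrote", f))
  }
  expect_true(all(c("snr", "eps_res", "eps_over", "n_frames") %in%
                    names(res$metrics)))
  expect_gt(res$metrics$snr, 0)
})

test_that("the same configuration and seed reproduce byte-identical metrics", {
  out1 <- tempfile(); out2 <- tempfile()
  run_experiment(small_cfg(seed = 17), out1)
  run_experiment(small_cfg(seed = 17), out2)
  expect_identical(readBin(file.path(out1, "metrics.json"), "raw", 1e6),
                   readBin(file.path(out2, "metrics.json"), "raw", 1e6))
})

test_that("configuration validation names the offending field", {
  bad <- small_cfg()
  bad$filters$minus$low$element <- "Xx"
  expect_error(run_experiment(bad), "filters.minus.low.element")

  bad2 <- small_cfg()
  bad2$source$cutoff_keV <- 45
  expect_error(validate_config(bad2), "source.cutoff_keV")

  bad3 <- small_cfg()
  bad3$pipeline$mode <- "quadratic"
  expect_error(validate_config(bad3), "pipeline.mode")
})

test_that("configurations round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(source = list(kvp = 35, cutoff_keV = 9, seed = 4),
                        pipeline = list(n_frames = 2)), f)
  cfg <- load_config(f)
  expect_equal(cfg$source$kvp, 35)
  expect_equal(cfg$pipeline$n_frames, 2)
  expect_equal(cfg$pipeline$subtraction, "weighted")  # default preserved
})

test_that("a single-count averaging study agrees with run_experiment", {
  cfg <- small_cfg(seed = 21)
  tab <- averaging_study(cfg, frame_counts = 1)
  res <- run_experiment(cfg)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$snr, res$metrics$snr, tolerance = 1e-12)
  expect_equal(tab$eps_res, res$metrics$eps_res, tolerance = 1e-12)

  expect_error(averaging_study(cfg, frame_counts = c(0, 5)), "positive")
  expect_error(averaging_study(small_cfg()), "seed")
})

test_that("the design-pair CLI subcommand emits a complete JSON report", {
  f <- tempfile(fileext = ".json")
  code <- cli_main(c("design-pair", "--fixed-element", "Nb",
                     "--fixed-thickness-um", "30",
                     "--partner-element", "Mo", "--out", f))
  expect_equal(code, 0L)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$elements, c("Nb", "Mo"))
  expect_lt(abs(rep$thicknesses_um[2] - 24) / 24, 0.15)
  expect_equal(round(rep$E_lo_keV, 2), 18.99)
  expect_gt(rep$band_flux, 0)
  expect_lt(rep$residual, 0.05)

  expect_equal(cli_main(character()), 2L)
  expect_equal(cli_main("no-such-command"), 2L)
  expect_equal(cli_main(c("design-pair", "--fixed-element", "Nb")), 2L)
})
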