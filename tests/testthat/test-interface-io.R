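test_that("presets expand to the documented parameter blocks", {
  pre <- crowdcell_presets()
  rib <- pre[["ribosomal-pathway"]]
  expect_equal(rib$KM0, 130)
  expect_equal(rib$theta, 2.3)
  expect_equal(rib$N, 20)
  p <- pathway_params(rib$preset)
  expect_equal(p$kinetics$substrate$radius, 2.4)
  expect_equal(p$kinetics$catalyst$radius, 13)
  wc <- pre[["wholecell-default"]]
  wpar <- wholecell_params(N = wc$N, s_ext = wc$s_ext)
  expect_equal(wpar$kcat_R, 22.0)
  expect_equal(wpar$KM0_R, 120)
  expect_equal(wpar$l_R, 7459)
  expect_equal(pre[["wholecell-theta46"]]$theta_metabolic, 4.6)
  expect_true(all(c("N140", "N150", "N174", "N206", "N250", "N259") %in%
                    names(pre)))
})

test_that("config loading validates keys, presets and precedence", {
  cfg <- load_run_config(preset = "ribosomal-pathway", seed = 7)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$model, "pathway")
  expect_equal(cfg$seed, 7)
  # explicit override beats the preset value
  cfg2 <- load_run_config(preset = "ribosomal-pathway", N = 100)
  expect_equal(cfg2$N, 100)
  expect_error(load_run_config(preset = "wholecell-default", bogus_key = 1),
               "bogus_key")
  expect_error(load_run_config(path = tempfile()), "not found")
  expect_error(load_run_config(seed = 1), "model")
  # JSON file round trip
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(model = "wholecell", N = 150, s_ext = 10),
                       f, auto_unbox = TRUE)
  cfg3 <- load_run_config(f)
  expect_equal(cfg3$N, 150)
  expect_equal(cfg3$s_ext, 10)
})

test_that("scan writer produces deterministic provenance-stamped files", {
  cfg <- load_run_config(preset = "metabolic-pathway", seed = 3)
  sc <- scan_optimal_occupancy(
    pathway_params("metabolic"),
    scan_grid(rho_min = 0.1, rho_max = 0.3, rho_step = 0.05,
              rho_step_fine = NULL, share_ratio = 1.2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_scan(sc, f1, "csv", config = cfg)
  write_scan(sc, f2, "csv", config = cfg)
  expect_identical(readLines(f1), readLines(f2))   # determinism contract
  expect_true(any(grepl("^# config_md5=", readLines(f1))))
  expect_true(any(grepl("^# seed=3", readLines(f1))))
  # round trip at the printed precision
  back <- read_scan(f1)
  expect_equal(back$mu, signif(sc$envelope$mu, 12))
  expect_equal(back$rho, sc$envelope$rho)
  # empty result: error, no file created
  f3 <- tempfile()
  expect_error(write_scan(data.frame(), f3), "empty")
  expect_false(file.exists(f3))
  # JSON output parses back
  f4 <- tempfile(fileext = ".json")
  write_scan(sc, f4, "json", config = cfg)
  expect_equal(jsonlite::fromJSON(f4)$data$rho, sc$envelope$rho)
})

test_that("the command-line wrapper script is shipped and syntactically valid", {
  cli <- system.file("cli", "crowdcell.R", package = "crowdcell")
  expect_true(nzchar(cli))
  expect_silent(parse(cli))
})
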