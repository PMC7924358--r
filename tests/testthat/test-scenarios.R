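test_that("synthetic fixture profiles satisfy the waveform contracts", {
  tri <- generate_fixture_profile("triangle", period = 0.27,
                                  amplitude = 0.015)
  expect_lt(abs(mean(tri$heights)), 1e-9)
  expect_equal(tri$c_max, 0.015, tolerance = 0.01)   # C = amplitude
  expect_equal(length(tri$heights), 270L)

  sine <- generate_fixture_profile("sine", amplitude = 0.012)
  expect_lt(abs(mean(sine$heights)), 1e-9)
  expect_equal(sine$c_max, 0.012)
  expect_equal(sine$heights[1], max(sine$heights))   # peak-first

  # seeding contract: same seed reproduces, different seed perturbs
  j1 <- generate_fixture_profile("jitter", seed = 7)
  j2 <- generate_fixture_profile("jitter", seed = 7)
  j3 <- generate_fixture_profile("jitter", seed = 8)
  expect_identical(j1$heights, j2$heights)
  expect_false(identical(j1$heights, j3$heights))
  expect_error(generate_fixture_profile("sawtooth"), "arg")
})

test_that("presets resolve to valid components with the studied verdicts", {
  expect_setequal(list_presets(),
                  c("FeCr_H2SO4", "CoCrMo_NaCl_pH2.3", "CoCrMo_NaCl_pH5.6",
                    "Ti6Al4V_NaCl_pH2.3", "Ti6Al4V_NaCl_pH5.6"))
  for (nm in list_presets()) {
    p <- material_preset(nm)
    expect_lte(p$material$e_corr, p$material$e_pass)
    expect_gt(p$electrolyte$conductivity, 0)
  }
  expect_error(material_preset("nope"), "unknown preset")

  # the biomedical alloys stay passive; the FeCr reference does not
  for (nm in c("Ti6Al4V_NaCl_pH5.6", "Ti6Al4V_NaCl_pH2.3",
               "CoCrMo_NaCl_pH2.3", "CoCrMo_NaCl_pH5.6"))
    expect_equal(attr(run_scenario(nm), "verdict"), "no crevice corrosion")
  expect_equal(attr(run_scenario("FeCr_H2SO4"), "verdict"),
               "crevice corrosion sustainable")
})

test_that("scenario runs are deterministic down to the CSV bytes", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(run_scenario("CoCrMo_NaCl_pH2.3"), f1)
  write_profile_csv(run_scenario("CoCrMo_NaCl_pH2.3"), f2)
  expect_identical(readLines(f1), readLines(f2))

  js <- withr::local_tempfile(fileext = ".json")
  write_summary_json(run_scenario("Ti6Al4V_NaCl_pH5.6"), js)
  smry <- jsonlite::read_json(js)
  expect_equal(smry$verdict, "no crevice corrosion")
  expect_null(smry$e_pass_crossing_mm)
  expect_true(is.numeric(smry$max_drop_mV))
})

test_that("narrower mismatch angles raise the drop at every depth", {
  base <- preset_scenario("CoCrMo_NaCl_pH2.3")
  sw <- sweep_mismatch_angle(base, c(0.02, 0.01, 0.005))
  expect_equal(sw$summaries$value, c(0.02, 0.01, 0.005))
  d <- lapply(sw$profiles, function(p) p$drop_mV[-1])
  expect_true(all(d[[2]] > d[[1]]))
  expect_true(all(d[[3]] > d[[2]]))
  expect_true(all(diff(sw$summaries$max_drop_mV) > 0))

  # a single angle reduces to a plain scenario run
  one <- sweep_mismatch_angle(base, 0.02)
  expect_equal(one$profiles[[1]]$E_V, run_scenario(base)$E_V)
  expect_error(sweep_mismatch_angle(base, c(0.02, 0.02)), "distinct")
  expect_error(sweep_mismatch_angle(base, c(0.02, -0.01)), "positive")
})

test_that("smoothing the roughness (scale 1/5) raises the drop at every depth", {
  base <- preset_scenario("CoCrMo_NaCl_pH2.3")
  sw <- sweep_roughness_scale(base, c(1.0, 0.2))
  d1 <- sw$profiles[[1]]$drop_mV[-1]
  d02 <- sw$profiles[[2]]$drop_mV[-1]
  expect_true(all(d02 > d1))

  # scale 1 is the identity
  expect_equal(sw$profiles[[1]]$E_V, run_scenario(base)$E_V)
  expect_error(sweep_roughness_scale(base, c(1, 0)), "positive")
})

test_that("scenario configs round-trip losslessly, presets included", {
  scn <- preset_scenario("Ti6Al4V_NaCl_pH2.3",
                         profile_spec = list(amplitude_um = 12))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(scn, path)
  back <- read_scenario_config(path)
  expect_equal(back$geometry, scn$geometry)
  expect_equal(back$electrolyte$conductivity, scn$electrolyte$conductivity)
  expect_equal(back$material[c("e_pass", "i_pass", "e_corr", "e_out")],
               scn$material[c("e_pass", "i_pass", "e_corr", "e_out")])
  expect_equal(back$profile_spec$amplitude_um, 12)
  expect_equal(run_scenario(back)$E_V, run_scenario(scn)$E_V)

  # a preset named in a config stands for its full parameter block
  cfgp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: FeCr_H2SO4",
               "electrolyte:", "  rho_ohm_mm: 350",
               "  conductivity_mS_cm: null"), cfgp)
  fe <- read_scenario_config(cfgp)
  expect_equal(fe$electrolyte$rho, 350)
  expect_equal(fe$material$i_pass, 1.8)
})

test_that("a measured-trace file drives the same pipeline as a waveform", {
  tri <- generate_fixture_profile("triangle", amplitude = 0.015)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# units: mm",
               paste(tri$positions, tri$heights)), path)
  scn <- preset_scenario("CoCrMo_NaCl_pH2.3",
                         profile_spec = list(kind = "file", path = path,
                                             period_mm = 0.27))
  sol_file <- run_scenario(scn)
  sol_wave <- run_scenario("CoCrMo_NaCl_pH2.3")
  expect_equal(sol_file$E_V, sol_wave$E_V, tolerance = 1e-9)
})

test_that("shipped example config and synthetic curve work end to end", {
  cfg <- system.file("extdata", "fecr_h2so4.yaml", package = "crevsim")
  scn <- read_scenario_config(cfg)
  expect_equal(scn$electrolyte$rho, 350)
  sol <- run_scenario(scn)
  expect_equal(attr(sol, "verdict"), "crevice corrosion sustainable")

  curve <- system.file("extdata", "synthetic_fecr_polarization.txt",
                       package = "crevsim")
  fit <- tafel_extrapolate(read_polarization_file(curve),
                           anodic_window = c(-0.35, -0.15),
                           cathodic_window = c(-0.85, -0.65))
  expect_equal(fit$e_corr, -0.5, tolerance = 0.05)
  expect_equal(fit$i_corr, 0.5, tolerance = 0.05)
})
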