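make_screen_inputs <- function(seed = 2026) {
  specs <- list(
    sensitizer_spec("pdt_lead", a_irr = 0.25, effective_phi = 2),
    sensitizer_spec("apdi_lead", a_irr = 0.25, effective_phi = 1.2),
    sensitizer_spec("photochem", a_irr = 0.25, effective_phi = 0),
    sensitizer_spec("dud", a_irr = 0.05, effective_phi = 0)
  )
  plate <- simulate_dma_plate(specs, sim_config(seed = seed))
  dr <- rbind(
    simulate_dose_response(cytotox_spec("pdt_lead", Inf, 1), seed = seed + 1),
    simulate_dose_response(cytotox_spec("apdi_lead", Inf, Inf), seed = seed + 2),
    simulate_dose_response(cytotox_spec("photochem", Inf, 5), seed = seed + 3),
    simulate_dose_response(cytotox_spec("dud", Inf, Inf), seed = seed + 4)
  )
  list(plate = plate, dr = dr)
}

test_that("the end-to-end screen reproduces the generator's expected cases", {
  inp <- make_screen_inputs()
  out_dir <- tempfile("screen")
  cfg <- default_config(seed = 3, out_dir = out_dir, cytotox_n_boot = 100)
  res <- run_screen(cfg, plate = inp$plate, dose_response = inp$dr)

  rep <- res$report
  case_of <- function(s) rep$case[rep$sample_id == s]
  expect_equal(case_of("pdt_lead"), "case5_pdt_candidate")
  expect_equal(case_of("apdi_lead"), "case4_apdi_candidate")
  expect_equal(case_of("photochem"), "case2_photochemical")
  expect_equal(case_of("dud"), "inactive")
  expect_equal(rep$sample_id[rep$rank == 1], "pdt_lead")

  expect_true(file.exists(file.path(out_dir, "dma_results.csv")))
  expect_true(file.exists(file.path(out_dir, "cytotox_results.csv")))
  expect_true(file.exists(file.path(out_dir, "screen_report.csv")))
  expect_true(file.exists(file.path(out_dir, "screen_report.md")))
  expect_true(file.exists(file.path(out_dir, "screen_log.txt")))

  # every number in the report traces to a stage CSV
  dma_csv <- utils::read.csv(file.path(out_dir, "dma_results.csv"))
  expect_equal(
    sort(rep$relative_yield_pct),
    sort(dma_csv$relative_yield_pct[dma_csv$sample_id != "berberine"]),
    tolerance = 1e-9)
})

test_that("a rerun with the same config and seed is identical", {
  inp <- make_screen_inputs()
  cfg <- default_config(seed = 5, cytotox_n_boot = 50)
  r1 <- run_screen(cfg, plate = inp$plate, dose_response = inp$dr)
  r2 <- run_screen(cfg, plate = inp$plate, dose_response = inp$dr)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$cytotox, r2$cytotox)
})

test_that("DMA-only runs are reported as incomplete", {
  inp <- make_screen_inputs()
  res <- run_screen(default_config(seed = 1), plate = inp$plate)
  expect_true(all(res$report$status == "incomplete: cytotoxicity pending"))
  expect_true(all(is.na(res$report$case)))
  expect_null(res$cytotox)
})

test_that("the pipeline reads its inputs from CSV paths and runs dosimetry checks", {
  inp <- make_screen_inputs()
  dir <- tempfile("io"); dir.create(dir)
  write_plate(inp$plate, file.path(dir, "layout.csv"),
              file.path(dir, "readings.csv"))
  utils::write.csv(inp$dr, file.path(dir, "dr.csv"), row.names = FALSE)

  # actinometry producing a homogeneous ~20.6 mW cm-2 field
  h <- 6.62607015e-34; c0 <- 2.99792458e8; na <- 6.02214076e23
  e_mol <- na * h * c0 / 468e-9
  moles <- 20.6e-3 * 0.32 * 300 * 0.9 / e_mol
  act <- data.frame(well = inner_wells(), moles_fe2 = moles,
                    exposure_s = 300, area_cm2 = 0.32)
  utils::write.csv(act, file.path(dir, "act.csv"), row.names = FALSE)

  cfg <- default_config(
    layout_csv = file.path(dir, "layout.csv"),
    readings_csv = file.path(dir, "readings.csv"),
    dose_response_csv = file.path(dir, "dr.csv"),
    actinometry_csv = file.path(dir, "act.csv"),
    seed = 2, cytotox_n_boot = 50)
  res <- run_screen(cfg)
  expect_true(res$homogeneity$pass)
  expect_equal(res$homogeneity$mean, 20.6e-3 * 1200, tolerance = 1e-6)
  expect_equal(res$report$case[res$report$sample_id == "pdt_lead"],
               "case5_pdt_candidate")
})

test_that("the configuration round-trips through YAML unchanged", {
  cfg <- default_config(seed = 11, dma_positivity_pct = 7,
                        step_seconds = c(300, 300, 600))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))])
})
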