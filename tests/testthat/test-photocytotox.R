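test_that("SRB normalization maps blanks to 0% and untreated to 100%", {
  untreated <- c(1.0, 1.1, 0.9)
  blanks <- c(0.08, 0.12)
  expect_equal(normalize_srb(mean(untreated), untreated, blanks), 100)
  expect_equal(normalize_srb(mean(blanks), untreated, blanks), 0)
  half <- (mean(untreated) + mean(blanks)) / 2
  expect_equal(normalize_srb(half, untreated, blanks), 50)
  expect_error(normalize_srb(0.5, c(0.1), c(0.2)), "assay failure")
  expect_error(normalize_srb(0.5, numeric(0), blanks), "at least one")
})

test_that("the 4PL fit recovers exact parameters on noise-free data", {
  conc <- 50 / 3^(6:0)
  for (true in list(c(ec50 = 10, h = 1, top = 100, bottom = 0),
                    c(ec50 = 0.5, h = 2.5, top = 105, bottom = 10),
                    c(ec50 = 30, h = 0.8, top = 95, bottom = 5))) {
    d <- data.frame(
      concentration_ug_per_ml = rep(conc, each = 3),
      viability_pct = photoscreen:::four_pl(rep(conc, each = 3), true["ec50"],
                                            true["h"], true["top"],
                                            true["bottom"]))
    f <- fit_4pl(d, n_boot = 0)
    expect_true(f$fit_ok)
    expect_false(f$censored)
    expect_equal(f$ec50, unname(true["ec50"]), tolerance = 1e-6)
    expect_equal(f$hill, unname(true["h"]), tolerance = 1e-4)
  }
})

test_that("EC50 is equivariant under concentration rescaling", {
  conc <- 50 / 3^(6:0)
  d <- data.frame(concentration_ug_per_ml = rep(conc, each = 3),
                  viability_pct = photoscreen:::four_pl(
                    rep(conc, each = 3), 10, 1.3, 100, 0))
  f_ug <- fit_4pl(d, n_boot = 0)
  d_ng <- d
  d_ng$concentration_ug_per_ml <- d_ng$concentration_ug_per_ml * 1000
  f_ng <- fit_4pl(d_ng, n_boot = 0, activity_cap = 5e4)
  expect_equal(f_ng$ec50 / f_ug$ec50, 1000, tolerance = 1e-8)
})

test_that("flat or out-of-range responses are censored, never extrapolated", {
  conc <- 50 / 3^(6:0)
  flat <- data.frame(concentration_ug_per_ml = rep(conc, each = 3),
                     viability_pct = 100)
  f <- fit_4pl(flat, n_boot = 0)
  expect_true(f$censored)
  expect_false(f$active)
  expect_equal(f$ec50, Inf)
  expect_equal(f$max_tested, 50)

  # EC50 far above the tested range: censored at > max tested
  high <- data.frame(
    concentration_ug_per_ml = rep(conc, each = 3),
    viability_pct = photoscreen:::four_pl(rep(conc, each = 3), 500, 1, 100, 0))
  fh <- fit_4pl(high, n_boot = 0)
  expect_true(fh$censored)

  expect_error(fit_4pl(data.frame(concentration_ug_per_ml = c(1, 10),
                                  viability_pct = c(90, 10))),
               "at least 4")
})

test_that("noisy triplicate data recover the true EC50 inside the bootstrap CI", {
  dr <- simulate_dose_response(
    cytotox_spec("s", ec50_dark = Inf, ec50_irr = 1, noise_sd_pct = 5),
    seed = 42)
  f <- fit_4pl(dr[dr$arm == "irradiated", ], n_boot = 500, seed = 9)
  expect_false(f$censored)
  expect_lte(f$ec50_ci[1], f$ec50)
  expect_gte(f$ec50_ci[2], f$ec50)
  expect_gte(1, f$ec50_ci[1])
  expect_lte(1, f$ec50_ci[2])
  expect_lt(abs(f$ec50 - 1), 0.2)
})

test_that("selectivity follows EC50_dark / EC50_irradiated with censoring as bounds", {
  mk <- function(ec50, censored = FALSE, max_tested = 50) {
    structure(list(ec50 = if (censored) Inf else ec50,
                   ec50_ci = c(NA, NA), hill = 1, top = 100, bottom = 0,
                   censored = censored, max_tested = max_tested,
                   active = !censored && ec50 < 50, fit_ok = TRUE,
                   n_boot_ok = 0L, data = NULL),
              class = "dose_response_fit")
  }
  s <- selectivity(mk(50), mk(1))
  expect_equal(s$si, 50)
  expect_false(s$si_censored)
  expect_true(s$photo_enhanced)

  id <- selectivity(mk(10), mk(10))
  expect_equal(id$si, 1)
  expect_false(id$photo_enhanced)

  # dark arm censored at > 50, irradiated EC50 = 1: S.I. reported > 50
  bound <- selectivity(mk(NA, censored = TRUE), mk(1))
  expect_equal(bound$si, 50)
  expect_true(bound$si_censored)
  expect_true(bound$photo_enhanced)

  both <- selectivity(mk(NA, censored = TRUE), mk(NA, censored = TRUE))
  expect_true(is.na(both$si))
  expect_false(both$photo_enhanced)

  # irradiated censored: light adds nothing, never photo-enhanced
  irr_cens <- selectivity(mk(10), mk(NA, censored = TRUE))
  expect_false(irr_cens$photo_enhanced)
})

test_that("a simulated screen reproduces a > 50-fold selectivity bound", {
  dr <- simulate_dose_response(
    cytotox_spec("ac", ec50_dark = Inf, ec50_irr = 1, noise_sd_pct = 5),
    seed = 5)
  fd <- fit_4pl(dr[dr$arm == "dark", ], n_boot = 0)
  fi <- fit_4pl(dr[dr$arm == "irradiated", ], n_boot = 0)
  expect_true(fd$censored)
  s <- selectivity(fd, fi)
  expect_true(s$si_censored)
  expect_equal(s$si, 50 / fi$ec50, tolerance = 1e-12)
  expect_gt(s$si, 40)
})
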