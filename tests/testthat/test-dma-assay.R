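test_that("delta_od endpoint and slope agree on linear bleaching", {
  traj <- tibble::tibble(dose = c(0, 6.2, 12.4, 18.5, 24.7),
                         od = c(0.40, 0.35, 0.30, 0.25, 0.20),
                         se = 0)
  expect_equal(delta_od(traj, "endpoint")$delta, 0.20)

  # for data exactly linear in dose the two estimators coincide;
  # oracle: closed-form least-squares slope on 5 points
  lin <- tibble::tibble(dose = c(0, 6.2, 12.4, 18.5, 24.7), se = 0)
  lin$od <- 0.40 - (0.20 / 24.7) * lin$dose
  sl <- cov(lin$dose, lin$od) / var(lin$dose)
  expect_equal(-sl * 24.7, 0.20, tolerance = 1e-9)
  expect_equal(delta_od(lin, "slope")$delta, 0.20, tolerance = 1e-9)
  expect_equal(delta_od(lin, "endpoint")$delta, delta_od(lin, "slope")$delta,
               tolerance = 1e-9)

  flat <- tibble::tibble(dose = c(0, 24.7), od = c(0.4, 0.4), se = 0)
  expect_equal(delta_od(flat)$delta, 0)
  expect_error(delta_od(flat[1, ]), "at least 2")
})

test_that("absorbed fraction follows Beer-Lambert", {
  expect_equal(absorbed_fraction(0), 0)
  expect_equal(absorbed_fraction(0.2), 1 - 10^(-0.2)) # 0.36904
  expect_equal(round(absorbed_fraction(0.2), 4), 0.369)
  expect_equal(round(absorbed_fraction(3), 4), 0.999)
  expect_equal(absorbed_fraction(-0.005), 0) # within noise floor: clamped
  expect_error(absorbed_fraction(-0.5), "negative absorbance")
})

test_that("relative yield reproduces the reference-comparison formula", {
  # self-comparison anchors the reference at exactly 100%
  expect_identical(relative_yield(0.1, 0.2, 0.1, 0.2)$yield_pct, 100)
  expect_equal(relative_yield(0, 0.3, 0.1, 0.2)$yield_pct, 0)

  # hand evaluation: 100 * (0.2/0.1) * ((1-10^-0.2)/(1-10^-0.1));
  # 0.3690427 / 0.2056718 at full precision (4-digit intermediate
  # rounding would give 358.8)
  oracle <- 100 * 2 * (1 - 10^(-0.2)) / (1 - 10^(-0.1))
  expect_equal(round(oracle, 1), 358.9)
  expect_equal(relative_yield(0.2, 0.1, 0.1, 0.2)$yield_pct, oracle)

  # transparent but bleaching: physically inconsistent
  inc <- relative_yield(0.2, 0, 0.1, 0.2)
  expect_true(inc$inconsistent)
  expect_error(relative_yield(0.1, 0.2, 0, 0.2), "reference delta OD")

  # strictly increasing in sample dOD, strictly decreasing in sample A
  y <- function(d, a) relative_yield(d, a, 0.1, 0.2)$yield_pct
  ds <- seq(0.05, 0.4, by = 0.05)
  expect_true(all(diff(sapply(ds, y, a = 0.15)) > 0))
  as <- seq(0.05, 1.5, by = 0.1)
  expect_true(all(diff(sapply(as, function(a) y(0.2, a))) < 0))
})

test_that("quencher and side-reaction controls gate the positivity call", {
  ctl <- validate_controls(0.20, 0.02, 0.005)
  expect_equal(ctl$quench_ratio, 0.1)
  expect_true(ctl$quench_confirmed)
  expect_false(ctl$side_reaction_flag)

  weak <- validate_controls(0.20, 0.18, 0.005)
  expect_equal(weak$quench_ratio, 0.9)
  expect_false(weak$quench_confirmed)

  side <- validate_controls(0.20, 0.02, 0.10)
  expect_true(side$side_reaction_flag)

  # no signal to quench: ratio defined as 1, not confirmed
  null <- validate_controls(0.005, 0.001, 0)
  expect_equal(null$quench_ratio, 1)
  expect_false(null$quench_confirmed)
})

test_that("scoring a simulated plate recovers the generator's ground truth", {
  specs <- list(
    sensitizer_spec("strong", a_irr = 0.2, effective_phi = 2),
    sensitizer_spec("inert", a_irr = 0.2, effective_phi = 0),
    sensitizer_spec("nonquench", a_irr = 0.2, effective_phi = 1,
                    quenchable = 0),
    sensitizer_spec("sidereact", a_irr = 0.2, effective_phi = 1,
                    side_reaction_drift = 0.1)
  )
  ds <- simulate_dma_plate(specs, sim_config(seed = 101))
  res <- score_plate(ds)

  ref <- res[res$sample_id == "berberine", ]
  expect_equal(ref$relative_yield_pct, 100) # exact self-anchoring
  expect_true(ref$dma_positive)

  strong <- res[res$sample_id == "strong", ]
  expect_true(strong$dma_positive)
  expect_gt(strong$relative_yield_pct, 100)

  inert <- res[res$sample_id == "inert", ]
  expect_false(inert$dma_positive)
  expect_lt(abs(inert$relative_yield_pct), 3 * inert$relative_yield_se + 5)

  # bleaches DMA but unaffected by ascorbate: a non-1O2 mechanism
  nq <- res[res$sample_id == "nonquench", ]
  expect_false(nq$quench_confirmed)
  expect_false(nq$dma_positive)
  expect_gt(nq$relative_yield_pct, 50) # the bleaching itself is real

  expect_true(res$side_reaction[res$sample_id == "sidereact"])

  expect_error(score_extract(ds, "nope"), "nope")
})

test_that("equal-absorbance sensitizers recover their phi ratio within 3 SE", {
  specs <- list(sensitizer_spec("s205", a_irr = 0.2, effective_phi = 2.05))
  ds <- simulate_dma_plate(specs, sim_config(seed = 2024))
  res <- score_plate(ds)
  s <- res[res$sample_id == "s205", ]
  expect_lt(abs(s$relative_yield_pct - 205), 3 * s$relative_yield_se)
})

test_that("a sample identical to the solvent control scores zero within noise", {
  specs <- list(sensitizer_spec("ghost", a_irr = 0, effective_phi = 0))
  cfg <- sim_config(seed = 55)
  ds <- simulate_dma_plate(specs, cfg)
  res <- score_extract(ds, "ghost")
  expect_equal(res$relative_yield_pct, 0)
  expect_false(res$dma_positive)
})
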