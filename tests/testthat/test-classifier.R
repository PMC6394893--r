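ev <- function(dma, uv, ct, pct, ...) {
  evidence_vector("x", dma_positive = dma, quench_confirmed = dma,
                  uv_vis_change = uv, ct_positive = ct, pct_positive = pct,
                  ...)
}

test_that("the decision table assigns the rubric cases", {
  expect_equal(classify(ev(TRUE, TRUE, FALSE, TRUE))$case,
               "case5_pdt_candidate")
  expect_equal(classify(ev(TRUE, TRUE, TRUE, TRUE))$case,
               "case3_broad_toxic")
  expect_equal(classify(ev(TRUE, TRUE, FALSE, FALSE))$case,
               "case4_apdi_candidate")
  expect_equal(classify(ev(FALSE, TRUE, FALSE, TRUE))$case,
               "case2_photochemical")
  expect_equal(classify(ev(FALSE, TRUE, FALSE, FALSE))$case,
               "case1_sun_protect_or_inert")
  expect_equal(classify(ev(FALSE, FALSE, FALSE, FALSE))$case, "inactive")
  # dark-cytotoxic only folds into inactive with an explanatory rationale
  dark_only <- classify(ev(FALSE, FALSE, TRUE, FALSE))
  expect_equal(dark_only$case, "inactive")
  expect_match(dark_only$rationale, "dark-cytotoxic")
})

test_that("classification is total and deterministic over all evidence combinations", {
  combos <- expand.grid(dma = c(TRUE, FALSE), uv = c(TRUE, FALSE),
                        ct = c(TRUE, FALSE), pct = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    call1 <- classify(ev(combos$dma[i], combos$uv[i], combos$ct[i],
                         combos$pct[i]))
    expect_true(call1$case %in% photoscreen:::CASE_LEVELS)
    expect_true(nzchar(call1$rationale))
    call2 <- classify(ev(combos$dma[i], combos$uv[i], combos$ct[i],
                         combos$pct[i]))
    expect_identical(call1$case, call2$case)
  }
})

test_that("an unconfirmed quench demotes the DMA call", {
  e <- evidence_vector("x", dma_positive = TRUE, quench_confirmed = FALSE,
                       uv_vis_change = TRUE, ct_positive = FALSE,
                       pct_positive = TRUE)
  expect_false(e$dma_positive)
  expect_true(e$dma_demoted)
  call <- classify(e)
  expect_equal(call$case, "case2_photochemical") # treated as DMA-negative
  expect_match(call$rationale, "Type I")
})

test_that("the encoded fungal screen reproduces the printed case assignments", {
  fix <- screening_evidence()
  known <- fix[!is.na(fix$expected_case), ]
  expect_gte(nrow(known), 4)
  for (i in seq_len(nrow(known))) {
    expect_equal(classify(known[i, ])$case, known$expected_case[i],
                 label = known$sample_id[i])
  }
})

test_that("UV-Vis evolution is judged by the maximum absolute OD change", {
  sp <- function(od, dose) {
    tibble::tibble(wavelength_nm = seq(350, 550, by = 10), od = od,
                   cumulative_dose_J_cm2 = dose)
  }
  same <- rbind(sp(0.3, 0), sp(0.3, 24.7))
  expect_false(uv_vis_change(same))

  shifted <- rbind(sp(0.3, 0), sp(c(rep(0.3, 10), 0.5, rep(0.3, 10)), 24.7))
  expect_true(uv_vis_change(shifted))

  drift <- rbind(sp(0.3, 0), sp(0.34, 24.7))
  expect_false(uv_vis_change(drift, tolerance = 0.05)) # max |delta| = 0.04

  expect_error(uv_vis_change(sp(0.3, 0)), "2 doses")

  # interpolation onto the overlapping grid when wavelength grids differ
  a <- list(tibble::tibble(wavelength_nm = seq(350, 550, 10), od = 0.3),
            tibble::tibble(wavelength_nm = seq(355, 545, 10), od = 0.45))
  expect_true(uv_vis_change(a))
})

test_that("ranking orders by case priority, then S.I., then yield", {
  calls <- rbind(
    cbind(classify(ev(FALSE, FALSE, FALSE, FALSE)),
          tibble::tibble(si = NA_real_, si_censored = FALSE,
                         relative_yield_pct = 0)),
    cbind(classify(ev(TRUE, TRUE, TRUE, TRUE)),
          tibble::tibble(si = 3, si_censored = FALSE,
                         relative_yield_pct = 205)),
    cbind(classify(ev(TRUE, TRUE, FALSE, TRUE)),
          tibble::tibble(si = 5, si_censored = FALSE,
                         relative_yield_pct = 82))
  )
  calls$sample_id <- c("inert", "broad", "pdt")
  ranked <- rank_extracts(calls)
  expect_equal(ranked$sample_id, c("pdt", "broad", "inert"))
  expect_equal(ranked$rank, 1:3)

  # S.I. tie-break between two PDT candidates; censored bound beats an
  # equal point value
  two <- rbind(calls[3, ], calls[3, ], calls[3, ])
  two$sample_id <- c("si5", "si50", "si50bound")
  two$si <- c(5, 50, 50)
  two$si_censored <- c(FALSE, FALSE, TRUE)
  r2 <- rank_extracts(two)
  expect_equal(r2$sample_id, c("si50bound", "si50", "si5"))

  # no S.I. metadata at all: fall back to DMA yield
  noSI <- calls[2:3, c("sample_id", "case", "rationale", "rank_score",
                       "relative_yield_pct")]
  r3 <- rank_extracts(noSI)
  expect_equal(r3$sample_id[1], "pdt")

  # output is a permutation of the input
  expect_setequal(rank_extracts(calls)$sample_id, calls$sample_id)
})
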