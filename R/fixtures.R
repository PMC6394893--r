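## Worked-example evidence table: the qualitative screening outcomes of
## a fungal extract panel (three basidiomycetes, three ascomycetes),
## encoded as an evidence vector per extract together with the rubric
## case expected for the extracts whose interpretation is settled.

#' Fungal screening evidence fixture
#'
#' Evidence table for a screen of fungal extracts spanning all rubric
#' outcomes: a PDT candidate (Cortinarius croceus methanol extract), a
#' broadly toxic extract (C. croceus petrol ether), an aPDI candidate
#' (Metarhizium brunneum), and an oxygen-independent photochemical
#' actor (Beauveria brongniartii). Relative singlet-oxygen yields are
#' percentages of a berberine reference; `expected_case` is `NA` where
#' the interpretation is not settled by the screen alone.
#'
#' @return tibble with one evidence row per extract plus an
#'   `expected_case` column.
#' @examples
#' ev <- screening_evidence()
#' classify(ev[ev$sample_id == "C_croceus_MeOH", ])
#' @export
screening_evidence <- function() {
  mk <- function(id, dma, yield, se, uv, ct, pct, si = NA_real_,
                 si_cens = FALSE, expected = NA_character_) {
    cbind(
      evidence_vector(id, dma_positive = dma, quench_confirmed = dma,
                      uv_vis_change = uv, ct_positive = ct,
                      pct_positive = pct, si = si, si_censored = si_cens,
                      relative_yield_pct = yield),
      tibble::tibble(relative_yield_se = se, expected_case = expected)
    )
  }
  out <- rbind(
    mk("C_croceus_MeOH", TRUE, 82, 11, TRUE, FALSE, TRUE,
       expected = "case5_pdt_candidate"),
    mk("C_croceus_AC", TRUE, 205, 11, TRUE, FALSE, TRUE,
       si = 50, si_cens = TRUE),
    mk("C_croceus_PE", TRUE, 205, 12, TRUE, TRUE, TRUE,
       expected = "case3_broad_toxic"),
    mk("T_atrotomentosa_PE", FALSE, 0, 0, FALSE, TRUE, FALSE),
    mk("T_atrotomentosa_AC", TRUE, 6, 1, TRUE, FALSE, FALSE),
    mk("I_obliquus_AC", TRUE, 30, 2, TRUE, FALSE, FALSE),
    mk("R_subterranea", TRUE, 73, 15, TRUE, TRUE, TRUE),
    mk("M_brunneum", TRUE, 124, 11, TRUE, FALSE, FALSE,
       expected = "case4_apdi_candidate"),
    mk("B_brongniartii", FALSE, 0, 0, TRUE, FALSE, TRUE,
       expected = "case2_photochemical")
  )
  tibble::as_tibble(out)
}
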