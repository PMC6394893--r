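## Interpretation engine: map the combined evidence of the three
## sub-assays (DMA singlet-oxygen production, UV-Vis evolution under
## irradiation, dark cytotoxicity CT, photo-cytotoxicity PCT) onto a
## five-case phototoxicity rubric, and rank extracts by therapeutic
## promise.

CASE_LEVELS <- c(
  "case1_sun_protect_or_inert",
  "case2_photochemical",
  "case3_broad_toxic",
  "case4_apdi_candidate",
  "case5_pdt_candidate",
  "inactive"
)

## default ranking priority: PDT candidates first, then oxygen-independent
## photochemistry, then aPDI candidates, then broadly toxic, then inert
DEFAULT_CASE_PRIORITY <- c(
  case5_pdt_candidate = 6,
  case2_photochemical = 5,
  case4_apdi_candidate = 4,
  case3_broad_toxic = 3,
  case1_sun_protect_or_inert = 2,
  inactive = 1
)

#' Assemble an evidence vector for one extract
#'
#' A DMA-positive call with an unconfirmed ascorbate quench is demoted
#' to DMA-negative here (possible Type I photochemistry or artifact),
#' so the classifier only ever sees quench-backed singlet-oxygen calls.
#'
#' @param sample_id extract identifier.
#' @param dma_positive singlet-oxygen production detected (and
#'   quench-confirmed) in the DMA assay.
#' @param quench_confirmed ascorbate control confirmed the 1O2
#'   mechanism.
#' @param uv_vis_change UV-Vis spectrum evolved under irradiation.
#' @param ct_positive cytotoxic in the dark below the activity cap.
#' @param pct_positive cytotoxic under irradiation below the cap.
#' @param si optional selectivity index (or lower bound).
#' @param si_censored TRUE when `si` is a lower bound.
#' @param relative_yield_pct optional DMA relative yield, used as a
#'   ranking tie-break.
#' @return one-row tibble of class `evidence_vector`.
#' @export
evidence_vector <- function(sample_id, dma_positive, quench_confirmed,
                            uv_vis_change, ct_positive, pct_positive,
                            si = NA_real_, si_censored = FALSE,
                            relative_yield_pct = NA_real_) {
  demoted <- isTRUE(dma_positive) && !isTRUE(quench_confirmed)
  out <- tibble::tibble(
    sample_id = sample_id,
    dma_positive = isTRUE(dma_positive) && isTRUE(quench_confirmed),
    quench_confirmed = isTRUE(quench_confirmed),
    dma_demoted = demoted,
    uv_vis_change = isTRUE(uv_vis_change),
    ct_positive = isTRUE(ct_positive),
    pct_positive = isTRUE(pct_positive),
    si = si, si_censored = isTRUE(si_censored),
    relative_yield_pct = relative_yield_pct
  )
  class(out) <- c("evidence_vector", class(out))
  out
}

#' Classify an extract into the phototoxicity rubric
#'
#' Decision table over (DMA, UV, CT, PCT); every boolean combination
#' maps to exactly one outcome:
#' \describe{
#'   \item{case 5 (PDT candidate)}{1O2 produced; toxic only under
#'     irradiation (DMA+, CT-, PCT+).}
#'   \item{case 4 (aPDI candidate)}{1O2 produced but no cytotoxicity in
#'     either arm (DMA+, CT-, PCT-); the photosensitizer likely fails to
#'     cross the mammalian membrane and may still act on microbes.}
#'   \item{case 3 (broadly toxic)}{active on every level (DMA+, CT+,
#'     PCT+); possibly too toxic, matrix effects should be examined.}
#'   \item{case 2 (photochemical)}{photo-cytotoxic without 1O2 (DMA-,
#'     PCT+); an oxygen-independent photochemical mechanism, of interest
#'     for hypoxic tumours.}
#'   \item{case 1 (sun-protective or inert)}{no 1O2, no toxicity, but
#'     the UV-Vis spectrum evolves under irradiation (DMA-, CT-, PCT-,
#'     UV+).}
#'   \item{inactive}{everything negative; combinations with dark
#'     toxicity only (CT+ without any photo-activity) also land here,
#'     with a rationale noting the dark cytotoxicity.}
#' }
#'
#' @param ev an [evidence_vector()] (or a one-row data frame with the
#'   same logical columns).
#' @return one-row tibble of class `photoactivity_call` with columns
#'   `sample_id`, `case`, `rationale`, `rank_score`.
#' @export
classify <- function(ev) {
  dma <- isTRUE(ev$dma_positive)
  uv <- isTRUE(ev$uv_vis_change)
  ct <- isTRUE(ev$ct_positive)
  pct <- isTRUE(ev$pct_positive)
  note <- if (isTRUE(ev$dma_demoted)) {
    " DMA signal present but not quench-confirmed: possible Type I photochemistry or assay artifact; treated as DMA-negative."
  } else ""

  if (dma && ct && pct) {
    case <- "case3_broad_toxic"
    why <- "1O2 producer, cytotoxic in the dark and under light: broadly active; investigate matrix/synergistic effects before ranking it as a lead."
  } else if (dma && !ct && pct) {
    case <- "case5_pdt_candidate"
    why <- "1O2 producer, non-toxic in the dark but cytotoxic under irradiation: promising PDT candidate."
  } else if (dma && !ct && !pct) {
    case <- "case4_apdi_candidate"
    why <- "1O2 producer without (photo-)cytotoxicity on mammalian cells: candidate for antimicrobial photodynamic inhibition if it crosses microbial envelopes."
  } else if (dma && ct && !pct) {
    case <- "inactive"
    why <- "1O2 producer but dark-cytotoxic only; light adds no effect, so no photo-therapeutic lead (dark toxicity dominates)."
  } else if (!dma && pct) {
    case <- "case2_photochemical"
    why <- "photo-cytotoxic without detectable 1O2: an oxygen-independent photochemical mechanism; candidate for hypoxic-tumour applications."
  } else if (!dma && !pct && ct) {
    case <- "inactive"
    why <- "dark-cytotoxic only, no photoactivity on any level."
  } else if (!dma && !pct && !ct && uv) {
    case <- "case1_sun_protect_or_inert"
    why <- "UV-Vis spectrum evolves under irradiation without any toxicity: putative sun-protective action or photochemistry without biological relevance."
  } else {
    case <- "inactive"
    why <- "no singlet-oxygen production, no spectral change, no cytotoxicity in either arm."
  }

  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(ev)) ev$sample_id else NA_character_,
    case = case,
    rationale = paste0(why, note),
    rank_score = unname(DEFAULT_CASE_PRIORITY[case])
  )
  class(out) <- c("photoactivity_call", class(out))
  out
}

#' Detect evolution of a UV-Vis spectrum under irradiation
#'
#' Compares the first and last spectra of an irradiation series on a
#' common wavelength grid (linear interpolation over the overlapping
#' range when grids differ) and reports a change when the maximum
#' absolute OD difference exceeds `tolerance`.
#'
#' @param spectra data frame with columns `wavelength_nm`, `od` and
#'   `cumulative_dose_J_cm2` (>= 2 distinct doses), or a list of >= 2
#'   such two-column spectra ordered by dose.
#' @param tolerance OD change threshold (default 0.05).
#' @return logical: did the spectrum change?
#' @export
uv_vis_change <- function(spectra, tolerance = 0.05) {
  if (is.data.frame(spectra)) {
    doses <- sort(unique(spectra$cumulative_dose_J_cm2))
    if (length(doses) < 2) {
      stop("need spectra at >= 2 doses", call. = FALSE)
    }
    first <- spectra[spectra$cumulative_dose_J_cm2 == doses[1], ]
    last <- spectra[spectra$cumulative_dose_J_cm2 == doses[length(doses)], ]
  } else {
    if (length(spectra) < 2) stop("need >= 2 spectra", call. = FALSE)
    first <- spectra[[1]]
    last <- spectra[[length(spectra)]]
  }
  w0 <- first$wavelength_nm
  w1 <- last$wavelength_nm
  grid <- sort(unique(c(w0, w1)))
  grid <- grid[grid >= max(min(w0), min(w1)) & grid <= min(max(w0), max(w1))]
  if (!length(grid)) stop("spectra share no wavelength range", call. = FALSE)
  a0 <- if (length(w0) > 1) {
    stats::approx(w0, first$od, xout = grid)$y
  } else rep(first$od, length(grid))
  a1 <- if (length(w1) > 1) {
    stats::approx(w1, last$od, xout = grid)$y
  } else rep(last$od, length(grid))
  max(abs(a1 - a0)) > tolerance
}

#' Rank classified extracts by phototoxic potential
#'
#' Primary sort by case priority (PDT candidates first), ties broken by
#' selectivity index (descending; a censored lower bound sorts above an
#' equal point value) and then by DMA relative yield. Falls back to the
#' yield alone when no S.I. metadata is available.
#'
#' @param calls tibble of [classify()] outputs (one row per extract),
#'   optionally carrying `si`, `si_censored` and `relative_yield_pct`
#'   columns (joined from the evidence if present).
#' @param priority named numeric vector mapping cases to rank scores;
#'   larger ranks first. Default `DEFAULT_CASE_PRIORITY`.
#' @return the input tibble, ordered, with a `rank` column prepended.
#' @export
rank_extracts <- function(calls, priority = DEFAULT_CASE_PRIORITY) {
  stopifnot(nrow(calls) >= 1)
  score <- unname(priority[calls$case])
  si <- if ("si" %in% names(calls)) calls$si else rep(NA_real_, nrow(calls))
  si_c <- if ("si_censored" %in% names(calls)) {
    calls$si_censored
  } else rep(FALSE, nrow(calls))
  yld <- if ("relative_yield_pct" %in% names(calls)) {
    calls$relative_yield_pct
  } else rep(NA_real_, nrow(calls))
  si_key <- ifelse(is.na(si), -Inf, si + ifelse(si_c %in% TRUE, 1e-9, 0))
  yld_key <- ifelse(is.na(yld), -Inf, yld)
  ord <- order(-score, -si_key, -yld_key, calls$sample_id)
  out <- calls[ord, ]
  out <- tibble::as_tibble(cbind(rank = seq_len(nrow(out)), out))
  out
}
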