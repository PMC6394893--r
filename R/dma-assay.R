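## DMA singlet-oxygen assay scoring.
##
## 9,10-dimethylanthracene (DMA) is a selective 1O2 probe: the [4+2]
## photo-oxidation to the endoperoxide destroys its 377 nm band, so the
## drop in OD377 over the delivered light dose reports 1O2 production.
## Comparing a sample's DMA bleaching to that of a reference
## photosensitizer — after correcting each for the probability of
## absorbing the excitation light — yields a relative 1O2 score:
##
##   yield% = 100 * (dOD_s / dOD_ref) * (f_abs(A_ref) / f_abs(A_s)),
##   f_abs(A) = 1 - 10^(-A) at the irradiation wavelength.
##
## An ascorbate co-incubation (1O2 quencher) must suppress the bleaching
## for a positive call, and an extract-plus-ascorbate arm guards against
## direct extract/probe side reactions.

#' DMA assay configuration
#'
#' @param mode endpoint (default) uses OD377(0) - OD377(final dose);
#'   slope fits a least-squares line of OD377 against dose and reports
#'   -slope x final dose, which is more robust to read noise.
#' @param positivity_pct minimum relative yield (percent of reference)
#'   for a positive call (default 5, below which signals are treated as
#'   marginal).
#' @param quench_ratio_max maximum ascorbate/no-ascorbate bleaching
#'   ratio that still confirms the singlet-oxygen mechanism (default 0.5).
#' @param side_reaction_od maximum tolerated drift of the
#'   extract-plus-ascorbate control (OD units, default 0.02).
#' @param noise_floor_od OD differences at or below this magnitude are
#'   treated as zero signal (default 0.01).
#' @return list of class `dma_config`.
#' @export
dma_config <- function(mode = c("endpoint", "slope"), positivity_pct = 5,
                       quench_ratio_max = 0.5, side_reaction_od = 0.02,
                       noise_floor_od = 0.01) {
  mode <- match.arg(mode)
  stopifnot(positivity_pct >= 0, quench_ratio_max > 0,
            side_reaction_od >= 0, noise_floor_od >= 0)
  structure(list(mode = mode, positivity_pct = positivity_pct,
                 quench_ratio_max = quench_ratio_max,
                 side_reaction_od = side_reaction_od,
                 noise_floor_od = noise_floor_od),
            class = "dma_config")
}

#' Extract a replicate-aggregated DMA trajectory
#'
#' Collects the 377 nm readings of one sample/arm, averages replicates
#' per dose, and returns the OD377-versus-dose time course.
#'
#' @param ds a [plate_dataset()] (blank-corrected or raw).
#' @param sample_id sample to extract.
#' @param arm layout arm holding the trajectory (default `dma_probe`).
#' @param wavelength_nm probe wavelength (default 377).
#' @return tibble of class `dma_trajectory` with columns `dose`,
#'   `od`, `se`, `n`.
#' @export
dma_trajectory <- function(ds, sample_id, arm = "dma_probe",
                           wavelength_nm = 377) {
  stopifnot(inherits(ds, "plate_dataset"))
  wells <- ds$layout$well[ds$layout$sample_id == sample_id &
                            ds$layout$arm == arm]
  if (!length(wells)) {
    stop("no '", arm, "' wells for sample '", sample_id, "'", call. = FALSE)
  }
  rec <- ds$records[ds$records$well %in% wells &
                      ds$records$wavelength_nm == wavelength_nm, ]
  if (!nrow(rec)) {
    stop("no ", wavelength_nm, " nm readings for sample '", sample_id,
         "', arm '", arm, "'", call. = FALSE)
  }
  doses <- sort(unique(rec$cumulative_dose_J_cm2))
  agg <- lapply(doses, function(h) {
    v <- rec$od[rec$cumulative_dose_J_cm2 == h]
    n <- length(v)
    list(mean = mean(v), se = if (n > 1) stats::sd(v) / sqrt(n) else 0, n = n)
  })
  out <- tibble::tibble(
    dose = doses,
    od = vapply(agg, `[[`, numeric(1), "mean"),
    se = vapply(agg, `[[`, numeric(1), "se"),
    n = vapply(agg, `[[`, integer(1), "n")
  )
  structure(out, class = c("dma_trajectory", class(out)),
            sample_id = sample_id, arm = arm)
}

#' Absorbance drop of a DMA trajectory
#'
#' @param traj a [dma_trajectory()] or a data frame with `dose` and `od`.
#' @param mode `endpoint` (OD at dose 0 minus OD at the final dose) or
#'   `slope` (-least-squares slope x final dose).
#' @return list with `delta` (OD) and `se` (propagated from replicate
#'   SEs; endpoint mode only, 0 otherwise).
#' @export
delta_od <- function(traj, mode = c("endpoint", "slope")) {
  mode <- match.arg(mode)
  if (nrow(traj) < 2) stop("trajectory needs at least 2 points", call. = FALSE)
  ord <- order(traj$dose)
  dose <- traj$dose[ord]
  od <- traj$od[ord]
  se <- if ("se" %in% names(traj)) traj$se[ord] else rep(0, length(od))
  if (mode == "endpoint") {
    list(delta = od[1] - od[length(od)],
         se = sqrt(se[1]^2 + se[length(se)]^2))
  } else {
    fit <- stats::lm.fit(cbind(1, dose), od)
    list(delta = -fit$coefficients[[2]] * max(dose), se = 0)
  }
}

#' Pseudo-first-order bleaching rate of a trajectory
#'
#' Fits log(OD377) against dose by least squares and returns the decay
#' rate per J cm-2. Under exponential bleaching this recovers the rate
#' constant exactly on noise-free data, so rate ratios equal effective
#' quantum-yield ratios at matched absorbance — useful as a kinetics
#' diagnostic alongside the endpoint estimator.
#'
#' @param traj a [dma_trajectory()].
#' @return rate constant (per J cm-2).
#' @export
bleach_rate <- function(traj) {
  if (nrow(traj) < 2) stop("trajectory needs at least 2 points", call. = FALSE)
  if (any(traj$od <= 0)) {
    stop("bleach_rate requires strictly positive OD values", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, traj$dose), log(traj$od))
  -fit$coefficients[[2]]
}

#' Probability of absorption at the irradiation wavelength
#'
#' Beer-Lambert: a sample of absorbance A transmits 10^(-A) of the
#' incident light, so the fraction absorbed is 1 - 10^(-A).
#'
#' @param a_irr absorbance (OD) at the irradiation wavelength. Small
#'   negative values within `noise_floor` are clamped to 0.
#' @param noise_floor tolerated negative excursion (default 0.01 OD).
#' @return absorbed fraction in [0, 1).
#' @export
absorbed_fraction <- function(a_irr, noise_floor = 0.01) {
  if (any(a_irr < -noise_floor)) {
    stop("negative absorbance beyond the noise floor: ", min(a_irr),
         call. = FALSE)
  }
  a_irr <- pmax(a_irr, 0)
  1 - 10^(-a_irr)
}

#' Relative singlet-oxygen yield against a reference photosensitizer
#'
#' Scores a sample's DMA bleaching against the reference, each corrected
#' by its probability of absorbing the excitation light:
#' `100 * (delta_s / delta_ref) * (f_abs(a_ref) / f_abs(a_s))`. A
#' transparent sample (`a_s = 0`) with no bleaching scores 0; a
#' transparent sample that nevertheless bleaches DMA is physically
#' inconsistent and is flagged.
#'
#' @param delta_s,a_s sample DMA drop (OD) and absorbance at the
#'   irradiation wavelength.
#' @param delta_ref,a_ref same quantities for the reference PS;
#'   `delta_ref` must be positive (a reference that bleaches no DMA is
#'   invalid) and `a_ref` positive.
#' @param se_delta_s,se_a_s,se_delta_ref,se_a_ref optional standard
#'   errors; the yield SE is propagated to first order (delta method).
#' @return list with `yield_pct`, `se_pct`, `inconsistent`.
#' @export
relative_yield <- function(delta_s, a_s, delta_ref, a_ref,
                           se_delta_s = 0, se_a_s = 0,
                           se_delta_ref = 0, se_a_ref = 0) {
  if (delta_ref <= 0) {
    stop("reference delta OD must be positive", call. = FALSE)
  }
  if (a_ref <= 0) {
    stop("reference absorbance at the irradiation wavelength must be positive",
         call. = FALSE)
  }
  f_ref <- absorbed_fraction(a_ref)
  if (a_s <= 0) {
    if (abs(delta_s) <= .Machine$double.eps^0.5 || delta_s == 0) {
      return(list(yield_pct = 0, se_pct = 0, inconsistent = FALSE))
    }
    return(list(yield_pct = NA_real_, se_pct = NA_real_, inconsistent = TRUE))
  }
  f_s <- absorbed_fraction(a_s)
  y <- 100 * (delta_s / delta_ref) * (f_ref / f_s)

  # d log f / dA = ln(10) 10^-A / (1 - 10^-A)
  g <- function(a) log(10) * 10^(-a) / (1 - 10^(-a))
  rel_var <- 0
  if (delta_s != 0) rel_var <- rel_var + (se_delta_s / delta_s)^2
  rel_var <- rel_var + (se_delta_ref / delta_ref)^2 +
    (g(a_s) * se_a_s)^2 + (g(a_ref) * se_a_ref)^2
  list(yield_pct = y, se_pct = abs(y) * sqrt(rel_var), inconsistent = FALSE)
}

#' Evaluate the quencher and side-reaction controls
#'
#' The ascorbate co-incubation must suppress DMA bleaching for the
#' singlet-oxygen mechanism to be confirmed; the extract-plus-ascorbate
#' arm must stay flat, otherwise the extract reacts with the probe (or
#' the quencher) directly and the readout is unreliable.
#'
#' @param without_q DMA drop without quencher (OD).
#' @param with_q DMA drop with ascorbate (OD).
#' @param extract_plus_q_drift maximum absolute OD drift of the
#'   extract-plus-ascorbate control.
#' @param config a [dma_config()].
#' @return list with `quench_ratio`, `quench_confirmed`,
#'   `side_reaction_flag`.
#' @export
validate_controls <- function(without_q, with_q, extract_plus_q_drift,
                              config = dma_config()) {
  if (without_q <= config$noise_floor_od) {
    ratio <- 1 # no signal to quench; ratio is undefined, treated as unquenched
  } else {
    ratio <- with_q / without_q
  }
  list(
    quench_ratio = ratio,
    quench_confirmed = ratio <= config$quench_ratio_max,
    side_reaction_flag = extract_plus_q_drift > config$side_reaction_od
  )
}

## maximum |OD(t) - OD(0)| over a control trajectory
control_drift <- function(traj) {
  max(abs(traj$od - traj$od[which.min(traj$dose)]))
}

#' Score one extract on a DMA plate
#'
#' Runs the full per-extract evaluation: blank correction (if not yet
#' applied), endpoint/slope DMA drop for the probe and quencher arms,
#' subtraction of the solvent-control drop (direct DMA photobleaching
#' baseline), absorbance of the extract alone at the irradiation
#' wavelength, the relative yield against the plate's reference PS, and
#' the control verdicts. A sample is called DMA-positive when its
#' solvent-corrected relative yield reaches the positivity threshold
#' and the ascorbate quench confirms the mechanism.
#'
#' @param ds a [plate_dataset()] containing, for `sample_id`, the
#'   `dma_probe`, `extract_alone`, `dma_plus_quencher` and
#'   `extract_plus_quencher` arms, plus `reference_ps` and
#'   `solvent_control` wells.
#' @param sample_id sample to score.
#' @param config a [dma_config()].
#' @param wavelength_irr irradiation wavelength for the absorbed-fraction
#'   lookup (default 468 nm).
#' @return one-row tibble (class `dma_result`) with columns
#'   `sample_id, delta_od377, a_irr, absorbed_fraction,
#'   relative_yield_pct, relative_yield_se, quench_ratio,
#'   quench_confirmed, side_reaction, dma_positive`.
#' @export
score_extract <- function(ds, sample_id, config = dma_config(),
                          wavelength_irr = 468) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (!isTRUE(ds$blank_corrected)) ds <- blank_correct(ds)

  lay <- ds$layout
  ref_ids <- unique(lay$sample_id[lay$arm == "reference_ps"])
  if (!length(ref_ids)) stop("plate has no reference_ps wells", call. = FALSE)
  ref_id <- ref_ids[1]
  solv_ids <- unique(lay$sample_id[lay$arm == "solvent_control"])
  if (!length(solv_ids)) stop("plate has no solvent_control wells", call. = FALSE)

  is_ref <- identical(sample_id, ref_id)
  probe_arm <- if (is_ref) "reference_ps" else "dma_probe"

  need <- c(probe_arm, "extract_alone", "dma_plus_quencher",
            "extract_plus_quencher")
  have <- lay$arm[lay$sample_id == sample_id]
  missing_arm <- setdiff(need, have)
  if (length(missing_arm)) {
    stop("sample '", sample_id, "' is missing arm(s): ",
         paste(missing_arm, collapse = ", "), call. = FALSE)
  }

  traj_probe <- dma_trajectory(ds, sample_id, probe_arm)
  traj_quench <- dma_trajectory(ds, sample_id, "dma_plus_quencher")
  traj_side <- dma_trajectory(ds, sample_id, "extract_plus_quencher")
  traj_solv <- dma_trajectory(ds, solv_ids[1], "solvent_control")
  traj_ref <- dma_trajectory(ds, ref_id, "reference_ps")

  d_probe <- delta_od(traj_probe, config$mode)
  d_quench <- delta_od(traj_quench, config$mode)
  d_solv <- delta_od(traj_solv, config$mode)
  d_ref <- delta_od(traj_ref, config$mode)

  # solvent-control subtraction: remove direct DMA photobleaching
  delta_s <- d_probe$delta - d_solv$delta
  se_delta_s <- sqrt(d_probe$se^2 + d_solv$se^2)
  delta_r <- d_ref$delta - d_solv$delta
  se_delta_r <- sqrt(d_ref$se^2 + d_solv$se^2)
  if (delta_r <= 0) {
    stop("reference PS shows no DMA bleaching above the solvent control",
         call. = FALSE)
  }

  a_sample <- extract_absorbance(ds, sample_id, wavelength_irr)
  a_ref <- extract_absorbance(ds, ref_id, wavelength_irr)

  # a drop within the noise floor is no signal: score it as exactly zero
  small <- abs(delta_s) <= config$noise_floor_od
  yl <- relative_yield(
    if (small) 0 else delta_s,
    max(a_sample$mean, 0), delta_r, a_ref$mean,
    se_delta_s = se_delta_s, se_a_s = a_sample$se,
    se_delta_ref = se_delta_r, se_a_ref = a_ref$se
  )

  ctl <- validate_controls(delta_s, d_quench$delta - d_solv$delta,
                           control_drift(traj_side), config)

  positive <- !is.na(yl$yield_pct) &&
    yl$yield_pct >= config$positivity_pct && ctl$quench_confirmed

  out <- tibble::tibble(
    sample_id = sample_id,
    delta_od377 = delta_s,
    a_irr = a_sample$mean,
    absorbed_fraction = absorbed_fraction(max(a_sample$mean, 0)),
    relative_yield_pct = yl$yield_pct,
    relative_yield_se = yl$se_pct,
    quench_ratio = ctl$quench_ratio,
    quench_confirmed = ctl$quench_confirmed,
    side_reaction = ctl$side_reaction_flag,
    dma_positive = positive
  )
  class(out) <- c("dma_result", class(out))
  out
}

## replicate-aggregated absorbance of the extract alone at a wavelength
## (dose-0 reading)
extract_absorbance <- function(ds, sample_id, wavelength_nm) {
  arm <- if (any(ds$layout$sample_id == sample_id &
                   ds$layout$arm == "extract_alone")) {
    "extract_alone"
  } else {
    stop("no extract_alone wells for sample '", sample_id, "'", call. = FALSE)
  }
  wells <- ds$layout$well[ds$layout$sample_id == sample_id &
                            ds$layout$arm == arm]
  rec <- ds$records[ds$records$well %in% wells &
                      ds$records$wavelength_nm == wavelength_nm, ]
  if (!nrow(rec)) {
    stop("no ", wavelength_nm, " nm extract-alone readings for '",
         sample_id, "'", call. = FALSE)
  }
  rec <- rec[rec$cumulative_dose_J_cm2 == min(rec$cumulative_dose_J_cm2), ]
  v <- rec$od
  list(mean = mean(v),
       se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
}

#' Score every extract on a DMA plate
#'
#' Applies [score_extract()] to each sample that carries a probe arm
#' (including the reference PS, which scores 100% by construction).
#'
#' @inheritParams score_extract
#' @return tibble with one row per sample (see [score_extract()]).
#' @export
score_plate <- function(ds, config = dma_config(), wavelength_irr = 468) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (!isTRUE(ds$blank_corrected)) ds <- blank_correct(ds)
  ids <- unique(ds$layout$sample_id[ds$layout$arm %in%
                                      c("dma_probe", "reference_ps")])
  out <- lapply(ids, function(s) score_extract(ds, s, config, wavelength_irr))
  do.call(rbind, out)
}
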