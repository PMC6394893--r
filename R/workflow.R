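## Orchestration of the three sub-assays into one screen: dosimetry
## checks -> DMA scoring -> photo-cytotoxicity fits -> classification
## and ranking. The conclusion is drawn from the combined evidence; the
## order of the sub-assays is not fixed, so DMA-only runs are allowed
## and reported as incomplete.

#' Default pipeline configuration
#'
#' Flat key-value configuration covering every module threshold; it
#' round-trips unchanged through [write_config()] / [read_config()].
#'
#' @param layout_csv,readings_csv paths to the DMA plate CSVs
#'   (see [read_plate()]); may be `NA` when a plate object is passed to
#'   [run_screen()] directly.
#' @param dose_response_csv optional path to the SRB dose-response CSV
#'   (`sample_id,cell_line,arm,concentration_ug_per_ml,replicate,viability_pct`).
#' @param actinometry_csv optional path to an actinometry CSV
#'   (`well,moles_fe2,exposure_s,area_cm2`) for the homogeneity check.
#' @param wavelength_nm,bandwidth_nm,irradiance_mw_cm2,step_seconds
#'   irradiation schedule (see [irradiation_schedule()]).
#' @param dma_mode,dma_positivity_pct,dma_quench_ratio_max,dma_side_reaction_od,dma_noise_floor_od
#'   DMA thresholds (see [dma_config()]).
#' @param cytotox_activity_cap,cytotox_n_boot,cytotox_min_effect,si_threshold
#'   photo-cytotoxicity settings (see [fit_4pl()], [selectivity()]).
#' @param uv_tolerance OD threshold for [uv_vis_change()].
#' @param homogeneity_cv_max CV threshold for [homogeneity_report()].
#' @param actinometry_quantum_yield ferrioxalate quantum yield.
#' @param seed RNG seed for the bootstrap.
#' @param out_dir output directory for the stage CSVs and report.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(layout_csv = NA_character_,
                           readings_csv = NA_character_,
                           dose_response_csv = NA_character_,
                           actinometry_csv = NA_character_,
                           wavelength_nm = 468, bandwidth_nm = 27.3,
                           irradiance_mw_cm2 = 20.6,
                           step_seconds = rep(300, 4),
                           dma_mode = "endpoint", dma_positivity_pct = 5,
                           dma_quench_ratio_max = 0.5,
                           dma_side_reaction_od = 0.02,
                           dma_noise_floor_od = 0.01,
                           cytotox_activity_cap = 50, cytotox_n_boot = 1000,
                           cytotox_min_effect = 25, si_threshold = 2,
                           uv_tolerance = 0.05, homogeneity_cv_max = 0.10,
                           actinometry_quantum_yield = 0.9,
                           seed = 1, out_dir = NA_character_) {
  cfg <- list(
    layout_csv = layout_csv, readings_csv = readings_csv,
    dose_response_csv = dose_response_csv, actinometry_csv = actinometry_csv,
    wavelength_nm = wavelength_nm, bandwidth_nm = bandwidth_nm,
    irradiance_mw_cm2 = irradiance_mw_cm2,
    step_seconds = as.numeric(step_seconds),
    dma_mode = dma_mode, dma_positivity_pct = dma_positivity_pct,
    dma_quench_ratio_max = dma_quench_ratio_max,
    dma_side_reaction_od = dma_side_reaction_od,
    dma_noise_floor_od = dma_noise_floor_od,
    cytotox_activity_cap = cytotox_activity_cap,
    cytotox_n_boot = cytotox_n_boot,
    cytotox_min_effect = cytotox_min_effect,
    si_threshold = si_threshold, uv_tolerance = uv_tolerance,
    homogeneity_cv_max = homogeneity_cv_max,
    actinometry_quantum_yield = actinometry_quantum_yield,
    seed = as.integer(seed), out_dir = out_dir
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$irradiance_mw_cm2 > 0, all(cfg$step_seconds > 0),
    cfg$dma_mode %in% c("endpoint", "slope"),
    cfg$dma_positivity_pct >= 0, cfg$dma_quench_ratio_max > 0,
    cfg$dma_side_reaction_od >= 0, cfg$dma_noise_floor_od >= 0,
    cfg$cytotox_activity_cap > 0, cfg$cytotox_n_boot >= 0,
    cfg$cytotox_min_effect >= 0, cfg$si_threshold > 0,
    cfg$uv_tolerance > 0, cfg$homogeneity_cv_max > 0,
    cfg$actinometry_quantum_yield > 0
  )
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [default_config()] list.
#' @param path YAML file path.
#' @return `read_config()` returns the `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  cfg$step_seconds <- as.numeric(cfg$step_seconds)
  cfg$seed <- as.integer(cfg$seed)
  cfg[vapply(cfg, is.null, logical(1))] <- NA_character_
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

schedule_from_config <- function(cfg) {
  irradiation_schedule(cfg$wavelength_nm, cfg$bandwidth_nm,
                       cfg$irradiance_mw_cm2, cfg$step_seconds)
}

dma_config_from <- function(cfg) {
  dma_config(mode = cfg$dma_mode, positivity_pct = cfg$dma_positivity_pct,
             quench_ratio_max = cfg$dma_quench_ratio_max,
             side_reaction_od = cfg$dma_side_reaction_od,
             noise_floor_od = cfg$dma_noise_floor_od)
}

## UV-Vis change verdict per sample from the extract-alone records
uv_evidence <- function(ds, sample_ids, tolerance) {
  vapply(sample_ids, function(s) {
    wells <- ds$layout$well[ds$layout$sample_id == s &
                              ds$layout$arm == "extract_alone"]
    rec <- ds$records[ds$records$well %in% wells, ]
    if (!nrow(rec) || length(unique(rec$cumulative_dose_J_cm2)) < 2) {
      return(NA)
    }
    agg <- stats::aggregate(
      od ~ wavelength_nm + cumulative_dose_J_cm2, data = rec, FUN = mean)
    uv_vis_change(agg, tolerance = tolerance)
  }, logical(1))
}

#' Run the full screening pipeline
#'
#' Executes dosimetry checks (when actinometry data are supplied), DMA
#' scoring, photo-cytotoxicity fitting (when dose-response data are
#' supplied), classification and ranking. Stage tables are written as
#' CSVs under `cfg$out_dir` together with a ranked Markdown report and
#' a log recording the configuration and seed; the run is deterministic
#' under a fixed seed. Without dose-response data, extracts are
#' reported with status `incomplete: cytotoxicity pending` and no case
#' is assigned.
#'
#' @param cfg a [default_config()] list (or path to a YAML written by
#'   [write_config()]).
#' @param plate optional [plate_dataset()], overriding the CSV paths in
#'   the config.
#' @param dose_response optional dose-response data frame, overriding
#'   `cfg$dose_response_csv`.
#' @return list with elements `dma`, `cytotox` (or `NULL`), `report`,
#'   `homogeneity` (or `NULL`), invisibly. Side effect: files under
#'   `cfg$out_dir` when set.
#' @export
run_screen <- function(cfg = default_config(), plate = NULL,
                       dose_response = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  schedule <- schedule_from_config(cfg)

  log_lines <- c(
    paste0("photoscreen ", as.character(utils::packageVersion("photoscreen"))),
    paste0("seed: ", cfg$seed),
    paste0("schedule: ", cfg$wavelength_nm, " nm, ", cfg$irradiance_mw_cm2,
           " mW cm-2, total dose ",
           format_dose(cumulative_dose(schedule)), " J cm-2"),
    paste0("note: the relative-yield formula applies the absorbed-fraction ",
           "correction 1 - 10^(-A) to sample and reference alike")
  )

  # --- dosimetry stage -------------------------------------------------
  homog <- NULL
  if (!is.na(cfg$actinometry_csv) && nzchar(cfg$actinometry_csv)) {
    act <- utils::read.csv(cfg$actinometry_csv,
                           colClasses = c(well = "character"))
    irr <- irradiance_from_actinometry(
      act$moles_fe2, act$exposure_s, act$area_cm2,
      quantum_yield = cfg$actinometry_quantum_yield,
      wavelength_nm = cfg$wavelength_nm)
    doses <- irr / 1000 * sum(cfg$step_seconds)
    names(doses) <- act$well
    homog <- homogeneity_report(doses, cv_threshold = cfg$homogeneity_cv_max)
    log_lines <- c(log_lines, paste0(
      "homogeneity: mean ", format_dose(homog$mean), " J cm-2, CV ",
      signif(100 * homog$cv, 3), "% -> ",
      if (homog$pass) "pass" else "FAIL"))
  }

  # --- DMA stage -------------------------------------------------------
  if (is.null(plate)) {
    if (is.na(cfg$layout_csv) || is.na(cfg$readings_csv)) {
      stop("run_screen needs a plate dataset or layout/readings CSV paths",
           call. = FALSE)
    }
    plate <- read_plate(cfg$layout_csv, cfg$readings_csv, schedule = schedule)
  }
  plate <- blank_correct(plate)
  dma <- tryCatch(
    score_plate(plate, dma_config_from(cfg),
                wavelength_irr = cfg$wavelength_nm),
    error = function(e) stop("DMA stage failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  uv <- uv_evidence(plate, dma$sample_id, cfg$uv_tolerance)

  # --- photo-cytotoxicity stage ---------------------------------------
  cyto <- NULL
  if (is.null(dose_response) && !is.na(cfg$dose_response_csv) &&
        nzchar(cfg$dose_response_csv)) {
    dose_response <- utils::read.csv(cfg$dose_response_csv)
  }
  if (!is.null(dose_response)) {
    cyto <- tryCatch(
      fit_dose_response_table(
        dose_response, n_boot = cfg$cytotox_n_boot, seed = cfg$seed,
        activity_cap = cfg$cytotox_activity_cap,
        min_effect = cfg$cytotox_min_effect,
        si_threshold = cfg$si_threshold),
      error = function(e) stop("photo-cytotoxicity stage failed: ",
                               conditionMessage(e), call. = FALSE)
    )
  }

  # --- classification --------------------------------------------------
  extract_ids <- setdiff(dma$sample_id,
                         unique(plate$layout$sample_id[
                           plate$layout$arm == "reference_ps"]))
  rows <- lapply(extract_ids, function(s) {
    d <- dma[dma$sample_id == s, ]
    cy <- if (!is.null(cyto)) cyto[cyto$sample_id == s, ] else NULL
    complete <- !is.null(cy) && nrow(cy) >= 1
    ev <- evidence_vector(
      s, dma_positive = d$dma_positive, quench_confirmed = d$quench_confirmed,
      uv_vis_change = isTRUE(uv[[s]]),
      ct_positive = complete && any(cy$active_dark),
      pct_positive = complete && any(cy$active_irr),
      si = if (complete) max(cy$si, na.rm = FALSE) else NA_real_,
      si_censored = complete && any(cy$si_censored %in% TRUE),
      relative_yield_pct = d$relative_yield_pct
    )
    call <- classify(ev)
    tibble::tibble(
      sample_id = s,
      case = if (complete) call$case else NA_character_,
      rationale = if (complete) call$rationale else
        "incomplete: cytotoxicity pending",
      status = if (complete) "complete" else "incomplete: cytotoxicity pending",
      si = ev$si, si_censored = ev$si_censored,
      relative_yield_pct = d$relative_yield_pct,
      dma_positive = d$dma_positive, uv_vis_change = ev$uv_vis_change,
      ct_positive = ev$ct_positive, pct_positive = ev$pct_positive
    )
  })
  report <- do.call(rbind, rows)
  if (all(report$status == "complete")) {
    report <- rank_extracts(report)
  } else {
    report <- tibble::as_tibble(cbind(rank = NA_integer_, report))
  }

  # --- outputs ---------------------------------------------------------
  if (!is.na(cfg$out_dir) && nzchar(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dma, file.path(cfg$out_dir, "dma_results.csv"),
                     row.names = FALSE)
    if (!is.null(cyto)) {
      utils::write.csv(cyto, file.path(cfg$out_dir, "cytotox_results.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(report, file.path(cfg$out_dir, "screen_report.csv"),
                     row.names = FALSE)
    writeLines(report_markdown(report, log_lines),
               file.path(cfg$out_dir, "screen_report.md"))
    writeLines(c(log_lines, paste0("config: ", names(unclass(cfg)), " = ",
                                   vapply(unclass(cfg), function(x)
                                     paste(x, collapse = ","), character(1)))),
               file.path(cfg$out_dir, "screen_log.txt"))
  }

  invisible(list(dma = dma, cytotox = cyto, report = report,
                 homogeneity = homog))
}

report_markdown <- function(report, header_lines) {
  out <- c("# Phototoxicity screen report", "",
           paste0("> ", header_lines), "")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    out <- c(out,
      paste0("## ", if (!is.na(r$rank)) paste0(r$rank, ". ") else "",
             r$sample_id),
      paste0("- case: ", ifelse(is.na(r$case), "(not assigned)", r$case)),
      paste0("- status: ", r$status),
      paste0("- DMA relative yield: ", signif(r$relative_yield_pct, 3), "%"),
      paste0("- S.I.: ", if (is.na(r$si)) "n/a" else
        paste0(if (isTRUE(r$si_censored)) "> " else "", signif(r$si, 3))),
      paste0("- rationale: ", r$rationale), "")
  }
  out
}
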