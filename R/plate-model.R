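## Plate data model: layout + long-format absorbance records, read/write,
## blank correction. Everything downstream (DMA scoring, UV-Vis change)
## consumes a `plate_dataset`.

#' Construct a plate dataset
#'
#' Bundles a plate layout (wells, sample assignments, assay arms) with
#' long-format absorbance records and, optionally, the irradiation
#' schedule under which the plate was exposed. All structural invariants
#' are checked: well coordinates within the 8 x 12 grid, unique layout
#' rows, referential integrity of records, monotone dose series, and —
#' when DMA-probe wells are present — 377 nm readings at dose zero and
#' at the final cumulative dose for every probe well.
#'
#' @param layout data frame with columns `well`, `sample_id`, `arm`,
#'   `concentration_ug_per_ml`, `replicate`.
#' @param records data frame with columns `well`, `wavelength_nm`,
#'   `cumulative_dose_J_cm2`, `od`.
#' @param schedule optional [irradiation_schedule()].
#' @param plate_id plate identifier carried through to reports.
#' @return an object of class `plate_dataset`.
#' @seealso [read_plate()], [blank_correct()], [simulate_dma_plate()]
#' @export
plate_dataset <- function(layout, records, schedule = NULL, plate_id = "plate-1") {
  layout <- tibble::as_tibble(layout)
  records <- tibble::as_tibble(records)

  need_l <- c("well", "sample_id", "arm", "concentration_ug_per_ml", "replicate")
  need_r <- c("well", "wavelength_nm", "cumulative_dose_J_cm2", "od")
  if (!all(need_l %in% names(layout))) {
    stop("layout is missing column(s): ",
         paste(setdiff(need_l, names(layout)), collapse = ", "), call. = FALSE)
  }
  if (!all(need_r %in% names(records))) {
    stop("records are missing column(s): ",
         paste(setdiff(need_r, names(records)), collapse = ", "), call. = FALSE)
  }

  check_wells(layout$well)
  if (anyDuplicated(layout$well)) {
    stop("duplicate well(s) in layout: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(layout$arm), WELL_ARMS)
  if (length(bad_arm)) {
    stop("unknown arm(s): ", paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  layout$replicate <- as.integer(layout$replicate)
  if (any(is.na(layout$replicate) | layout$replicate < 1L)) {
    stop("replicate must be an integer >= 1", call. = FALSE)
  }
  cyto <- layout$arm %in% c("cytotox_dark", "cytotox_irradiated")
  conc <- suppressWarnings(as.numeric(layout$concentration_ug_per_ml))
  if (any(cyto & (is.na(conc) | conc <= 0))) {
    stop("cytotox wells require a positive concentration_ug_per_ml", call. = FALSE)
  }
  layout$concentration_ug_per_ml <- conc

  check_wells(records$well)
  orphan <- setdiff(unique(records$well), layout$well)
  if (length(orphan)) {
    stop("record(s) reference well(s) absent from layout: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(records$wavelength_nm < 200 | records$wavelength_nm > 1000)) {
    stop("wavelength_nm out of range [200, 1000]", call. = FALSE)
  }
  if (any(records$cumulative_dose_J_cm2 < 0)) {
    stop("cumulative_dose_J_cm2 must be >= 0", call. = FALSE)
  }
  dup <- duplicated(records[, c("well", "wavelength_nm", "cumulative_dose_J_cm2")])
  if (any(dup)) {
    stop("duplicate dose entries for well/wavelength: ",
         paste(unique(records$well[dup]), collapse = ", "), call. = FALSE)
  }

  records <- records[order(records$well, records$wavelength_nm,
                           records$cumulative_dose_J_cm2), ]

  probe <- layout$well[layout$arm %in% c("dma_probe", "reference_ps",
                                         "dma_plus_quencher")]
  if (length(probe)) {
    r377 <- records[records$wavelength_nm == 377 & records$well %in% probe, ]
    hmax <- max(records$cumulative_dose_J_cm2)
    for (w in probe) {
      d <- r377$cumulative_dose_J_cm2[r377$well == w]
      if (!length(d) || min(d) > 0 || max(d) < hmax) {
        stop("DMA-probe well ", w,
             " lacks 377 nm readings at dose 0 and the final dose", call. = FALSE)
      }
    }
  }

  structure(
    list(plate_id = plate_id, layout = layout, records = records,
         schedule = schedule, blank_corrected = FALSE),
    class = "plate_dataset"
  )
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat("<plate_dataset> ", x$plate_id, ": ", nrow(x$layout), " wells, ",
      nrow(x$records), " records",
      if (isTRUE(x$blank_corrected)) " (blank-corrected)", "\n", sep = "")
  arms <- table(x$layout$arm)
  cat("  arms:", paste(names(arms), arms, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a plate dataset from layout and readings CSV files
#'
#' Both files are UTF-8 CSV with a mandatory header and `.` decimal
#' separator. The layout file has columns
#' `well,sample_id,arm,concentration_ug_per_ml,replicate` (concentration
#' may be empty); the readings file has
#' `well,wavelength_nm,cumulative_dose_J_cm2,od`, one row per reading.
#'
#' @param layout_path,readings_path paths to the CSV files.
#' @param schedule optional [irradiation_schedule()] to attach.
#' @param plate_id plate identifier; defaults to the layout file name.
#' @return a validated [plate_dataset()].
#' @export
read_plate <- function(layout_path, readings_path, schedule = NULL,
                       plate_id = NULL) {
  for (p in c(layout_path, readings_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  layout <- utils::read.csv(layout_path, colClasses = c(
    well = "character", sample_id = "character", arm = "character"))
  records <- utils::read.csv(readings_path, colClasses = c(well = "character"))
  if (is.null(plate_id)) {
    plate_id <- sub("\\.csv$", "", basename(layout_path))
  }
  plate_dataset(layout, records, schedule = schedule, plate_id = plate_id)
}

#' Write a plate dataset to layout and readings CSV files
#'
#' Inverse of [read_plate()]; the files round-trip through `read_plate()`
#' unchanged.
#'
#' @param ds a [plate_dataset()].
#' @param layout_path,readings_path output paths.
#' @return `ds`, invisibly.
#' @export
write_plate <- function(ds, layout_path, readings_path) {
  stopifnot(inherits(ds, "plate_dataset"))
  utils::write.csv(ds$layout, layout_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$records, readings_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Blank-correct absorbance records
#'
#' Subtracts, from every non-blank record, the mean optical density of
#' the blank wells at the same wavelength and dose step, then removes
#' the blank wells from the dataset. Negative corrected ODs are kept
#' (they carry noise information) but wells dipping below `floor` are
#' flagged in the `flag_low_od` column. Without any blank wells the
#' dataset is returned unchanged with a warning. Applying the correction
#' twice is a no-op since the blanks are consumed by the first pass.
#'
#' @param ds a [plate_dataset()].
#' @param floor OD below which a corrected reading is flagged
#'   (default -0.01).
#' @return the corrected `plate_dataset`.
#' @export
blank_correct <- function(ds, floor = -0.01) {
  stopifnot(inherits(ds, "plate_dataset"))
  blanks <- ds$layout$well[ds$layout$arm == "blank"]
  if (!length(blanks)) {
    if (!isTRUE(ds$blank_corrected)) {
      warning("no blank wells present; dataset returned unchanged", call. = FALSE)
    }
    return(ds)
  }
  rec <- ds$records
  is_blank <- rec$well %in% blanks
  key <- paste(rec$wavelength_nm, rec$cumulative_dose_J_cm2, sep = "@")
  blank_mean <- tapply(rec$od[is_blank], key[is_blank], mean)
  adj <- blank_mean[key]
  adj[is.na(adj)] <- 0
  rec$od <- rec$od - as.numeric(adj)
  rec <- rec[!is_blank, , drop = FALSE]
  rec$flag_low_od <- rec$od < floor

  ds$records <- tibble::as_tibble(rec)
  ds$layout <- ds$layout[ds$layout$arm != "blank", , drop = FALSE]
  ds$blank_corrected <- TRUE
  ds
}
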