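# Hand-written 6-well plate used by the plate-model tests:
# one sample with all four DMA arms plus solvent control and blank,
# 377 nm readings at two doses (24 records total with the 468 nm rows).
tiny_layout <- function() {
  tibble::tibble(
    well = c("A1", "A2", "A3", "A4", "A5", "A6"),
    sample_id = c("ext1", "ext1", "ext1", "ext1", "solvent", "blank"),
    arm = c("dma_probe", "extract_alone", "dma_plus_quencher",
            "extract_plus_quencher", "solvent_control", "blank"),
    concentration_ug_per_ml = NA_real_,
    replicate = 1L
  )
}

tiny_records <- function() {
  doses <- c(0, 24.7)
  grid <- expand.grid(well = c("A1", "A3", "A4", "A5", "A6"),
                      cumulative_dose_J_cm2 = doses,
                      stringsAsFactors = FALSE)
  od377 <- c(A1 = 0.40, A3 = 0.40, A4 = 0.02, A5 = 0.40, A6 = 0.05)
  drop <- c(A1 = 0.20, A3 = 0.02, A4 = 0.00, A5 = 0.01, A6 = 0.00)
  r377 <- tibble::tibble(
    well = grid$well, wavelength_nm = 377,
    cumulative_dose_J_cm2 = grid$cumulative_dose_J_cm2,
    od = unname(od377[grid$well] - drop[grid$well] *
                  (grid$cumulative_dose_J_cm2 > 0))
  )
  d468 <- c(0, 6.2, 12.4, 24.7)
  r468 <- tibble::tibble(
    well = rep(c("A2", "A6"), each = 4), wavelength_nm = 468,
    cumulative_dose_J_cm2 = rep(d468, 2),
    od = c(rep(0.30, 4), rep(0.00, 4))
  )
  # pad the probe wells with intermediate doses so trajectories have
  # more than two points where useful
  mid <- tibble::tibble(
    well = rep(c("A1", "A5"), each = 3), wavelength_nm = 377,
    cumulative_dose_J_cm2 = rep(c(6.2, 12.4, 18.5), 2),
    od = c(0.35, 0.30, 0.25, 0.3975, 0.395, 0.3925)
  )
  rbind(r377, r468, mid)
}

tiny_plate <- function() {
  plate_dataset(tiny_layout(), tiny_records(),
                schedule = irradiation_schedule(), plate_id = "tiny")
}

write_tiny_csvs <- function(dir = tempfile("plate")) {
  dir.create(dir, showWarnings = FALSE)
  lp <- file.path(dir, "layout.csv")
  rp <- file.path(dir, "readings.csv")
  utils::write.csv(tiny_layout(), lp, row.names = FALSE, quote = FALSE)
  utils::write.csv(tiny_records(), rp, row.names = FALSE, quote = FALSE)
  list(layout = lp, readings = rp)
}
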