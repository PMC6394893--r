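#' @keywords internal
"_PACKAGE"

## Shared helpers: well-coordinate handling, replicate aggregation,
## unit conversions used across the assay modules.

WELL_ARMS <- c(
  "dma_probe", "extract_alone", "dma_plus_quencher", "extract_plus_quencher",
  "solvent_control", "reference_ps", "cytotox_dark", "cytotox_irradiated",
  "untreated_control", "blank"
)

#' Validate 96-well plate coordinates
#'
#' Coordinates are letter+number, rows A-H and columns 1-12 (no zero
#' padding, so `"A1"` not `"A01"`).
#'
#' @param well character vector of well labels.
#' @return `well`, invisibly, if all labels are valid.
#' @examples
#' check_wells(c("A1", "H12"))
#' @export
check_wells <- function(well) {
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (!all(ok)) {
    stop("malformed well coordinate(s): ", paste(unique(well[!ok]), collapse = ", "),
         " (expected A1..H12)", call. = FALSE)
  }
  invisible(well)
}

well_row <- function(well) match(substr(well, 1, 1), LETTERS[1:8])
well_col <- function(well) as.integer(substring(well, 2))

#' Aggregate replicate measurements
#'
#' Returns the mean, standard error (sd/sqrt(n)) and n of a set of
#' replicate values. A single replicate yields SE = 0 with a warning,
#' so downstream error propagation degrades gracefully.
#'
#' @param values numeric vector of replicate measurements.
#' @return list with elements `mean`, `se`, `n`.
#' @examples
#' aggregate_replicates(c(1, 2, 3))
#' @export
aggregate_replicates <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("no replicate values to aggregate", call. = FALSE)
  if (n == 1L) {
    warning("single replicate: standard error reported as 0", call. = FALSE)
    return(list(mean = values, se = 0, n = 1L))
  }
  list(mean = mean(values), se = stats::sd(values) / sqrt(n), n = n)
}

#' Convert a mass concentration to molarity
#'
#' @param conc_ug_per_ml concentration in micrograms per millilitre.
#' @param molar_mass molar mass in g per mol.
#' @return concentration in micromolar (umol per litre).
#' @examples
#' mass_to_molar(50, 336.36) # berberine at 50 ug/mL
#' @export
mass_to_molar <- function(conc_ug_per_ml, molar_mass) {
  stopifnot(conc_ug_per_ml >= 0, molar_mass > 0)
  conc_ug_per_ml / molar_mass * 1000
}

#' Percent by volume of a mixture component
#'
#' @param volume_component,volume_total volumes in the same unit.
#' @return percentage of the total volume.
#' @examples
#' percent_by_volume(10, 200) # 10 uL DMSO in a 200 uL well -> 5 %
#' @export
percent_by_volume <- function(volume_component, volume_total) {
  stopifnot(volume_component >= 0, volume_total > 0,
            volume_component <= volume_total)
  100 * volume_component / volume_total
}

## run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
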