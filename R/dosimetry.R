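## Light-dose arithmetic for the 96-LED array, ferrioxalate actinometry,
## and irradiation homogeneity over the inner 60 wells.

PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C  <- 2.99792458e8     # m / s
AVOGADRO <- 6.02214076e23    # 1 / mol

#' Define an irradiation schedule
#'
#' The LED array delivers a constant irradiance; exposures are taken in
#' discrete steps with absorbance read between steps, so light dose
#' accumulates as irradiance x elapsed time. Defaults describe a
#' blue-LED panel (468 +/- 27.3 nm) at 20.6 mW cm-2 run in four 5-min
#' steps, i.e. 6.2 J cm-2 per step.
#'
#' @param wavelength_nm nominal emission wavelength (nm).
#' @param bandwidth_nm emission half-width (nm).
#' @param irradiance_mw_cm2 power density at the plate (mW cm-2).
#' @param step_seconds durations of the irradiation steps (s).
#' @return an object of class `irradiation_schedule`.
#' @examples
#' sch <- irradiation_schedule()
#' cumulative_dose(sch, 1) # 6.18 J cm-2 (prints as 6.2)
#' @export
irradiation_schedule <- function(wavelength_nm = 468, bandwidth_nm = 27.3,
                                 irradiance_mw_cm2 = 20.6,
                                 step_seconds = rep(300, 4)) {
  stopifnot(irradiance_mw_cm2 > 0, length(step_seconds) >= 1,
            all(step_seconds > 0))
  structure(
    list(wavelength_nm = wavelength_nm, bandwidth_nm = bandwidth_nm,
         irradiance_mw_cm2 = irradiance_mw_cm2,
         step_seconds = as.numeric(step_seconds)),
    class = "irradiation_schedule"
  )
}

#' @export
print.irradiation_schedule <- function(x, ...) {
  cat("<irradiation_schedule> ", x$wavelength_nm, " nm (+/-", x$bandwidth_nm,
      " nm), ", x$irradiance_mw_cm2, " mW cm-2, ", length(x$step_seconds),
      " step(s), total dose ",
      format_dose(cumulative_dose(x, length(x$step_seconds))),
      " J cm-2\n", sep = "")
  invisible(x)
}

#' Cumulative light dose through an irradiation step
#'
#' Dose (fluence) in J cm-2 is irradiance (converted mW -> W) times the
#' summed step durations. `through_step = 0` means no exposure.
#'
#' @param schedule an [irradiation_schedule()].
#' @param through_step number of completed steps (0 to the number of
#'   steps; default all).
#' @return dose in J cm-2 (unrounded; see [format_dose()] for display).
#' @export
cumulative_dose <- function(schedule,
                            through_step = length(schedule$step_seconds)) {
  stopifnot(inherits(schedule, "irradiation_schedule"))
  n <- length(schedule$step_seconds)
  if (through_step < 0 || through_step > n) {
    stop("through_step must be between 0 and ", n, call. = FALSE)
  }
  if (through_step == 0) return(0)
  schedule$irradiance_mw_cm2 / 1000 *
    sum(schedule$step_seconds[seq_len(through_step)])
}

#' All cumulative doses of a schedule
#'
#' @param schedule an [irradiation_schedule()].
#' @return numeric vector of doses after 0, 1, ..., n steps (J cm-2).
#' @export
schedule_doses <- function(schedule) {
  vapply(0:length(schedule$step_seconds),
         function(k) cumulative_dose(schedule, k), numeric(1))
}

#' Round a dose for display (3 significant figures)
#' @param dose dose in J cm-2.
#' @return rounded numeric.
#' @export
format_dose <- function(dose) signif(dose, 3)

#' Irradiance from a ferrioxalate actinometer reading
#'
#' Ferrioxalate photo-reduces Fe(III) to Fe(II) with a known quantum
#' yield, so the moles of Fe(II) formed measure the absorbed photon
#' flux: flux = n(Fe2+) / (phi x t). Multiplying by the photon energy
#' N_A h c / lambda and dividing by the illuminated area gives the
#' power density.
#'
#' @param moles_photoproduct mol Fe(II) formed.
#' @param exposure_s exposure time (s).
#' @param area_cm2 illuminated area (cm2).
#' @param quantum_yield ferrioxalate quantum yield at the working
#'   wavelength (dimensionless; default 0.9 for blue light — a
#'   configuration parameter, not a constant, since literature values
#'   are wavelength-dependent).
#' @param wavelength_nm photon wavelength (nm), 300-700.
#' @return irradiance in mW cm-2.
#' @export
irradiance_from_actinometry <- function(moles_photoproduct, exposure_s,
                                        area_cm2, quantum_yield = 0.9,
                                        wavelength_nm = 468) {
  if (any(c(moles_photoproduct, exposure_s, area_cm2, quantum_yield) <= 0)) {
    stop("all actinometry inputs must be positive", call. = FALSE)
  }
  if (wavelength_nm < 300 || wavelength_nm > 700) {
    stop("wavelength_nm must lie in [300, 700]", call. = FALSE)
  }
  photon_flux <- moles_photoproduct / (quantum_yield * exposure_s) # mol/s
  photon_energy <- PLANCK_H * LIGHT_C / (wavelength_nm * 1e-9)     # J
  watts <- photon_flux * AVOGADRO * photon_energy
  watts / area_cm2 * 1000
}

#' Wells of the inner 60-well region
#'
#' Rows B-G crossed with columns 2-11: the only contiguous 60-well
#' interior of a 96-well plate, used for the irradiation homogeneity
#' check (edge wells sit under the rim of the LED field).
#'
#' @return character vector of 60 well labels.
#' @export
inner_wells <- function() {
  as.vector(outer(LETTERS[2:7], 2:11, paste0))
}

#' Irradiation homogeneity over the inner 60 wells
#'
#' Computes the coefficient of variation of per-well doses across the
#' inner 60 wells; the field passes when CV does not exceed
#' `cv_threshold`.
#'
#' @param per_well_doses named numeric vector, well label -> dose
#'   (J cm-2). Must cover all inner wells; extra wells are ignored with
#'   a warning.
#' @param cv_threshold maximum acceptable CV (default 0.10).
#' @return list with `mean`, `cv`, `pass`, `n`.
#' @export
homogeneity_report <- function(per_well_doses, cv_threshold = 0.10) {
  inner <- inner_wells()
  missing <- setdiff(inner, names(per_well_doses))
  if (length(missing)) {
    stop("missing dose(s) for inner well(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(per_well_doses), inner)
  if (length(extra)) {
    warning(length(extra), " well(s) outside the inner region ignored",
            call. = FALSE)
  }
  d <- per_well_doses[inner]
  m <- mean(d)
  cv <- stats::sd(d) / m
  list(mean = m, cv = cv, pass = cv <= cv_threshold, n = length(d))
}
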