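## Synthetic plate generator with known ground truth.
##
## DMA photobleaching is simulated as pseudo-first-order decay whose
## rate scales with the sensitizer's absorbed fraction and effective
## singlet-oxygen efficiency:
##
##   OD377(H) = od0 * exp(-kappa * H) + eps,
##   kappa = kappa0 * effective_phi * (1 - 10^(-a_irr)),
##
## with H the cumulative light dose (J cm-2) and eps additive Gaussian
## read noise. The ascorbate arm multiplies kappa by (1 - quenchable);
## the solvent-control arm bleaches slowly at `solvent_bleach_rate`;
## the extract-plus-ascorbate arm drifts linearly by
## `side_reaction_drift` over the full schedule (a nonzero drift
## emulates a direct extract/probe side reaction).

#' Describe a simulated photosensitizer
#'
#' @param sample_id identifier.
#' @param a_irr absorbance (OD) of the extract alone at the irradiation
#'   wavelength.
#' @param effective_phi relative singlet-oxygen efficiency (>= 0);
#'   the reference PS is simulated at 1 by convention.
#' @param quenchable fraction of the bleaching suppressed by ascorbate
#'   (in \[0, 1\]; a true Type II sensitizer is close to 1, a probe
#'   artifact close to 0).
#' @param side_reaction_drift OD drift of the extract-plus-ascorbate
#'   control over the full light dose (default 0).
#' @param a_377 absorbance of the extract alone at 377 nm (baseline of
#'   the side-reaction control; default 0.02).
#' @return list of class `sensitizer_spec`.
#' @export
sensitizer_spec <- function(sample_id, a_irr, effective_phi,
                            quenchable = 0.95, side_reaction_drift = 0,
                            a_377 = 0.02) {
  stopifnot(a_irr >= 0, effective_phi >= 0,
            quenchable >= 0, quenchable <= 1)
  structure(list(sample_id = sample_id, a_irr = a_irr,
                 effective_phi = effective_phi, quenchable = quenchable,
                 side_reaction_drift = side_reaction_drift, a_377 = a_377),
            class = "sensitizer_spec")
}

#' Simulation configuration for DMA plates
#'
#' Defaults mirror the screening conditions the package analyses: a
#' blue-LED schedule of four 5-min steps at 20.6 mW cm-2 (6.2 J cm-2
#' per step), an initial DMA OD377 of 0.8, triplicate wells, and
#' additive read noise of 0.005 OD. `kappa0` = 0.012 per J cm-2 places
#' the reference PS (phi = 1, a_irr = 0.2) in the mild-bleaching regime
#' seen in screening time courses (~10% DMA consumption over the full
#' dose).
#'
#' @param schedule an [irradiation_schedule()].
#' @param dma_od0 initial DMA absorbance at 377 nm.
#' @param kappa0 bleaching rate per J cm-2 at unit absorbed fraction
#'   and unit effective phi.
#' @param noise_sd additive Gaussian read noise (OD).
#' @param replicates wells per arm.
#' @param seed RNG seed, recorded in the output metadata.
#' @param solvent_bleach_rate direct DMA photobleaching rate of the
#'   solvent control (per J cm-2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(schedule = irradiation_schedule(), dma_od0 = 0.8,
                       kappa0 = 0.012, noise_sd = 0.005, replicates = 3,
                       seed = 1, solvent_bleach_rate = 2e-4) {
  stopifnot(noise_sd >= 0, replicates >= 1, dma_od0 > 0, kappa0 >= 0,
            solvent_bleach_rate >= 0)
  structure(list(schedule = schedule, dma_od0 = dma_od0, kappa0 = kappa0,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 solvent_bleach_rate = solvent_bleach_rate),
            class = "sim_config")
}

#' Default simulated reference photosensitizer
#'
#' A berberine-like yellow reference: moderate blue absorbance,
#' effective phi fixed at 1 (the 100% anchor), strongly quenchable.
#'
#' @return a [sensitizer_spec()].
#' @export
reference_spec <- function() {
  sensitizer_spec("berberine", a_irr = 0.2, effective_phi = 1,
                  quenchable = 0.95)
}

#' Simulate a DMA assay plate
#'
#' Lays out, for every sensitizer spec and for the reference PS, the
#' four assay arms (DMA + extract, extract alone, DMA + extract +
#' ascorbate, extract + ascorbate), plus solvent-control and blank
#' wells, and generates absorbance records at every cumulative dose of
#' the schedule: 377 nm trajectories for the probe-bearing arms and
#' 468 nm (irradiation-wavelength) readings for the extract-alone arms.
#' Fully reproducible from `cfg$seed`; the ground-truth parameters are
#' attached as the `ground_truth` attribute.
#'
#' @param specs list of [sensitizer_spec()]s (the extracts).
#' @param cfg a [sim_config()].
#' @param reference the reference PS spec (default [reference_spec()]).
#' @return a [plate_dataset()] with attribute `ground_truth`.
#' @export
simulate_dma_plate <- function(specs, cfg = sim_config(),
                               reference = reference_spec()) {
  if (inherits(specs, "sensitizer_spec")) specs <- list(specs)
  stopifnot(inherits(cfg, "sim_config"))
  all_specs <- c(specs, list(reference))
  reps <- cfg$replicates
  n_wells <- length(all_specs) * 4L * reps + 2L * reps # + solvent + blanks
  if (n_wells > 96) {
    stop("layout needs ", n_wells, " wells (> 96); split the specs over ",
         "several plates", call. = FALSE)
  }

  wells <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0))) # A1, A2, ...
  doses <- schedule_doses(cfg$schedule)
  h_max <- max(doses)
  lambda_irr <- cfg$schedule$wavelength_nm

  layout <- list()
  records <- list()
  widx <- 0L
  next_well <- function() {
    widx <<- widx + 1L
    wells[widx]
  }
  add_well <- function(sample_id, arm, replicate) {
    w <- next_well()
    layout[[length(layout) + 1L]] <<- tibble::tibble(
      well = w, sample_id = sample_id, arm = arm,
      concentration_ug_per_ml = NA_real_, replicate = replicate)
    w
  }
  add_records <- function(well, wavelength, od) {
    records[[length(records) + 1L]] <<- tibble::tibble(
      well = well, wavelength_nm = wavelength,
      cumulative_dose_J_cm2 = doses, od = od)
  }

  with_seed(cfg$seed, {
    noise <- function() stats::rnorm(length(doses), 0, cfg$noise_sd)
    for (sp in all_specs) {
      is_ref <- identical(sp$sample_id, reference$sample_id)
      kappa <- cfg$kappa0 * sp$effective_phi * (1 - 10^(-sp$a_irr))
      for (r in seq_len(reps)) {
        w <- add_well(sp$sample_id,
                      if (is_ref) "reference_ps" else "dma_probe", r)
        add_records(w, 377, cfg$dma_od0 * exp(-kappa * doses) + noise())

        w <- add_well(sp$sample_id, "extract_alone", r)
        add_records(w, lambda_irr, sp$a_irr + noise())

        w <- add_well(sp$sample_id, "dma_plus_quencher", r)
        kq <- kappa * (1 - sp$quenchable)
        add_records(w, 377, cfg$dma_od0 * exp(-kq * doses) + noise())

        w <- add_well(sp$sample_id, "extract_plus_quencher", r)
        drift <- if (h_max > 0) sp$side_reaction_drift * doses / h_max else 0
        add_records(w, 377, sp$a_377 + drift + noise())
      }
    }
    for (r in seq_len(reps)) {
      w <- add_well("solvent", "solvent_control", r)
      add_records(w, 377,
                  cfg$dma_od0 * exp(-cfg$solvent_bleach_rate * doses) + noise())
    }
    for (r in seq_len(reps)) {
      w <- add_well("blank", "blank", r)
      add_records(w, 377, noise())
      records[[length(records) + 1L]] <- tibble::tibble(
        well = w, wavelength_nm = lambda_irr,
        cumulative_dose_J_cm2 = doses, od = noise())
    }
  })

  ds <- plate_dataset(do.call(rbind, layout), do.call(rbind, records),
                      schedule = cfg$schedule, plate_id = "simulated-dma")
  attr(ds, "ground_truth") <- list(
    specs = all_specs, config = cfg,
    reference_id = reference$sample_id, seed = cfg$seed
  )
  ds
}

#' Describe a simulated cytotoxicity dose-response
#'
#' @param sample_id identifier.
#' @param ec50_dark,ec50_irr true EC50s (ug/mL) of the dark and
#'   irradiated arms; `Inf` means inactive (flat response at `top`).
#' @param hill Hill slope (> 0: viability decreases with dose).
#' @param top,bottom viability plateaus (%).
#' @param noise_sd_pct additive Gaussian noise on viability (%).
#' @return list of class `cytotox_spec`.
#' @export
cytotox_spec <- function(sample_id, ec50_dark = Inf, ec50_irr = Inf,
                         hill = 1.5, top = 100, bottom = 0,
                         noise_sd_pct = 5) {
  stopifnot(ec50_dark > 0, ec50_irr > 0, noise_sd_pct >= 0)
  structure(list(sample_id = sample_id, ec50_dark = ec50_dark,
                 ec50_irr = ec50_irr, hill = hill, top = top,
                 bottom = bottom, noise_sd_pct = noise_sd_pct),
            class = "cytotox_spec")
}

#' Simulate SRB dose-response data for dark and irradiated arms
#'
#' Viability is drawn from the four-parameter logistic at the spec's
#' true parameters plus Gaussian noise, truncated to the plausible SRB
#' range [-20, 150]. An infinite EC50 produces a flat response at
#' `top`.
#'
#' @param spec a [cytotox_spec()].
#' @param concentrations tested concentrations (ug/mL, strictly
#'   positive). Default: seven 1:3 dilutions from 50 ug/mL down.
#' @param replicates replicate measurements per concentration and arm.
#' @param seed RNG seed.
#' @param cell_line label carried through (default "A549").
#' @return tibble with columns `sample_id, cell_line, arm,
#'   concentration_ug_per_ml, replicate, viability_pct`.
#' @export
simulate_dose_response <- function(spec, concentrations = 50 / 3^(6:0),
                                   replicates = 3, seed = 1,
                                   cell_line = "A549") {
  stopifnot(inherits(spec, "cytotox_spec"), all(concentrations > 0))
  concentrations <- sort(concentrations)
  arms <- c(dark = spec$ec50_dark, irradiated = spec$ec50_irr)
  with_seed(seed, {
    rows <- lapply(names(arms), function(arm) {
      mu <- four_pl(rep(concentrations, each = replicates), arms[[arm]],
                    spec$hill, spec$top, spec$bottom)
      v <- mu + stats::rnorm(length(mu), 0, spec$noise_sd_pct)
      tibble::tibble(
        sample_id = spec$sample_id, cell_line = cell_line, arm = arm,
        concentration_ug_per_ml = rep(concentrations, each = replicates),
        replicate = rep(seq_len(replicates), times = length(concentrations)),
        viability_pct = pmin(pmax(v, -20), 150)
      )
    })
    do.call(rbind, rows)
  })
}
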