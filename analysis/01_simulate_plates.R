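#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic screening panel.
#
# Four extracts spanning the rubric: a PDT-type lead (strong 1O2
# producer, phototoxic only), an aPDI-type lead (1O2 producer without
# cytotoxicity), a photochemically active extract (no 1O2 but
# phototoxic), and an inert extract. The plate follows the study
# conditions: blue-LED schedule (468 nm, 20.6 mW cm-2, four 5-min
# steps), triplicate wells, 0.005 OD read noise; dose-response arms are
# triplicates over seven 1:3 dilutions from 50 ug/mL with 5% viability
# noise. Outputs: plate layout/readings CSVs and the SRB table under
# results/simulated/.

library(photoscreen)

seed <- 20260924
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  sensitizer_spec("pdt_lead",  a_irr = 0.25, effective_phi = 2.05),
  sensitizer_spec("apdi_lead", a_irr = 0.25, effective_phi = 1.2),
  sensitizer_spec("photochem", a_irr = 0.25, effective_phi = 0),
  sensitizer_spec("inert",     a_irr = 0.05, effective_phi = 0)
)
plate <- simulate_dma_plate(specs, sim_config(seed = seed))
write_plate(plate, file.path(out, "layout.csv"), file.path(out, "readings.csv"))

dr <- rbind(
  simulate_dose_response(cytotox_spec("pdt_lead",  Inf, 1),  seed = seed + 1),
  simulate_dose_response(cytotox_spec("apdi_lead", Inf, Inf), seed = seed + 2),
  simulate_dose_response(cytotox_spec("photochem", Inf, 5),  seed = seed + 3),
  simulate_dose_response(cytotox_spec("inert",     Inf, Inf), seed = seed + 4)
)
utils::write.csv(dr, file.path(out, "dose_response.csv"), row.names = FALSE)

# ground-truth sidecar so downstream stages can be checked against it
gt <- data.frame(
  sample_id = vapply(specs, `[[`, character(1), "sample_id"),
  effective_phi = vapply(specs, `[[`, numeric(1), "effective_phi"),
  a_irr = vapply(specs, `[[`, numeric(1), "a_irr"),
  ec50_dark = Inf, ec50_irr = c(1, Inf, 5, Inf), seed = seed
)
utils::write.csv(gt, file.path(out, "ground_truth.csv"), row.names = FALSE)

cat("Simulated screening panel written to", out, "\n")
cat(" -", nrow(plate$layout), "wells,", nrow(plate$records),
    "absorbance records;", nrow(dr), "SRB viability rows\n")
cat(" - total light dose:",
    format_dose(cumulative_dose(plate$schedule)), "J cm-2\n")
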