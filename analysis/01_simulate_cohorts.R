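#!/usr/bin/env Rscript

# Stage 1: build the two study fixtures.
#
# The mouse fixture has 15 lymph-node samples treated in vitro with
# anti-CTLA-4 (8 published activation responders), imaged on days 2/7/14.
# The patient fixture has 22 melanoma patients (10 iR / 5 iSD / 7 iPD by
# iRECIST) whose blood lymphocytes were treated with the patient's own ICI
# and imaged on days 2/7. Printed per-arm summaries act as generator truth;
# unprinted arms follow the per-sample effect directions of the narrative.

suppressPackageStartupMessages(library(flimresponse))

seed <- 1L
dir.create("results", showWarnings = FALSE)

patient <- make_study_cohort("patient", seed = seed)
mouse <- make_study_cohort("mouse", seed = seed)

write.csv(patient$patients, "results/clinical.csv", row.names = FALSE)
write.csv(mouse$samples, "results/mouse_samples.csv", row.names = FALSE)
write.csv(patient$directions, "results/patient_flim_directions.csv",
          row.names = FALSE)
write.csv(mouse$directions, "results/mouse_flim_directions.csv",
          row.names = FALSE)

cat("Patient cohort:", nrow(patient$patients), "records —",
    sum(patient$patients$outcome_group == "iR"), "iR /",
    sum(patient$patients$outcome_group == "iSD"), "iSD /",
    sum(patient$patients$outcome_group == "iPD"), "iPD\n")
cat("Mouse cohort:", nrow(mouse$samples), "samples —",
    sum(mouse$samples$activation_label == "activation_response"),
    "activation responders\n")

# example raw data: the first cells of the M5 day-2 treated arm + the IRF
irf <- gaussian_irf()
arm <- suppressWarnings(
  simulate_arm(mouse$arm_specs[["M5_2_treated"]], irf = irf))
write_decays_csv(arm$cells[1:5], "results/example_decays_M5_d2_treated.csv")
write_irf_csv(irf, "results/irf.csv")
cat("Example decays written for 5 of", length(arm$cells),
    "cells of M5 day 2\n")
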