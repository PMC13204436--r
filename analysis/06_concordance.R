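#!/usr/bin/env Rscript

# Stage 6: concordance of the in vitro prediction with clinical outcome.
#
# Joins the day-7 FLIM calls (stage 3) to the iRECIST outcome groups and
# scores the platform on both dichotomies: iR vs rest (iSD counted as
# non-response) and iR vs iPD (iSD excluded).

suppressPackageStartupMessages(library(flimresponse))

calls <- read.csv("results/patient_run/calls.csv")
clinical <- read.csv("results/clinical.csv")

for (dich in c("iR_vs_rest", "iR_vs_iPD")) {
  rep <- concordance_report(calls, clinical, dichotomy = dich)
  write_concordance(rep, file.path("results/concordance", dich))
  cat("\n")
  print(rep)
}
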