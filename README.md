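# flimresponse

An in vitro platform for predicting a cancer patient's response to immune
checkpoint inhibitors (ICIs, anti-PD-1 / anti-CTLA-4) from fluorescence
lifetime imaging (FLIM) of NAD(P)H autofluorescence in isolated lymphocytes
— implemented as a fully simulated, tested analysis pipeline.

The biological idea: T-cell activation after ICI blockade is preceded by
metabolic reprogramming (more glycolysis, pentose phosphate pathway and
fatty-acid turnover). NAD(P)H FLIM reads this out label-free. The photon
decay of NAD(P)H in each cell is a two-component mixture

```
I(t) ∝ IRF ⊗ [ (α₁/100)·e^(−t/τ₁)/τ₁ + (α₂/100)·e^(−t/τ₂)/τ₂ ],   α₁ + α₂ = 100%
```

where τ₁ is the short lifetime of free NAD(P)H, τ₂ the long lifetime of the
protein-bound form, α₁/α₂ their relative contributions, and the
amplitude-weighted mean lifetime is τₘ = (α₁τ₁ + α₂τ₂)/(α₁ + α₂). A sample
whose lymphocytes show a statistically significant **increase in α₁ or τ₂**
(vs the untreated control arm, day 7 decisive) is called an in vitro
responder; these calls are scored against the clinical iRECIST outcome
groups (iR / iSD / iPD).

Because the study's raw per-cell data are not deposited, the package ships a
first-class synthetic-data module: per-cell TCSPC decay histograms with
instrument-response-function (IRF) convolution and Poisson photon noise,
generated from the published per-arm mean ± SEM summaries (cell-level SD
reconstructed as SEM·√35), plus cohort fixtures with the published
composition (22 patients: 10 iR / 5 iSD / 7 iPD; 15 mice: 8 flow-cytometry
activation responders), flow-cytometry subset counts and qPCR Cq tables.

## What is in the box

| Module | What it does |
|---|---|
| simulation (`simulate_cell_decay`, `simulate_arm`, `make_study_cohort`, `simulate_flow_summary`, `simulate_qpcr_table`) | every input the pipeline consumes, seeded and reproducible |
| decay fitting (`fit_biexponential`, `fit_sample`, `mean_lifetime`) | per-cell Poisson-MLE (or Neyman-weighted LS) bi-exponential fits with IRF convolution, time-shift, background, multi-start, QC |
| response statistics (`compare_groups`, `classify_flim_response`, `classify_timecourse`, `classify_cohort`) | Shapiro–Wilk-gated Student's t / Mann–Whitney U per parameter, α₁/τ₂ response rule, optional high-baseline rescue |
| flow activation (`compare_activation`, `classify_activation_response`) | pooled-event Fisher tests of CD25⁺/CD69⁺ fractions in CD8⁺ cells |
| qPCR (`log2_fold_change`, `expression_heatmap`) | efficiency-aware, two-reference (POLR2A+ELF1) log2 fold-changes and the gene-panel heatmap |
| concordance (`concordance_report`) | 2×2 contingency of in vitro call vs clinical outcome with exact intervals |
| orchestration (`run_pipeline`, `run_config`) | simulate → fit → classify → report, with manifest and logs |

The numbered scripts under `analysis/` run the whole study in order
(fixtures → anchor recovery → patient classification → flow → qPCR →
concordance) and write their tables under `results/`.

## Worked example

Simulate the M5 day-2 sample from its printed summaries (control
69.1 ± 0.8 % / 2.95 ± 0.08 ns, treated 72.2 ± 0.7 % / 3.66 ± 0.05 ns,
35 cells per arm, 5,000 photons per cell), fit every cell and classify:

```r
library(flimresponse)
irf <- gaussian_irf()
ctrl <- simulate_arm(arm_spec("M5", "control", day = 2,
  params_from_summary(69.1, 0.8, 2.95, 0.08), seed = 101), irf = irf)
trt  <- simulate_arm(arm_spec("M5", "treated", day = 2,
  params_from_summary(72.2, 0.7, 3.66, 0.05), seed = 102), irf = irf)
fits <- rbind(fit_sample(ctrl), fit_sample(trt))
cmp  <- compare_fit_table(fits, parameters = c("alpha1", "tau2"))
cmp[, c("parameter", "control_mean", "treated_mean", "test_used", "p_value", "direction")]
#>   parameter control_mean treated_mean test_used  p_value direction
#> 1    alpha1        70.32        72.12 student_t 9.36e-02      none
#> 2      tau2         2.81         3.54 student_t 7.10e-11  increase
classify_flim_response(cmp)[, c("sample_id", "day", "call")]
#>   sample_id day     call
#> 1        M5   2 response
```

The fitted arm means land on the generating summaries (the α₁ difference is
real but under-powered at n = 35 in this draw; τ₂ carries the call), and the
significant τ₂ increase triggers the response call — the same rule that,
applied on day 7 across the cohort, separates the clinical outcome groups.

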