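---
title: "Methods: the NAD(P)H FLIM lymphocyte platform, simulated and re-analysed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NAD(P)H FLIM lymphocyte platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flimresponse)
```

## The measurement model

Each lymphocyte contributes one TCSPC histogram: photon arrival times after
pulsed excitation, binned over a fixed acquisition window. The expected bin
counts follow a two-component decay convolved with the instrument response
function (IRF), plus a uniform background:

$$m_i = N\left[(1-b)\,\frac{(\mathrm{IRF}\otimes f)_i}{\sum_j (\mathrm{IRF}\otimes f)_j} + \frac{b}{n}\right],
\qquad
f(t) = \frac{\alpha_1}{100}\frac{e^{-t/\tau_1}}{\tau_1} + \frac{\alpha_2}{100}\frac{e^{-t/\tau_2}}{\tau_2},$$

with $\alpha_1+\alpha_2=100$ %. The short component $\tau_1$ is free
NAD(P)H, the long component $\tau_2$ the protein-bound form; the
amplitude-weighted mean lifetime is
$\tau_m = (\alpha_1\tau_1+\alpha_2\tau_2)/(\alpha_1+\alpha_2)$. Normalising
the convolved shape over the recorded window makes the expected total equal
the photon budget $N$; consequently truncation of the slow tail (window
shorter than $\approx 3\tau_2$) biases the shape rather than the total, and
the simulator emits a warning in that regime. Bin counts are independent
Poisson draws — the correct noise model for photon counting.

### Assumptions

* Two exponential components suffice (no third component, no phasor
  analysis, no flavin channel).
* Decay parameters are evaluated at bin centres; simulator and fitter share
  this discretisation, so no discretisation bias enters round trips.
* Cells are statistically independent units within an arm; fields of view
  are not modelled as a grouping level (the source data treat the 30–40
  cells per sample as the test units).

## Acquisition defaults

The source hardware (SPC-150N TCSPC card, hybrid detector) is named but its
settings are not printed, so the following are package conventions, chosen
to be typical of NAD(P)H FLIM and configurable everywhere: 12.5 ns window
(80 MHz repetition), 256 bins, Gaussian IRF with 180 ps FWHM peaking at
1 ns, 1 % uniform background, 5,000 photons per cell, 35 cells per arm (the
midpoint of the stated 30–40). They are not inferences about the actual
instrument.

## Fitting

Per cell, the fitter maximises the Poisson likelihood of the model above
(`method = "poisson_mle"`, the default — correct at low counts) or
minimises Neyman-weighted least squares with weights $1/\max(c_i,1)$
(`weighted_ls`, for likeness to commercial fitting software). Free
parameters: $\alpha_1 \in [0,100]$, $\tau_1 \in [0.05, 1.2]$ ns,
$\tau_2 \in [1.2, 8]$ ns, background $\in [0, 0.1]$, and an IRF time shift
of ±2 bins that absorbs alignment error. The likelihood is multimodal in
$(\tau_1,\tau_2)$, so optimisation is multi-start L-BFGS-B from the grid
$\tau_1 \in \{0.3, 0.5\}$, $\tau_2 \in \{2.0, 3.5\}$ ns,
$\alpha_1 \in \{60, 80\}$ % (NAD(P)H literature ranges); the best objective
wins, ties break to the lower $\tau_2$. Parameters whose box bounds
coincide are held fixed and masked out of the search (L-BFGS-B cannot
finite-difference a zero-width box). The objective is compiled (Rcpp) with
a direct convolution over the IRF support; an independent R implementation
built on `stats::convolve` is kept in the test suite and agrees to 1e-10,
and a property test verifies the optimizer never returns a worse objective
than an exhaustive 15×15×15 grid.

Quality control drops cells below 500 photons, non-converged fits,
non-identifiable fits ($\tau_2-\tau_1 < 0.05$ ns at the optimum) and
reduced $\chi^2 > 5$; drops are logged, never silent. Scale is profiled
out by fixing the expected total to the observed total, which is the MLE
under the Poisson model.

## The testing and classification procedure

Per sample, day and parameter, the two arms are compared with a
normality-gated two-sided test: Shapiro–Wilk on *each* arm (normal when
$p \ge 0.05$; the source does not state per-arm vs pooled, per-arm is our
reading), Student's t (equal variances) when both pass, otherwise
Mann–Whitney U. For arms of ≤8 observations the U distribution is
enumerated exhaustively with average ranks for ties; larger arms use the
normal approximation with tie correction and continuity correction.
Significance is $p \le 0.05$ per comparison with no multiplicity
correction, mirroring the per-comparison reporting of the source. $\tau_1$
and $\tau_m$ are computed and reported but never drive classification —
they corresponded worse with activation in the source data.

A sample **responds** when $\alpha_1$ or $\tau_2$ (or both) increases
significantly; it is a **non-responder** when at least one of the two
decreases and neither increases; otherwise **indeterminate**. The day-7
call is final; earlier days are consulted only when day 7 is absent. This
day-7-priority policy is our formalisation of samples that showed no change
on day 2 but responded overall.

**High-baseline rescue.** One published responder maintained high
$\alpha_1$/$\tau_2$ in both arms on day 7 without further increase. The
optional rescue rule (off by default, enabled per run) upgrades an
indeterminate call to a response when, for *both* parameters, both arm
means lie above the cohort's 75th-percentile of control-arm means on the
decision day. The quantile and the both-parameters requirement are design
choices: the source narrates the case but states no rule.

## The synthetic cohorts

Published per-arm summaries are means ± SEM over cells; the generator draws
cell-level truth from truncated normals (α₁ in (0,100), τ positive,
τ₂ > τ₁ per cell) with SD = SEM·√35. Where an arm is printed it is used
verbatim; unprinted arms start from baseline defaults (patients
71.0 % / 3.30 ns, mice 69.5 % / 2.95 ns, with small per-sample jitter) and
apply the sample's narrated effect direction with shifts of ±3 percentage
points (α₁) and ±0.4 ns (τ₂) — magnitudes inside the printed range
(1.9–5.9 points, 0.23–0.76 ns). Unprinted τ₁ defaults to 0.4 ± 0.05 ns
(typical free NAD(P)H) — a fixture convention, not a published value. Three
narrative ambiguities are resolved as fixture conventions: day-7
single-parameter changes whose parameter is unnamed are assigned to τ₂;
one mouse listed both as declining and unchanged on day 7 is encoded
unchanged on day 7 (the more specific clause) and declining on day 14; one
printed control SEM of 0.0 is replaced by 0.7 (the median of neighbouring
SEMs) as a presumed typo.

Clinical fixtures reproduce the printed marginals exactly (22 patients,
9 M / 13 F, ages uniform 40–80, 19 anti-PD-1 / 3 combination, outcome
groups 10 iR / 5 iSD / 7 iPD with the published iRECIST breakdown); sexes,
ages and the assignment of the combination therapy beyond those marginals
are randomised under the seed. The mouse fixture carries the 8 published
activation-response labels.

Flow-cytometry summaries are binomial draws of CD25⁺/CD69⁺ events within
CD8⁺ and conventional CD4⁺FoxP3⁻ parents (3 wells × 2,000 parent events);
treated "up" arms triple the odds. Replicate wells default to exchangeable
binomial splits (no extra-binomial well noise), consistent with the
pooled-event Fisher testing downstream — with overdispersed wells a pooled
test would not hold its nominal size, and a noise option exists to
demonstrate exactly that. qPCR tables follow the efficiency-aware model
$Cq = Cq_0 - \mathrm{lfc}\cdot\log 2/\log E$ with per-gene efficiencies in
(1.8, 2.0), duplicate reactions and 0.15-cycle replicate noise;
normalisation uses the geometric mean of the two reference genes
(Pfaffl-style ratio — the source names the references but not the
combination rule).

### What passing tests do and do not show

The generator matches the *statistical* structure the study reports:
two-component decays, printed arm means and dispersions, Poisson photon
noise, cohort composition, effect directions. It does not emulate optical
artefacts (scattered excitation light, detector afterpulsing, incomplete
decay pile-up), inter-day drift, cell segmentation error, or any real
biological correlation between a patient's FLIM shift, gene expression and
flow phenotype — those are generated independently per module. Tests
passing here therefore validate the *analysis chain* under the stated
noise model, not the biological claim itself.

## Numerical choices

* Truncated normals are drawn by inverse-CDF, exact and vectorised.
* All stochastic stages consume named substreams derived from one master
  seed (`derive_seed`), so every artifact is bit-reproducible and
  subsetting one stage does not shift another's draws.
* Exact Mann–Whitney p-values use the permutation definition
  $P(|U-\mathbb{E}U|\ge|u-\mathbb{E}U|)$, which coincides with the
  standard two-sided exact p for tie-free data (verified against
  `wilcox.test` for all arm sizes ≤6) and remains well-defined under ties.
* Degenerate (constant) arms bypass Shapiro–Wilk (undefined there) and
  fall back to the rank test with a warning.
* Fisher's exact test is used for pooled flow tables below 10,000 parent
  events per arm, chi-square above.

## Problem sizes

The shipped drivers and tests use the study-scale design throughout:
35 cells per arm at 5,000 photons in 256 bins; the full day-7 patient run
fits ~1,500 cells in a few minutes; property tests use 64-bin, 2,000-photon
instances (grid oracle), 1,000 null replicates at n = 35 (type-I), and 200
replicates for power.

## Known limitations

* Cell-level pseudo-replication is reproduced deliberately: cells, not
  samples, are the test units, as in the source analysis. A mixed-effects
  treatment is out of scope.
* No claim of numerical equivalence with the commercial fitting software —
  only model equivalence; binning/threshold defaults of that software are
  unknown.
* iSD patients have no principled binary label; they are counted as
  non-responders in the `iR_vs_rest` dichotomy and excluded in
  `iR_vs_iPD`, both reported.
* The α₁-only power at the weakest printed day-2 effect is ≈0.83 at n = 35
  (analytic and simulated); single-parameter detection at such effect
  sizes is not guaranteed in any one replicate — the response rule's power
  comes from the τ₂ channel.
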