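# Shared fixtures and independent oracles used across the suite.

shared_irf <- gaussian_irf()
shared_irf64 <- gaussian_irf(n_bins = 64L, window_ns = 12.5)

# Independent R-side Poisson NLL for the IRF-convolved two-component decay,
# built on stats::convolve (the fitter uses its own compiled path).
oracle_nll <- function(alpha1, tau1, tau2, counts, irf, bg = 0.01) {
  n <- length(counts)
  edges <- irf$bin_edges
  centers <- (edges[-1] + edges[-(n + 1)]) / 2
  d <- (alpha1 / 100) * exp(-centers / tau1) / tau1 +
    (1 - alpha1 / 100) * exp(-centers / tau2) / tau2
  conv <- pmax(convolve(d, rev(irf$amplitudes), type = "open")[seq_len(n)], 0)
  s <- (1 - bg) * conv / sum(conv) + bg / n
  m <- sum(counts) * s
  sum(m - counts * log(pmax(m, 1e-12)))
}

# Best objective over a coarse grid of (alpha1, tau1, tau2), background and
# shift held at the simulator settings.
oracle_grid_best <- function(counts, irf, k = 15L, bg = 0.01) {
  best <- Inf
  for (a1 in seq(5, 95, length.out = k))
    for (t1 in seq(0.1, 1.1, length.out = k))
      for (t2 in seq(1.3, 6, length.out = k))
        best <- min(best, oracle_nll(a1, t1, t2, counts, irf, bg = bg))
  best
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
# (probability-ordering convention), independent of stats::fisher.test.
oracle_fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x12; n <- x21 + x22; k <- x11 + x21
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(x11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Collect identity checks on any table of fits.
expect_fit_identities <- function(fits) {
  expect_equal(fits$alpha1 + fits$alpha2, rep(100, nrow(fits)))
  expect_true(all(fits$tau1 < fits$tau2))
  tau_m <- (fits$alpha1 * fits$tau1 + fits$alpha2 * fits$tau2) /
    (fits$alpha1 + fits$alpha2)
  expect_equal(fits$tau_m, tau_m, tolerance = 1e-12)
  expect_true(all(fits$tau1 <= fits$tau_m & fits$tau_m <= fits$tau2))
}
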