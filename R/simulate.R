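#' Gaussian instrument response function on a TCSPC bin grid
#'
#' Builds an IRF trace sampled at the bin centres of a uniform acquisition
#' window, as used by both the decay simulator and the fitter. The default
#' 180 ps FWHM is typical of a hybrid-detector TCSPC setup.
#'
#' @param n_bins Number of time bins.
#' @param window_ns Acquisition window length in ns.
#' @param fwhm_ns Full width at half maximum of the IRF in ns.
#' @param center_ns Position of the IRF peak in ns.
#' @return An `irf_trace` object (bin edges in ns plus non-negative
#'   amplitudes).
#' @export
gaussian_irf <- function(n_bins = 256L, window_ns = 12.5, fwhm_ns = 0.18,
                         center_ns = 1.0) {
  edges <- seq(0, window_ns, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  amp <- dnorm(centers, mean = center_ns, sd = fwhm_ns / (2 * sqrt(2 * log(2))))
  amp[amp < 1e-12 * max(amp)] <- 0
  irf_trace(edges, amp)
}

#' IRF trace constructor
#'
#' @param bin_edges Monotone increasing bin edges in ns (length `n_bins + 1`).
#' @param amplitudes Non-negative amplitudes at the bin centres.
#' @return An `irf_trace` object.
#' @export
irf_trace <- function(bin_edges, amplitudes) {
  stopifnot(is.numeric(bin_edges), is.numeric(amplitudes),
            length(bin_edges) == length(amplitudes) + 1L,
            all(diff(bin_edges) > 0), all(amplitudes >= 0))
  if (sum(amplitudes) <= 0) stop("IRF amplitudes must sum to a positive value")
  structure(list(bin_edges = bin_edges, amplitudes = amplitudes),
            class = "irf_trace")
}

#' Per-cell decay histogram constructor
#'
#' @param bin_edges Uniform, monotone increasing bin edges in ns.
#' @param counts Non-negative integer photon counts per bin.
#' @param cell_id Cell identifier.
#' @param metadata Named list; conventionally `sample_id`, `condition`, `day`.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(bin_edges, counts, cell_id = "cell",
                            metadata = list()) {
  stopifnot(is.numeric(bin_edges), is.numeric(counts),
            length(bin_edges) == length(counts) + 1L,
            all(diff(bin_edges) > 0), all(counts >= 0))
  if (length(counts) < 64L) stop("decay histograms need at least 64 bins")
  structure(list(bin_edges = bin_edges, counts = as.integer(round(counts)),
                 cell_id = cell_id, metadata = metadata),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %s: %d bins over [0, %.3g] ns, %d photons\n",
              x$cell_id, length(x$counts), max(x$bin_edges), sum(x$counts)))
  invisible(x)
}

#' Expected bin probabilities of the IRF-convolved two-component decay
#'
#' The model underlying both simulation and fitting: a mixture of two
#' exponential decays (free and protein-bound NAD(P)H) with relative
#' contributions `alpha1` and `100 - alpha1`, convolved with the IRF, plus a
#' uniform background. Returns the per-bin probability vector (sums to 1).
#'
#' @param alpha1 Relative contribution of the short component, percent.
#' @param tau1,tau2 Short and long lifetime components in ns (`tau1 < tau2`).
#' @param irf An `irf_trace` on the same bin grid.
#' @param background_fraction Fraction of photons from uniform background.
#' @return Numeric vector of per-bin probabilities.
#' @export
expected_decay_shape <- function(alpha1, tau1, tau2, irf,
                                 background_fraction = 0.01) {
  edges <- irf$bin_edges
  n <- length(irf$amplitudes)
  centers <- (edges[-1] + edges[-(n + 1L)]) / 2
  d <- (alpha1 / 100) * exp(-centers / tau1) / tau1 +
    (1 - alpha1 / 100) * exp(-centers / tau2) / tau2
  conv <- convolve(d, rev(irf$amplitudes), type = "open")[seq_len(n)]
  conv <- pmax(conv, 0)
  (1 - background_fraction) * conv / sum(conv) + background_fraction / n
}

#' Simulate one cell's TCSPC photon decay histogram
#'
#' Draws Poisson photon counts around the expected IRF-convolved
#' two-component decay. The expected total over the recorded window equals
#' the photon budget.
#'
#' @inheritParams expected_decay_shape
#' @param photons Expected total photon count for the cell (> 0).
#' @param irf Optional `irf_trace`; defaults to [gaussian_irf()] on the
#'   requested grid.
#' @param window_ns,n_bins Acquisition window (ns) and number of bins; only
#'   used when `irf` is `NULL`.
#' @param seed Optional integer seed; identical seeds give identical
#'   histograms.
#' @param cell_id,metadata Passed to [decay_histogram()].
#' @return A `decay_histogram`; the generating parameters are attached as
#'   attribute `"truth"`, and histograms below 100 expected photons carry
#'   attribute `"low_count" = TRUE` (with a warning).
#' @export
simulate_cell_decay <- function(alpha1, tau1, tau2, photons, irf = NULL,
                                window_ns = 12.5, n_bins = 256L,
                                background_fraction = 0.01, seed = NULL,
                                cell_id = "cell", metadata = list()) {
  stopifnot(is.numeric(alpha1), is.numeric(tau1), is.numeric(tau2),
            is.numeric(photons))
  if (photons <= 0) stop("photons must be positive")
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  if (alpha1 < 0 || alpha1 > 100) stop("alpha1 must lie in [0, 100]")
  if (tau1 >= tau2) stop("component ordering violated: need tau1 < tau2")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must lie in [0, 1)")
  if (is.null(irf)) irf <- gaussian_irf(n_bins = n_bins, window_ns = window_ns)
  window <- max(irf$bin_edges)
  if (window < 3 * tau2)
    warning(sprintf(
      "window (%.3g ns) is shorter than 3*tau2 (%.3g ns): truncation bias",
      window, 3 * tau2))
  low_count <- photons < 100
  if (low_count)
    warning(sprintf("low photon budget (%d): fits will be unreliable",
                    as.integer(photons)))
  shape <- expected_decay_shape(alpha1, tau1, tau2, irf, background_fraction)
  counts <- with_seed(seed, rpois(length(shape), photons * shape))
  out <- decay_histogram(irf$bin_edges, counts, cell_id = cell_id,
                         metadata = metadata)
  attr(out, "truth") <- list(alpha1 = alpha1, tau1 = tau1, tau2 = tau2)
  if (low_count) attr(out, "low_count") <- TRUE
  out
}

#' Population-level decay parameters for one sample arm
#'
#' Describes the cell-to-cell distribution of the true decay parameters in
#' one arm (means and SDs of alpha1, tau1, tau2), the number of cells imaged
#' and the photon budget per cell.
#'
#' @param mean_alpha1,sd_alpha1 Mean and SD of alpha1 across cells, percent.
#' @param mean_tau1,sd_tau1 Mean and SD of tau1 across cells, ns.
#' @param mean_tau2,sd_tau2 Mean and SD of tau2 across cells, ns.
#' @param n_cells Number of cells per arm (>= 2; 30--40 per sample is the
#'   platform's sampling design, default 35).
#' @param photons_per_cell Expected photons collected per cell.
#' @return A `population_params` object.
#' @export
population_params <- function(mean_alpha1, sd_alpha1, mean_tau1 = 0.4,
                              sd_tau1 = 0.05, mean_tau2, sd_tau2,
                              n_cells = 35L, photons_per_cell = 5000L) {
  stopifnot(mean_alpha1 > 0, mean_alpha1 < 100,
            mean_tau1 > 0, mean_tau1 < mean_tau2,
            sd_alpha1 >= 0, sd_tau1 >= 0, sd_tau2 >= 0,
            n_cells >= 2, photons_per_cell > 0)
  structure(list(mean_alpha1 = mean_alpha1, sd_alpha1 = sd_alpha1,
                 mean_tau1 = mean_tau1, sd_tau1 = sd_tau1,
                 mean_tau2 = mean_tau2, sd_tau2 = sd_tau2,
                 n_cells = as.integer(n_cells),
                 photons_per_cell = as.integer(photons_per_cell)),
            class = "population_params")
}

#' Population parameters from a printed mean +/- SEM arm summary
#'
#' Published arm summaries report the mean and SEM over the 30--40 cells of a
#' sample; the cell-to-cell SD is reconstructed as `SEM * sqrt(n_cells)`.
#'
#' @param mean_alpha1,sem_alpha1 Printed alpha1 mean and SEM, percent.
#' @param mean_tau2,sem_tau2 Printed tau2 mean and SEM, ns.
#' @param n_cells Cells per arm used for the SEM -> SD conversion.
#' @param ... Passed on to [population_params()] (e.g. tau1 settings).
#' @return A `population_params` object.
#' @export
params_from_summary <- function(mean_alpha1, sem_alpha1, mean_tau2, sem_tau2,
                                n_cells = 35L, ...) {
  population_params(mean_alpha1 = mean_alpha1,
                    sd_alpha1 = sem_alpha1 * sqrt(n_cells),
                    mean_tau2 = mean_tau2,
                    sd_tau2 = sem_tau2 * sqrt(n_cells),
                    n_cells = n_cells, ...)
}

#' Arm specification: one sample x condition x day
#'
#' @param sample_id Sample (mouse or patient) identifier.
#' @param condition `"control"` or `"treated"`.
#' @param day Measurement day (2, 7 or 14).
#' @param params A `population_params` object.
#' @param seed Integer seed for this arm's draws.
#' @return An `arm_spec` object.
#' @export
arm_spec <- function(sample_id, condition = c("control", "treated"), day,
                     params, seed) {
  condition <- match.arg(condition)
  stopifnot(day %in% c(2L, 7L, 14L), inherits(params, "population_params"))
  structure(list(sample_id = sample_id, condition = condition,
                 day = as.integer(day), params = params,
                 seed = as.integer(seed)),
            class = "arm_spec")
}

#' Simulate all cell decays of one arm
#'
#' Per-cell true parameters are drawn from truncated normal distributions
#' with the arm's means and SDs (alpha1 truncated to (0, 100), tau1 positive,
#' tau2 > tau1), then each cell's histogram is simulated with
#' [simulate_cell_decay()]. Fully reproducible given the arm seed.
#'
#' @param spec An `arm_spec`.
#' @param irf Optional shared `irf_trace` (default [gaussian_irf()]).
#' @param window_ns,n_bins,background_fraction Acquisition settings.
#' @return A `flim_arm` object: the spec, a per-cell truth table and the list
#'   of `decay_histogram`s.
#' @export
simulate_arm <- function(spec, irf = NULL, window_ns = 12.5, n_bins = 256L,
                         background_fraction = 0.01) {
  stopifnot(inherits(spec, "arm_spec"))
  p <- spec$params
  if (is.null(irf)) irf <- gaussian_irf(n_bins = n_bins, window_ns = window_ns)
  truth <- with_seed(derive_seed(spec$seed, "truth"), {
    a1 <- rnorm_trunc(p$n_cells, p$mean_alpha1, p$sd_alpha1,
                      lower = 1e-3, upper = 100 - 1e-3)
    t1 <- rnorm_trunc(p$n_cells, p$mean_tau1, p$sd_tau1, lower = 0.01)
    t2 <- rnorm_trunc(p$n_cells, p$mean_tau2, p$sd_tau2,
                      lower = t1 + 0.05)
    data.frame(cell_id = sprintf("%s_d%d_%s_c%02d", spec$sample_id, spec$day,
                                 spec$condition, seq_len(p$n_cells)),
               alpha1 = a1, tau1 = t1, tau2 = t2)
  })
  meta <- list(sample_id = spec$sample_id, condition = spec$condition,
               day = spec$day)
  cells <- lapply(seq_len(p$n_cells), function(i) {
    simulate_cell_decay(truth$alpha1[i], truth$tau1[i], truth$tau2[i],
                        photons = p$photons_per_cell, irf = irf,
                        background_fraction = background_fraction,
                        seed = derive_seed(spec$seed, "cell", i),
                        cell_id = truth$cell_id[i], metadata = meta)
  })
  structure(list(spec = spec, truth = truth, cells = cells, irf = irf),
            class = "flim_arm")
}

#' @export
print.flim_arm <- function(x, ...) {
  cat(sprintf("<flim_arm> %s / %s / day %d: %d cells\n", x$spec$sample_id,
              x$spec$condition, x$spec$day, length(x$cells)))
  invisible(x)
}
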