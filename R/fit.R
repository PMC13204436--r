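#' Amplitude-weighted mean NAD(P)H lifetime
#'
#' `tau_m = (alpha1 * tau1 + alpha2 * tau2) / (alpha1 + alpha2)` with
#' `alpha2 = 100 - alpha1`.
#'
#' @param alpha1 Short-component contribution, percent; or a `biexp_fit`.
#' @param tau1,tau2 Lifetime components in ns (ignored when a fit is given).
#' @return Mean lifetime in ns.
#' @export
mean_lifetime <- function(alpha1, tau1 = NULL, tau2 = NULL) {
  if (inherits(alpha1, "biexp_fit")) {
    f <- alpha1
    return(mean_lifetime(f$alpha1, f$tau1, f$tau2))
  }
  alpha2 <- 100 - alpha1
  (alpha1 * tau1 + alpha2 * tau2) / (alpha1 + alpha2)
}

default_fit_options <- function() {
  list(
    min_photons = 500L,
    maxit = 200L,
    factr = 1e8,
    fit_shift = TRUE,
    # multi-start grid: NAD(P)H literature ranges
    start_tau1 = c(0.3, 0.5),
    start_tau2 = c(2.0, 3.5),
    start_alpha1 = c(60, 80),
    lower = c(alpha1 = 0, tau1 = 0.05, tau2 = 1.2, bg = 0, shift = -2),
    upper = c(alpha1 = 100, tau1 = 1.2, tau2 = 8.0, bg = 0.1, shift = 2),
    identifiability_gap = 0.05
  )
}

#' Fit the two-component NAD(P)H decay model to one cell
#'
#' Estimates `alpha1`, `tau1`, `tau2`, a uniform background fraction and an
#' IRF time shift by maximising the Poisson likelihood (default) or
#' minimising a Neyman-weighted chi-square of the model
#' `scale * (IRF (*) bi-exponential) + background`. Multi-start L-BFGS-B over
#' a small grid of literature starting values; the best objective wins, ties
#' broken towards the lower `tau2`.
#'
#' @param hist A `decay_histogram`.
#' @param irf An `irf_trace` on the same grid (default [gaussian_irf()]).
#' @param method `"poisson_mle"` or `"weighted_ls"`.
#' @param options Named list overriding [default fit options][fit_biexponential]:
#'   `min_photons` (refuse below, default 500), `maxit`, `fit_shift`,
#'   start grids, box bounds, `identifiability_gap` (minimum `tau2 - tau1`).
#' @return A `biexp_fit`: `alpha1`, `alpha2` (= 100 - alpha1 exactly),
#'   `tau1 < tau2` (enforced by post-fit swap), `tau_m`, `background`,
#'   `shift`, `gof` (reduced chi-square), `objective`, `total_photons`,
#'   `converged` and `identifiable` flags.
#' @export
fit_biexponential <- function(hist, irf = NULL,
                              method = c("poisson_mle", "weighted_ls"),
                              options = list()) {
  method <- match.arg(method)
  stopifnot(inherits(hist, "decay_histogram"))
  opt <- modifyList(default_fit_options(), options)
  counts <- as.numeric(hist$counts)
  n <- length(counts)
  total <- sum(counts)
  if (total < opt$min_photons)
    stop(errorCondition(
      sprintf("cell %s has %d photons, below the minimum of %d",
              hist$cell_id, as.integer(total), as.integer(opt$min_photons)),
      class = c("flim_low_count_error", "error", "condition")))
  if (is.null(irf))
    irf <- gaussian_irf(n_bins = n, window_ns = max(hist$bin_edges))
  if (length(irf$amplitudes) != n)
    stop("IRF and histogram must share the same binning")
  dt <- diff(hist$bin_edges[1:2])
  irf_amp <- irf$amplitudes / sum(irf$amplitudes)
  poisson <- method == "poisson_mle"

  obj <- function(theta) cpp_decay_objective(theta, counts, irf_amp, dt, poisson)

  lower <- opt$lower
  upper <- opt$upper
  if (!opt$fit_shift) lower["shift"] <- upper["shift"] <- 0
  # parameters with equal bounds are held fixed and masked out of the
  # optimisation (L-BFGS-B cannot finite-difference a zero-width box)
  fixed <- lower >= upper
  to_full <- function(free) {
    th <- lower
    th[!fixed] <- free
    unname(th)
  }
  starts <- expand.grid(alpha1 = opt$start_alpha1, tau1 = opt$start_tau1,
                        tau2 = opt$start_tau2)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    th0 <- pmin(pmax(c(starts$alpha1[i], starts$tau1[i], starts$tau2[i],
                       0.01, 0), lower), upper)
    if (all(fixed))
      return(list(par = th0, value = obj(th0), convergence = 0L))
    res <- tryCatch(
      optim(th0[!fixed], function(free) obj(to_full(free)),
            method = "L-BFGS-B", lower = lower[!fixed], upper = upper[!fixed],
            control = list(maxit = opt$maxit, factr = opt$factr)),
      error = function(e) list(value = Inf, par = th0[!fixed],
                               convergence = 99L)
    )
    res$par <- to_full(res$par)
    res
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-9)
  if (length(cand) > 1) {           # tie-break: lower tau2
    t2s <- vapply(fits[cand], function(f) f$par[3], numeric(1))
    cand <- cand[which.min(t2s)]
  }
  best <- fits[[cand[1]]]
  th <- best$par
  alpha1 <- th[1]; tau1 <- th[2]; tau2 <- th[3]
  if (tau1 > tau2) {                # enforce component ordering
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    alpha1 <- 100 - alpha1
    th <- c(alpha1, tau1, tau2, th[4], th[5])
  }
  m <- cpp_decay_model(th, irf_amp, dt, total)
  gof <- sum((counts - m)^2 / pmax(m, 1)) / (n - 5)
  structure(list(
    alpha1 = alpha1, alpha2 = 100 - alpha1, tau1 = tau1, tau2 = tau2,
    tau_m = mean_lifetime(alpha1, tau1, tau2),
    background = th[4], shift = th[5],
    gof = gof, objective = best$value, total_photons = total,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    identifiable = (tau2 - tau1) >= opt$identifiability_gap,
    method = method, n_bins = n, cell_id = hist$cell_id,
    metadata = hist$metadata
  ), class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> %s: alpha1 = %.1f%%, tau1 = %.3f ns, tau2 = %.3f ns, tau_m = %.3f ns (%s, %s)\n",
    x$cell_id, x$alpha1, x$tau1, x$tau2, x$tau_m, x$method,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit every cell of a sample with quality control
#'
#' Fits all histograms and drops cells that fail QC: below the photon
#' minimum, non-converged, non-identifiable (`tau2 - tau1` collapsed) or a
#' reduced chi-square above the cutoff. Dropped counts are logged on the
#' returned table.
#'
#' @param cells A list of `decay_histogram`s or a `flim_arm`.
#' @param irf Optional shared `irf_trace`.
#' @param method Passed to [fit_biexponential()].
#' @param qc List: `min_photons` (default 500), `max_red_chisq` (default 5),
#'   `require_convergence` (default TRUE).
#' @param options Passed to [fit_biexponential()].
#' @return A data frame with one row per retained cell (`cell_id`,
#'   `sample_id`, `condition`, `day`, `alpha1`, `alpha2`, `tau1`, `tau2`,
#'   `tau_m`, `gof`, `photons`, `qc_flag = "ok"`); attributes `qc_log`
#'   (named drop counts) and `dropped` (per-cell drop reasons).
#' @export
fit_sample <- function(cells, irf = NULL, method = "poisson_mle",
                       qc = list(), options = list()) {
  if (inherits(cells, "flim_arm")) {
    if (is.null(irf)) irf <- cells$irf
    cells <- cells$cells
  }
  stopifnot(is.list(cells), length(cells) >= 2)
  qc <- modifyList(list(min_photons = 500L, max_red_chisq = 5,
                        require_convergence = TRUE), qc)
  options$min_photons <- qc$min_photons
  rows <- list(); dropped <- list()
  for (h in cells) {
    fit <- tryCatch(fit_biexponential(h, irf = irf, method = method,
                                      options = options),
                    flim_low_count_error = function(e) "low_count")
    flag <- if (is.character(fit)) fit
    else if (qc$require_convergence && !fit$converged) "non_converged"
    else if (!fit$identifiable) "non_identifiable"
    else if (fit$gof > qc$max_red_chisq) "poor_fit"
    else "ok"
    if (flag == "ok") {
      md <- h$metadata
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = h$cell_id,
        sample_id = md$sample_id %||% NA_character_,
        condition = md$condition %||% NA_character_,
        day = md$day %||% NA_integer_,
        alpha1 = fit$alpha1, alpha2 = fit$alpha2,
        tau1 = fit$tau1, tau2 = fit$tau2, tau_m = fit$tau_m,
        gof = fit$gof, photons = fit$total_photons, qc_flag = "ok")
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(cell_id = h$cell_id,
                                                    reason = flag)
    }
  }
  if (length(rows) == 0)
    stop("all cells failed quality control: empty sample")
  out <- do.call(rbind, rows)
  drop_df <- if (length(dropped)) do.call(rbind, dropped)
  else data.frame(cell_id = character(), reason = character())
  attr(out, "qc_log") <- table(drop_df$reason)
  attr(out, "dropped") <- drop_df
  out
}

#' Fit a simulated arm and keep the generating truth alongside
#'
#' @param arm A `flim_arm` from [simulate_arm()].
#' @inheritParams fit_sample
#' @return The [fit_sample()] table joined with `true_alpha1`, `true_tau1`,
#'   `true_tau2` columns.
#' @export
fit_arm <- function(arm, method = "poisson_mle", qc = list(), options = list()) {
  stopifnot(inherits(arm, "flim_arm"))
  fits <- fit_sample(arm, method = method, qc = qc, options = options)
  truth <- arm$truth
  names(truth)[-1] <- paste0("true_", names(truth)[-1])
  out <- merge(fits, truth, by = "cell_id", sort = FALSE)
  attr(out, "qc_log") <- attr(fits, "qc_log")
  attr(out, "dropped") <- attr(fits, "dropped")
  out
}
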