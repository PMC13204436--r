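#' Two-sided Mann-Whitney U test with exact small-sample enumeration
#'
#' For arms of at most `exact_max_n` observations each, the permutation
#' distribution of U is enumerated exhaustively over all group assignments
#' (average ranks for ties), and the two-sided p-value is
#' `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`. Larger arms use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (control and treated arms).
#' @param exact_max_n Enumerate exactly when both arms are at most this size.
#' @return List with `statistic` (U for `y` vs `x`), `p_value` and `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 8L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    cmb <- combn(n, n1)
    us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u_obs, p_value = 1, exact = FALSE))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    exact <- FALSE
  }
  list(statistic = u_obs, p_value = p, exact = exact)
}

#' Compare treated vs control cell values for one decay parameter
#'
#' The testing procedure of the platform: each arm's distribution is checked
#' with the Shapiro-Wilk test; when both arms are normal (p >= 0.05) a
#' two-sided Student's t-test is used, otherwise a two-sided Mann-Whitney U
#' test. Significance direction is the sign of the treated - control mean
#' difference when `p <= alpha`.
#'
#' @param control,treated Numeric per-cell values (>= 3 each).
#' @param alpha Significance threshold (default 0.05, two-sided, no
#'   multiplicity correction).
#' @param sample_id,day,parameter Optional labels carried into the result.
#' @return One-row data frame (`sample_id`, `day`, `parameter`,
#'   `control_mean`, `control_sem`, `treated_mean`, `treated_sem`,
#'   `n_control`, `n_treated`, `test_used`, `p_value`, `direction`).
#' @export
compare_groups <- function(control, treated, alpha = 0.05,
                           sample_id = NA_character_, day = NA_integer_,
                           parameter = NA_character_) {
  stopifnot(is.numeric(control), is.numeric(treated))
  control <- control[is.finite(control)]
  treated <- treated[is.finite(treated)]
  if (length(control) < 3 || length(treated) < 3)
    stop("insufficient data: need at least 3 finite values per arm")
  degenerate <- length(unique(control)) == 1 || length(unique(treated)) == 1
  if (degenerate) {
    warning("constant arm(s): falling back to the Mann-Whitney U test")
    normal <- FALSE
  } else {
    normal <- shapiro.test(control)$p.value >= 0.05 &&
      shapiro.test(treated)$p.value >= 0.05
  }
  if (normal) {
    test_used <- "student_t"
    p <- t.test(treated, control, var.equal = TRUE)$p.value
  } else {
    test_used <- "mann_whitney"
    p <- mann_whitney_u(control, treated)$p_value
  }
  cm <- mean(control); tm <- mean(treated)
  direction <- if (p <= alpha) {
    if (tm > cm) "increase" else "decrease"
  } else "none"
  data.frame(sample_id = sample_id, day = day, parameter = parameter,
             control_mean = cm, control_sem = sd(control) / sqrt(length(control)),
             treated_mean = tm, treated_sem = sd(treated) / sqrt(length(treated)),
             n_control = length(control), n_treated = length(treated),
             test_used = test_used, p_value = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' All treated-vs-control comparisons in a per-cell fit table
#'
#' Runs [compare_groups()] for every sample x day present in a [fit_sample()]
#' style table, for each requested decay parameter. `tau1` and `tau_m` are
#' reported for completeness but never drive response classification.
#'
#' @param fits Data frame with columns `sample_id`, `condition`, `day` and
#'   the parameter columns.
#' @param alpha Significance threshold.
#' @param parameters Parameter columns to test.
#' @return Data frame of stacked [compare_groups()] rows.
#' @export
compare_fit_table <- function(fits, alpha = 0.05,
                              parameters = c("alpha1", "tau2", "tau1", "tau_m")) {
  stopifnot(all(c("sample_id", "condition", "day") %in% names(fits)))
  keys <- unique(fits[, c("sample_id", "day")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- fits[fits$sample_id == keys$sample_id[i] & fits$day == keys$day[i], ]
    ctrl <- sub[sub$condition == "control", ]
    trt <- sub[sub$condition == "treated", ]
    if (nrow(ctrl) == 0 || nrow(trt) == 0) next
    for (par in parameters) {
      rows[[length(rows) + 1L]] <- compare_groups(
        ctrl[[par]], trt[[par]], alpha = alpha,
        sample_id = keys$sample_id[i], day = keys$day[i], parameter = par)
    }
  }
  do.call(rbind, rows)
}

#' Classify one sample's FLIM response from its alpha1/tau2 comparisons
#'
#' A sample responds when either `alpha1` or `tau2` (or both) shows a
#' statistically significant increase over the untreated control; it is a
#' non-responder when at least one of the two decreases significantly and
#' neither increases; otherwise the call is indeterminate. An optional
#' high-baseline rescue (off by default) upgrades an indeterminate call to a
#' response when both arms of both parameters sit above cohort-level
#' thresholds (formalising samples that maintain high baseline values
#' without further increase).
#'
#' @param comparisons [compare_groups()] rows for one sample and day; must
#'   contain both `alpha1` and `tau2`.
#' @param rescue Apply the high-baseline rescue rule.
#' @param rescue_thresholds Named numeric (`alpha1`, `tau2`): cohort
#'   thresholds (e.g. 75th percentile of control means); required when
#'   `rescue = TRUE`.
#' @return One-row data frame (`sample_id`, `day`, `call`, `rescue_applied`,
#'   plus the serialized decision basis columns `p_alpha1`, `dir_alpha1`,
#'   `p_tau2`, `dir_tau2`); the full comparison rows are attached as
#'   attribute `"basis"`.
#' @export
classify_flim_response <- function(comparisons, rescue = FALSE,
                                   rescue_thresholds = NULL) {
  need <- c("alpha1", "tau2")
  have <- intersect(need, comparisons$parameter)
  if (length(have) < 2)
    stop("missing parameter comparison(s): ",
         paste(setdiff(need, have), collapse = ", "))
  cmp <- comparisons[comparisons$parameter %in% need, ]
  any_up <- any(cmp$direction == "increase")
  any_down <- any(cmp$direction == "decrease")
  call <- if (any_up) "response"
  else if (any_down) "no_response"
  else "indeterminate"
  rescue_applied <- FALSE
  if (call == "indeterminate" && isTRUE(rescue)) {
    if (is.null(rescue_thresholds))
      stop("rescue = TRUE requires rescue_thresholds for alpha1 and tau2")
    high <- vapply(need, function(par) {
      row <- cmp[cmp$parameter == par, ]
      thr <- rescue_thresholds[[par]]
      is.finite(thr) && row$control_mean >= thr && row$treated_mean >= thr
    }, logical(1))
    if (all(high)) {
      call <- "response"
      rescue_applied <- TRUE
    }
  }
  a1 <- cmp[cmp$parameter == "alpha1", ]
  t2 <- cmp[cmp$parameter == "tau2", ]
  out <- data.frame(sample_id = cmp$sample_id[1], day = cmp$day[1],
                    call = call, rescue_applied = rescue_applied,
                    p_alpha1 = a1$p_value, dir_alpha1 = a1$direction,
                    p_tau2 = t2$p_value, dir_tau2 = t2$direction,
                    stringsAsFactors = FALSE)
  attr(out, "basis") <- cmp
  out
}

#' Resolve per-day calls into a sample's final call
#'
#' Default policy: the day-`final_day` (day 7) call is the sample's final
#' call; earlier days are consulted only when the final day is absent, in
#' which case the latest available day is used.
#'
#' @param calls Data frame of per-day [classify_flim_response()] rows for one
#'   sample.
#' @param final_day The decision day (default 7).
#' @return The selected one-row call.
#' @export
classify_timecourse <- function(calls, final_day = 7L) {
  if (is.null(calls) || nrow(calls) == 0) stop("no per-day calls supplied")
  pick <- if (final_day %in% calls$day) which(calls$day == final_day)
  else which.max(calls$day)
  calls[pick[1], , drop = FALSE]
}

#' Comparisons, per-day calls and final calls for a whole cohort fit table
#'
#' @param fits Per-cell fit table covering one or more samples and days.
#' @param alpha Significance threshold.
#' @param final_day Decision day for [classify_timecourse()].
#' @param rescue Enable the high-baseline rescue; thresholds are the
#'   `rescue_quantile` quantile of the control-arm means (per parameter) on
#'   the final day across the cohort.
#' @param rescue_quantile Cohort quantile defining "high baseline".
#' @return List with `comparisons`, `calls_by_day` and `calls` (one final
#'   row per sample, including `rescue_applied`).
#' @export
classify_cohort <- function(fits, alpha = 0.05, final_day = 7L,
                            rescue = FALSE, rescue_quantile = 0.75) {
  comparisons <- compare_fit_table(fits, alpha = alpha)
  thresholds <- NULL
  if (isTRUE(rescue)) {
    base <- comparisons[comparisons$day == final_day, ]
    thresholds <- vapply(c("alpha1", "tau2"), function(par)
      quantile(base$control_mean[base$parameter == par], rescue_quantile,
               names = FALSE, type = 7),
      numeric(1))
  }
  by_day <- list()
  for (sid in unique(comparisons$sample_id)) {
    for (d in unique(comparisons$day[comparisons$sample_id == sid])) {
      cmp <- comparisons[comparisons$sample_id == sid & comparisons$day == d, ]
      by_day[[length(by_day) + 1L]] <- classify_flim_response(
        cmp, rescue = rescue, rescue_thresholds = thresholds)
    }
  }
  calls_by_day <- do.call(rbind, by_day)
  finals <- lapply(split(calls_by_day, calls_by_day$sample_id),
                   classify_timecourse, final_day = final_day)
  calls <- do.call(rbind, finals)
  rownames(calls) <- NULL
  list(comparisons = comparisons, calls_by_day = calls_by_day, calls = calls)
}
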