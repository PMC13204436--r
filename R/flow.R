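# Flow-cytometry arm of the platform: gated subset summaries (CD8+ and
# conventional CD4+FoxP3- parents; CD25+/CD69+ children) and the
# activation-response call.

.flow_subsets <- c("CD8", "CD4convFoxP3neg")
.flow_markers <- c("CD25", "CD69")

#' Simulate gated flow-cytometry summary counts for one arm
#'
#' Generates positive-event counts for the activation markers CD25 and CD69
#' within the CD8+ and conventional CD4+FoxP3- T-cell subsets, over replicate
#' wells. For treated arms, `effect = "up"` shifts the child fractions
#' upward (activation), `"down"` downward; control arms always draw from the
#' baseline rates. Child counts are binomial draws from the parent events,
#' so gating nesting (`positive <= parent`) holds by construction.
#'
#' @param sample_id Sample identifier.
#' @param condition `"control"` or `"treated"`.
#' @param effect `"none"`, `"up"` or `"down"` (applied to treated arms only).
#' @param seed Integer seed.
#' @param day Measurement day (the platform reads activation on day 14).
#' @param parent_events Parent-subset events per well.
#' @param n_replicates Replicate wells.
#' @param base_rates Named baseline positive fractions per marker.
#' @param effect_size Multiplicative shift of the odds for `"up"` (inverse
#'   for `"down"`).
#' @param well_noise_sd Logit-scale well-to-well variability. The default of
#'   0 keeps replicate wells exchangeable binomial splits, matching the
#'   pooled-event testing downstream; raise it to emulate extra-binomial
#'   well variation (which pooled tests do not account for).
#' @return Data frame of `FlowSummary` rows (`sample_id`, `condition`, `day`,
#'   `parent_subset`, `marker`, `parent_events`, `positive_events`,
#'   `replicate`).
#' @export
simulate_flow_summary <- function(sample_id, condition = c("control", "treated"),
                                  effect = c("none", "up", "down"),
                                  seed = NULL, day = 14L,
                                  parent_events = 2000L, n_replicates = 3L,
                                  base_rates = c(CD25 = 0.10, CD69 = 0.12),
                                  effect_size = 3, well_noise_sd = 0) {
  condition <- match.arg(condition)
  effect <- match.arg(effect)
  rows <- expand.grid(parent_subset = .flow_subsets, marker = .flow_markers,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(rows)), function(i) {
      p <- base_rates[[rows$marker[i]]]
      if (condition == "treated" && effect != "none") {
        odds <- p / (1 - p) * if (effect == "up") effect_size else 1 / effect_size
        p <- odds / (1 + odds)
      }
      lo <- log(p / (1 - p)) + rnorm(1, 0, well_noise_sd)
      p_well <- 1 / (1 + exp(-lo))
      data.frame(sample_id = sample_id, condition = condition, day = day,
                 parent_subset = rows$parent_subset[i],
                 marker = rows$marker[i],
                 parent_events = as.integer(parent_events),
                 positive_events = rbinom(1, parent_events, p_well),
                 replicate = rows$replicate[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Compare treated vs control activation-marker fractions
#'
#' Replicate wells are pooled per arm, and each subset x marker pair is
#' tested as a 2x2 table (arm x positive/negative): Fisher's exact test when
#' either arm has fewer than 10,000 pooled parent events, chi-square
#' otherwise.
#'
#' @param control,treated [simulate_flow_summary()]-shaped rows.
#' @param alpha Significance threshold.
#' @return Data frame with one row per subset x marker: pooled fractions,
#'   `test_used`, `p_value` and `direction`.
#' @export
compare_activation <- function(control, treated, alpha = 0.05) {
  stopifnot(nrow(control) >= 1, nrow(treated) >= 1)
  rows <- list()
  for (subset in unique(c(control$parent_subset, treated$parent_subset))) {
    for (marker in unique(c(control$marker, treated$marker))) {
      cc <- control[control$parent_subset == subset & control$marker == marker, ]
      tt <- treated[treated$parent_subset == subset & treated$marker == marker, ]
      if (nrow(cc) == 0 || nrow(tt) == 0) next
      cp <- sum(cc$parent_events); cx <- sum(cc$positive_events)
      tp <- sum(tt$parent_events); tx <- sum(tt$positive_events)
      if (cp == 0 || tp == 0) stop("zero parent events for ", subset, "/", marker)
      tab <- matrix(c(tx, tp - tx, cx, cp - cx), nrow = 2,
                    dimnames = list(arm = c("treated", "control"),
                                    state = c("positive", "negative")))
      if (min(cp, tp) < 10000) {
        test_used <- "fisher_exact"
        p <- fisher.test(tab)$p.value
      } else {
        test_used <- "chi_square"
        p <- chisq.test(tab, correct = TRUE)$p.value
      }
      cf <- cx / cp; tf <- tx / tp
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = tt$sample_id[1], parent_subset = subset, marker = marker,
        control_frac = cf, treated_frac = tf,
        control_events = cp, treated_events = tp,
        test_used = test_used, p_value = p,
        direction = if (p <= alpha) {
          if (tf > cf) "increase" else "decrease"
        } else "none",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Activation-response call from flow comparisons
#'
#' A sample is an activation responder when the percentages of both CD25+
#' and CD69+ cells increase significantly within the CD8+ T-cell subset
#' (CD4+ conventional increases are recorded as supporting evidence but not
#' required); otherwise it is a non-responder. `require = "any"` relaxes the
#' rule to either CD8 marker.
#'
#' @param comparisons [compare_activation()] rows for one sample.
#' @param require `"both"` (default) or `"any"` CD8 markers.
#' @return One-row data frame (`sample_id`, `call`, `cd8_cd25`, `cd8_cd69`,
#'   `cd4_support`).
#' @export
classify_activation_response <- function(comparisons, require = c("both", "any")) {
  require <- match.arg(require)
  cd8 <- comparisons[comparisons$parent_subset == "CD8", ]
  if (!all(.flow_markers %in% cd8$marker))
    stop("missing CD8 comparisons for: ",
         paste(setdiff(.flow_markers, cd8$marker), collapse = ", "))
  up <- vapply(.flow_markers, function(m)
    cd8$direction[cd8$marker == m] == "increase", logical(1))
  hit <- if (require == "both") all(up) else any(up)
  cd4 <- comparisons[comparisons$parent_subset == "CD4convFoxP3neg", ]
  data.frame(sample_id = comparisons$sample_id[1],
             call = if (hit) "activation_response" else "no_activation_response",
             cd8_cd25 = cd8$direction[cd8$marker == "CD25"],
             cd8_cd69 = cd8$direction[cd8$marker == "CD69"],
             cd4_support = any(cd4$direction == "increase"),
             stringsAsFactors = FALSE)
}

#' Simulate and classify the whole mouse flow fixture
#'
#' @param cohort A mouse `cohort_fixture` (for sample ids and effect
#'   directions).
#' @param seed Master seed (substreams per sample).
#' @param ... Passed to [simulate_flow_summary()].
#' @return List with the pooled `flow` table, `comparisons` and per-sample
#'   `calls`.
#' @export
run_flow_cohort <- function(cohort, seed = cohort$seed, ...) {
  stopifnot(inherits(cohort, "cohort_fixture"), cohort$kind == "mouse")
  eff <- cohort$flow_effects
  flows <- list(); cmps <- list(); calls <- list()
  for (i in seq_len(nrow(eff))) {
    sid <- eff$sample_id[i]
    ctrl <- simulate_flow_summary(sid, "control", effect = "none",
                                  seed = derive_seed(seed, "flow", sid, "control"),
                                  ...)
    trt <- simulate_flow_summary(sid, "treated", effect = eff$effect[i],
                                 seed = derive_seed(seed, "flow", sid, "treated"),
                                 ...)
    cmp <- compare_activation(ctrl, trt)
    flows[[i]] <- rbind(ctrl, trt)
    cmps[[i]] <- cmp
    calls[[i]] <- classify_activation_response(cmp)
  }
  list(flow = do.call(rbind, flows), comparisons = do.call(rbind, cmps),
       calls = do.call(rbind, calls))
}
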