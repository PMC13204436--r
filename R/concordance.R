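# Concordance between the in vitro FLIM response call and the clinical
# iRECIST outcome group.

#' Map iRECIST categories to outcome groups
#'
#' iCR/iPR -> iR (immune response), iSD -> iSD, iUPD/iCPD -> iPD.
#'
#' @param irecist Character vector of iRECIST categories.
#' @return Character vector of outcome groups.
#' @export
derive_outcome_group <- function(irecist) {
  map <- c(iCR = "iR", iPR = "iR", iSD = "iSD", iUPD = "iPD", iCPD = "iPD")
  bad <- setdiff(unique(irecist), names(map))
  if (length(bad)) stop("unknown iRECIST label(s): ", paste(bad, collapse = ", "))
  unname(map[irecist])
}

#' Concordance of in vitro calls with clinical outcome
#'
#' Joins the final per-sample FLIM calls to the clinical records, excludes
#' indeterminate calls, builds the 2x2 contingency table of in vitro call
#' (response / no_response) against clinical outcome, and reports
#' sensitivity, specificity and accuracy with exact Clopper-Pearson 95%
#' intervals. The positive clinical class is iR; `dichotomy = "iR_vs_rest"`
#' treats iSD with iPD as non-responders, `"iR_vs_iPD"` drops iSD patients
#' from the table.
#'
#' @param calls Data frame with `sample_id` and `call` (final per-sample
#'   calls, e.g. from [classify_cohort()]).
#' @param clinical Data frame with `patient_id` and either `outcome_group`
#'   or `irecist`.
#' @param dichotomy `"iR_vs_rest"` (default) or `"iR_vs_iPD"`.
#' @return A `concordance_report`: `contingency` (2x2 counts), `metrics`
#'   (estimate + exact CI per metric), `excluded` (dropped samples with
#'   reasons), `dichotomy`, `n_classified`.
#' @export
concordance_report <- function(calls, clinical,
                               dichotomy = c("iR_vs_rest", "iR_vs_iPD")) {
  dichotomy <- match.arg(dichotomy)
  if (nrow(calls) == 0) stop("empty call set")
  if (!"outcome_group" %in% names(clinical))
    clinical$outcome_group <- derive_outcome_group(clinical$irecist)
  orphans <- setdiff(calls$sample_id, clinical$patient_id)
  if (length(orphans))
    stop("calls without clinical records: ", paste(orphans, collapse = ", "))
  merged <- merge(calls, clinical, by.x = "sample_id", by.y = "patient_id")
  excluded <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  ind <- merged$call == "indeterminate"
  if (any(ind))
    excluded <- rbind(excluded, data.frame(sample_id = merged$sample_id[ind],
                                           reason = "indeterminate_call"))
  merged <- merged[!ind, ]
  if (dichotomy == "iR_vs_iPD") {
    isd <- merged$outcome_group == "iSD"
    if (any(isd))
      excluded <- rbind(excluded, data.frame(sample_id = merged$sample_id[isd],
                                             reason = "iSD_not_in_dichotomy"))
    merged <- merged[!isd, ]
  }
  if (nrow(merged) == 0) stop("no classifiable samples after exclusions")
  pred <- factor(merged$call, levels = c("response", "no_response"))
  truth <- factor(ifelse(merged$outcome_group == "iR", "iR", "non-iR"),
                  levels = c("iR", "non-iR"))
  tab <- table(in_vitro = pred, clinical = truth)
  tp <- tab["response", "iR"]; fn <- tab["no_response", "iR"]
  fp <- tab["response", "non-iR"]; tn <- tab["no_response", "non-iR"]
  metric <- function(name, x, n) {
    ci <- if (n > 0) binom.test(x, n)$conf.int else c(NA_real_, NA_real_)
    data.frame(metric = name, estimate = if (n > 0) x / n else NA_real_,
               lower = ci[1], upper = ci[2], n = n, stringsAsFactors = FALSE)
  }
  metrics <- rbind(metric("sensitivity", tp, tp + fn),
                   metric("specificity", tn, tn + fp),
                   metric("accuracy", tp + tn, sum(tab)))
  structure(list(contingency = tab, metrics = metrics, excluded = excluded,
                 dichotomy = dichotomy, n_classified = sum(tab)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %s, n = %d classified (%d excluded)\n",
              x$dichotomy, x$n_classified, nrow(x$excluded)))
  print(x$contingency)
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Write a concordance report as JSON + markdown
#'
#' @param report A `concordance_report`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_concordance <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(list(
    dichotomy = report$dichotomy,
    contingency = as.data.frame(report$contingency),
    metrics = report$metrics,
    excluded = report$excluded,
    n_classified = report$n_classified
  ), json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  lines <- c(
    sprintf("# Concordance report (%s)", report$dichotomy),
    "", "## Contingency (in vitro x clinical)", "",
    paste(capture.output(print(report$contingency)), collapse = "\n"),
    "", "## Metrics", "",
    paste(capture.output(print(report$metrics, row.names = FALSE)),
          collapse = "\n"),
    "", sprintf("Excluded: %d", nrow(report$excluded)))
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}
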