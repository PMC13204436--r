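# Orchestration: simulate -> fit -> classify -> (flow) -> concordance, with
# manifest, logging and plain-text CSV interchange.

#' Default pipeline configuration
#'
#' @param seed Master seed (every stochastic stage derives a named
#'   substream).
#' @param kind Cohort kind, `"patient"` or `"mouse"`.
#' @param out_dir Run directory.
#' @param ... Overrides: `alpha`, `final_day`, `rescue`, `rescue_quantile`,
#'   `method`, `days` (subset of measurement days), `sample_ids` (subset of
#'   samples), `n_cells`, `photons_per_cell`, `write_decays`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, kind = "patient", out_dir = tempfile("run_"),
                       ...) {
  cfg <- modifyList(list(
    seed = as.integer(seed), kind = kind, out_dir = out_dir,
    alpha = 0.05, final_day = 7L, rescue = FALSE, rescue_quantile = 0.75,
    method = "poisson_mle", days = NULL, sample_ids = NULL,
    n_cells = 35L, photons_per_cell = 5000L, write_decays = FALSE
  ), list(...))
  structure(cfg, class = "run_config")
}

#' Run the full platform pipeline
#'
#' Executes the stages in dependency order: cohort fixture, decay
#' simulation, per-cell fitting, treated-vs-control comparison and response
#' classification, flow-cytometry activation calls (mouse) and clinical
#' concordance (patient). All artifacts are plain-text CSV/JSON in the run
#' directory, stamped with the config hash; `run.log` records per-stage
#' counts and QC drops. Reruns with an identical config are reproducible.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the run directory and the in-memory
#'   stage outputs (`cohort`, `fits`, `comparisons`, `calls`, `flow`,
#'   `report`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  hash <- object_hash(unclass(config))
  log_line("run %s: kind=%s seed=%d", hash, config$kind, config$seed)

  cohort <- stage("cohort", make_study_cohort(
    config$kind, seed = config$seed, n_cells = config$n_cells,
    photons_per_cell = config$photons_per_cell))
  specs <- cohort$arm_specs
  if (!is.null(config$days))
    specs <- Filter(function(s) s$day %in% config$days, specs)
  if (!is.null(config$sample_ids))
    specs <- Filter(function(s) s$sample_id %in% config$sample_ids, specs)
  log_line("cohort: %d arm specs selected", length(specs))

  subjects <- if (config$kind == "patient") cohort$patients else cohort$samples
  write.csv(subjects, file.path(config$out_dir, "clinical.csv"),
            row.names = FALSE)

  irf <- gaussian_irf()
  fits <- stage("fit", {
    tabs <- lapply(specs, function(sp) {
      arm <- simulate_arm(sp, irf = irf)
      if (isTRUE(config$write_decays))
        write_decays_csv(arm, file.path(config$out_dir, "decays.csv"),
                         append = file.exists(file.path(config$out_dir,
                                                        "decays.csv")))
      tab <- fit_sample(arm, method = config$method)
      drops <- attr(tab, "qc_log")
      if (length(drops))
        log_line("fit %s/%s/d%d: %d cells kept, dropped: %s",
                 sp$sample_id, sp$condition, sp$day, nrow(tab),
                 paste(names(drops), drops, sep = "=", collapse = ", "))
      tab
    })
    do.call(rbind, tabs)
  })
  rownames(fits) <- NULL
  fits$config_hash <- hash
  write.csv(fits, file.path(config$out_dir, "fits.csv"), row.names = FALSE)
  log_line("fit: %d cells fitted", nrow(fits))

  cls <- stage("classify", classify_cohort(
    fits, alpha = config$alpha, final_day = config$final_day,
    rescue = config$rescue, rescue_quantile = config$rescue_quantile))
  write.csv(cls$comparisons, file.path(config$out_dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(cls$calls, file.path(config$out_dir, "calls.csv"),
            row.names = FALSE)
  log_line("classify: %d samples called (%s)", nrow(cls$calls),
           paste(names(table(cls$calls$call)), table(cls$calls$call),
                 sep = "=", collapse = ", "))

  flow <- NULL
  if (config$kind == "mouse") {
    flow <- stage("flow", run_flow_cohort(cohort, seed = config$seed))
    write.csv(flow$flow, file.path(config$out_dir, "flow.csv"),
              row.names = FALSE)
    write.csv(flow$calls, file.path(config$out_dir, "calls_flow.csv"),
              row.names = FALSE)
    log_line("flow: %d activation responses of %d samples",
             sum(flow$calls$call == "activation_response"), nrow(flow$calls))
  }

  report <- NULL
  if (config$kind == "patient") {
    report <- stage("concordance", concordance_report(
      cls$calls, cohort$patients, dichotomy = "iR_vs_rest"))
    write_concordance(report, config$out_dir)
    log_line("concordance: accuracy %.3f on %d classified",
             report$metrics$estimate[report$metrics$metric == "accuracy"],
             report$n_classified)
  }

  manifest <- c(unclass(config),
                list(config_hash = hash,
                     package_version = as.character(packageVersion("flimresponse")),
                     irf = list(n_bins = length(irf$amplitudes),
                                window_ns = max(irf$bin_edges),
                                fwhm_ns = 0.18, center_ns = 1.0)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dir = config$out_dir, cohort = cohort, fits = fits,
                 comparisons = cls$comparisons, calls = cls$calls,
                 flow = flow, report = report))
}

#' Write / read per-cell decay histograms as long CSV
#'
#' Long format: one row per cell x bin (`cell_id`, `sample_id`, `condition`,
#' `day`, `bin_start_ns`, `counts`).
#'
#' @param arm A `flim_arm` (or list of `decay_histogram`s).
#' @param path Output CSV path.
#' @param append Append instead of overwrite.
#' @return `path`, invisibly.
#' @export
write_decays_csv <- function(arm, path, append = FALSE) {
  cells <- if (inherits(arm, "flim_arm")) arm$cells else arm
  tabs <- lapply(cells, function(h) {
    md <- h$metadata
    data.frame(cell_id = h$cell_id,
               sample_id = md$sample_id %||% NA_character_,
               condition = md$condition %||% NA_character_,
               day = md$day %||% NA_integer_,
               bin_start_ns = h$bin_edges[-length(h$bin_edges)],
               counts = h$counts)
  })
  tab <- do.call(rbind, tabs)
  if (append) {
    write.table(tab, path, sep = ",", row.names = FALSE, col.names = FALSE,
                append = TRUE)
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_decays_csv
#' @return `read_decays_csv()`: a list of `decay_histogram`s.
#' @export
read_decays_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$cell_id), function(sub) {
    sub <- sub[order(sub$bin_start_ns), ]
    dt <- diff(sub$bin_start_ns[1:2])
    decay_histogram(c(sub$bin_start_ns, max(sub$bin_start_ns) + dt),
                    sub$counts, cell_id = sub$cell_id[1],
                    metadata = list(sample_id = sub$sample_id[1],
                                    condition = sub$condition[1],
                                    day = sub$day[1]))
  })
}

#' Write / read an IRF trace as CSV
#'
#' @param irf An `irf_trace`.
#' @param path CSV path (`bin_start_ns`, `amplitude`).
#' @return `path` / an `irf_trace`.
#' @export
write_irf_csv <- function(irf, path) {
  write.csv(data.frame(bin_start_ns = irf$bin_edges[-length(irf$bin_edges)],
                       amplitude = irf$amplitudes),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_irf_csv
#' @export
read_irf_csv <- function(path) {
  tab <- read.csv(path)
  dt <- diff(tab$bin_start_ns[1:2])
  irf_trace(c(tab$bin_start_ns, max(tab$bin_start_ns) + dt), tab$amplitude)
}
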