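# Cohort fixtures reproducing the published study structure: sample lists,
# outcome composition, per-sample effect directions, and the printed
# per-arm mean +/- SEM anchors used as simulation ground truth.

#' Printed per-arm decay-parameter summaries used as generator anchors
#'
#' Control/treated means and SEMs (over cells) of alpha1 (percent) and tau2
#' (ns) for the samples and days where the source study prints them; `NA`
#' where a value is not printed. The P14 day-7 control alpha1 SEM is printed
#' as 0.0, which is implausible over 30--40 cells; the fixture substitutes
#' 0.7 (the median of nearby printed SEMs).
#'
#' @return Data frame keyed by `sample_id`, `day`.
#' @export
flim_anchors <- function() {
  read.csv(text = "sample_id,day,a1_c,a1_c_sem,a1_t,a1_t_sem,t2_c,t2_c_sem,t2_t,t2_t_sem
M5,2,69.1,0.8,72.2,0.7,2.95,0.08,3.66,0.05
M8,7,70.3,0.9,76.2,0.8,NA,NA,NA,NA
M4,7,NA,NA,NA,NA,2.86,0.06,3.16,0.04
M12,14,67.7,0.8,63.4,0.8,2.96,0.06,2.20,0.06
P17,2,71.4,0.8,75.8,0.8,3.32,0.06,3.86,0.05
P15,7,71.8,0.7,73.7,0.6,3.22,0.05,3.45,0.04
P17,7,73.6,0.5,73.6,0.6,3.84,0.04,3.86,0.04
P6,2,73.3,0.6,70.4,1.3,3.59,0.05,3.11,0.05
P14,7,70.1,0.7,65.1,1.0,3.37,0.07,3.00,0.07
", stringsAsFactors = FALSE)
}

# direction tables: per sample x day, alpha1 and tau2 in {up, down, none}
.patient_directions <- function() {
  rows <- rbind(
    # day 2 -- response group
    c("P13", 2, "up", "none"),
    c("P2", 2, "none", "up"), c("P7", 2, "none", "up"),
    c("P15", 2, "none", "up"), c("P18", 2, "none", "up"),
    c("P12", 2, "up", "up"), c("P17", 2, "up", "up"), c("P23", 2, "up", "up"),
    c("P4", 2, "none", "none"), c("P16", 2, "none", "none"),
    # day 2 -- stable disease
    c("P8", 2, "none", "down"), c("P10", 2, "none", "down"),
    c("P19", 2, "none", "up"),
    c("P1", 2, "none", "none"), c("P24", 2, "none", "none"),
    # day 2 -- progressive disease
    c("P6", 2, "down", "down"),
    c("P9", 2, "none", "down"), c("P14", 2, "none", "down"),
    c("P26", 2, "none", "down"),
    c("P20", 2, "none", "none"), c("P21", 2, "none", "none"),
    c("P22", 2, "none", "none"),
    # day 7 -- response group
    c("P4", 7, "none", "up"), c("P7", 7, "none", "up"),
    c("P12", 7, "none", "up"), c("P16", 7, "none", "up"),
    c("P18", 7, "none", "up"), c("P23", 7, "none", "up"),
    c("P2", 7, "up", "up"), c("P13", 7, "up", "up"), c("P15", 7, "up", "up"),
    c("P17", 7, "none", "none"),   # maintained high baseline (rescue case)
    # day 7 -- stable disease
    c("P8", 7, "down", "none"),
    c("P19", 7, "none", "down"), c("P24", 7, "none", "down"),
    c("P1", 7, "none", "none"), c("P10", 7, "none", "none"),
    # day 7 -- progressive disease
    c("P6", 7, "none", "down"), c("P20", 7, "none", "down"),
    c("P22", 7, "none", "down"), c("P26", 7, "none", "down"),
    c("P9", 7, "down", "down"), c("P14", 7, "down", "down"),
    c("P21", 7, "down", "down"))
  data.frame(sample_id = rows[, 1], day = as.integer(rows[, 2]),
             alpha1 = rows[, 3], tau2 = rows[, 4], stringsAsFactors = FALSE)
}

.mouse_directions <- function() {
  up_both <- function(ids, day) cbind(ids, day, "up", "up")
  down_both <- function(ids, day) cbind(ids, day, "down", "down")
  none_both <- function(ids, day) cbind(ids, day, "none", "none")
  rows <- rbind(
    up_both(c("M3", "M4", "M5", "M9", "M14"), 2),
    none_both(c("M2", "M8", "M15"), 2),
    none_both(c("M10", "M11", "M12", "M13"), 2),
    down_both(c("M1", "M6", "M7"), 2),
    c("M8", 7, "up", "none"), c("M4", 7, "none", "up"),
    up_both(c("M2", "M3", "M5", "M9", "M14", "M15"), 7),
    down_both(c("M1", "M6", "M7"), 7),
    c("M10", 7, "none", "down"),
    none_both(c("M11", "M12", "M13"), 7),
    up_both(c("M2", "M3", "M4", "M5", "M8", "M9", "M14", "M15"), 14),
    down_both(c("M1", "M6", "M7", "M10", "M11", "M12", "M13"), 14))
  data.frame(sample_id = rows[, 1], day = as.integer(rows[, 2]),
             alpha1 = rows[, 3], tau2 = rows[, 4], stringsAsFactors = FALSE)
}

.mouse_activation <- function() {
  responders <- c("M2", "M3", "M4", "M5", "M8", "M9", "M14", "M15")
  ids <- paste0("M", 1:15)
  data.frame(sample_id = ids,
             activation_label = ifelse(ids %in% responders,
                                       "activation_response",
                                       "no_activation_response"),
             stringsAsFactors = FALSE)
}

.mouse_flow_effects <- function() {
  lab <- .mouse_activation()
  effect <- ifelse(lab$activation_label == "activation_response", "up", "down")
  effect[lab$sample_id %in% c("M10", "M11")] <- "none"
  data.frame(sample_id = lab$sample_id, effect = effect,
             stringsAsFactors = FALSE)
}

.patient_groups <- function() {
  list(iR = c("P2", "P4", "P7", "P12", "P13", "P15", "P16", "P17", "P18", "P23"),
       iSD = c("P1", "P8", "P10", "P19", "P24"),
       iPD = c("P6", "P9", "P14", "P20", "P21", "P22", "P26"))
}

# Build population_params for one arm from anchors where printed, otherwise
# from baseline defaults shifted by the sample's effect direction.
.arm_params <- function(sample_id, day, condition, dirs, anchors, baseline,
                        deltas, n_cells = 35L, photons = 5000L) {
  a <- anchors[anchors$sample_id == sample_id & anchors$day == day, ]
  d <- dirs[dirs$sample_id == sample_id & dirs$day == day, ]
  shift <- c(up = 1, none = 0, down = -1)
  ctrl_a1 <- if (nrow(a) && is.finite(a$a1_c)) a$a1_c else baseline$a1[sample_id]
  sem_a1_c <- if (nrow(a) && is.finite(a$a1_c_sem)) a$a1_c_sem else baseline$sem_a1
  ctrl_t2 <- if (nrow(a) && is.finite(a$t2_c)) a$t2_c else baseline$t2[sample_id]
  sem_t2_c <- if (nrow(a) && is.finite(a$t2_c_sem)) a$t2_c_sem else baseline$sem_t2
  if (condition == "control") {
    m_a1 <- ctrl_a1; s_a1 <- sem_a1_c
    m_t2 <- ctrl_t2; s_t2 <- sem_t2_c
  } else {
    m_a1 <- if (nrow(a) && is.finite(a$a1_t)) a$a1_t
    else ctrl_a1 + shift[[d$alpha1]] * deltas$a1
    s_a1 <- if (nrow(a) && is.finite(a$a1_t_sem)) a$a1_t_sem else baseline$sem_a1
    m_t2 <- if (nrow(a) && is.finite(a$t2_t)) a$t2_t
    else ctrl_t2 + shift[[d$tau2]] * deltas$t2
    s_t2 <- if (nrow(a) && is.finite(a$t2_t_sem)) a$t2_t_sem else baseline$sem_t2
  }
  params_from_summary(mean_alpha1 = m_a1, sem_alpha1 = s_a1,
                      mean_tau2 = m_t2, sem_tau2 = s_t2,
                      n_cells = n_cells, photons_per_cell = photons)
}

#' Build the published cohort fixture (mouse or patient)
#'
#' `kind = "patient"`: 22 clinical records with the published outcome
#' composition (10 iR of which 8 on anti-PD-1 and 2 on the combination;
#' 5 iSD; 7 iPD; 9 males / 13 females; ages uniform in 40--80) and one
#' control/treated arm specification per sample for days 2 and 7, with
#' effect directions encoding each sample's reported behaviour.
#' `kind = "mouse"`: 15 samples with the published activation labels
#' (8 activation responders), arm specifications for days 2, 7 and 14, and
#' flow-cytometry effect directions.
#'
#' Printed per-arm summaries are used verbatim as generator truth; arms the
#' study does not print are generated from baseline defaults (patients:
#' alpha1 71 +/- 0.7 SEM, tau2 3.30 +/- 0.05 SEM; mice: 69.5 +/- 0.8,
#' 2.95 +/- 0.06) with small per-sample baseline jitter and effect shifts of
#' +/- 3 percentage points (alpha1) and +/- 0.4 ns (tau2), magnitudes in the
#' range of the printed examples.
#'
#' @param kind `"patient"` or `"mouse"`.
#' @param seed Master integer seed.
#' @param n_cells,photons_per_cell Per-arm sampling design.
#' @return A `cohort_fixture`: `kind`, `patients` (or `samples`),
#'   `arm_specs` (named list of `arm_spec`s), `directions`, `flow_effects`
#'   (mouse only) and `seed`.
#' @export
make_study_cohort <- function(kind = c("patient", "mouse"), seed = 1L,
                              n_cells = 35L, photons_per_cell = 5000L) {
  kind <- match.arg(kind)
  if (kind == "patient") {
    groups <- .patient_groups()
    ids <- unlist(groups, use.names = FALSE)
    dirs <- .patient_directions()
    days <- c(2L, 7L)
    clin <- with_seed(derive_seed(seed, "clinical"), {
      therapy <- setNames(rep("anti_PD1", length(ids)), ids)
      combo <- c(sample(groups$iR, 2), sample(groups$iPD, 1))
      therapy[combo] <- "anti_PD1_plus_anti_CTLA4"
      irecist <- setNames(rep(NA_character_, length(ids)), ids)
      irecist[groups$iSD] <- "iSD"
      # iR: the 2 combination patients are iCR; anti-PD-1: 2 iCR + 6 iPR
      ir_combo <- intersect(groups$iR, combo)
      ir_mono <- setdiff(groups$iR, ir_combo)
      irecist[ir_combo] <- "iCR"
      icr_mono <- sample(ir_mono, 2)
      irecist[icr_mono] <- "iCR"
      irecist[setdiff(ir_mono, icr_mono)] <- "iPR"
      # iPD: 1 iUPD on anti-PD-1, combination case iCPD, rest iCPD
      ipd_mono <- setdiff(groups$iPD, combo)
      iupd <- sample(ipd_mono, 1)
      irecist[groups$iPD] <- "iCPD"
      irecist[iupd] <- "iUPD"
      sex <- sample(rep(c("M", "F"), c(9, 13)))
      age <- sample(40:80, length(ids), replace = TRUE)
      data.frame(patient_id = ids, sex = sex, age = age,
                 therapy = unname(therapy), irecist = unname(irecist),
                 stringsAsFactors = FALSE)
    })
    clin$outcome_group <- derive_outcome_group(clin$irecist)
    baseline <- with_seed(derive_seed(seed, "baseline"), list(
      a1 = setNames(71.0 + rnorm(length(ids), 0, 0.5), ids),
      t2 = setNames(3.30 + rnorm(length(ids), 0, 0.05), ids),
      sem_a1 = 0.7, sem_t2 = 0.05))
    subjects <- list(patients = clin)
    anchors <- flim_anchors()
    deltas <- list(a1 = 3.0, t2 = 0.40)
  } else {
    samples <- .mouse_activation()
    ids <- samples$sample_id
    dirs <- .mouse_directions()
    days <- c(2L, 7L, 14L)
    baseline <- with_seed(derive_seed(seed, "baseline"), list(
      a1 = setNames(69.5 + rnorm(length(ids), 0, 0.5), ids),
      t2 = setNames(2.95 + rnorm(length(ids), 0, 0.05), ids),
      sem_a1 = 0.8, sem_t2 = 0.06))
    subjects <- list(samples = samples)
    anchors <- flim_anchors()
    deltas <- list(a1 = 3.0, t2 = 0.40)
  }
  specs <- list()
  for (sid in ids) for (d in days) for (cond in c("control", "treated")) {
    params <- .arm_params(sid, d, cond, dirs, anchors, baseline, deltas,
                          n_cells = n_cells, photons = photons_per_cell)
    sp <- arm_spec(sid, cond, d, params, derive_seed(seed, "arm", sid, d, cond))
    specs[[paste(sid, d, cond, sep = "_")]] <- sp
  }
  structure(c(list(kind = kind), subjects,
              list(arm_specs = specs, directions = dirs,
                   flow_effects = if (kind == "mouse") .mouse_flow_effects(),
                   seed = as.integer(seed))),
            class = "cohort_fixture")
}

#' @export
print.cohort_fixture <- function(x, ...) {
  n <- if (x$kind == "patient") nrow(x$patients) else nrow(x$samples)
  cat(sprintf("<cohort_fixture> %s: %d subjects, %d arm specs (seed %d)\n",
              x$kind, n, length(x$arm_specs), x$seed))
  invisible(x)
}
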