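# Efficiency-aware qPCR expression analysis: two-reference normalisation
# (POLR2A + ELF1, geometric-mean combination) and log2 fold-changes of the
# metabolic gene panel, treated vs control.

#' Metabolic gene panel with pathway annotation
#'
#' @return Data frame (`gene`, `pathway`) covering glycolysis, the pentose
#'   phosphate pathway, fatty acid synthesis and oxidation, the TCA cycle,
#'   OXPHOS and mitochondrial biogenesis.
#' @export
metabolic_gene_panel <- function() {
  data.frame(
    gene = c("HK1", "LDHA", "PDK1", "G6PD", "ACACA", "ACADM", "HADHA",
             "OGDH", "NDUFS1", "NDUFA6", "ATP5F1B", "TFB2M"),
    pathway = c("glycolysis", "glycolysis", "glycolysis", "PPP",
                "FA_synthesis", "FAO", "FAO", "TCA", "OXPHOS", "OXPHOS",
                "OXPHOS", "mito_biogenesis"),
    stringsAsFactors = FALSE)
}

.default_refs <- c("POLR2A", "ELF1")

#' Simulate a qPCR Cq table with known fold changes
#'
#' Generates Cq values per gene x condition x replicate consistent with the
#' requested true log2 fold-changes under per-gene amplification
#' efficiencies: a one-unit log2 change in quantity shifts Cq by
#' `-log(2)/log(E)` cycles. Reference genes must be present with a true
#' log2FC of 0.
#'
#' @param true_log2fc Named numeric vector of per-gene true log2
#'   fold-changes (treated vs control).
#' @param seed Integer seed.
#' @param n_replicates Replicates per gene x condition (>= 2 in the assay
#'   design).
#' @param efficiencies Optional named per-gene efficiencies; drawn uniformly
#'   in the interval (1.8, 2.0) when `NULL`.
#' @param reference_genes Names of the reference genes (default POLR2A,
#'   ELF1).
#' @param cq_noise_sd Replicate-level Cq noise (cycles).
#' @return Data frame (`gene`, `condition`, `replicate`, `cq`,
#'   `efficiency`).
#' @export
simulate_qpcr_table <- function(true_log2fc, seed = NULL, n_replicates = 2L,
                                efficiencies = NULL,
                                reference_genes = .default_refs,
                                cq_noise_sd = 0.15) {
  genes <- names(true_log2fc)
  missing_refs <- setdiff(reference_genes, genes)
  if (length(missing_refs))
    stop("missing reference gene(s): ", paste(missing_refs, collapse = ", "))
  if (any(true_log2fc[reference_genes] != 0))
    stop("reference genes must have true_log2fc = 0")
  with_seed(seed, {
    if (is.null(efficiencies))
      efficiencies <- setNames(runif(length(genes), 1.8, 2.0), genes)
    base_cq <- setNames(runif(length(genes), 20, 28), genes)
    grid <- expand.grid(gene = genes, condition = c("control", "treated"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    eff <- efficiencies[grid$gene]
    shift <- ifelse(grid$condition == "treated",
                    -true_log2fc[grid$gene] * log(2) / log(eff), 0)
    grid$cq <- base_cq[grid$gene] + shift + rnorm(nrow(grid), 0, cq_noise_sd)
    grid$efficiency <- unname(eff)
    grid
  })
}

#' Reference-normalised log2 fold-change for one target gene
#'
#' Efficiency-aware ratio: relative quantity per condition is
#' `E_target^(-Cq_target)` normalised by the geometric mean of
#' `E_ref^(-Cq_ref)` over both reference genes; replicate Cq values are
#' averaged within condition before ratioing, and the log2 of the
#' treated/control quantity ratio is reported with a replicate-spread
#' standard error.
#'
#' @param table A Cq table as from [simulate_qpcr_table()].
#' @param target Target gene name.
#' @param reference_genes Reference gene names (must be measured in both
#'   conditions).
#' @return One-row data frame (`gene`, `log2fc`, `se`, `n_control`,
#'   `n_treated`).
#' @export
log2_fold_change <- function(table, target, reference_genes = .default_refs) {
  needed <- c(target, reference_genes)
  for (g in needed) for (cond in c("control", "treated")) {
    if (!any(table$gene == g & table$condition == cond))
      stop(sprintf("gene %s not measured in %s condition", g, cond))
  }
  sub <- table[table$gene %in% needed, ]
  if (min(table(sub$gene, sub$condition)) < 2)
    warning("single replicate for at least one gene/condition")
  eff <- vapply(needed, function(g) table$efficiency[table$gene == g][1],
                numeric(1))
  # per-condition log2 relative quantity and its replicate-based variance
  lq <- function(cond) {
    terms <- lapply(needed, function(g) {
      cq <- sub$cq[sub$gene == g & sub$condition == cond]
      w <- if (g == target) -1 else 1 / length(reference_genes)
      list(mean = w * mean(cq) * log2(eff[[g]]),
           var = (w * log2(eff[[g]]))^2 * stats::var(cq) / length(cq),
           n = length(cq))
    })
    list(mean = sum(vapply(terms, `[[`, numeric(1), "mean")),
         var = sum(vapply(terms, function(t) ifelse(is.na(t$var), 0, t$var),
                          numeric(1))),
         n = terms[[1]]$n)
  }
  ctrl <- lq("control"); trt <- lq("treated")
  data.frame(gene = target, log2fc = trt$mean - ctrl$mean,
             se = sqrt(trt$var + ctrl$var),
             n_control = ctrl$n, n_treated = trt$n,
             stringsAsFactors = FALSE)
}

#' Log2 fold-changes for all target genes in a Cq table
#'
#' @inheritParams log2_fold_change
#' @param targets Target genes (default: every non-reference gene present).
#' @return Data frame of stacked [log2_fold_change()] rows.
#' @export
log2_fold_change_table <- function(table, targets = NULL,
                                   reference_genes = .default_refs) {
  if (is.null(targets))
    targets <- setdiff(unique(table$gene), reference_genes)
  do.call(rbind, lapply(targets, log2_fold_change, table = table,
                        reference_genes = reference_genes))
}

#' Patients x genes expression heatmap
#'
#' Renders the per-patient, per-gene log2 fold-change matrix on a diverging
#' scale centred at zero and optionally writes it to file.
#'
#' @param results Long data frame (`patient_id`, `gene`, `log2fc`) or an
#'   already-shaped patients x genes matrix.
#' @param gene_panel Genes (column order); default [metabolic_gene_panel()].
#' @param filename Optional output file (png/pdf via pheatmap).
#' @return The patients x genes matrix, invisibly.
#' @export
expression_heatmap <- function(results, gene_panel = metabolic_gene_panel()$gene,
                               filename = NA) {
  if (is.matrix(results)) {
    mat <- results
  } else {
    stopifnot(all(c("patient_id", "gene", "log2fc") %in% names(results)))
    patients <- unique(results$patient_id)
    genes <- intersect(gene_panel, unique(results$gene))
    mat <- matrix(NA_real_, length(patients), length(genes),
                  dimnames = list(patients, genes))
    for (i in seq_len(nrow(results)))
      if (results$gene[i] %in% genes)
        mat[results$patient_id[i], results$gene[i]] <- results$log2fc[i]
  }
  lim <- max(abs(mat), 0.1, na.rm = TRUE)
  pheatmap::pheatmap(
    mat, cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(-lim, lim, length.out = 101),
    color = colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100),
    filename = if (is.na(filename)) NA else filename, silent = TRUE)
  invisible(mat)
}
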