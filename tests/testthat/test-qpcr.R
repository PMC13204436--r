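qpcr_rows <- function(gene, cq_control, cq_treated, efficiency = 2) {
  rbind(
    data.frame(gene = gene, condition = "control",
               replicate = seq_along(cq_control), cq = cq_control,
               efficiency = efficiency),
    data.frame(gene = gene, condition = "treated",
               replicate = seq_along(cq_treated), cq = cq_treated,
               efficiency = efficiency))
}

flat_table <- function() {
  rbind(qpcr_rows("POLR2A", c(24, 24.1), c(24, 24.1)),
        qpcr_rows("ELF1", c(25, 25.1), c(25, 25.1)),
        qpcr_rows("HK1", c(26, 26.1), c(26, 26.1)))
}

test_that("identical Cq values give a zero fold change", {
  expect_equal(log2_fold_change(flat_table(), "HK1")$log2fc, 0)
})

test_that("a one-cycle drop at perfect efficiency doubles expression", {
  tab <- rbind(qpcr_rows("POLR2A", c(24, 24), c(24, 24)),
               qpcr_rows("ELF1", c(25, 25), c(25, 25)),
               qpcr_rows("HK1", c(26, 26), c(25, 25)))
  res <- log2_fold_change(tab, "HK1")
  expect_equal(res$log2fc, 1)
  # textbook 2^-ddCq oracle at E = 2 with averaged references
  ddcq <- (25 - (24 + 25) / 2) - (26 - (24 + 25) / 2)
  expect_equal(2^res$log2fc, 2^(-ddcq))
})

test_that("simulated spikes are recovered by the analysis", {
  truth <- c(POLR2A = 0, ELF1 = 0, LDHA = 1.5, HK1 = 1, OGDH = 0)
  est <- t(vapply(1:10, function(i) {
    tab <- simulate_qpcr_table(truth, seed = 100 + i)
    c(log2_fold_change(tab, "LDHA")$log2fc,
      log2_fold_change(tab, "HK1")$log2fc)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 1.5), 0.15)
  expect_lt(abs(mean(est[, 2]) - 1), 0.15)
})

test_that("null tables recover near-zero fold changes at duplicate level", {
  truth <- c(POLR2A = 0, ELF1 = 0, HK1 = 0)
  est <- vapply(1:50, function(i)
    log2_fold_change(simulate_qpcr_table(truth, seed = 300 + i), "HK1")$log2fc,
    numeric(1))
  expect_lt(abs(mean(est)), 0.1)
})

test_that("swapping condition labels negates the fold change exactly", {
  tab <- simulate_qpcr_table(c(POLR2A = 0, ELF1 = 0, LDHA = 1.2), seed = 9)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "control", "treated", "control")
  expect_equal(log2_fold_change(swapped, "LDHA")$log2fc,
               -log2_fold_change(tab, "LDHA")$log2fc, tolerance = 1e-12)
})

test_that("a global Cq offset in one condition cancels at equal efficiency", {
  tab <- flat_table()
  tab$cq[tab$condition == "treated"] <- tab$cq[tab$condition == "treated"] + 1.7
  expect_equal(log2_fold_change(tab, "HK1")$log2fc, 0, tolerance = 1e-12)
})

test_that("missing references and single replicates are caught", {
  tab <- flat_table()
  expect_error(log2_fold_change(tab[tab$gene != "ELF1", ], "HK1"), "ELF1")
  expect_error(simulate_qpcr_table(c(POLR2A = 0, HK1 = 1), seed = 1), "ELF1")
  expect_error(simulate_qpcr_table(c(POLR2A = 0, ELF1 = 0.5, HK1 = 1),
                                   seed = 1),
               "reference")
  single <- tab[tab$replicate == 1 | tab$gene != "HK1", ]
  expect_warning(log2_fold_change(single, "HK1"), "single replicate")
})

test_that("fold-change tables and heatmaps reflect the expression profile", {
  panel <- metabolic_gene_panel()
  truth_resp <- setNames(rep(1.2, nrow(panel)), panel$gene)
  truth_resp[c("NDUFS1", "NDUFA6", "ATP5F1B")] <- 0.2
  long <- do.call(rbind, lapply(c("Pa", "Pb"), function(pid) {
    tab <- simulate_qpcr_table(c(POLR2A = 0, ELF1 = 0, truth_resp),
                               seed = derive_seed(5, pid))
    res <- log2_fold_change_table(tab)
    res$patient_id <- pid
    res
  }))
  f <- file.path(tempdir(), "hm.png")
  mat <- expression_heatmap(long, filename = f)
  expect_true(file.exists(f))
  expect_equal(dim(mat), c(2, nrow(panel)))
  expect_true(all(rowMeans(mat) > 0))
  # non-responder profile: predominantly negative matrix
  truth_non <- setNames(rep(-1, nrow(panel)), panel$gene)
  tabn <- simulate_qpcr_table(c(POLR2A = 0, ELF1 = 0, truth_non), seed = 77)
  resn <- log2_fold_change_table(tabn)
  resn$patient_id <- "Pn"
  matn <- expression_heatmap(resn)
  expect_lt(mean(matn), 0)
  unlink(f)
})
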