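writeTargetFile <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("target predictions union across databases with attribution", {
  d <- withr::local_tempdir()
  p1 <- writeTargetFile(data.frame(mirna = c("mmu-miR-29a-5p", "mir-1-5p"),
                                   gene = c("Ube2d3", "Chm")),
                        file.path(d, "ts.tsv"))
  p2 <- writeTargetFile(data.frame(mirna = "miR-29a-5p", gene = "UBE2D3"),
                        file.path(d, "db.tsv"))
  tps <- loadTargetPredictions(c(TargetScan = p1, mirDB = p2))
  e <- targetEdges(tps)
  expect_equal(nrow(e), 2)            # case-variant symbols merged
  row <- e[e$gene == "UBE2D3" & e$mirna == "mir-29a-5p", ]
  expect_equal(row$sources, "TargetScan,mirDB")

  p3 <- writeTargetFile(data.frame(mirna = character(0), gene = character(0)),
                        file.path(d, "empty.tsv"))
  expect_warning(loadTargetPredictions(c(TargetScan = p1, DIANA = p3)),
                 "empty")
  p4 <- writeTargetFile(data.frame(x = 1), file.path(d, "bad.tsv"))
  expect_error(loadTargetPredictions(c(DIANA = p4)), "bad.tsv")
  expect_error(loadTargetPredictions(unname(c(p1))), "named")
})

test_that("layer overlap counts nest and handle edge cases", {
  de <- deRecord(c("GENE1", "GENE2", "GENE3"), c(1, -2, 0.5),
                 c(0.01, 0.01, 0.01))
  pc <- data.frame(protein_id = c("GENE2", "GENE9"), log2fc = c(1.7, -2),
                   direction = c("up", "down"))
  ov <- layerOverlap(de, c("GENE2", "GENE3", "GENE9"), pc)
  expect_equal(ov$n_de_mrna, 3)
  expect_equal(ov$n_de_mrna_detected_in_proteome, 2)
  expect_equal(ov$n_both_layers, 1)
  expect_equal(ov$both_layer_records$gene, "GENE2")
  expect_equal(ov$both_layer_records$protein_log2fc, 1.7)
  expect_true(ov$n_both_layers <= ov$n_de_mrna_detected_in_proteome)

  ov0 <- layerOverlap(de, "OTHER", pc[0, , drop = FALSE])
  expect_equal(c(ov0$n_de_mrna_detected_in_proteome, ov0$n_both_layers),
               c(0, 0))
})

test_that("anti-correlation requires a predicted edge, layer filter and opposite sign", {
  tps <- TargetPredictionSet(rep("mir-5-5p", 3), c("G1", "G2", "G3"),
                             rep("TargetScan", 3))
  cand <- data.frame(mirna_id = "mir-5-5p", log2fc_1 = 1, p_1 = 0.01,
                     log2fc_2 = 1, p_2 = 0.01, direction = "up")
  de <- deRecord(c("G1", "G2", "G4"), c(-1, 1, -2), 0.01)
  pc <- data.frame(protein_id = "G3", log2fc = -1.8, direction = "down")
  res <- suppressMessages(antiCorrelatedTargets(cand, de, pc, tps))
  hits <- res$per_mirna[["mir-5-5p"]]
  expect_equal(hits$mrna_hits$gene, "G1")      # G2 wrong sign, G4 no edge
  expect_equal(hits$protein_hits$gene, "G3")
  expect_equal(res$n_target_mrnas, 1)
  expect_equal(res$n_target_mrnas_down, 1)
  expect_equal(res$n_target_mrnas_up, 0)
})

test_that("noise-free planted inputs recover exactly the planted edge set", {
  sim <- simulateStudy(tinyConfig(seed = 31, anticorr_target_fraction = 0.4))
  truth <- sim$truth
  rec <- truthRecords(truth)
  res <- suppressMessages(antiCorrelatedTargets(
    rec$candidates, rec$de_mrna, rec$protein_candidates, sim$targets))
  got <- unique(unlist(lapply(names(res$per_mirna), function(m) {
    h <- res$per_mirna[[m]]
    paste(m, c(h$mrna_hits$gene, h$protein_hits$gene))
  })))
  want <- paste(truth@target_edges$mirna, truth@target_edges$gene)
  expect_setequal(got, want)
})

test_that("hit sets are invariant under global direction flip", {
  sim <- simulateStudy(tinyConfig(seed = 37))
  rec <- truthRecords(sim$truth)
  flip <- function(df, fc_col = "log2fc") {
    df[[fc_col]] <- -df[[fc_col]]
    df$direction <- ifelse(df$direction == "up", "down", "up")
    df
  }
  rec2 <- list(candidates = {
    x <- rec$candidates
    x$log2fc_1 <- -x$log2fc_1; x$log2fc_2 <- -x$log2fc_2
    x$direction <- ifelse(x$direction == "up", "down", "up"); x
  }, de_mrna = flip(rec$de_mrna), protein_candidates = flip(rec$protein_candidates))
  r1 <- suppressMessages(antiCorrelatedTargets(
    rec$candidates, rec$de_mrna, rec$protein_candidates, sim$targets))
  r2 <- suppressMessages(antiCorrelatedTargets(
    rec2$candidates, rec2$de_mrna, rec2$protein_candidates, sim$targets))
  for (m in names(r1$per_mirna)) {
    expect_setequal(r1$per_mirna[[m]]$mrna_hits$gene,
                    r2$per_mirna[[m]]$mrna_hits$gene)
    expect_setequal(r1$per_mirna[[m]]$protein_hits$gene,
                    r2$per_mirna[[m]]$protein_hits$gene)
  }
})

test_that("tightening the mRNA filter never adds anti-correlated hits", {
  sim <- simulateStudy(tinyConfig(seed = 41))
  de_all <- deTest(sim$mrna)
  q <- quantifyProteins(normalizeChannels(sim$peptides))
  pc <- proteinCandidates(q)
  de1 <- deTest(sim$mirna_cohort1); de2 <- deTest(sim$mirna_cohort2)
  cand <- suppressMessages(concordantMirnaCandidates(de1, de2))
  prev <- NULL
  for (alpha in c(0.2, 0.05, 0.01)) {
    de <- filterDeMrna(de_all, alpha = alpha, use_adjusted = FALSE)
    res <- suppressMessages(antiCorrelatedTargets(cand, de, pc, sim$targets))
    genes <- unique(unlist(lapply(res$per_mirna, function(h) h$mrna_hits$gene)))
    if (!is.null(prev)) expect_true(all(genes %in% prev))
    prev <- genes
  }
})

test_that("top-regulated matrix matches a brute-force double loop", {
  sim <- simulateStudy(tinyConfig(seed = 43))
  rec <- truthRecords(sim$truth)
  # grade the planted fold changes so the top-N selection is non-trivial
  set.seed(1)
  rec$de_mrna$log2fc <- rec$de_mrna$log2fc * runif(nrow(rec$de_mrna), 0.5, 1.5)
  mat <- topRegulatedMatrix(rec$de_mrna, rec$candidates, sim$targets, n = 10)
  expect_equal(nrow(mat), 10)
  edges <- targetEdges(sim$targets)
  for (g in rownames(mat)) for (m in colnames(mat)) {
    lfc <- rec$de_mrna$log2fc[rec$de_mrna$feature_id == g]
    dir <- rec$candidates$direction[rec$candidates$mirna_id == m]
    expected <- any(edges$mirna == m & edges$gene == g) &&
      sign(lfc) == -ifelse(dir == "up", 1, -1)
    expect_identical(unname(mat[g, m]), expected)
  }
  # truncation when fewer features than n; rejection of bad n
  small <- rec$de_mrna[1:4, ]
  expect_equal(nrow(topRegulatedMatrix(small, rec$candidates, sim$targets,
                                       n = 15)), 4)
  expect_error(topRegulatedMatrix(small, rec$candidates, sim$targets, n = 0),
               "positive")
})

test_that("per-miRNA report is consistent with the global hit sets", {
  sim <- simulateStudy(tinyConfig(seed = 47, anticorr_target_fraction = 0.5))
  rec <- truthRecords(sim$truth)
  res <- suppressMessages(antiCorrelatedTargets(
    rec$candidates, rec$de_mrna, rec$protein_candidates, sim$targets))
  m <- rec$candidates$mirna_id[1]
  rep_ <- mirnaTargetReport(m, res)
  expect_setequal(rep_$mrna$gene, res$per_mirna[[m]]$mrna_hits$gene)
  expect_setequal(rep_$protein$gene, res$per_mirna[[m]]$protein_hits$gene)
  expect_false(is.unsorted(rep_$mrna$log2fc))
  expect_true(all(grepl("TargetScan|mirDB|DIANA", rep_$mrna$sources)))
  expect_error(mirnaTargetReport("mir-none-5p", res), "not among")
})
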