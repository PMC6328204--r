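peptideFixture <- function(intens, protein = paste0("P", seq_len(nrow(intens))),
                           peptide = paste0("pep", seq_len(nrow(intens)))) {
  colnames(intens) <- c("126", "127")[seq_len(ncol(intens))]
  if (ncol(intens) == 6) colnames(intens) <- as.character(126:131)
  PeptideReporterTable(peptide, protein, intens,
                       setNames(rep(c("naive", "stressed"),
                                    each = ncol(intens) / 2),
                                colnames(intens)))
}

test_that("channel normalization equalizes totals and conserves grand signal", {
  # totals 100 and 200 -> factors 1.5 and 0.75, both totals 150
  tab <- peptideFixture(cbind(c(40, 60), c(80, 120)))
  norm <- normalizeChannels(tab)
  expect_equal(unname(colSums(reporterIntensities(norm))), c(150, 150))
  expect_equal(reporterIntensities(norm)[, 1],
               reporterIntensities(tab)[, 1] * 1.5)
  expect_equal(sum(reporterIntensities(norm)), sum(reporterIntensities(tab)))

  # already equal totals: identity
  tab2 <- peptideFixture(cbind(c(30, 70), c(50, 50)))
  expect_equal(reporterIntensities(normalizeChannels(tab2)),
               reporterIntensities(tab2))

  # global rescaling is equivariant
  tab3 <- peptideFixture(cbind(c(40, 60), c(80, 120)) * 7)
  expect_equal(reporterIntensities(normalizeChannels(tab3)),
               reporterIntensities(norm) * 7)
})

test_that("a channel with zero total fails naming the channel", {
  tab <- suppressWarnings(peptideFixture(cbind(c(1, 1), c(0, 0))))
  expect_error(normalizeChannels(tab), "127")
})

test_that("protein quantification aggregates peptides and computes log2fc", {
  # one protein, group means naive 100 / stressed 25 -> log2fc -2
  intens <- matrix(c(60, 40, 60, 40, 60, 40,
                     15, 10, 15, 10, 15, 10), nrow = 2,
                   dimnames = list(NULL, as.character(126:131)))
  tab <- PeptideReporterTable(c("pep1", "pep2"), c("P1", "P1"), intens,
                              setNames(rep(c("naive", "stressed"), each = 3),
                                       as.character(126:131)))
  q <- quantifyProteins(tab)
  expect_equal(q$log2fc, -2)
  expect_equal(q$naive_intensity, 100)
  expect_equal(q$n_peptides, 2L)

  # row order and row splitting do not change the quantification
  tab_rev <- PeptideReporterTable(c("pep2", "pep1"), c("P1", "P1"),
                                  intens[2:1, ], channelGroups(tab))
  expect_equal(quantifyProteins(tab_rev)$log2fc, q$log2fc)
  half <- intens[1, , drop = FALSE] / 2
  split_tab <- PeptideReporterTable(c("pep1a", "pep1b", "pep2"),
                                    rep("P1", 3), rbind(half, half, intens[2, ]),
                                    channelGroups(tab))
  expect_equal(quantifyProteins(split_tab)$log2fc, q$log2fc)
})

test_that("relabeling groups negates every protein log2fc", {
  sim <- simulatePeptideTable(tinyConfig(seed = 17))
  tab <- normalizeChannels(sim$table)
  swapped <- tab
  swapped@channelGroups <- setNames(
    ifelse(channelGroups(tab) == "naive", "stressed", "naive"),
    names(channelGroups(tab)))
  q1 <- quantifyProteins(tab)
  q2 <- quantifyProteins(swapped)
  expect_equal(q2$log2fc, -q1$log2fc)
})

test_that("zero naive intensity excludes the protein with a warning", {
  intens <- matrix(c(0, 0, 0, 10, 10, 10,
                     5, 5, 5, 10, 10, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, as.character(126:131)))
  tab <- PeptideReporterTable(c("pep1", "pep2"), c("P1", "P2"), intens,
                              setNames(rep(c("naive", "stressed"), each = 3),
                                       as.character(126:131)))
  expect_warning(q <- quantifyProteins(tab), "P1")
  expect_equal(q$protein_id, "P2")
})

test_that("candidate filter boundary is inclusive and monotone in lfc_min", {
  q <- data.frame(protein_id = c("A", "B", "C"),
                  naive_intensity = 1, stressed_intensity = 1,
                  log2fc = c(1.5, -1.49, -2.2), n_peptides = 2L)
  cand <- proteinCandidates(q)
  expect_setequal(cand$protein_id, c("A", "C"))
  expect_equal(cand$direction[cand$protein_id == "A"], "up")
  expect_equal(nrow(proteinCandidates(q, inclusive = FALSE)), 1)
  n_prev <- Inf
  for (thr in c(0.5, 1, 1.5, 2, 2.5)) {
    n <- nrow(proteinCandidates(q, lfc_min = thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("planted protein fold changes are recovered within 0.3 log2 units", {
  cfg <- tinyConfig(seed = 23, n_peptides_per_protein = 10,
                    planted_protein_lfc = 2)
  sim <- simulatePeptideTable(cfg)
  q <- quantifyProteins(normalizeChannels(sim$table))
  tp <- sim$truth@de_protein
  est <- q$log2fc[match(tp$protein, q$protein_id)]
  expected <- ifelse(tp$direction == "up", 2, -2)
  expect_true(all(abs(est - expected) <= 0.3))
})
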