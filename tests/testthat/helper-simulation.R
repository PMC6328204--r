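# small configs and noise-free record builders shared across test files

tinyConfig <- function(seed = 11, ...) {
  args <- list(seed = seed, n_features_mirna = 60, n_features_mrna = 150,
               n_proteins = 60, n_peptides_per_protein = 3,
               n_planted_concordant_mirna = 5,
               n_planted_single_cohort_mirna = 2,
               n_planted_de_mrna = 20, n_planted_de_protein = 10)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}

# DE / quant records carrying exactly the planted log2FCs with p = 0:
# what the layers would report with no measurement noise
truthRecords <- function(truth, lfc_mrna = 2, lfc_prot = 2) {
  sgn <- function(d) ifelse(d == "up", 1, -1)
  list(
    de_mrna = data.frame(
      feature_id = truth@de_mrna$gene,
      log2fc = sgn(truth@de_mrna$direction) * lfc_mrna,
      p_value = 0, adj_p = 0,
      direction = truth@de_mrna$direction, stringsAsFactors = FALSE),
    protein_candidates = data.frame(
      protein_id = truth@de_protein$protein,
      log2fc = sgn(truth@de_protein$direction) * lfc_prot,
      n_peptides = 1L,
      direction = truth@de_protein$direction, stringsAsFactors = FALSE),
    candidates = data.frame(
      mirna_id = truth@concordant_mirna$mirna,
      log2fc_1 = sgn(truth@concordant_mirna$direction),
      p_1 = 0,
      log2fc_2 = sgn(truth@concordant_mirna$direction),
      p_2 = 0,
      direction = truth@concordant_mirna$direction, stringsAsFactors = FALSE)
  )
}

# minimal DE record table for concordance-rule unit tests
deRecord <- function(ids, lfc, p) {
  data.frame(feature_id = ids, base_mean = 100, log2fc = lfc, p_value = p,
             adj_p = pmin(1, p * 2),
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             stringsAsFactors = FALSE)
}
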