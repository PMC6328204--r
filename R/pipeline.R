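#' Pipeline configuration
#'
#' Bundles input paths and analysis thresholds. Threshold defaults are the
#' published rules: miRNA concordance at |log2FC| >= 0.5 with raw p < 0.05 in
#' both cohorts; mRNA selection at adjusted p < 0.05; protein candidacy at
#' |log2FC| >= 1.5; top-15 regulation matrices.
#'
#' @param mirna_cohort1,mirna_cohort1_sheet,mirna_cohort2,mirna_cohort2_sheet
#'   per-cohort miRNA count matrix and sample sheet paths.
#' @param mrna,mrna_sheet mRNA count matrix and sample sheet paths.
#' @param peptides,channel_map peptide table and channel map paths.
#' @param target_files named character vector of per-database target TSVs.
#' @param gene_sets optional GMT path; enrichment is skipped when `NULL`.
#' @param ct_table optional qPCR Ct TSV; the qPCR stage is skipped when
#'   `NULL`.
#' @param mirna_lfc_min,mirna_alpha miRNA concordance thresholds.
#' @param mrna_alpha,mrna_use_adjusted mRNA significance filter.
#' @param protein_lfc_min protein candidate threshold.
#' @param top_n rows of the regulation matrices.
#' @param out_dir output directory for stage tables and the summary JSON.
#' @return a validated list of class `stressomics_config`.
#' @export
pipelineConfig <- function(mirna_cohort1, mirna_cohort1_sheet,
                           mirna_cohort2, mirna_cohort2_sheet,
                           mrna, mrna_sheet, peptides, channel_map,
                           target_files, gene_sets = NULL, ct_table = NULL,
                           mirna_lfc_min = 0.5, mirna_alpha = 0.05,
                           mrna_alpha = 0.05, mrna_use_adjusted = TRUE,
                           protein_lfc_min = 1.5, top_n = 15,
                           out_dir = "stressomics_out") {
  cfg <- list(mirna_cohort1 = mirna_cohort1,
              mirna_cohort1_sheet = mirna_cohort1_sheet,
              mirna_cohort2 = mirna_cohort2,
              mirna_cohort2_sheet = mirna_cohort2_sheet,
              mrna = mrna, mrna_sheet = mrna_sheet,
              peptides = peptides, channel_map = channel_map,
              target_files = target_files, gene_sets = gene_sets,
              ct_table = ct_table,
              mirna_lfc_min = mirna_lfc_min, mirna_alpha = mirna_alpha,
              mrna_alpha = mrna_alpha, mrna_use_adjusted = mrna_use_adjusted,
              protein_lfc_min = protein_lfc_min, top_n = as.integer(top_n),
              out_dir = out_dir)
  if (cfg$mirna_alpha <= 0 || cfg$mirna_alpha >= 1 ||
      cfg$mrna_alpha <= 0 || cfg$mrna_alpha >= 1)
    stop("alpha thresholds must lie in (0, 1)")
  if (cfg$mirna_lfc_min < 0 || cfg$protein_lfc_min < 0)
    stop("fold-change thresholds must be non-negative")
  if (cfg$top_n < 1L) stop("top_n must be >= 1")
  class(cfg) <- "stressomics_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; `target_files` is a named
#' mapping database -> path.
#'
#' @param path YAML file path.
#' @return a `stressomics_config`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$target_files <- unlist(y$target_files)
  do.call(pipelineConfig, y)
}

#' Run the full integration pipeline
#'
#' Orchestrates: per-cohort miRNA differential expression and the concordance
#' filter; mRNA differential expression and significance filtering; TMT
#' channel normalization, protein quantification and candidate filtering;
#' target-prediction loading; transcriptome/proteome overlap; anti-correlation
#' integration; top-N regulation matrices; optional enrichment and qPCR
#' stages. All stage tables are written to `config$out_dir` together with a
#' machine-readable `summary.json`.
#'
#' @param config a `stressomics_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, a list with all stage outputs and the `summary` list.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "stressomics_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  message("[de_mirna] two-cohort differential expression")
  c1 <- readCountMatrix(config$mirna_cohort1, config$mirna_cohort1_sheet,
                        layer = "mirna")
  c2 <- readCountMatrix(config$mirna_cohort2, config$mirna_cohort2_sheet,
                        layer = "mirna")
  de1 <- deTest(c1); de2 <- deTest(c2)
  wtsv(de1, "de_mirna_cohort1.tsv"); wtsv(de2, "de_mirna_cohort2.tsv")
  candidates <- concordantMirnaCandidates(de1, de2,
                                          lfc_min = config$mirna_lfc_min,
                                          alpha = config$mirna_alpha)
  wtsv(candidates, "mirna_candidates.tsv")
  message("[de_mrna] differential expression")
  rna <- readCountMatrix(config$mrna, config$mrna_sheet, layer = "mrna")
  de_rna_all <- deTest(rna)
  wtsv(de_rna_all, "de_mrna_all.tsv")
  de_rna <- filterDeMrna(de_rna_all, alpha = config$mrna_alpha,
                         use_adjusted = config$mrna_use_adjusted)
  wtsv(de_rna, "de_mrna_significant.tsv")
  message("[tmt] protein quantification")
  pep <- readPeptideTable(config$peptides, config$channel_map)
  quants <- quantifyProteins(normalizeChannels(pep))
  wtsv(quants, "protein_quant.tsv")
  prot_cand <- proteinCandidates(quants, lfc_min = config$protein_lfc_min)
  wtsv(prot_cand, "protein_candidates.tsv")
  message("[integrate] cross-layer alignment")
  targets <- loadTargetPredictions(config$target_files)
  overlap <- layerOverlap(de_rna, quants$protein_id, prot_cand)
  wtsv(overlap$both_layer_records, "both_layer_records.tsv")
  anti <- antiCorrelatedTargets(candidates, de_rna, prot_cand, targets)
  mat_rna <- topRegulatedMatrix(de_rna, candidates, targets, n = config$top_n)
  mat_prot <- topRegulatedMatrix(prot_cand, candidates, targets,
                                 n = config$top_n)
  utils::write.table(mat_rna * 1L,
                     file.path(config$out_dir, "top_matrix_mrna.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(mat_prot * 1L,
                     file.path(config$out_dir, "top_matrix_protein.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  enrich <- NULL
  if (!is.null(config$gene_sets)) {
    message("[enrich] over-representation analysis")
    coll <- readGmt(config$gene_sets)
    query <- unique(unlist(lapply(candidates$mirna_id, predictedTargets,
                                  x = targets)))
    if (length(intersect(normalizeGeneSymbols(query),
                         geneUniverse(coll))) > 0) {
      enrich <- ora(query, coll)
      wtsv(enrich, "enrichment.tsv")
    } else {
      message("[enrich] no candidate targets in the gene-set universe; skipped")
    }
  } else message("[enrich] no gene sets supplied; skipped")
  qpcr <- NULL
  if (!is.null(config$ct_table)) {
    message("[qpcr] delta-delta-Ct quantification")
    ct <- utils::read.delim(config$ct_table, stringsAsFactors = FALSE)
    qpcr <- lapply(split(ct, ct$target_id), function(sub) {
      rq <- ddctFoldChange(sub)
      test <- oneSampleFcTest(rq$rel_quantity[rq$group == "stressed"])
      list(quantities = rq, test = test)
    })
  } else message("[qpcr] no Ct table supplied; skipped")
  summary <- list(
    n_candidate_mirna = nrow(candidates),
    n_mirna_up = sum(candidates$direction == "up"),
    n_mirna_down = sum(candidates$direction == "down"),
    n_de_mrna = overlap$n_de_mrna,
    n_de_mrna_detected_in_proteome = overlap$n_de_mrna_detected_in_proteome,
    n_both_layers = overlap$n_both_layers,
    n_proteins_detected = nrow(quants),
    n_protein_candidates = nrow(prot_cand),
    n_target_mrnas = anti$n_target_mrnas,
    n_target_mrnas_up = anti$n_target_mrnas_up,
    n_target_mrnas_down = anti$n_target_mrnas_down,
    n_target_proteins = anti$n_target_proteins,
    enrichment_run = !is.null(enrich),
    qpcr_run = !is.null(qpcr),
    thresholds = config[c("mirna_lfc_min", "mirna_alpha", "mrna_alpha",
                          "mrna_use_adjusted", "protein_lfc_min", "top_n")],
    version = as.character(utils::packageVersion("stressomics")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(de_mirna_cohort1 = de1, de_mirna_cohort2 = de2,
                 candidates = candidates, de_mrna_all = de_rna_all,
                 de_mrna = de_rna, protein_quant = quants,
                 protein_candidates = prot_cand, targets = targets,
                 overlap = overlap, anti_correlated = anti,
                 top_matrix_mrna = mat_rna, top_matrix_protein = mat_prot,
                 enrichment = enrich, qpcr = qpcr, summary = summary))
}
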