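#' Read a count matrix with its sample sheet
#'
#' The count TSV has the feature id in the first column and one column per
#' sample; the sample sheet TSV has columns `sample_id`, `group`, `cohort`.
#' Mismatched sample sets, duplicated ids and non-integer counts are rejected
#' with messages naming the offenders.
#'
#' @param path count TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @param layer `"mirna"` or `"mrna"`.
#' @return an [OmicsCounts-class].
#' @export
readCountMatrix <- function(path, sample_sheet_path,
                            layer = c("mirna", "mrna")) {
  layer <- match.arg(layer)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("non-integer or negative counts in '", path, "' at row(s): ",
         paste(utils::head(ids[rowSums(is.na(m) | m != round(m) | m < 0) > 0], 5),
               collapse = ", "))
  rownames(m) <- ids
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "cohort") %in% colnames(sheet)))
    stop("sample sheet needs columns sample_id, group, cohort")
  only_mat <- setdiff(colnames(m), sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, colnames(m))
  if (length(only_mat) || length(only_sheet))
    stop("sample mismatch between matrix and sheet; matrix-only: [",
         paste(only_mat, collapse = ", "), "], sheet-only: [",
         paste(only_sheet, collapse = ", "), "]")
  sheet <- sheet[match(colnames(m), sheet$sample_id), ]
  OmicsCounts(m, group = sheet$group, cohort = sheet$cohort, layer = layer)
}

#' Write a count matrix and its sample sheet
#'
#' @param counts an [OmicsCounts-class].
#' @param path count TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @return invisibly, the two paths.
#' @export
writeCountMatrix <- function(counts, path, sample_sheet_path) {
  m <- SummarizedExperiment::assay(counts, "counts")
  tab <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(m), group = groupLabels(counts),
                      cohort = cohortLabels(counts))
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Read a peptide reporter table with its channel map
#'
#' The peptide TSV has columns `peptide_id`, `protein_id` and one numeric
#' column per channel; the channel map TSV has columns `channel`, `group`.
#'
#' @param path peptide TSV path.
#' @param channel_map_path channel map TSV path.
#' @return a [PeptideReporterTable-class].
#' @export
readPeptideTable <- function(path, channel_map_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "protein_id") %in% colnames(tab)))
    stop("peptide table needs columns peptide_id and protein_id")
  cmap <- utils::read.delim(channel_map_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!all(c("channel", "group") %in% colnames(cmap)))
    stop("channel map needs columns channel and group")
  chans <- as.character(cmap$channel)
  missing <- setdiff(chans, colnames(tab))
  if (length(missing))
    stop("channel(s) in map but not in table: ",
         paste(missing, collapse = ", "))
  PeptideReporterTable(tab$peptide_id, tab$protein_id,
                       as.matrix(tab[, chans, drop = FALSE]),
                       stats::setNames(cmap$group, chans))
}

#' Write a peptide reporter table and its channel map
#'
#' @param table a [PeptideReporterTable-class].
#' @param path peptide TSV path.
#' @param channel_map_path channel map TSV path.
#' @return invisibly, the two paths.
#' @export
writePeptideTable <- function(table, path, channel_map_path) {
  out <- data.frame(peptide_id = table@peptide, protein_id = table@protein,
                    table@intensities, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- data.frame(channel = names(table@channelGroups),
                     group = unname(table@channelGroups))
  utils::write.table(cmap, channel_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, channel_map_path))
}

#' Write a target-prediction set as per-database TSVs
#'
#' @param targets a [TargetPredictionSet-class].
#' @param dir output directory; one `targets_<db>.tsv` per database.
#' @return named character vector of paths, usable with
#'   [loadTargetPredictions()].
#' @export
writeTargetPredictions <- function(targets, dir) {
  edges <- targetEdges(targets)
  dbs <- sort(unique(unlist(strsplit(edges$sources, ",", fixed = TRUE))))
  paths <- character(0)
  for (db in dbs) {
    sel <- grepl(db, edges$sources, fixed = TRUE)
    path <- file.path(dir, paste0("targets_", db, ".tsv"))
    utils::write.table(edges[sel, c("mirna", "gene")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[db] <- path
  }
  paths
}

#' Serialize ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(concordant_mirna = truth@concordant_mirna,
              single_cohort_mirna = truth@single_cohort_mirna,
              de_mrna = truth@de_mrna, de_protein = truth@de_protein,
              target_edges = truth@target_edges)
  jsonlite::write_json(obj, path, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Reproduce the study's printed summary counts from result tables
#'
#' Applies the published selection rules to locally supplied TSV exports of
#' the study's supplementary result tables: per-cohort miRNA DE tables
#' (columns `mirna`, `log2fc`, `p_value`), a protein quantification table
#' (`protein`, `log2fc`) and an mRNA DE table (`gene`, `log2fc`, `p_value`,
#' `adj_p`). Returns the candidate and overlap counts those rules produce.
#'
#' @param mirna_cohort1,mirna_cohort2 paths to the per-cohort miRNA DE TSVs.
#' @param protein path to the protein quant TSV.
#' @param mrna path to the mRNA DE TSV.
#' @param mrna_use_adjusted filter mRNAs on adjusted p (default `TRUE`).
#' @return list of counts: `n_candidate_mirna`, `n_mirna_up`, `n_mirna_down`,
#'   `n_protein_candidates`, `n_protein_up`, `n_protein_down`, `n_de_mrna`,
#'   `n_mrna_up`, `n_mrna_down`, `n_de_mrna_detected_in_proteome`,
#'   `n_both_layers`.
#' @export
supplementaryCounts <- function(mirna_cohort1, mirna_cohort2, protein, mrna,
                                mrna_use_adjusted = TRUE) {
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  m1 <- rd(mirna_cohort1); m2 <- rd(mirna_cohort2)
  de1 <- data.frame(feature_id = m1$mirna, log2fc = m1$log2fc,
                    p_value = m1$p_value)
  de2 <- data.frame(feature_id = m2$mirna, log2fc = m2$log2fc,
                    p_value = m2$p_value)
  cand <- concordantMirnaCandidates(de1, de2)
  prot <- rd(protein)
  quants <- data.frame(protein_id = prot$protein, log2fc = prot$log2fc)
  pc <- proteinCandidates(quants)
  rna <- rd(mrna)
  rna_rec <- data.frame(feature_id = rna$gene, log2fc = rna$log2fc,
                        p_value = rna$p_value,
                        adj_p = if ("adj_p" %in% colnames(rna)) rna$adj_p
                                else bhAdjust(rna$p_value))
  de_rna <- filterDeMrna(rna_rec, use_adjusted = mrna_use_adjusted)
  ov <- layerOverlap(de_rna, quants$protein_id, pc)
  list(n_candidate_mirna = nrow(cand),
       n_mirna_up = sum(cand$direction == "up"),
       n_mirna_down = sum(cand$direction == "down"),
       n_protein_candidates = nrow(pc),
       n_protein_up = sum(pc$direction == "up"),
       n_protein_down = sum(pc$direction == "down"),
       n_de_mrna = nrow(de_rna),
       n_mrna_up = sum(de_rna$direction == "up"),
       n_mrna_down = sum(de_rna$direction == "down"),
       n_de_mrna_detected_in_proteome = ov$n_de_mrna_detected_in_proteome,
       n_both_layers = ov$n_both_layers)
}
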