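#' Load miRNA target predictions from per-database tables
#'
#' Reads one two-column (miRNA, gene) TSV per database, unions the edges and
#' keeps per-edge source attribution. IDs are normalized so edges from
#' different databases and cohorts merge onto shared keys.
#'
#' @param paths named character vector of file paths; names are the database
#'   labels (e.g. `c(TargetScan = "...", mirDB = "...", DIANA = "...")`).
#' @return a [TargetPredictionSet-class].
#' @export
loadTargetPredictions <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be named by their database label")
  rows <- list()
  for (db in names(paths)) {
    path <- paths[[db]]
    tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                    error = function(e)
                      stop("cannot read target file '", path, "': ",
                           conditionMessage(e)))
    if (!all(c("mirna", "gene") %in% colnames(tab)))
      stop("target file '", path, "' lacks columns 'mirna' and 'gene'")
    if (nrow(tab) == 0L) {
      warning("target file '", path, "' is empty; ", db,
              " contributes no edges")
      next
    }
    rows[[db]] <- data.frame(mirna = tab$mirna, gene = tab$gene, source = db,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no target-prediction edges could be read")
  flat <- do.call(rbind, rows)
  TargetPredictionSet(flat$mirna, flat$gene, flat$source)
}

#' Overlap between the DE transcriptome and the quantified proteome
#'
#' Counts the DE mRNAs, those whose symbol was technically detected in the
#' proteomics run, and those additionally passing the protein candidate
#' filter, and materializes the both-layer records with the fold change in
#' each layer.
#'
#' @param de_mrna data.frame of DE mRNA records (already significance
#'   filtered, see [filterDeMrna()]).
#' @param detected_proteins character vector of all protein ids detected by
#'   mass spec (candidates and non-candidates).
#' @param protein_candidates data.frame from [proteinCandidates()].
#' @return list with counts `n_de_mrna`, `n_de_mrna_detected_in_proteome`,
#'   `n_both_layers` and data.frame `both_layer_records`
#'   (gene, mrna_log2fc, protein_log2fc).
#' @export
layerOverlap <- function(de_mrna, detected_proteins, protein_candidates) {
  genes <- normalizeGeneSymbols(de_mrna$feature_id)
  detected <- unique(normalizeGeneSymbols(detected_proteins))
  cand <- normalizeGeneSymbols(protein_candidates$protein_id)
  in_prot <- genes %in% detected
  in_cand <- genes %in% cand
  idx <- which(in_cand)
  both <- data.frame(
    gene = genes[idx],
    mrna_log2fc = de_mrna$log2fc[idx],
    protein_log2fc = protein_candidates$log2fc[match(genes[idx], cand)],
    stringsAsFactors = FALSE, row.names = NULL)
  both <- both[order(both$gene), , drop = FALSE]
  rownames(both) <- NULL
  list(n_de_mrna = length(genes),
       n_de_mrna_detected_in_proteome = sum(in_prot),
       n_both_layers = sum(in_cand),
       both_layer_records = both)
}

#' Anti-correlated predicted targets of candidate miRNAs
#'
#' For each candidate miRNA, a gene is an mRNA-layer hit iff it is a predicted
#' target of that miRNA, appears in the supplied (significance-filtered) DE
#' mRNA list, and its fold change opposes the miRNA's direction — the pattern
#' expected under miRNA-mediated repression (and, for down-regulated miRNAs,
#' de-repression). Protein-layer hits are defined analogously over the protein
#' candidate list. Global counts deduplicate genes across miRNAs. Passing
#' unfiltered DE tables relaxes the definition to direction opposition alone.
#'
#' @param candidates data.frame from [concordantMirnaCandidates()].
#' @param de_mrna significance-filtered DE mRNA data.frame.
#' @param protein_candidates data.frame from [proteinCandidates()].
#' @param targets a [TargetPredictionSet-class].
#' @return list with `per_mirna` (named list; each element has data.frames
#'   `mrna_hits` and `protein_hits` with gene, log2fc, sources),
#'   `n_target_mrnas`, `n_target_mrnas_up`, `n_target_mrnas_down`,
#'   `n_target_proteins`, `n_target_proteins_up`, `n_target_proteins_down`.
#' @export
antiCorrelatedTargets <- function(candidates, de_mrna, protein_candidates,
                                  targets) {
  stopifnot(is(targets, "TargetPredictionSet"))
  edges <- targetEdges(targets)
  mg <- normalizeGeneSymbols(de_mrna$feature_id)
  pg <- normalizeGeneSymbols(protein_candidates$protein_id)
  per_mirna <- list()
  mrna_hit_rows <- list(); prot_hit_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    m <- normalizeMirnaIds(candidates$mirna_id[i])
    msign <- if (candidates$direction[i] == "up") 1 else -1
    e <- edges[edges$mirna == m, , drop = FALSE]
    if (nrow(e) == 0L)
      message("candidate miRNA ", m, " has no predicted targets")
    im <- match(e$gene, mg)
    keep_m <- !is.na(im) & sign(de_mrna$log2fc[im]) == -msign
    mrna_hits <- data.frame(gene = e$gene[keep_m],
                            log2fc = de_mrna$log2fc[im[keep_m]],
                            sources = e$sources[keep_m],
                            stringsAsFactors = FALSE, row.names = NULL)
    ip <- match(e$gene, pg)
    keep_p <- !is.na(ip) & sign(protein_candidates$log2fc[ip]) == -msign
    prot_hits <- data.frame(gene = e$gene[keep_p],
                            log2fc = protein_candidates$log2fc[ip[keep_p]],
                            sources = e$sources[keep_p],
                            stringsAsFactors = FALSE, row.names = NULL)
    per_mirna[[m]] <- list(mrna_hits = mrna_hits, protein_hits = prot_hits)
    mrna_hit_rows[[m]] <- mrna_hits
    prot_hit_rows[[m]] <- prot_hits
  }
  all_m <- do.call(rbind, c(mrna_hit_rows,
                            list(data.frame(gene = character(0),
                                            log2fc = numeric(0),
                                            sources = character(0)))))
  all_p <- do.call(rbind, c(prot_hit_rows,
                            list(data.frame(gene = character(0),
                                            log2fc = numeric(0),
                                            sources = character(0)))))
  um <- all_m[!duplicated(all_m$gene), , drop = FALSE]
  up_ <- all_p[!duplicated(all_p$gene), , drop = FALSE]
  list(per_mirna = per_mirna,
       n_target_mrnas = nrow(um),
       n_target_mrnas_up = sum(um$log2fc > 0),
       n_target_mrnas_down = sum(um$log2fc < 0),
       n_target_proteins = nrow(up_),
       n_target_proteins_up = sum(up_$log2fc > 0),
       n_target_proteins_down = sum(up_$log2fc < 0))
}

#' Top-N regulated features against candidate miRNAs
#'
#' Rows are the `n` features with the largest absolute fold change in one
#' layer (ties broken lexicographically by id); columns are the candidate
#' miRNAs; a cell is `TRUE` iff a predicted edge exists and the feature's
#' change opposes the miRNA's direction.
#'
#' @param layer_records data.frame with columns `feature_id` (or `gene` /
#'   `protein_id`) and `log2fc`.
#' @param candidates data.frame from [concordantMirnaCandidates()].
#' @param targets a [TargetPredictionSet-class].
#' @param n number of rows (default 15); fewer if fewer features exist.
#' @return logical matrix, features x miRNAs.
#' @export
topRegulatedMatrix <- function(layer_records, candidates, targets, n = 15) {
  if (n <= 0) stop("n must be a positive count")
  idcol <- intersect(c("feature_id", "gene", "protein_id"),
                     colnames(layer_records))[1]
  if (is.na(idcol)) stop("layer_records needs a feature id column")
  ids <- normalizeGeneSymbols(layer_records[[idcol]])
  lfc <- layer_records$log2fc
  ord <- order(-abs(lfc), ids)
  top <- utils::head(ord, n)
  edges <- targetEdges(targets)
  mids <- normalizeMirnaIds(candidates$mirna_id)
  msign <- ifelse(candidates$direction == "up", 1, -1)
  mat <- matrix(FALSE, nrow = length(top), ncol = length(mids),
                dimnames = list(ids[top], mids))
  ekey <- paste(edges$mirna, edges$gene)
  for (j in seq_along(mids)) {
    has_edge <- paste(mids[j], ids[top]) %in% ekey
    mat[, j] <- has_edge & sign(lfc[top]) == -msign[j]
  }
  mat
}

#' Per-miRNA anti-correlated target report
#'
#' Two tables (mRNA layer and protein layer) of a candidate miRNA's
#' opposite-direction targets, each sorted by fold change and carrying the
#' source-database attribution of the prediction.
#'
#' @param mirna_id the miRNA to report (normalized internally).
#' @param summary output of [antiCorrelatedTargets()].
#' @return list with data.frames `mrna` and `protein`.
#' @export
mirnaTargetReport <- function(mirna_id, summary) {
  m <- normalizeMirnaIds(mirna_id)
  if (!m %in% names(summary$per_mirna))
    stop("miRNA '", m, "' is not among the candidates in this summary")
  hits <- summary$per_mirna[[m]]
  sort_fc <- function(df) {
    df <- df[order(df$log2fc, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(mrna = sort_fc(hits$mrna_hits), protein = sort_fc(hits$protein_hits))
}
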