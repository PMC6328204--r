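#' Normalize TMT channel loading
#'
#' The total reporter signal over all peptides is summed per channel and every
#' channel is rescaled by (grand mean of channel totals) / (its own total), so
#' all channel totals become equal. This removes uneven labeling or sample
#' handling differences between channels; the grand total signal is conserved.
#'
#' @param table a [PeptideReporterTable-class].
#' @return a [PeptideReporterTable-class] with adjusted intensities.
#' @export
normalizeChannels <- function(table) {
  stopifnot(is(table, "PeptideReporterTable"))
  totals <- colSums(table@intensities)
  if (any(totals <= 0))
    stop("channel(s) with zero total signal: ",
         paste(colnames(table@intensities)[totals <= 0], collapse = ", "))
  factors <- mean(totals) / totals
  out <- table
  out@intensities <- sweep(table@intensities, 2, factors, "*")
  out
}

#' Protein-level quantification from a channel-normalized peptide table
#'
#' Per protein, adjusted peptide intensities are summed within each channel,
#' channels are averaged within each group, and
#' `log2fc = log2(stressed_mean / naive_mean)`. The design has one pooled
#' sample per group, so no p-values are produced; candidate status is decided
#' by fold-change thresholding alone ([proteinCandidates()]). Proteins with
#' zero naive-group intensity have an undefined ratio and are excluded with a
#' warning.
#'
#' @param table a [PeptideReporterTable-class], already channel-normalized.
#' @return data.frame with columns `protein_id`, `naive_intensity`,
#'   `stressed_intensity`, `log2fc`, `n_peptides`.
#' @export
quantifyProteins <- function(table) {
  stopifnot(is(table, "PeptideReporterTable"))
  grp <- table@channelGroups[colnames(table@intensities)]
  prot <- factor(table@protein, levels = unique(table@protein))
  by_prot <- rowsum(table@intensities, prot)
  naive <- rowMeans(by_prot[, grp == "naive", drop = FALSE])
  stressed <- rowMeans(by_prot[, grp == "stressed", drop = FALSE])
  n_pep <- as.integer(table(prot))
  bad <- naive == 0
  if (any(bad))
    warning(sum(bad), " protein(s) with zero naive-group intensity excluded: ",
            paste(utils::head(levels(prot)[bad], 5), collapse = ", "))
  keep <- !bad
  data.frame(protein_id = levels(prot)[keep],
             naive_intensity = naive[keep],
             stressed_intensity = stressed[keep],
             log2fc = log2(stressed[keep] / naive[keep]),
             n_peptides = n_pep[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold-change candidate filter for proteins
#'
#' Retains proteins with `|log2fc| >= lfc_min`; the threshold is inclusive
#' ("at least"), with `inclusive = FALSE` available for a strict reading.
#'
#' @param quants data.frame from [quantifyProteins()].
#' @param lfc_min minimum absolute log2 fold change (default 1.5).
#' @param inclusive whether the boundary value itself qualifies (default
#'   `TRUE`).
#' @return the filtered data.frame with a `direction` column added.
#' @export
proteinCandidates <- function(quants, lfc_min = 1.5, inclusive = TRUE) {
  keep <- if (inclusive) abs(quants$log2fc) >= lfc_min
          else abs(quants$log2fc) > lfc_min
  out <- quants[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
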