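#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. The universe defaults to the union of all members.
#'
#' @param path GMT file path.
#' @param universe optional explicit background; defaults to the union of all
#'   set members.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("GMT file '", path, "' has lines without members: ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (is.null(universe)) universe <- unique(unlist(sets))
  geneSetCollection(sets, universe)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test per set: with a universe of `N` genes, a set
#' of size `K`, a query of size `n` and overlap `k`, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Query genes outside the
#' universe are dropped (count reported via message). P-values are BH-adjusted
#' across sets and results sorted by p.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection a [GeneSetCollection-class].
#' @param k_min minimum overlap for a set to be reported (default 0: all).
#' @return data.frame with columns `set_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adj_p`.
#' @export
ora <- function(query_genes, collection, k_min = 0) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- geneUniverse(collection)
  q <- unique(normalizeGeneSymbols(query_genes))
  dropped <- setdiff(q, universe)
  if (length(dropped) > 0)
    message(length(dropped), " query gene(s) outside the universe dropped")
  q <- intersect(q, universe)
  if (length(q) == 0L)
    stop("query is empty after restriction to the universe")
  N <- length(universe); n <- length(q)
  sets <- geneSets(collection)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(s, q)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_id = names(sets), k = k, K = K, n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$k >= k_min, , drop = FALSE]
  if (nrow(out) == 0L) return(cbind(out, adj_p = numeric(0)))
  out$adj_p <- bhAdjust(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway table for a candidate miRNA list with a focus-miRNA flag
#'
#' Runs [ora()] on the union of all candidate miRNAs' predicted targets and
#' flags, for each reported set, whether it intersects the focus miRNA's own
#' predicted targets.
#'
#' @param candidates data.frame from [concordantMirnaCandidates()].
#' @param targets a [TargetPredictionSet-class].
#' @param collection a [GeneSetCollection-class].
#' @param focus_mirna id of the miRNA to flag (must be among the candidates).
#' @param top_n number of top sets to report (default 10).
#' @return data.frame as [ora()] plus a logical `flagged_mirna_targeted`.
#' @export
mirnaPathwayTable <- function(candidates, targets, collection, focus_mirna,
                              top_n = 10) {
  focus <- normalizeMirnaIds(focus_mirna)
  cand_ids <- normalizeMirnaIds(candidates$mirna_id)
  if (!focus %in% cand_ids)
    stop("focus miRNA '", focus, "' is not among the candidates")
  query <- unique(unlist(lapply(cand_ids, predictedTargets, x = targets)))
  res <- ora(query, collection)
  res <- utils::head(res, top_n)
  focus_targets <- predictedTargets(targets, focus)
  sets <- geneSets(collection)
  res$flagged_mirna_targeted <- vapply(
    res$set_id, function(s) length(intersect(sets[[s]], focus_targets)) > 0,
    logical(1))
  res
}
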