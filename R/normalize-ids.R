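#' Normalize miRNA identifiers
#'
#' Merging two sequencing cohorts and three target-prediction databases
#' requires one spelling per miRNA. The rule: lowercase everything, strip a
#' species prefix such as `mmu-`, and unify the `miR`/`mir` stem, so
#' `"mmu-miR-29a-5p"`, `"miR-29a-5p"` and `"mir-29a-5p"` all map to
#' `"mir-29a-5p"`.
#'
#' @param x character vector of miRNA ids.
#' @return character vector of normalized ids.
#' @examples
#' normalizeMirnaIds(c("mmu-miR-29a-5p", "MIR-187-3p"))
#' @export
normalizeMirnaIds <- function(x) {
  x <- tolower(as.character(x))
  x <- sub("^[a-z]{3}-(?=(mir|let))", "", x, perl = TRUE)
  x
}

#' Normalize gene symbols to a single case
#'
#' Gene-to-protein matching and target-database joins are by symbol equality;
#' symbols are uppercased so `"Ube2d3"` and `"UBE2D3"` merge.
#'
#' @param x character vector of gene symbols.
#' @return character vector of uppercased symbols.
#' @export
normalizeGeneSymbols <- function(x) toupper(trimws(as.character(x)))
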