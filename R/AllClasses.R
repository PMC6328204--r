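#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Feature-by-sample count container with stress-study annotations
#'
#' `OmicsCounts` extends [SummarizedExperiment::SummarizedExperiment] with the
#' invariants the downstream differential-expression machinery relies on: a
#' single integer, non-negative `counts` assay, unique feature and sample
#' identifiers, and per-sample `group` (naive/stressed) and `cohort` labels.
#'
#' @slot layer character scalar, `"mirna"` or `"mrna"`, recording which
#'   molecular layer the matrix measures.
#'
#' @export
setClass("OmicsCounts",
  contains = "SummarizedExperiment",
  slots = c(layer = "character")
)

setValidity("OmicsCounts", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers with no NAs")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "cohort") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group' and 'cohort'")
  else {
    if (!all(cd$group %in% c("naive", "stressed")))
      msg <- c(msg, "group labels must be 'naive' or 'stressed'")
  }
  if (length(object@layer) != 1L || !object@layer %in% c("mirna", "mrna"))
    msg <- c(msg, "layer must be 'mirna' or 'mrna'")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsCounts object
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param group character/factor of per-sample labels in `{naive, stressed}`.
#' @param cohort character/factor of per-sample cohort labels.
#' @param layer `"mirna"` or `"mrna"`.
#'
#' @return An [OmicsCounts-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
#' oc <- OmicsCounts(m, group = rep(c("naive", "stressed"), each = 2),
#'                   cohort = "c1", layer = "mrna")
#' groupLabels(oc)
#' @export
OmicsCounts <- function(counts, group, cohort, layer = c("mirna", "mrna")) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature ids (rownames) and sample ids (colnames)")
  cd <- S4Vectors::DataFrame(
    group = as.character(rep(group, length.out = ncol(counts))),
    cohort = as.character(rep(cohort, length.out = ncol(counts))),
    row.names = colnames(counts)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("OmicsCounts", se, layer = layer)
}

#' @describeIn OmicsCounts per-sample group labels (naive/stressed)
#' @param x an `OmicsCounts` object
#' @export
groupLabels <- function(x) as.character(SummarizedExperiment::colData(x)$group)

#' @describeIn OmicsCounts per-sample cohort labels
#' @export
cohortLabels <- function(x) as.character(SummarizedExperiment::colData(x)$cohort)

#' @describeIn OmicsCounts molecular layer ("mirna" or "mrna")
#' @export
layerType <- function(x) x@layer

setMethod("show", "OmicsCounts", function(object) {
  cat("OmicsCounts (", object@layer, " layer): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  tab <- table(groupLabels(object), cohortLabels(object))
  cat("samples per group x cohort:\n")
  print(tab)
})

#' Peptide-level TMT reporter-intensity table
#'
#' Holds one row per peptide with positive reporter-ion intensities across the
#' TMT channels and a channel-to-group map assigning each channel to a pooled
#' naive or stressed sample.
#'
#' @slot peptide character vector of peptide identifiers.
#' @slot protein character vector (parallel to `peptide`) of protein ids.
#' @slot intensities numeric matrix, peptides x channels, non-negative.
#' @slot channelGroups named character vector mapping channel name to group
#'   (`naive`/`stressed`).
#'
#' @export
setClass("PeptideReporterTable",
  slots = c(peptide = "character", protein = "character",
            intensities = "matrix", channelGroups = "character")
)

setValidity("PeptideReporterTable", function(object) {
  msg <- character(0)
  n <- length(object@peptide)
  if (length(object@protein) != n || nrow(object@intensities) != n)
    msg <- c(msg, "peptide, protein and intensity rows must be parallel")
  if (any(!nzchar(object@protein)))
    msg <- c(msg, "protein ids must be non-empty")
  if (any(is.na(object@intensities)) || any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative with no NAs")
  ch <- colnames(object@intensities)
  if (is.null(ch) || !setequal(ch, names(object@channelGroups)))
    msg <- c(msg, "channel names must match names(channelGroups)")
  if (!all(object@channelGroups %in% c("naive", "stressed")))
    msg <- c(msg, "channel groups must be 'naive' or 'stressed'")
  else if (length(unique(object@channelGroups)) < 2L)
    msg <- c(msg, "at least one channel per group is required")
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideReporterTable
#'
#' @param peptide character vector of peptide ids.
#' @param protein character vector of protein ids, parallel to `peptide`.
#' @param intensities numeric matrix (peptides x channels) of reporter-ion
#'   intensities; column names are channel names.
#' @param channelGroups named character vector, channel -> group.
#' @return A [PeptideReporterTable-class].
#' @export
PeptideReporterTable <- function(peptide, protein, intensities, channelGroups) {
  intensities <- as.matrix(intensities)
  new("PeptideReporterTable", peptide = as.character(peptide),
      protein = as.character(protein), intensities = intensities,
      channelGroups = channelGroups)
}

setMethod("show", "PeptideReporterTable", function(object) {
  cat("PeptideReporterTable: ", length(object@peptide), " peptides, ",
      length(unique(object@protein)), " proteins, ",
      ncol(object@intensities), " channels\n", sep = "")
  cat("channel map: ",
      paste(names(object@channelGroups), object@channelGroups,
            sep = "=", collapse = ", "), "\n", sep = "")
})

#' @describeIn PeptideReporterTable channel -> group map
#' @param x a `PeptideReporterTable`
#' @export
channelGroups <- function(x) x@channelGroups

#' @describeIn PeptideReporterTable peptide-by-channel intensity matrix
#' @export
reporterIntensities <- function(x) x@intensities

#' @describeIn PeptideReporterTable per-row protein ids
#' @export
proteinIds <- function(x) x@protein

#' miRNA target-prediction set unioned over source databases
#'
#' One row per unique (miRNA, gene) edge; the databases predicting the edge
#' are recorded as a collapsed, comma-separated attribution string. miRNA ids
#' and gene symbols are normalized on construction (see
#' [normalizeMirnaIds()] and [normalizeGeneSymbols()]).
#'
#' @slot edges data.frame with columns `mirna`, `gene`, `sources`.
#'
#' @export
setClass("TargetPredictionSet", slots = c(edges = "data.frame"))

setValidity("TargetPredictionSet", function(object) {
  msg <- character(0)
  if (!all(c("mirna", "gene", "sources") %in% colnames(object@edges)))
    msg <- c(msg, "edges needs columns mirna, gene, sources")
  else if (anyDuplicated(object@edges[c("mirna", "gene")]))
    msg <- c(msg, "duplicate (mirna, gene) edges are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetPredictionSet from an edge table
#'
#' @param mirna character vector of miRNA ids.
#' @param gene character vector of target gene symbols.
#' @param source character vector of database labels, parallel to the edges;
#'   duplicate (miRNA, gene) pairs are merged and their source labels unioned.
#' @return A [TargetPredictionSet-class].
#' @export
TargetPredictionSet <- function(mirna, gene, source) {
  mirna <- normalizeMirnaIds(mirna)
  gene <- normalizeGeneSymbols(gene)
  key <- paste(mirna, gene, sep = "\r")
  src <- split(as.character(source), key)
  uk <- names(src)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  edges <- data.frame(
    mirna = parts[, 1], gene = parts[, 2],
    sources = vapply(src, function(s) paste(sort(unique(s)), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new("TargetPredictionSet", edges = edges)
}

setMethod("show", "TargetPredictionSet", function(object) {
  cat("TargetPredictionSet: ", nrow(object@edges), " edges, ",
      length(unique(object@edges$mirna)), " miRNAs, ",
      length(unique(object@edges$gene)), " genes\n", sep = "")
})

#' @describeIn TargetPredictionSet edge table (mirna, gene, sources)
#' @param x a `TargetPredictionSet`
#' @export
targetEdges <- function(x) x@edges

#' @describeIn TargetPredictionSet predicted target genes of one miRNA
#' @param mirna_id miRNA identifier (normalized internally)
#' @export
predictedTargets <- function(x, mirna_id) {
  id <- normalizeMirnaIds(mirna_id)
  unique(x@edges$gene[x@edges$mirna == id])
}

#' Named gene-set collection with an explicit universe
#'
#' @slot sets named list of character vectors (gene symbols).
#' @slot universe character vector of gene symbols; sets are restricted to it.
#'
#' @export
setClass("GeneSetCollection", slots = c(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must be uniquely named")
  if (any(vapply(object@sets, length, integer(1)) == 0L))
    msg <- c(msg, "every set must be non-empty after universe restriction")
  if (!all(unlist(object@sets) %in% object@universe))
    msg <- c(msg, "sets must be subsets of the universe")
  if (length(msg)) msg else TRUE
})

#' Construct a gene-set collection
#'
#' Symbols are case-normalized; sets are restricted to the universe and sets
#' left empty by the restriction are dropped with a warning.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe character vector of gene symbols defining the background.
#' @return A [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, universe) {
  universe <- unique(normalizeGeneSymbols(universe))
  if (length(universe) == 0L) stop("universe is empty")
  sets <- lapply(sets, function(s) intersect(unique(normalizeGeneSymbols(s)),
                                             universe))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after universe restriction; dropped")
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no gene sets remain after universe restriction")
  new("GeneSetCollection", sets = sets, universe = universe)
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection: ", length(object@sets), " sets over a universe of ",
      length(object@universe), " genes\n", sep = "")
})

#' @describeIn GeneSetCollection the named list of sets
#' @param x a `GeneSetCollection`
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection the background universe
#' @export
geneUniverse <- function(x) x@universe
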