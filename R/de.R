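#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over reference features of
#' count / geometric-mean(count across samples). Features containing a zero
#' in any sample are excluded from the reference set, since their geometric
#' mean is zero.
#'
#' @param counts an [OmicsCounts-class] or a count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(counts) {
  m <- if (is(counts, "OmicsCounts"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no feature has nonzero counts in every sample; ",
         "size factors are undefined")
  lm_ <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(lm_)
  sf <- apply(lm_, 2, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(sf, colnames(m))
}

# per-feature NB dispersion: method-of-moments estimate shrunk 50% toward a
# parametric a0 + a1/mu trend fitted across features
.moderatedDispersion <- function(norm, group) {
  groups <- unique(group)
  n1 <- sum(group == groups[1]); n2 <- sum(group == groups[2])
  v1 <- apply(norm[, group == groups[1], drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, group == groups[2], drop = FALSE], 1, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  bm <- rowMeans(norm)
  raw <- (pooled - bm) / bm^2
  raw[!is.finite(raw)] <- 0
  raw <- pmin(pmax(raw, 1e-8), 10)
  use <- bm > 0 & raw > 1e-8
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / bm[use]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-8)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(raw[use]), 1e-8); a1 <- 0
  }
  trend <- a0 + a1 / pmax(bm, 1e-8)
  pmax(0.5 * raw + 0.5 * trend, 1e-8)
}

#' Negative-binomial Wald differential expression (stressed vs naive)
#'
#' Per feature: counts are normalized by median-of-ratios size factors; the
#' fold change is `log2((mean_stressed + c) / (mean_naive + c))` on normalized
#' counts with pseudo-count `c`; the group effect is tested by a Wald test in
#' a negative-binomial GLM with a log link, log size factors as offset, and a
#' method-of-moments dispersion shrunk 50% toward a `a0 + a1/mu` trend fitted
#' across features. Given the small per-group sample sizes the Wald statistic
#' is referred to a t distribution with `n_samples - 2` degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted over tested features (those with
#' nonzero total count); all-zero features get `log2fc = 0`, `p = 1` and are
#' excluded from the adjustment.
#'
#' @param counts an [OmicsCounts-class] with both groups present.
#' @param lfc_prior_count pseudo-count added to each group mean (normalized
#'   scale) before taking the log ratio; stabilizes fold changes near zero.
#' @return data.frame with columns `feature_id`, `base_mean`, `log2fc`,
#'   `p_value`, `adj_p`, `direction` (`up`/`down`/`none`).
#' @export
deTest <- function(counts, lfc_prior_count = 0.5) {
  stopifnot(is(counts, "OmicsCounts"))
  group <- groupLabels(counts)
  if (length(unique(group)) < 2L)
    stop("both a naive and a stressed group are required")
  m <- SummarizedExperiment::assay(counts, "counts")
  sf <- computeSizeFactors(m)
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)
  mean_n <- rowMeans(norm[, group == "naive", drop = FALSE])
  mean_s <- rowMeans(norm[, group == "stressed", drop = FALSE])
  c0 <- lfc_prior_count
  log2fc <- log2((mean_s + c0) / (mean_n + c0))
  tested <- rowSums(m) > 0
  log2fc[!tested] <- 0
  disp <- .moderatedDispersion(norm, group)
  gfac <- factor(group, levels = c("naive", "stressed"))
  off <- log(sf)
  dfree <- ncol(m) - 2L
  p <- rep(1, nrow(m))
  for (i in which(tested)) {
    y <- m[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ gfac + offset(off), family = fam)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2 || !is.finite(cf[2, 2]) || cf[2, 2] <= 0) next
    wald <- cf[2, 1] / cf[2, 2]
    p[i] <- 2 * stats::pt(-abs(wald), df = dfree)
  }
  adj <- rep(1, nrow(m))
  adj[tested] <- bhAdjust(p[tested])
  direction <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none"))
  data.frame(feature_id = rownames(m), base_mean = base_mean,
             log2fc = log2fc, p_value = p, adj_p = adj,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving FDR adjustment (`p * m / rank`, monotone-enforced from the
#' largest p down, capped at 1), delegated to [stats::p.adjust()] after
#' validating the inputs.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  stats::p.adjust(p, method = "BH")
}

#' Two-cohort concordance filter for candidate miRNAs
#'
#' A miRNA is a candidate when, in BOTH cohorts, its absolute log2 fold change
#' is at least `lfc_min` (inclusive) and its raw p-value is below `alpha`
#' (strict), with the same sign of change in both. Raw p-values are used:
#' replication across two independent cohorts is the multiplicity control.
#' IDs are normalized before matching; features present in only one cohort
#' are skipped with a message.
#'
#' @param de1,de2 data.frames from [deTest()] for cohorts 1 and 2.
#' @param lfc_min minimum absolute log2 fold change (default 0.5).
#' @param alpha per-cohort raw p-value cutoff (default 0.05).
#' @return data.frame with one row per candidate: `mirna_id`, per-cohort
#'   `log2fc_1/2`, `p_1/2`, and shared `direction`.
#' @export
concordantMirnaCandidates <- function(de1, de2, lfc_min = 0.5, alpha = 0.05) {
  d1 <- de1; d2 <- de2
  d1$key <- normalizeMirnaIds(d1$feature_id)
  d2$key <- normalizeMirnaIds(d2$feature_id)
  shared <- intersect(d1$key, d2$key)
  n_skip <- length(union(d1$key, d2$key)) - length(shared)
  if (n_skip > 0)
    message(n_skip, " miRNA(s) present in only one cohort were skipped")
  if (length(shared) == 0L) {
    warning("no shared miRNA ids between the two cohorts")
    return(data.frame(mirna_id = character(0), log2fc_1 = numeric(0),
                      p_1 = numeric(0), log2fc_2 = numeric(0),
                      p_2 = numeric(0), direction = character(0)))
  }
  i1 <- match(shared, d1$key); i2 <- match(shared, d2$key)
  lfc1 <- d1$log2fc[i1]; lfc2 <- d2$log2fc[i2]
  p1 <- d1$p_value[i1]; p2 <- d2$p_value[i2]
  ok <- abs(lfc1) >= lfc_min & abs(lfc2) >= lfc_min &
    p1 < alpha & p2 < alpha & sign(lfc1) == sign(lfc2) & lfc1 != 0
  out <- data.frame(mirna_id = shared[ok],
                    log2fc_1 = lfc1[ok], p_1 = p1[ok],
                    log2fc_2 = lfc2[ok], p_2 = p2[ok],
                    direction = ifelse(lfc1[ok] > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$mirna_id), , drop = FALSE]
}

#' Significance filter for DE mRNAs
#'
#' Retains records whose selected p-value (adjusted by default) is below
#' `alpha` and populates the direction from the fold-change sign.
#'
#' @param records data.frame from [deTest()].
#' @param alpha significance cutoff (default 0.05).
#' @param use_adjusted if `TRUE` (default) filter on `adj_p`, else on raw
#'   `p_value`.
#' @return the filtered data.frame.
#' @export
filterDeMrna <- function(records, alpha = 0.05, use_adjusted = TRUE) {
  p <- if (use_adjusted) records$adj_p else records$p_value
  out <- records[p < alpha, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", "none"))
  rownames(out) <- NULL
  out
}
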