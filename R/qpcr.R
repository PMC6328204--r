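#' Delta-delta-Ct relative quantification
#'
#' Per sample, replicate Ct values are averaged, then
#' `dCt = mean(target Ct) - mean(reference Ct)` (the reference being a
#' housekeeping small RNA such as snord68),
#' `ddCt = dCt - mean(dCt over naive samples)`, and the relative quantity is
#' `2^(-ddCt)`. Samples missing all reference replicates are excluded with a
#' warning.
#'
#' @param ct_table data.frame with columns `sample_id`, `group`
#'   (naive/stressed), `target_id`, replicate columns matching
#'   `^ct_target` and `^ct_reference` (NAs allowed within replicates).
#' @return data.frame with `sample_id`, `group`, `delta_ct`, `ddct`,
#'   `rel_quantity`, one row per sample.
#' @examples
#' tab <- data.frame(sample_id = c("n1", "n2", "s1", "s2"),
#'                   group = c("naive", "naive", "stressed", "stressed"),
#'                   target_id = "mir-x",
#'                   ct_target_rep1 = c(25, 25, 24, 24),
#'                   ct_reference_rep1 = 20)
#' ddctFoldChange(tab)  # stressed samples have relative quantity 2
#' @export
ddctFoldChange <- function(ct_table) {
  tcols <- grep("^ct_target", colnames(ct_table), value = TRUE)
  rcols <- grep("^ct_reference", colnames(ct_table), value = TRUE)
  if (length(tcols) == 0L || length(rcols) == 0L)
    stop("ct_table needs ct_target* and ct_reference* columns")
  if (!all(ct_table$group %in% c("naive", "stressed")))
    stop("group must be 'naive' or 'stressed'")
  tmean <- rowMeans(ct_table[tcols], na.rm = TRUE)
  rmean <- rowMeans(ct_table[rcols], na.rm = TRUE)
  drop <- !is.finite(rmean) | !is.finite(tmean)
  if (any(drop)) {
    warning(sum(drop), " sample(s) without usable Ct values excluded: ",
            paste(ct_table$sample_id[drop], collapse = ", "))
    ct_table <- ct_table[!drop, , drop = FALSE]
    tmean <- tmean[!drop]; rmean <- rmean[!drop]
  }
  if (!all(c("naive", "stressed") %in% ct_table$group))
    stop("both groups must be present after exclusions")
  dct <- tmean - rmean
  ddct <- dct - mean(dct[ct_table$group == "naive"])
  data.frame(sample_id = ct_table$sample_id, group = ct_table$group,
             delta_ct = dct, ddct = ddct, rel_quantity = 2^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-tailed one-sample t-test of relative quantities
#'
#' Tests the stressed samples' relative quantities against a null fold change
#' of `null_value` (1 on the raw ratio scale; with `log_scale = TRUE` the
#' values are log2-transformed and tested against `log2(null_value)`, i.e. 0
#' by default). Degrees of freedom are `n - 1`. A degenerate sample with zero
#' variance at the null mean returns `t = 0`, `p = 1` by convention.
#'
#' @param stressed_quantities numeric vector of relative quantities (>= 2
#'   values).
#' @param null_value null fold change (default 1).
#' @param log_scale test on the log2 scale (default `FALSE`).
#' @return list with `estimate`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`.
#' @export
oneSampleFcTest <- function(stressed_quantities, null_value = 1,
                            log_scale = FALSE) {
  x <- as.numeric(stressed_quantities)
  if (length(x) < 2L) stop("at least two stressed samples are required")
  mu <- null_value
  if (log_scale) { x <- log2(x); mu <- log2(null_value) }
  if (stats::sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), mu))) {
      message("zero variance at the null mean; returning t = 0, p = 1")
      return(list(estimate = mean(x), t_statistic = 0,
                  degrees_of_freedom = length(x) - 1L, p_value = 1))
    }
    stop("zero variance away from the null; t is undefined")
  }
  tt <- stats::t.test(x, mu = mu, alternative = "two.sided")
  list(estimate = unname(tt$estimate), t_statistic = unname(tt$statistic),
       degrees_of_freedom = unname(tt$parameter), p_value = tt$p.value)
}
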