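#' Simulation configuration for the synthetic multi-omics study
#'
#' Encodes the study conditions the generator emulates: two independently
#' sequenced small-RNA cohorts (3 and 4 animals per group), an unbalanced
#' RNA-seq design (2 naive vs 4 stressed), and a 6-plex TMT run with one
#' pooled sample per group split over 3 + 3 channels. Planted effects carry
#' directions; the default up/down splits follow the observed splits in the
#' study system (3 of 18 candidate miRNAs up, 431 of 630 DE mRNAs up, 92 of
#' 224 candidate proteins up).
#'
#' @slot n_features_mirna total simulated miRNAs.
#' @slot n_features_mrna total simulated mRNAs.
#' @slot n_proteins total simulated proteins (drawn from the shared gene
#'   namespace, so proteome detection overlaps the transcriptome).
#' @slot n_peptides_per_protein peptides backing each protein.
#' @slot samples_per_group_per_cohort integer length-2: animals per group in
#'   cohorts 1 and 2.
#' @slot mrna_samples_per_group integer length-2 (naive, stressed) for the
#'   RNA-seq design.
#' @slot n_planted_concordant_mirna miRNAs shifted in both cohorts.
#' @slot n_planted_single_cohort_mirna miRNAs shifted in cohort 1 only.
#' @slot planted_mirna_lfc magnitude (log2) of planted miRNA shifts.
#' @slot mirna_up_fraction fraction of planted concordant miRNAs shifted up.
#' @slot n_planted_de_mrna planted DE genes.
#' @slot planted_mrna_lfc magnitude (log2) of planted gene shifts.
#' @slot mrna_up_fraction fraction of planted DE genes shifted up.
#' @slot n_planted_de_protein planted DE proteins.
#' @slot planted_protein_lfc magnitude (log2) of planted protein shifts.
#' @slot protein_up_fraction fraction of planted proteins shifted up.
#' @slot nb_dispersion negative-binomial dispersion of the count layers.
#' @slot channel_loading_spread log-scale sd of the multiplicative per-channel
#'   TMT loading bias.
#' @slot anticorr_target_fraction fraction of each planted concordant miRNA's
#'   predicted-target edges that point at planted opposite-direction targets.
#' @slot seed integer seed; all generator randomness derives from it.
#'
#' @export
setClass("SimulationConfig", representation(
  n_features_mirna = "integer", n_features_mrna = "integer",
  n_proteins = "integer", n_peptides_per_protein = "integer",
  samples_per_group_per_cohort = "integer", mrna_samples_per_group = "integer",
  n_planted_concordant_mirna = "integer", n_planted_single_cohort_mirna = "integer",
  planted_mirna_lfc = "numeric", mirna_up_fraction = "numeric",
  n_planted_de_mrna = "integer", planted_mrna_lfc = "numeric",
  mrna_up_fraction = "numeric",
  n_planted_de_protein = "integer", planted_protein_lfc = "numeric",
  protein_up_fraction = "numeric",
  nb_dispersion = "numeric", channel_loading_spread = "numeric",
  anticorr_target_fraction = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  pos <- c("n_features_mirna", "n_features_mrna", "n_proteins",
           "n_peptides_per_protein")
  for (f in pos)
    if (slot(object, f) < 1L) msg <- c(msg, paste(f, "must be >= 1"))
  if (any(object@samples_per_group_per_cohort < 2L) ||
      length(object@samples_per_group_per_cohort) != 2L)
    msg <- c(msg, "samples_per_group_per_cohort must be two values >= 2")
  if (any(object@mrna_samples_per_group < 2L) ||
      length(object@mrna_samples_per_group) != 2L)
    msg <- c(msg, "mrna_samples_per_group must be two values >= 2")
  if (object@n_planted_concordant_mirna + object@n_planted_single_cohort_mirna >
      object@n_features_mirna)
    msg <- c(msg, "planted miRNA counts exceed n_features_mirna")
  if (object@n_planted_de_mrna > object@n_features_mrna)
    msg <- c(msg, "n_planted_de_mrna exceeds n_features_mrna")
  if (object@n_planted_de_protein > object@n_proteins)
    msg <- c(msg, "n_planted_de_protein exceeds n_proteins")
  if (object@nb_dispersion <= 0)
    msg <- c(msg, "nb_dispersion must be strictly positive")
  if (object@channel_loading_spread < 0)
    msg <- c(msg, "channel_loading_spread must be >= 0")
  for (f in c("mirna_up_fraction", "mrna_up_fraction", "protein_up_fraction",
              "anticorr_target_fraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Build a SimulationConfig
#'
#' Defaults encode the emulated study design; see
#' [SimulationConfig-class] for the meaning of each parameter.
#'
#' @param n_features_mirna,n_features_mrna,n_proteins,n_peptides_per_protein
#'   feature totals per layer.
#' @param samples_per_group_per_cohort integer length-2 (cohort 1, cohort 2).
#' @param mrna_samples_per_group integer length-2 (naive, stressed).
#' @param n_planted_concordant_mirna,n_planted_single_cohort_mirna,planted_mirna_lfc,mirna_up_fraction
#'   planted miRNA effects.
#' @param n_planted_de_mrna,planted_mrna_lfc,mrna_up_fraction planted gene
#'   effects.
#' @param n_planted_de_protein,planted_protein_lfc,protein_up_fraction planted
#'   protein effects.
#' @param nb_dispersion,channel_loading_spread noise levels.
#' @param anticorr_target_fraction fraction of a planted miRNA's edges pointing
#'   at opposite-direction planted targets.
#' @param seed integer seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, n_features_mirna = 100)
#' @export
simulationConfig <- function(
    n_features_mirna = 600, n_features_mrna = 2000, n_proteins = 500,
    n_peptides_per_protein = 5,
    samples_per_group_per_cohort = c(3, 4),
    mrna_samples_per_group = c(2, 4),
    n_planted_concordant_mirna = 18, n_planted_single_cohort_mirna = 5,
    planted_mirna_lfc = 1.0, mirna_up_fraction = 3 / 18,
    n_planted_de_mrna = 100, planted_mrna_lfc = 2.0,
    mrna_up_fraction = 431 / 630,
    n_planted_de_protein = 48, planted_protein_lfc = 2.0,
    protein_up_fraction = 92 / 224,
    nb_dispersion = 0.02, channel_loading_spread = 0.2,
    anticorr_target_fraction = 0.3, seed = 1) {
  new("SimulationConfig",
      n_features_mirna = as.integer(n_features_mirna),
      n_features_mrna = as.integer(n_features_mrna),
      n_proteins = as.integer(n_proteins),
      n_peptides_per_protein = as.integer(n_peptides_per_protein),
      samples_per_group_per_cohort = as.integer(samples_per_group_per_cohort),
      mrna_samples_per_group = as.integer(mrna_samples_per_group),
      n_planted_concordant_mirna = as.integer(n_planted_concordant_mirna),
      n_planted_single_cohort_mirna = as.integer(n_planted_single_cohort_mirna),
      planted_mirna_lfc = as.numeric(planted_mirna_lfc),
      mirna_up_fraction = as.numeric(mirna_up_fraction),
      n_planted_de_mrna = as.integer(n_planted_de_mrna),
      planted_mrna_lfc = as.numeric(planted_mrna_lfc),
      mrna_up_fraction = as.numeric(mrna_up_fraction),
      n_planted_de_protein = as.integer(n_planted_de_protein),
      planted_protein_lfc = as.numeric(planted_protein_lfc),
      protein_up_fraction = as.numeric(protein_up_fraction),
      nb_dispersion = as.numeric(nb_dispersion),
      channel_loading_spread = as.numeric(channel_loading_spread),
      anticorr_target_fraction = as.numeric(anticorr_target_fraction),
      seed = as.integer(seed))
}

#' Ground truth of a simulation
#'
#' Records the planted structure so parameter-recovery tests can score the
#' pipeline. Slots start empty and are filled by the generator functions;
#' [mergeGroundTruth()] combines the pieces.
#'
#' @slot mirna_ids all simulated miRNA ids.
#' @slot gene_namespace all simulated gene symbols (shared by mRNA, protein
#'   and target layers).
#' @slot concordant_mirna data.frame (mirna, direction) planted in both
#'   cohorts.
#' @slot single_cohort_mirna data.frame (mirna, direction) planted in cohort 1
#'   only.
#' @slot de_mrna data.frame (gene, direction) of planted DE genes.
#' @slot de_protein data.frame (protein, direction) of planted DE proteins.
#' @slot target_edges data.frame (mirna, gene, anti_correlated) of planted
#'   prediction edges.
#'
#' @export
setClass("GroundTruth", representation(
  mirna_ids = "character", gene_namespace = "character",
  concordant_mirna = "data.frame", single_cohort_mirna = "data.frame",
  de_mrna = "data.frame", de_protein = "data.frame",
  target_edges = "data.frame"
), prototype(
  mirna_ids = character(0), gene_namespace = character(0),
  concordant_mirna = data.frame(mirna = character(0), direction = character(0)),
  single_cohort_mirna = data.frame(mirna = character(0), direction = character(0)),
  de_mrna = data.frame(gene = character(0), direction = character(0)),
  de_protein = data.frame(protein = character(0), direction = character(0)),
  target_edges = data.frame(mirna = character(0), gene = character(0),
                            anti_correlated = logical(0))
))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      nrow(object@concordant_mirna), "concordant miRNAs,",
      nrow(object@single_cohort_mirna), "single-cohort miRNAs,",
      nrow(object@de_mrna), "DE genes,",
      nrow(object@de_protein), "DE proteins,",
      nrow(object@target_edges), "prediction edges\n")
})

#' Merge ground-truth pieces from the generator functions
#'
#' @param ... GroundTruth objects; non-empty slots later in the list override
#'   empty ones earlier.
#' @return a single [GroundTruth-class].
#' @export
mergeGroundTruth <- function(...) {
  out <- new("GroundTruth")
  for (gt in list(...)) {
    stopifnot(is(gt, "GroundTruth"))
    for (s in slotNames("GroundTruth")) {
      v <- slot(gt, s)
      if ((is.data.frame(v) && nrow(v) > 0) ||
          (is.character(v) && length(v) > 0))
        slot(out, s) <- v
    }
  }
  out
}

.geneNamespace <- function(config) {
  sprintf("GENE%05d", seq_len(max(config@n_features_mrna, config@n_proteins)))
}

.mirnaIds <- function(config) {
  sprintf("mir-%d-%s", seq_len(config@n_features_mirna),
          rep(c("5p", "3p"), length.out = config@n_features_mirna))
}

# planted effects are drawn from the expressed stratum (expected baseline
# mean >= min_mu): effects planted in barely-detected features are
# unrecoverable by any method and the study's candidates are quantifiable
.plantable <- function(mu, n_planted, min_mu = 20) {
  eligible <- which(mu >= min_mu)
  if (length(eligible) < n_planted)
    eligible <- order(mu, decreasing = TRUE)[seq_len(min(n_planted, length(mu)))]
  eligible[sample.int(length(eligible), min(n_planted, length(eligible)))]
}

.directions <- function(ids, up_fraction) {
  n_up <- round(up_fraction * length(ids))
  data.frame(id = ids,
             direction = c(rep("up", n_up), rep("down", length(ids) - n_up)),
             stringsAsFactors = FALSE)
}

# NB counts for one cohort: features x samples, planted rows shifted in the
# stressed group by 2^(signed lfc)
.nbCohort <- function(mu, n_per_group, fc_stressed, dispersion, lib_sd = 0.15) {
  n_samp <- 2L * n_per_group
  lib <- stats::rlnorm(n_samp, 0, lib_sd)
  grp <- rep(c("naive", "stressed"), each = n_per_group)
  mu_mat <- outer(mu, lib)
  mu_mat[, grp == "stressed"] <- mu_mat[, grp == "stressed"] * fc_stressed
  cts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                               size = 1 / dispersion),
                nrow = length(mu))
  list(counts = cts, group = grp)
}

#' Simulate two small-RNA sequencing cohorts with planted concordant miRNAs
#'
#' Counts follow a negative-binomial model with log-normal feature means,
#' log-normal library-size variation and the configured common dispersion.
#' Planted concordant miRNAs are shifted by `planted_mirna_lfc` (signed by
#' their planted direction) in the stressed group of both cohorts;
#' single-cohort miRNAs are shifted in cohort 1 only.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `cohort1`, `cohort2` ([OmicsCounts-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateMirnaCohorts(simulationConfig(n_features_mirna = 50,
#'                                              n_planted_concordant_mirna = 3,
#'                                              n_planted_single_cohort_mirna = 1))
#' sim$truth
#' @export
simulateMirnaCohorts <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ids <- .mirnaIds(config)
  mu <- stats::rlnorm(length(ids), meanlog = log(100), sdlog = 1.3)
  n_conc <- config@n_planted_concordant_mirna
  n_single <- config@n_planted_single_cohort_mirna
  planted <- ids[.plantable(mu, n_conc + n_single)]
  conc <- .directions(planted[seq_len(n_conc)], config@mirna_up_fraction)
  single <- .directions(planted[n_conc + seq_len(n_single)],
                        config@mirna_up_fraction)
  names(conc)[1] <- names(single)[1] <- "mirna"
  fc_of <- function(df) {
    fc <- rep(1, length(ids))
    idx <- match(df$mirna, ids)
    fc[idx] <- 2^(ifelse(df$direction == "up", 1, -1) * config@planted_mirna_lfc)
    fc
  }
  fc1 <- fc_of(conc) * fc_of(single)
  fc2 <- fc_of(conc)
  mats <- list()
  for (k in 1:2) {
    n_per <- config@samples_per_group_per_cohort[k]
    sim <- .nbCohort(mu, n_per, if (k == 1) fc1 else fc2, config@nb_dispersion)
    dimnames(sim$counts) <- list(ids, sprintf("c%d_%s_%d", k, sim$group,
                                              ave(seq_along(sim$group),
                                                  sim$group, FUN = seq_along)))
    mats[[k]] <- OmicsCounts(sim$counts, group = sim$group,
                             cohort = paste0("cohort", k), layer = "mirna")
  }
  truth <- new("GroundTruth", mirna_ids = ids, concordant_mirna = conc,
               single_cohort_mirna = single)
  list(cohort1 = mats[[1]], cohort2 = mats[[2]], truth = truth)
}

#' Simulate an mRNA count matrix with planted DE genes
#'
#' Gene symbols come from the namespace shared with the protein layer and the
#' target database, so downstream joins are exercised without external
#' annotation. The design is unbalanced by default (2 naive vs 4 stressed).
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `counts` ([OmicsCounts-class]) and `truth`.
#' @export
simulateMrnaCounts <- function(config) {
  validObject(config)
  set.seed(config@seed + 1L)
  ns <- .geneNamespace(config)
  genes <- ns[seq_len(config@n_features_mrna)]
  mu <- stats::rlnorm(length(genes), meanlog = log(200), sdlog = 1.2)
  n_pl <- config@n_planted_de_mrna
  planted <- .directions(genes[.plantable(mu, n_pl)],
                         config@mrna_up_fraction)
  names(planted)[1] <- "gene"
  fc <- rep(1, length(genes))
  fc[match(planted$gene, genes)] <-
    2^(ifelse(planted$direction == "up", 1, -1) * config@planted_mrna_lfc)
  n_n <- config@mrna_samples_per_group[1]
  n_s <- config@mrna_samples_per_group[2]
  lib <- stats::rlnorm(n_n + n_s, 0, 0.15)
  grp <- rep(c("naive", "stressed"), c(n_n, n_s))
  mu_mat <- outer(mu, lib)
  mu_mat[, grp == "stressed"] <- mu_mat[, grp == "stressed"] * fc
  cts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                               size = 1 / config@nb_dispersion),
                nrow = length(genes),
                dimnames = list(genes, sprintf("rna_%s_%d", grp,
                                               ave(seq_along(grp), grp,
                                                   FUN = seq_along))))
  truth <- new("GroundTruth", gene_namespace = ns, de_mrna = planted)
  list(counts = OmicsCounts(cts, group = grp, cohort = "rnaseq",
                            layer = "mrna"),
       truth = truth)
}

#' Simulate a 6-plex TMT peptide reporter table with planted protein effects
#'
#' Each protein gets `n_peptides_per_protein` peptides with log-normal
#' abundances; channels carry a multiplicative log-normal loading bias of
#' log-sd `channel_loading_spread`, and every cell has mild multiplicative
#' measurement noise. Planted proteins are shifted between the naive (channels
#' 126-128) and stressed (channels 129-131) groups by `planted_protein_lfc`.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `table` ([PeptideReporterTable-class]) and
#'   `truth`.
#' @export
simulatePeptideTable <- function(config) {
  validObject(config)
  set.seed(config@seed + 2L)
  ns <- .geneNamespace(config)
  prot <- ns[seq_len(config@n_proteins)]
  planted <- .directions(sample(prot, config@n_planted_de_protein),
                         config@protein_up_fraction)
  names(planted)[1] <- "protein"
  npp <- config@n_peptides_per_protein
  protein <- rep(prot, each = npp)
  peptide <- sprintf("%s_pep%d", protein, rep(seq_len(npp), times = length(prot)))
  channels <- c("126", "127", "128", "129", "130", "131")
  chan_grp <- stats::setNames(rep(c("naive", "stressed"), each = 3), channels)
  base <- stats::rlnorm(length(prot), meanlog = log(1e5), sdlog = 1.0)
  pep_eff <- stats::rlnorm(length(peptide), 0, 0.5)
  loading <- stats::rlnorm(length(channels), 0, config@channel_loading_spread)
  fc <- rep(1, length(prot))
  fc[match(planted$protein, prot)] <-
    2^(ifelse(planted$direction == "up", 1, -1) * config@planted_protein_lfc)
  mu <- outer(rep(base, each = npp) * pep_eff, loading)
  stressed <- chan_grp == "stressed"
  mu[, stressed] <- mu[, stressed] * rep(fc, each = npp)
  noise <- matrix(stats::rlnorm(length(mu), 0, 0.1), nrow = nrow(mu))
  intens <- mu * noise
  colnames(intens) <- channels
  truth <- new("GroundTruth", gene_namespace = ns, de_protein = planted)
  list(table = PeptideReporterTable(peptide, protein, intens, chan_grp),
       truth = truth)
}

#' Simulate a multi-database miRNA target-prediction set
#'
#' Every planted concordant miRNA receives a block of predicted-target edges;
#' a fraction `anticorr_target_fraction` of them point at planted targets
#' regulated in the opposite direction (in the mRNA layer, the protein layer,
#' or both), and the rest at background genes that are not opposite-direction
#' planted targets. Remaining miRNAs receive background edges only. Each edge
#' is attributed to 1-3 of the TargetScan/mirDB/DIANA labels.
#'
#' @param config a [SimulationConfig-class].
#' @param truth a merged [GroundTruth-class] containing the miRNA, mRNA and
#'   protein planted structure (see [mergeGroundTruth()]).
#' @param edges_per_mirna predicted edges per planted miRNA (background
#'   miRNAs get a third as many).
#' @return list with elements `targets` ([TargetPredictionSet-class]) and
#'   `truth` (input truth with `target_edges` filled).
#' @export
simulateTargetDb <- function(config, truth, edges_per_mirna = 30L) {
  validObject(config)
  stopifnot(is(truth, "GroundTruth"))
  if (length(truth@mirna_ids) == 0L || length(truth@gene_namespace) == 0L)
    stop("truth must carry miRNA ids and the gene namespace; ",
         "merge the generator outputs first")
  set.seed(config@seed + 3L)
  ns <- truth@gene_namespace
  dbs <- c("TargetScan", "mirDB", "DIANA")
  down_pool <- unique(c(truth@de_mrna$gene[truth@de_mrna$direction == "down"],
                        truth@de_protein$protein[truth@de_protein$direction == "down"]))
  up_pool <- unique(c(truth@de_mrna$gene[truth@de_mrna$direction == "up"],
                      truth@de_protein$protein[truth@de_protein$direction == "up"]))
  rows <- list()
  add_edges <- function(mirna, genes, anti) {
    if (length(genes) == 0L) return(NULL)
    data.frame(mirna = mirna, gene = genes, anti_correlated = anti,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth@concordant_mirna))) {
    m <- truth@concordant_mirna$mirna[i]
    dir <- truth@concordant_mirna$direction[i]
    opp <- if (dir == "up") down_pool else up_pool
    n_anti <- min(round(config@anticorr_target_fraction * edges_per_mirna),
                  length(opp))
    anti_genes <- if (n_anti > 0) sample(opp, n_anti) else character(0)
    bg_candidates <- setdiff(ns, opp)
    bg <- sample(bg_candidates, edges_per_mirna - n_anti)
    rows[[length(rows) + 1L]] <- add_edges(m, anti_genes, TRUE)
    rows[[length(rows) + 1L]] <- add_edges(m, bg, FALSE)
  }
  other <- setdiff(truth@mirna_ids, truth@concordant_mirna$mirna)
  n_bg_mirna <- min(length(other), 50L)
  for (m in sample(other, n_bg_mirna)) {
    rows[[length(rows) + 1L]] <-
      add_edges(m, sample(ns, max(1L, edges_per_mirna %/% 3L)), FALSE)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[!duplicated(edges[c("mirna", "gene")]), , drop = FALSE]
  n_src <- sample(1:3, nrow(edges), replace = TRUE)
  src <- lapply(n_src, function(k) sample(dbs, k))
  flat <- data.frame(mirna = rep(edges$mirna, n_src),
                     gene = rep(edges$gene, n_src),
                     source = unlist(src), stringsAsFactors = FALSE)
  truth@target_edges <- edges[edges$anti_correlated, , drop = FALSE]
  rownames(truth@target_edges) <- NULL
  list(targets = TargetPredictionSet(flat$mirna, flat$gene, flat$source),
       truth = truth)
}

#' Run all generators and merge their ground truth
#'
#' @param config a [SimulationConfig-class].
#' @return list with `mirna_cohort1`, `mirna_cohort2`, `mrna`, `peptides`,
#'   `targets`, `truth`.
#' @export
simulateStudy <- function(config) {
  mir <- simulateMirnaCohorts(config)
  rna <- simulateMrnaCounts(config)
  pep <- simulatePeptideTable(config)
  truth <- mergeGroundTruth(mir$truth, rna$truth, pep$truth)
  tdb <- simulateTargetDb(config, truth)
  list(mirna_cohort1 = mir$cohort1, mirna_cohort2 = mir$cohort2,
       mrna = rna$counts, peptides = pep$table, targets = tdb$targets,
       truth = tdb$truth)
}
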