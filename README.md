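# stressomics

Multi-omics integration of long-lasting acute-stress signatures in brain
tissue.

A single acute stressor can alter microRNA, mRNA and protein expression in
the basolateral amygdala weeks after the event. Detecting those changes
reliably is hard: the designs are small (3–4 animals per group, one pooled
mass-spec sample per condition), so the analysis leans on *replication* and
*cross-layer convergence* instead of raw statistical power. `stressomics`
implements that analysis chain for researchers working with small-RNA
sequencing, RNA-seq and 6-plex TMT proteomics from the same tissue:

* **Differential expression** — median-of-ratios normalization and a
  negative-binomial Wald test with moderated method-of-moments dispersion
  (`computeSizeFactors()`, `deTest()`, `bhAdjust()`).
* **Two-cohort concordance filter** — a miRNA is a candidate only if
  |log2FC| ≥ 0.5 with raw p < 0.05, in the *same direction*, in two
  independently sequenced cohorts (`concordantMirnaCandidates()`).
* **TMT protein quantification** — channel-loading normalization, peptide
  aggregation and pooled-sample log2 fold changes with a ≥ 1.5-log2FC
  candidate screen (`normalizeChannels()`, `quantifyProteins()`,
  `proteinCandidates()`).
* **Anti-correlation integration** — predicted targets (TargetScan / mirDB
  / DIANA exports, unioned with source attribution) of candidate miRNAs
  that move in the opposite direction at the mRNA or protein layer
  (`antiCorrelatedTargets()`, `layerOverlap()`, `topRegulatedMatrix()`,
  `mirnaTargetReport()`).
* **Over-representation analysis** — upper-tail hypergeometric test of
  target lists against GMT gene-set collections (`ora()`).
* **qPCR validation** — delta-delta-Ct relative quantification against a
  housekeeping small RNA and two-tailed one-sample fold-change tests
  (`ddctFoldChange()`, `oneSampleFcTest()`).
* **Synthetic studies with ground truth** — `simulateStudy()` generates all
  pipeline inputs (negative-binomial counts, log-normal TMT reporter
  intensities, a planted target database) with recorded truth, so
  sensitivity and calibration are measurable.

The model and conventions are documented in
`vignettes/stress-multiomics-methods.Rmd`.

## Worked example

Simulate a two-cohort study (4 animals/group/cohort, 200 miRNAs, planted
effects recorded in the ground truth), then run the full chain:

```r
library(stressomics)

cfg <- simulationConfig(seed = 7, n_features_mirna = 200,
                        samples_per_group_per_cohort = c(4, 4))
sim <- simulateStudy(cfg)
sim$mirna_cohort1
#> OmicsCounts (mirna layer): 200 features x 8 samples
#> samples per group x cohort:
#>            cohort1
#>   naive          4
#>   stressed       4

de1 <- deTest(sim$mirna_cohort1)
de2 <- deTest(sim$mirna_cohort2)
cand <- concordantMirnaCandidates(de1, de2)
head(cand, 3)
#>     mirna_id   log2fc_1          p_1   log2fc_2          p_2 direction
#> 1   mir-1-5p -0.9913709 6.158795e-05 -1.0194485 5.275034e-04      down
#> 6 mir-124-3p -1.0254365 2.998554e-05 -1.0470143 1.591979e-04      down
#> 7 mir-127-5p -0.9682325 3.917161e-03 -0.9490444 6.397941e-05      down
```

This run yields 15 candidates (3 up, 12 down) — the planted direction split
is 3 up / 15 down, so the filter recovered most planted miRNAs and, because
concordance is required, none of the cohort-1-only decoys. Continue across
layers:

```r
q    <- quantifyProteins(normalizeChannels(sim$peptides))
pc   <- proteinCandidates(q)                      # |log2FC| >= 1.5
dem  <- filterDeMrna(deTest(sim$mrna), use_adjusted = FALSE)
ov   <- layerOverlap(dem, q$protein_id, pc)
#> DE mRNAs: 201 | detected in proteome: 51 | both layers: 5

anti <- antiCorrelatedTargets(cand, dem, pc, sim$targets)
#> anti-correlated targets: mRNA 74 (58 up / 16 down), protein 28
mirnaTargetReport(cand$mirna_id[1], anti)$mrna[1:3, ]
#>        gene    log2fc                sources
#> 1 GENE00307 0.2302039       DIANA,TargetScan
#> 2 GENE01547 1.6258225                  DIANA
#> 3 GENE01658 1.6633571 DIANA,mirDB,TargetScan
```

The first candidate is down-regulated, so its reported targets are
up-regulated predicted targets — the de-repression pattern the integration
step looks for — each with the databases that predicted the edge.

For file-based workflows, `runAll(pipelineConfig(...))` (or
`inst/scripts/run_pipeline.R` from a shell) reads TSV count matrices,
sample sheets, peptide tables and per-database target files, writes every
stage table plus a `summary.json`, and skips the enrichment/qPCR stages
when their inputs are not supplied.

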