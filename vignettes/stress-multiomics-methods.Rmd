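---
title: "Methods: multi-omics integration of long-lasting acute-stress signatures"
author: "stressomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration of long-lasting acute-stress signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressomics)
```

## The analysis problem

A single stressful event can leave molecular traces in the basolateral
amygdala complex (BLC) weeks later, across three layers of gene expression:
microRNAs, mRNAs and proteins. The designs that detect such traces are
small — a handful of animals per group, two independently sequenced small-RNA
cohorts, an unbalanced RNA-seq run, and a single 6-plex TMT mass-spectrometry
run with one pooled sample per group. `stressomics` implements the analysis
chain such a study needs:

1. count-based differential expression (stressed vs naive) per layer,
2. a **two-cohort concordance filter** that calls a miRNA a candidate only
   when it replicates in direction and significance across both cohorts,
3. pooled-sample TMT protein quantification with fold-change thresholding,
4. **anti-correlation integration**: predicted targets of candidate miRNAs
   that move in the opposite direction at the mRNA or protein level,
5. hypergeometric over-representation analysis of target lists, and
6. delta-delta-Ct qPCR quantification with one-sample fold-change tests.

A synthetic-data generator with recorded ground truth backs every step, so
the pipeline's sensitivity and calibration are measurable rather than
assumed.

## Differential expression model

Counts for feature $i$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_{i,g(j)}$ and common-shape dispersion $\alpha_i$, where $s_j$
is a sample size factor and $g(j)$ the group. The pieces:

**Size factors** are median-of-ratios: for sample $j$,
$s_j = \mathrm{median}_{i \in R}\, k_{ij} / (\prod_{j'} k_{ij'})^{1/n}$,
with the reference set $R$ restricted to features with nonzero counts in
every sample. A matrix in which no feature is nonzero everywhere has no
defined factors and is rejected.

**Fold changes** are computed on normalized counts with a pseudo-count:
$\log_2\!\big((\bar{k}^{\mathrm{str}}_i + c) / (\bar{k}^{\mathrm{nv}}_i +
c)\big)$ with $c = 0.5$ by default. The pseudo-count keeps fold changes
finite when one group mean is zero; its influence is negligible for
moderately expressed features.

**Dispersion** is estimated per feature by method of moments from the pooled
within-group variance ($\hat\alpha_i = (v_i - \bar{k}_i)/\bar{k}_i^2$,
clipped to $[10^{-8}, 10]$), then moderated by shrinking 50% toward a
parametric trend $a_0 + a_1/\mu$ fitted across features. With 3–4 samples
per group the raw estimate is extremely noisy; the trend borrows strength
across features the way mainstream count-DE tools do, while remaining a
closed-form, dependency-free computation.

**Testing** is a Wald test of the group coefficient in a per-feature NB GLM
(log link, log size factors as offset) at the moderated dispersion. The
statistic is referred to a $t$ distribution with $n_{\mathrm{samples}} - 2$
degrees of freedom rather than the normal: at $n = 3$–4 per group the
normal reference produced 10–14% of null features at $p < 0.05$ in our
calibration simulations, while the $t$ reference produces 3.5–7%, inside
the nominal band. This is the package's small-sample convention and it costs
some power relative to tools with more elaborate dispersion estimators —
an accepted trade-off for honest type-I control at these sample sizes.

Features with all-zero counts are reported with `log2fc = 0`, `p = 1` and
excluded from the Benjamini-Hochberg adjustment, which runs over tested
features only.

## The concordance filter

`concordantMirnaCandidates()` declares a miRNA a candidate when
$|\mathrm{log2FC}| \ge 0.5$ (inclusive) and raw $p < 0.05$ (strict) **in
both cohorts**, with agreeing signs. Raw rather than adjusted p-values are
used deliberately: the replication requirement across two independent
cohorts is the multiplicity control, and under the null the chance of a
feature passing both cohorts with matching signs is roughly
$\alpha^2/2$ before the fold-change condition. The boundary conventions
(fold change inclusive, p strict) are exposed through the arguments.

miRNA identifiers are normalized before matching (`normalizeMirnaIds()`):
lowercase, species prefix stripped, `miR`/`mir` unified — two sequencing
facilities and three target databases rarely agree on spelling.

The mRNA filter (`filterDeMrna()`) defaults to adjusted $p < 0.05$, with
`use_adjusted = FALSE` available; single-cohort bulk RNA-seq has no
replication to lean on, so FDR control is the default there.

## TMT protein quantification

`normalizeChannels()` rescales each channel by (grand mean of channel
totals)/(channel total), equalizing total reporter signal across the six
channels while conserving the grand total. `quantifyProteins()` then sums
peptide intensities per protein within channels, averages channels within
groups, and takes the log2 ratio. Summation is the simplest aggregation
consistent with channel-level adjustment; proteins backed by a single
peptide are retained but their `n_peptides` is recorded so users can filter.
Because each group is one pooled sample, there is no variance estimate and
no p-value: candidacy is $|\mathrm{log2FC}| \ge 1.5$ (inclusive; a strict
variant is a flag).

## Integration

A predicted target of an up-regulated candidate miRNA counts as an
mRNA-layer hit when it is in the target database, passes the mRNA
significance filter, and is down-regulated (and symmetrically for
down-regulated miRNAs, consistent with de-repression); protein-layer hits
are defined over the protein candidate list. Requiring the layer filter —
not just direction opposition — is the default because the integrated lists
should inherit each layer's evidence threshold; passing an unfiltered DE
table relaxes this to direction-only. Global target counts deduplicate
genes across miRNAs; per-miRNA lists deduplicate across databases while
keeping the source attribution. Top-N regulation matrices rank by
$|\mathrm{log2FC}|$ (ties broken lexicographically, then truncated — a
deterministic ordering), cross candidate miRNAs, and mark
opposite-direction predicted edges.

## Enrichment

`ora()` is an upper-tail hypergeometric test per gene set,
$P(X \ge k)$ with universe size $N$, set size $K$ and query size $n$,
BH-adjusted across sets. The universe is the collection's declared
background — a deliberate choice, since tool-internal universes of
commercial pathway software are not reproducible. There is no default
minimum-overlap filter (`k_min = 0`).

## qPCR

`ddctFoldChange()` averages replicate Ct values per sample, subtracts the
reference (housekeeping) Ct, centres on the naive-group mean delta-Ct and
reports $2^{-\Delta\Delta Ct}$. `oneSampleFcTest()` runs the two-tailed
one-sample t-test of stressed-sample quantities against 1 (df $= n - 1$);
testing on the raw ratio scale is the default, with a log2-scale option,
since the two give different nulls for skewed ratios and published work in
this area typically reports the raw-scale test.

## The synthetic-data generator

`simulateStudy()` emulates the study conditions end to end:

* **miRNA layer**: two cohorts with 3 and 4 animals/group by default,
  negative-binomial counts with log-normal baseline means
  (meanlog $=\log 100$, sdlog $= 1.3$), log-normal library-size variation
  (sd 0.15) and common dispersion 0.02. 18 planted concordant miRNAs
  (3 up / 15 down by default) shifted by $\pm 1$ log2 unit in both cohorts;
  5 additional miRNAs shifted in cohort 1 only (the decoys the concordance
  filter must reject).
* **mRNA layer**: 2 naive vs 4 stressed samples, 2000 genes, 100 planted DE
  genes at $\pm 2$ log2 units.
* **protein layer**: 6 TMT channels (3 naive, 3 stressed), 500 proteins
  sharing the gene namespace with the mRNA layer, 5 peptides/protein,
  per-channel log-normal loading bias (sd 0.2), 48 planted proteins at
  $\pm 2$ log2 units.
* **target database**: each planted concordant miRNA receives 30 predicted
  edges, 30% of them pointing at planted opposite-direction targets, the
  rest at background genes excluded from the opposite-direction pool; edges
  carry 1–3 of the TargetScan/mirDB/DIANA labels.

Two generator choices deserve justification. The common dispersion of 0.02
reflects the replicate variability of well-expressed features in inbred-mouse
bulk sequencing and was fixed during method development by requiring that
(a) null simulations flag 2–9% of features at $p < 0.05$ and (b) planted
1-log2FC concordant effects are recoverable with sensitivity $\ge 0.8$ at
$n = 4$/group/cohort — conditions a real study of this design plausibly
meets. Planted effects are drawn from the **expressed stratum** (expected
baseline mean $\ge 20$): an effect planted in a barely-detected feature is
unrecoverable by any method, and real candidate calls come from quantifiable
features.

What the generator does **not** emulate: mapping artifacts, miRNA isoform
ambiguity, correlated features, peptide-level missingness, isotope-impurity
cross-talk between TMT channels, and batch structure beyond per-channel
loading. Passing tests on this generator therefore demonstrates the
correctness and calibration of the statistical machinery under its stated
model, not robustness to those real-data pathologies.

## Problem sizes and determinism

The test suite runs the generator at 60–200 miRNAs, 150–400 genes and 60–200
proteins; the acceptance script uses 200–600 miRNAs, 2000 genes and 500
proteins. These sizes give stable estimates of the recovery and calibration
quantities while keeping a full run in tens of seconds. All randomness flows
from a single integer seed per simulated object (the generator functions
re-seed from `config@seed` plus a fixed per-layer offset), so identical
configurations are bit-reproducible.

## Known limitations

* The DE test trades power for calibration at very small $n$; with 2 vs 4
  samples and FDR adjustment, planted 2-log2FC genes are only partially
  recovered — an honest property of that design, visible in the generator.
* One pooled sample per group in the TMT layer means protein candidacy has
  no error control; it is a fold-change screen, as in the emulated design.
* Gene/protein matching is by normalized symbol equality; isoforms and
  many-to-one protein groups are out of scope.
* Enrichment results depend entirely on the supplied gene-set collection
  and universe; the package ships no pathway knowledge base.
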