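---
title: "Methods: signature-based screen scoring and tumor immune biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based screen scoring and tumor immune biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscreen)
```

`sigscreen` implements two analysis arcs around a tumor chemokine gene
signature (CXCL1/CXCL2 by default): ranking compounds from plate-based
sequencing screens by their ability to down-regulate the signature, and
quantifying the signature's association with MDSC infiltration and
clinical outcome in single-cell and survival data. This vignette documents
the models, the defaults and why they were chosen, the numerical
edge-case policies, and what the synthetic-data module does and does not
emulate.

## Screen quantification

**Read counting.** Screens are read out by sequencing pooled capture
probes (short fixed-length sequences, default 30 nt, one or more per
gene). A read is assigned to the unique probe at minimal Hamming distance,
provided that distance is at most `max_mismatches` (default 3). Reads tied
between two probes at the minimal distance are discarded and tallied per
well rather than split fractionally: splitting would invent weights the
assay gives no basis for. Indels are not modeled — the probes are short
fixed-length capture sequences, so substitution-only (Hamming) matching is
the appropriate error model — and `N` bases always count as mismatches.
Only reads of exactly the probe length are accepted; there is no trimming
policy.

**Stable-gene normalization.** Each well's size factor is the sum of its
stable ("housekeeping-like") probe counts divided by the across-well
median of those sums, and all counts are divided by it. Anchoring at the
median keeps normalized values on the count scale and makes the transform
exactly the identity when all wells are already balanced. The identity of
the stable panel is an input: the probe FASTA declares stability
explicitly (`stable=1`), because the stable set is assay-specific. A well
with zero stable counts is an error naming the well — silent imputation
would corrupt every downstream fold change.

## Batch diagnosis and empirical-Bayes correction

Plates are the default batch unit (configurable). `pca_batch_diag`
computes PCs of the log2(x+1), probe-centered matrix and reports, per PC,
the R² of a one-way ANOVA of scores on batch — a leading PC with high
batch R² means batch dominates the signal.

`combat_fit`/`combat_adjust` implement the standard parametric
empirical-Bayes location/scale adjustment: per-probe standardization
(batch-design grand mean and optional covariates removed, pooled SD
divided out), per-batch per-probe location `gamma` and scale `delta²`
estimates, normal and inverse-gamma priors moment-matched across probes,
and the usual iterative conditional solve (tolerance 1e-4, at most 100
iterations). Three deliberate choices:

* **Maximum-likelihood (1/n) variance denominators** throughout, rather
  than n−1. With a single batch the standardized data then have per-probe
  mean exactly 0 and variance exactly 1, the degenerate priors collapse
  onto the estimates, and the transform is exactly the identity — a
  property we consider non-negotiable for a correction step. The cost is a
  small (order 1/n) difference from implementations using n−1, which the
  test suite checks against with a loose tolerance.
* **Degenerate-prior fallbacks**: when the across-probe spread of the
  batch estimates is numerically zero, shrinkage targets equal the raw
  estimates instead of dividing by zero.
* **Zero-variance probes pass through uncorrected with a warning** rather
  than failing the run; compound identity is *not* a covariate, since it
  would absorb exactly the treatment effects the screen measures. DMSO and
  compound wells are corrected jointly.

## Compound ranking

Per compound and signature gene, the log2 fold change is the mean of
treated log2 values minus each treated well's own-plate DMSO mean
(plate-local baselines are what make multi-plate screens comparable), and
significance is a two-sample pooled-variance Student's t test of treated
versus same-plate DMSO values. A variance floor of 1e-6 keeps t finite
when replicates are degenerate; single-replicate compounds are retained
with p = 1 (zero score contribution) so the ranked table always covers the
library, with a flag.

The combined score, `mean_g[(-log10 p_g) x (-log2FC_g) x dir]`, is the
simplest statistic monotone in both the evidence and the effect axis of
the usual volcano representation; it is isolated in `score_compound` so a
rank-sum or signed-minimum variant can be swapped in without touching the
rest. Raw p values are ranked (no multiplicity correction affects order);
BH-adjusted columns are emitted for reporting only. Ties are broken by
smaller mean p, then compound id, making the ranking deterministic.

## Single-cell module

Cells are filtered by the conventional QC rule (fewer than 200 detected
genes, or more than 30% mitochondrial counts, excluded; mitochondrial =
`MT-`/`mt-` symbol prefix, configurable) and log-normalized
(`log(1 + 1e4 * count / cell_total)`).

**Module scores** use expression-bin-matched controls: all genes are cut
into `nbin = 24` equal-frequency bins by across-cell mean expression, each
signature gene draws `nctrl = 100` control genes from its bin under a
fixed seed, and the score is the per-cell signature mean minus the control
mean. 24/100 are the conventional defaults of the binned-control
algorithm. On a constant matrix the score is exactly zero, and on
unstructured data the mean score over random gene sets centers on zero —
both are tested.

**Stratification** defaults to a median split (ties go low); the cutoff
rule is explicit because the source analyses state only "high or low".
For the two-gene chemokine signature, patient grouping uses the mean
log-normalized expression of the two genes (not the module score), which
is what "average combined expression" means operationally; module scores
are for multi-gene sets.

Composition differences use Pearson's chi-square without continuity
correction (composition tables typically have df > 1; a sub-1 expected
cell attaches a warning). Two-group comparisons use the Mann-Whitney test
with an exact null for tie-free groups of at most 8 and the
tie-corrected normal approximation otherwise; an all-tied comparison
returns U = n1n2/2 and p = 1 where the approximation is 0/0. `U/(n1 n2)`
equals the ROC AUC of the same data, an identity the tests verify
exactly. Spatial coexpression of two genes is presence (count > 0) of
both transcripts in the same spot.

## MDSC reference projection

The classifier embeds query cells into a PCA space fit on an annotated
reference and classifies there, never refitting on the query: reference
genes are standardized (centers/scales stored), decomposed by truncated
PCA (`n_pcs = 30`), and for each class the PCs whose scores separate
class from rest (two-sided Wilcoxon, BH-adjusted p < 0.05) are selected.
On those PCs a one-vs-rest probabilistic linear classifier is fit —
ridge-regularized logistic regression with a small fixed penalty, which is
deterministic and immune to the perfect-separation divergence that plain
maximum-likelihood logistic fits suffer on well-separated classes. A cell
is labelled with its maximum-probability class only when that probability
reaches `prob_threshold = 0.55` (the conventional rejection default);
otherwise it is `unassigned`. Query genes are aligned by symbol; genes
missing from the query contribute 0 after centering, i.e. are imputed at
the reference mean. All hyperparameters are documented assumptions and
configurable; the reference tool's kernel variant is intentionally out of
scope, isolated behind `classifier_params`.

## Outcome biomarkers

* **z-scores**: per-gene center *and* scale (sample SD) before averaging
  across signature genes. The source procedure states mean subtraction;
  full standardization is our assumption, adopted so multi-gene averages
  are not dominated by high-variance genes.
* **ROC/AUC** from midranks (exact U identity); the curve sweeps unique
  thresholds descending.
* **Kaplan-Meier and log-rank** are computed by the survival package
  (product-limit estimator; unweighted Mantel-Cox statistic with the
  standard tie-corrected hypergeometric variance); the test suite
  cross-checks the statistic against a term-by-term hypergeometric oracle
  on small tables. Note that adding a subject censored after the last
  event *does* change the earlier survival estimates (it enlarges every
  risk set); what it cannot do is add a drop to the curve.
* **best_cutoff** scans every unique score in the 25-75% quantile window
  (the common auto-cutoff convention; the exact window used by public
  web tools is not recoverable, so it is a parameter) and reports the
  cutoff minimizing the log-rank p. That minimum is an optimized
  quantity, not a nominal p — the result always carries
  `optimized = TRUE`, and a permutation-adjusted p (rescanning under
  label permutation) is available; the tests demonstrate the inflation on
  null data.
* **H-score** (`sum(intensity 0-3 x percent)`) and the caliper tumor
  volume `width² x length / 2` (width the smaller dimension, swapped with
  a warning) are included as exact clinical formulas.

## Synthetic data: what it emulates, and what it does not

The generators encode the study conditions the pipeline is meant to
recover, with ground truth returned alongside the data (never
reconstructed from file names):

* `gen_screen`: negative-binomial counts (gamma-Poisson, shared
  dispersion 0.1 — overdispersed sequencing counts; no generative model is
  prescribed by the source, so NB is the field-standard choice);
  384-well plates with 16 DMSO wells each; per-plate *probe-specific*
  additive shifts on the log2 mean (SD 0.5 by default) plus a plate-wide
  dispersion multiplier (log-SD 0.2) — exactly the location/scale
  structure the EB correction models; hit compounds multiply signature
  probe means by `2^hit_log2fc`; stable probes are never affected by
  treatment. Replicates per compound default to 3; the original screen's
  replicate count is not documented, so this is a flagged, configurable
  assumption.
* `gen_reads` realizes a count table as per-well reads with independent
  per-base substitution errors (read length = probe length; no indels,
  matching the Hamming counting model) and conserves counts exactly.
* `gen_scrna`: four cell-type programs (tumor, T cell, MDSC, other
  myeloid) with 50 markers each at +3 log2 units — comfortably above the
  2-log-unit separation at which classification is expected to be
  reliable; a per-patient latent chemokine activity multiplies tumor-cell
  CXCL1/CXCL2 means and couples, through a logistic link (slope 2,
  baseline MDSC share 25% of myeloid cells), to the patient's MDSC
  fraction — the positive chemokine-MDSC association the cell arc
  recovers. Cohort default: 30 patients x 100 cells, 1,000 genes.
* `gen_survival`: exponential event times, high-group hazard =
  `hazard_ratio` x baseline (0.1 events/unit), independent exponential
  censoring calibrated to the requested censored fraction.
* `gen_response`: response probability `plogis(-slope x score)` — high
  signature scores predict non-response, matching the direction of the
  chemokine/MDSC biology.

Not emulated: doublets, ambient RNA, UMI deduplication, patient-level
batch effects in the single-cell data, non-proportional hazards, and
informative censoring. Passing tests therefore demonstrate that the
*methods* recover known structure under their own model assumptions — not
that real screens or cohorts satisfy those assumptions.

## Problem sizes and determinism

The test suite and the acceptance script run the pipeline at moderated
sizes chosen to exercise every code path while staying quick on a laptop:
the spike-in screen uses 2,000 compounds x 3 replicates (about 6,500
wells x 40 probes), the classifier cohorts 30 patients x 100 cells x
1,000 genes, and the log-rank calibration 1,000 null cohorts of n = 200.
Every stochastic step routes through an explicit integer seed, and
same-seed runs are bit-identical — the pipeline tests assert this on
output hashes.

## Known limitations

* The combined compound score is one defensible choice among several
  monotone statistics; rank stability under alternatives is not assessed.
* The EB correction assumes batches share the biological signal;
  plate-confounded designs (a compound on exactly one plate with strong
  plate effects) cannot be disentangled.
* The projection classifier assumes reference and query share expression
  scale after log-normalization; cross-platform batch alignment is out of
  scope.
* `best_cutoff`'s permutation adjustment treats subjects as exchangeable;
  covariate-stratified designs are not supported.
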