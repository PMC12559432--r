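---
title: "Tracing the tissue of origin of neuroendocrine neoplasms from methylation arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the tissue of origin of neuroendocrine neoplasms from methylation arrays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neuroendocrine neoplasms (NEN) arise in many organs — pancreas, ileum,
colorectum, stomach/duodenum, appendix, lung, skin (Merkel cell carcinoma) —
and frequently present in the liver either as metastases or as tumors without
a detectable primary (cancer of unknown primary, CUP). Because therapy
depends strongly on the organ of origin, assigning hepatic NEN to their most
likely primary site is clinically consequential. DNA methylation profiles
measured on Infinium-style CpG arrays carry a stable imprint of a tumor's
tissue of origin, which this package exploits: it classifies samples into
organ-site classes, while explicitly modeling the one nuisance signal that
most corrupts biopsy material — admixed normal tissue and leukocytes.

`methorigin` implements the full chain: probe-level preprocessing, latent
methylation component (LMC) deconvolution, purity estimation and
residualization, Random Forest origin classification with proportional
prediction scores, SNP-fingerprint sample identity, and copy-number profiling
from array intensities. A synthetic cohort generator with complete ground
truth makes every stage testable without any external download.

## Preprocessing

Beta values are the methylated-signal fraction
$\beta = M / (M + U + \text{offset})$ with a default offset of 100
intensity units, which regularizes low-intensity probes toward 0 and keeps
the ratio defined when both channels are empty. Probe filtering removes, in
a fixed order, probes flagged as SNP-overlapping, cross-reactive, low
quality, and sex-chromosomal; the removal report counts each probe once at
the first step that catches it, so step counts are disjoint and sum to the
total removed. Probe quality is an input annotation on the manifest rather
than recomputed from detection p-values, which are not part of this
package's input contract.

Cross-platform merging intersects probe sets and concatenates samples.
Batch correction fits, per probe and per channel separately, a univariable
linear model of log2 intensity on the batch factor and removes the fitted
batch effects so all batches share the reference batch's mean; with a single
categorical covariate this is exactly a per-batch mean shift, and the
operation is idempotent.

Two site-selection procedures feed downstream stages:

* **Most variable sites** — per-probe sample standard deviation
  (denominator $n-1$), descending, ties broken lexicographically by probe
  id for determinism.
* **Differential + variable** — per class, a one-vs-rest Welch $t$ screen
  gated at Benjamini–Hochberg adjusted $p < 0.05$ within the comparison,
  ranked by absolute mean beta difference with the top 500 kept per class,
  unioned across classes and with the top 5000 most-variable sites. The
  significance gate and its threshold are this package's design decision:
  the ranking criterion is the methylation difference itself, and the
  Welch/BH gate simply keeps unstable small-variance probes out without
  introducing an empirical-Bayes moderation step. Differences are computed
  on the beta scale, not M-values, so the ranking matches the reported
  score's units. Probes with any missing value are excluded from both
  procedures.

## Deconvolution model

A beta matrix $D$ (probes × samples) is decomposed into $k$ latent
methylation components $T$ and mixing proportions $A$ by approximately
minimizing

$$\|D - TA\|_F^2 \;+\; \lambda \sum_{ij} T_{ij}(1 - T_{ij}),
\qquad 0 \le T \le 1,\; A \ge 0,\; \mathbf{1}^\top A = \mathbf{1}^\top,$$

i.e. component profiles are valid methylation fractions, every sample is a
convex mixture of components, and the penalty (maximal at $T = 1/2$, zero
at $T \in \{0,1\}$) pushes profiles toward the 0/1 bimodality typical of
cell-type methylomes.

The solver alternates two monotone steps:

* **Proportions:** per-sample simplex-constrained least squares by
  projected gradient with step $1/L$, $L = 2\,\lambda_{\max}(T^\top T)$,
  using the sorting-based Euclidean simplex projection. Each step cannot
  increase the objective.
* **Components:** exact coordinate descent over component columns. For
  column $j$ the subproblem is a per-probe quadratic
  $(G_{jj} - \lambda)t^2 - 2rt$; when convex, its box-clipped stationary
  point is taken, and when $\lambda$ makes it concave, the better endpoint
  of $\{0, 1\}$ — so the step is an exact minimizer either way.

The recorded objective trace is therefore non-increasing, which the tests
assert on arbitrary inputs. Optimization is non-convex, so `n_restarts`
initializations are used: restart 1 seeds $T$ deterministically with
furthest-point data columns (mixtures of distinct classes are far apart, so
extreme samples approximate pure profiles); remaining restarts use uniform
random matrices, keeping the solution equivariant under sample permutation.
Defaults ($\lambda$ grid $\{0, 0.001, 0.01, 0.1\}$ with quarter-holdout
cross-validated reconstruction error via `deconvolution_cv_error()`, 10
restarts) were chosen so that desk-scale recovery experiments at a few
thousand probes and on the order of a hundred samples converge within
minutes on one CPU; $k$ is a user input, with the cross-validated error
report as the only selection aid.

## Purity: LUMP and the flagged component

Tumor purity is scored LUMP-style: the mean beta over designated
leukocyte-unmethylated probes divided by 0.85 and capped at 1. The probe
set is configurable because the canonical list is an external resource; the
synthetic manifest marks its own designated LUMP probes. Each LMC's
proportion row is correlated against $1 - \text{LUMP}$ (normal-cell
content, so the expected association is positive); the component with the
largest $|r| \ge 0.7$ is flagged as the purity component and excluded from
class-discriminative use. The orientation convention matters only for the
sign of the reported $r$; flagging uses the absolute value.

## Classification

Features are the most variable of the selected sites (default 2000 at the
synthetic scale). To remove normal-cell confounding, each probe's betas are
regressed on the flagged purity-LMC proportion; where the slope is
significant ($p < 0.05$, no multiplicity correction — a deliberately
liberal gate, since over-adjusting a null probe merely subtracts an
estimated-zero slope), the feature becomes residuals re-centered by the
fitted intercept, algebraically $\beta - \hat b \cdot \text{purity}$,
keeping features on the beta scale. The records $(\hat b, \hat a, p)$ are
stored; query samples are adjusted with training-time coefficients only,
their purity proportion estimated by simplex least squares against the
trained $T$ — no leakage of query data into the adjustment.

The classifier is a probability Random Forest (1500 trees, $\sqrt{p}$
feature subsampling, Gini splits, depth cap 12, out-of-bag scoring, fixed
seed 3) — `ranger` supplies the implementation since tree induction itself
is standard machinery. Per-class scores are the forest's class-probability
estimates; they sum to 1 and are reported as proportional probabilities.
The predicted label is the argmax, ties broken by class order and flagged.
Evaluation uses stratified 3-fold cross-validation with pooled held-out
scores and per-class one-vs-rest AUC computed by the rank (Mann–Whitney)
identity; `pROC` serves only as an independent cross-check in the tests.
A gradient-boosting funnel (`xgboost`, softprob) ranks features by gain,
keeps the top 404 by default, retrains the forest on the subset and reports
the AUC comparison of both pipelines.

Whether origin classification should consume residualized CpG features or
the LMC proportions themselves is genuinely open; the CpG-level path is the
primary implementation, and passing `fit$A` rows as a feature matrix covers
the LMC-proportion variant without a dedicated mode.

## Sample identity from SNP probes

SNP probes yield three beta clusters; calls use thresholds 1/3 and 2/3 with
boundaries inclusive to heterozygous — a symmetric, assumption-free
partition. The SNP distance between samples $i,j$ is
$d_{ij} = \sum_k \mathbf{1}\{g_{i,k} \ne g_{j,k}\} / M$ over the $M$ loci
non-missing in both; a strict mode restricts to loci shared across all
samples, avoiding missing-data bias in cohort-level analyses, and the two
policies agree exactly on complete data. Average-linkage hierarchical
clustering with a 0.10 identity cutoff (both package defaults, as no
community standard exists for array fingerprints) reports co-merging pairs
as same-individual candidates.

## Copy-number profiles

Combined intensities $M + U$ are library-normalized so each sample's median
matches the reference median, then log2 ratios are formed against the mean
of flat-genome reference samples. Probes are collected into fixed-span bins
grown rightward to at least 20 probes (median per bin); the baseline is the
kernel-density mode of the bin-ratio distribution — robust to unbalanced
gain/loss burdens, unlike the mean — with a median fallback for very short
tracks. Binary segmentation splits each chromosome while the best split's
between-segment sum-of-squares gain exceeds the penalty (default 0.1 in
squared log2-ratio units); segments are called gain/loss at mean ratio
±0.15. The bin span, thresholds and penalty are package defaults chosen so
that arm-scale events of $|\log_2| \approx 0.585$ (1.5× / 0.67×) are
recovered at desk scale; none of them is a community constant. Cohort
frequency tracks report the per-bin fraction of samples called gain and
loss.

## The synthetic cohort generator

The generator emulates, with known ground truth, exactly the data features
the pipeline consumes:

* **Bimodal components.** Per-probe baselines sit near 0.05/0.95 (equal
  weight) with small jitter; each class has a disjoint informative block
  (default 50 probes, delta-beta 0.5) shifted toward the opposite mode; the
  leukocyte component has its own block plus designated LUMP probes where
  it is unmethylated while tumor components are methylated.
* **Contamination.** Each sample mixes its class component with the
  leukocyte component at a proportion drawn uniformly in $[0.05, 0.5]$ —
  spanning the purity range a >50% tumor-content cohort plausibly shows.
* **Noise.** Beta-scale Gaussian noise, default SD 0.02; the value is a
  fixture parameter, not a cohort estimate, as per-probe noise magnitude
  is not identifiable from the package's inputs.
* **Intensities.** Combined intensity = base × copy-ratio × per-probe
  lognormal affinity × per-batch log2 offset, with optional per-measurement
  lognormal noise (cohort default sdlog 0.1, so that copy-number recovery
  is tested against non-trivial variation); the methylated/unmethylated
  split reproduces beta exactly at offset 0.
* **SNPs.** Per-locus MAF uniform in [0.1, 0.5], Hardy–Weinberg genotypes
  per patient, shared exactly within a patient; beta clusters at
  0.05/0.5/0.95.
* **CNA.** Per-class recurrent segments (default: one chromosome-arm loss
  at ratio $2^{-0.585}$, one gain at 1.5) on a two-chromosome genome of
  evenly spaced probes, 0-based half-open coordinates.
* **Batches, flags, pairs.** Round-robin batch assignment with log2
  offsets; planted quality flags outside informative blocks; a few
  patients contribute two samples for identity checks.

All randomness flows from one master seed through fixed per-stage offsets;
identical configuration gives byte-identical fixtures, and the TSV writers
use 17 significant digits so matrices round-trip losslessly.

What the generator does **not** emulate: Infinium type I/II probe chemistry
and dye bias, detection p-values, sex chromosomes, focal (sub-arm) CNA,
relatedness beyond identity, and realistic linkage disequilibrium. Passing
tests therefore demonstrate that the algorithms recover the structure they
assume, at realistic noise levels — not that real-cohort performance
figures transfer.

## Problem sizes and numerical choices

The recovery experiments run at deliberate desk scale: deconvolution at
2,000 probes × 120 samples with $k=5$ and 10 restarts; classification at 8
classes × 20 samples with 400 informative CpGs and 2,000 features; 40
extra-contaminated held-out queries for the metastasis-like transfer check;
1,000 random genotype pairs for distance exactness. Convergence tolerance
is $10^{-8}$ relative objective change (cap 200 iterations); simplex sums
are enforced to $10^{-12}$ by construction; tie-breaks are lexicographic
throughout; degenerate inputs (single batch, constant purity, zero-variance
proportion rows, chromosomes shorter than a bin) warn or record `NA` rather
than fail, as documented per function.

## Known limitations

* The deconvolution objective is non-convex; restarts mitigate but do not
  eliminate local minima, and $k$ misspecification degrades components
  gracefully rather than detectably.
* Residualization assumes a linear purity effect per CpG.
* The binary-segmentation penalty is scale-dependent; tracks with very
  different bin noise need a re-tuned penalty.
* Genotype calling ignores allelic intensity imbalance; aggressive
  filtering of SNP probes upstream removes the identity signal entirely.
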