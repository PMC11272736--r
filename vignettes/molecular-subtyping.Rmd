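---
title: "Single-method WES molecular subtyping of endometrial cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-method WES molecular subtyping of endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotype)
```

## The problem

Endometrial cancer falls into four prognostically distinct molecular
subtypes: POLE-ultramutated (excellent prognosis), MSI-hypermutated and
copy-number (CN) low (intermediate), and CN high / serous-like (poor). The
reference classification requires multi-omics profiling; the widely used
surrogate (ProMisE-style) classification requires both immunohistochemistry
and targeted sequencing. `endotype` implements a *single-method* alternative:
every marker is derived from one paired tumor/normal whole-exome sequencing
(WES) run, and both classifications are produced side by side:

* **TCGA-analogue track** — POLE > MSI > CN high > CN low,
* **Surrogate track** — POLEmut > dMMR > p53abn > NSMP.

The precedence matters clinically: a tumor with both a pathogenic POLE
mutation and a TP53 mutation is POLEmut (good prognosis), not p53abn;
misordering these would misdirect adjuvant therapy.

## Decision rules and their parameters

### POLE-ultramutated signature

POLE exonuclease-domain mutants produce a characteristic ultramutated,
C>A-rich / C>G-poor spectrum. A sample is signature-POLE when, over its
filtered somatic SNVs,

$$ n_{\mathrm{SNV}} > 500, \qquad f_{C>A} > 0.2, \qquad f_{C>G} < 0.03, $$

with all three inequalities strict and class fractions computed in the
standard pyrimidine-collapsed convention (C>A pools C→A with G→T, etc.).
The surrogate track instead requires a *pathogenic* POLE mutation: a
transparent, editable whitelist of exonuclease-domain hotspots (P286R,
V411L, S297F, A456P, S459F) plus any missense at residues 268–471
(`pole_whitelist()`). Samples with no SNVs have an undefined spectrum and
can never satisfy the rule.

The upstream somatic filter (`filter_config()`) is this package's own
definition — the typical paired-WES heuristics FILTER = PASS, tumor allele
fraction ≥ 0.05, normal allele fraction ≤ 0.02, tumor depth ≥ 20 — because
clinical pipelines rarely disclose theirs. All thresholds are configurable.

### Microsatellite instability

Per microsatellite locus the tumor and normal repeat-length read histograms
are compared by the stepwise difference, defined here as total-variation
distance between the count-normalised distributions:

$$ d(T, N) = \tfrac{1}{2} \sum_k \lvert f_T(k) - f_N(k) \rvert \in [0, 1]. $$

It is zero iff the distributions coincide, one iff the supports are
disjoint, symmetric, and scale-invariant. Loci with fewer than 20 reads in
either sample are unusable; the sample score is the unweighted mean over
usable loci and MSI-H is called at aggregate ≥ 0.3 (*inclusive*). This is a
MANTIS-analogue statistic, not a bit-exact port of that tool; the 0.3
operating threshold is retained even though it differs from common MANTIS
defaults, and is configurable. With no usable locus the sample is MSI-
indeterminate and is routed to the non-MSI branch with a warning; it becomes
unclassifiable only if its mutation spectrum is *also* undefined.

### Copy-number cluster-4 prediction

CN-high membership is predicted by a Gaussian Naive Bayes model of the TCGA
serous-like cluster (cluster 4) from per-sample CN features: total gain and
loss counts, gain/loss counts per chromosome (chr1–22, X), alteration
counts for the 25 most recurrently altered genes (re-derived at training
time, ties broken lexicographically, frozen into the model), ploidy
(length-weighted mean copy number), and altered megabases. Gains are merged
segments with copy number > 2.5, losses < 1.5 — the cutoffs are this
package's choice, configurable, since "gain/loss" is rarely defined in
print. Adjacent equal-CN segments are merged first so counts do not depend
on how a constant run was segmented. "Ploidy and length of CN alterations
per megabase" is read as two features (ploidy; altered Mb); the alternative
alterations-per-Mb rate is computed too (`alt_per_mb`) but not used by
default. The features plainly violate NB's independence assumption; the
model is nonetheless robust here, which is why it was chosen. Variances are
floored at $10^{-9}$ times the largest feature variance (the usual
variance-smoothing convention); priors are empirical. Performance is
assessed by stratified 5-fold cross-validation (accuracy, precision,
recall, F1 at the 0.5 posterior cut; ROC-AUC from posteriors), averaged
unweighted over folds.

### QC plausibility flags

In FFPE material, degraded DNA inflates apparent microsatellite
instability. Four sequencing metrics flag samples whose MSI-H call is at
risk of being an artifact: mapped reads < 92%, on-target reads < 66%, short
fragments > 93%, adapter contamination > 6.34% (strict, OR-combined). These
are deliberately implemented as *annotations*, never as a classification
rule: reading them as a definition of MSI would let DNA quality overwrite
biology, whereas flags keep the cascade auditable without changing its
output.

### Survival evaluation

Each track's strata are compared by Kaplan–Meier curves, the k-group
log-rank test, and Cox proportional-hazards regression with one indicator
per non-reference subtype (reference CN low / NSMP — the strata a clinical
reader benchmarks against), Efron tie handling, and Wald 95% confidence
intervals (the CI flavour is unstated in most clinical reports; Wald is the
default of standard software). A stratum with zero events is reported with
the degenerate convention HR 0, CI (0, Inf) rather than a meaningless
near-zero estimate with astronomical standard error. Subjects missing time
or status are dropped per endpoint.

## The synthetic cohort generator

No patient-level data accompany this method, so validation uses a seeded
generator (`generate_cohort()`) that plants subtype-determining signals
*strictly inside* the corresponding decision regions, away from the
boundaries, so that a correct pipeline recovers every planted label
exactly:

* signature-POLE samples draw 600–2500 SNVs with C>A share 0.27–0.38 and
  C>G share 0.008–0.018; non-POLE samples stay below 500 SNVs;
* MSI-H samples get per-locus stepwise scores of 0.42–0.65 (60 loci, 100
  reads per locus, two loci left under-covered to exercise the usability
  rule); stable samples stay at or below 0.08;
* cluster-4 genomes carry 3–6 whole-chromosome gains plus 22–32 focal
  events genome-wide; quiet genomes draw 0–8 alterations from a fixed
  catalog of 24 recurrent CNV regions. The catalog serves two purposes: it
  reflects that CN-low/MSI endometrial tumors do carry some recurrent
  alterations rather than pristine genomes, and it guarantees that any
  feature pattern a quiet sample can show is represented in a training
  cohort's negative class, keeping planted-quiet samples away from the
  classifier's decision boundary;
* FFPE degradation affects only the QC metric values, not the molecular
  data, mirroring how the QC rules themselves operate;
* survival times are exponential with multiplicative per-subtype hazards on
  the surrogate truth label (OS multipliers: POLEmut 0.05 — near-zero
  events; dMMR 1.44; NSMP 1; p53abn 12.84; PFS: 0.05 / 2.07 / 1 / 9.58)
  under uniform administrative censoring on [0, 140] months. Baseline rates
  (0.0015 and 0.0022 events/month) are set so a 108-sample cohort accrues
  roughly 20 OS and 28 PFS events over that follow-up — a realistic event
  yield for a mostly stage-I endometrioid cohort. Exponential times with
  proportional hazards make the Cox recovery experiment well-posed.

The packaged 108-sample fixture (`default_fixture_spec()`) plants 9
signature-POLE samples (6 pathogenic; of the 3 signature-only, 2 MSI-H and
1 TP53-mutant), 51 further MSI-H, 15 cluster-4 (6 TP53-mutant), and 4 quiet
TP53-mutant samples. The cascade rules then *force* the distribution
9/51/33/15 (TCGA-analogue) and 6/53/38/11 (surrogate); in particular dMMR
exceeds the MSI label count by exactly the two signature-only POLE MSI-H
samples — the cross-track asymmetry is structural, not accidental. The
cluster-4 training cohort (`cn_training_spec()`) has 240 samples with 62
(26%) positives, labels assigned rather than sampled.

What the generator does **not** emulate: read-level data, realistic
trinucleotide signature composition, germline variation, correlated
OS/PFS within patients, and feature correlations of real CN profiles.
Passing tests therefore demonstrate correctness of the *rules and
estimators* under controlled signals — not clinical performance on real
FFPE WES data.

## Numerical and degenerate-input choices

* Percentages round half-up to one decimal (`round_half_up()`), matching
  how clinical tables print.
* Zero-SNV samples: spectrum undefined, non-POLE, warning.
* Zero-depth / shallow loci: unusable, excluded; no usable locus → MSI
  indeterminate.
* Zero-segment samples: all-zero CN features, ploidy 2.0, warning.
* Single-class training sets: training refuses, rather than producing a
  degenerate model.
* Per-sample pipeline failures (e.g. one corrupt VCF) are isolated: that
  sample is unclassifiable with a recorded reason, the cohort proceeds.
* Determinism: every generator component has its own RNG substream derived
  from the spec seed, so a component generated alone is identical to the
  same component inside a full bundle, and the whole pipeline is
  byte-reproducible for a fixed seed.

## Known limitations

* The permutation null of the cluster-4 classifier does not sit at the
  majority rate: a generative Gaussian NB re-discovers strongly bimodal
  cluster structure from the class variances even when labels are permuted,
  so permuted-label CV accuracy falls near 0.5 rather than 0.74 (the same
  behaviour is reproduced by other Gaussian NB implementations on the same
  features). Calibration-style nulls for this model need a discriminative
  baseline or variance-pooled model instead.
* Cox hazard ratios from strata with very few events carry the usual
  small-sample upward bias of partial likelihood; the recovery experiment
  in the test suite therefore measures bias with an adequately powered
  two-group design (about 23 reference events).
* The MSI statistic is an analogue of the published tumor/normal
  instability score, not a re-implementation of that tool's internals.
* The POLE pathogenicity whitelist is intentionally minimal; real
  deployments should substitute a curated clinical knowledge base.

## Problem sizes used in the test suite

The shipped tests run the full 108-sample fixture end to end, a 240-sample
training cohort for each of 10 cross-validation seeds, 200 replicate
cohorts (n = 108) for hazard-ratio recovery, and 100 permutation
replicates for the log-rank null — sizes chosen to keep the whole suite in
the low minutes on a single core while leaving every statistical check
well-powered.

## A worked end-to-end run

```{r example, eval = FALSE}
spec <- default_fixture_spec(seed = 1)
bundle <- generate_cohort(spec)
model <- train_cn_model(pipeline_config(seed = 2))
calls <- classify_cohort(bundle, model = model)
summarize_cohort(calls)
evaluate_survival(calls, bundle$clinical)
```
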