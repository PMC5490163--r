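---
title: "Classifying somatic mutations without matched normals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic mutations without matched normals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isown)
```

## The classification problem

A tumor-only variant caller emits a mixture of somatic mutations and the
donor's germline polymorphisms. Common polymorphisms are easily removed
with population databases, but each genome carries hundreds of thousands
of rare inherited variants absent from any catalogue. `isown` treats the
separation as a supervised learning problem at the level of *collapsed
alleles*: all calls across the cohort that share (chromosome, position,
reference, alternate) are merged into one unique variant, under the
assumption that such an allele is either somatic in everyone or germline
in everyone. Collapsing shrinks the prediction set by orders of magnitude
and, more importantly, makes cohort-level features (sample frequency,
mean VAF, flanking-SNP agreement) well defined.

Alleles whose paired-caller training labels disagree across samples
violate the collapsing assumption; they are excluded from training and
from accuracy denominators rather than majority-voted, and their count is
reported. This is conservative and cheap: such alleles are rare.

## Stages

The pipeline runs strictly in this order: quality filtering, annotation,
per-call feature computation, collapsing, pre-labeling, classification.

**Filtering.** Records are dropped, each charged to the *first* failing
check: unparseable; not a single-base substitution (indels and
multi-allelic records are excluded, not decomposed — there is no
principled decomposition for the downstream features); `N` reference;
caller FILTER other than PASS; depth below 10×; homozygous (only when
`drop_homozygous` is set — several public paired call sets ship without
homozygous calls, so this is a dataset-harmonization knob, not part of
the method); and without a known coding annotation (silent calls are
dropped unless `include_silent`). Depth is taken as the sum of allelic
depths when the caller provides them, falling back to the record's `DP`,
so that `alt_count/depth` is internally consistent.

**Pre-labeling.** Two rules bypass learning. An allele present in the
common-polymorphism set and absent from the somatic catalogue
(`cnt == 0`) is germline: the overwhelming majority of such alleles are
inherited, and removing them collapses the class imbalance by roughly
two thirds. An allele with a somatic-catalogue sample count
`cnt >= 100` (threshold inclusive, configurable) is a recurrent driver
and labeled somatic. The rules are disjoint by construction — the
germline rule requires catalogue absence — and pre-labeled alleles never
reach the classifier.

**Classification.** The ten features are described in the README. The
common-polymorphism membership is deliberately *not* a feature: it is
consumed entirely by the germline pre-labeling rule, while the
rare-polymorphism membership is the feature. Hard labels use a 0.5
threshold on the somatic score; the threshold is configurable for
precision/recall trade-off studies.

## The flanking-region feature

VAF alone is informative (heterozygous germline VAF centers on 0.5,
somatic VAF is usually subclonal) but confounded by copy-number
alterations, which shift germline VAFs too. Because copy-number events
are large, a germline variant's VAF should *agree with its neighbours*,
while a somatic variant's should not. For each call we take the nearest
catalogued common SNP called in the same sample within 2 Mbp upstream and
downstream (heterozygous where genotype is known; a call is never its own
flank) and compare 95% Clopper–Pearson intervals of the three VAFs:

* both flanks exist and both intervals overlap the call's: germline-like;
* the call overlaps neither flank while the flanks overlap each other:
  somatic-like;
* anything else, including a missing flank: not applicable.

Interval overlap is closed (`lo1 <= hi2 && lo2 <= hi1`). Per-allele, the
carrier assessments collapse to a weight: germline-like count over
carrier count, not-applicable entries remaining in the denominator; a
weight of all-not-applicable carriers is missing. The exact
(Clopper–Pearson) interval was chosen over asymptotic approximations
because read depths vary widely and exact intervals are reproducible
without continuity-correction choices; they are computed from the beta
quantile representation. "Nearest per side" is used when several
candidates fall in the window — proximity maximizes the chance of a
shared copy-number context.

## The naive Bayes classifier

The default learner is implemented in the package to control
missing-value semantics exactly:

* categorical features: Laplace(+1)-smoothed per-class frequencies over
  the *observed* levels; the dedicated `missing` level is not a category
  but an absence marker, and a missing feature is omitted from the
  likelihood product (never imputed);
* continuous features (`cnt`, `sample_frequency`, `mean_vaf`,
  `flank_weight`): per-class Gaussians with a variance floor of 1e-6 to
  keep degenerate (near-constant) features from dominating; `NA` values
  are omitted from the product;
* posteriors over the two classes sum to one; the somatic posterior is
  the score.

Tree-based learners receive missing differently, mirroring classic
decision-tree toolkits: categorical missing is a dedicated level, and
continuous missing becomes a sentinel value plus a companion indicator
column (the boosted-tree kind routes `NA` natively instead). The random
forest stands behind `tree_ensemble`; a gradient-boosted tree ensemble
(`boosted_tree`) stands in for boosted decision-tree learners of the
LADTree family, which have no maintained R implementation; `logistic` is
a baseline linear model on the one-hot encoding. All four share one
training/prediction interface and one fitted-model class with
`print`/`summary`/`predict` methods, and every source of randomness fans
out from a single run-level seed through named substreams (set sampling,
fold assignment, forest bootstrap), so identical configurations reproduce
identical outputs.

Model comparison uses tenfold cross-validation on balanced training sets
(default 700 somatic + 700 germline per set, sampled without replacement
within a set), stratified fold assignment, metrics on the pooled
out-of-fold predictions of each set, and means with normal-approximation
CIs over sets. The best kind is the highest mean AUC, ties broken by mean
F1, then lexicographically. Feature relevance is measured by information
gain in bits, with continuous features discretized into 10 equal-frequency
bins (quantile cut points, duplicates merged) and missing values forming
their own category.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure that makes the
classification problem solvable, with defaults chosen as a realistic
mid-size exome cohort:

* 50 samples; somatic mutations private per sample, Poisson with mean
  100 — a moderately mutated tumor type;
* a pool of 22,500 common germline alleles recurring across samples at
  beta-distributed population frequencies, plus ~50 private rare germline
  variants per sample, for a collapsed germline:somatic ratio near 5:1 —
  within the 2:1 to 1:10 span seen across public tumor cohorts;
* read depth negative-binomial around 100×; calls require 3
  alt-supporting reads (a caller detection limit);
* germline VAF binomial around 0.5; 20% of the genome per sample lies in
  copy-number segments that shift germline VAF centers coherently to 1/3
  or 2/3, giving the flanking feature true signal to find; no homozygous
  calls by default, matching paired call sets distributed without them;
* somatic VAF beta-distributed with mean 0.25 (subclonality and normal
  admixture), scaled by tumor purity;
* annotation realism: 45% of somatic alleles carry a heavy-tailed
  catalogue count with a small recurrent-driver fraction reaching
  `cnt >= 100`; 2% of germline alleles carry a small spurious count; the
  common-polymorphism set covers 90% of the common pool; membership
  coverages (population exome 95%/25%, rare set 80%) and small
  cross-contaminations exercise the pre-labeling/classifier boundary;
* class-skewed functional impact (germline 42% neutral vs somatic 25%,
  with somatic enrichment in high/medium impact and truncating
  categories) and substitution-pattern enrichment (somatic in CA,
  germline in TC), matching the direction and rough magnitude of the
  skews reported for real cohorts;
* silent (8%) and unknown (2%) annotations to exercise the coding
  filters.

Identical configurations and seeds give byte-identical outputs, including
written files.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium and realistic
SNP spacing; mutational-signature structure in the sequence context
(context is near-uninformative in simulation, whereas real cohorts show
AGA-type enrichments); sequencing artifacts, FFPE damage and mapping
errors in tandem-repeat genes, which dominate real false positives and
must be removed upstream; and caller-specific filtering biases, which in
real cohorts can outweigh biology.

**Purity.** The purity knob scales somatic VAF only, since germline
heterozygous VAF is purity-independent in tumor-only calling. A
consequence worth stating plainly: *lowering* purity widens the gap
between somatic and germline VAF distributions and can improve
classification in this model, the opposite of the practical intuition
that impure samples are harder (which is driven by detection limits and
artifacts the simulator does not model). Separability in this emulation
is therefore degraded along the axes that genuinely carry it — annotation
coverage and the somatic VAF's distance from the 0.5 heterozygous center
(somatic mutations approaching clonality) — and the monotone-degradation
property is tested on those axes.

## Problem sizes and numerical choices in the test suite

The suite exercises the full pipeline at reduced scale, chosen to keep a
complete run fast while leaving the statistical checks well powered:
structural tests use 6-sample cohorts; classifier tests 20-sample
cohorts (~60 somatic/sample); the end-to-end recovery check uses the
default 50-sample cohort with a 25-sample training split and asserts
held-out F1 ≥ 0.90 with FPR ≤ 0.05; the learning-curve check compares 5
vs 50 training samples over five 70-sample cohorts (~40 somatic/sample)
with a fixed 10-sample evaluation split; the label-shuffling null uses 50
balanced sets of 200+200. Exact oracles back the arithmetic: an
independent formula re-implementation for the six measures, an exhaustive
three-interval truth table for the flanking decision, tail-sum bisection
for the Clopper–Pearson bounds (agreement to 1e-9 for all counts up to
n = 200), brute-force pair counting for AUC, and closed-form posteriors
for the naive Bayes.

## Limitations

Accuracy degrades for cohorts with few samples (the sample-frequency and
flanking features need carriers) and for very low mutational loads, where
training somatic alleles are scarce. The classifier's ceiling is the
paired caller that produced its training labels. Only single-base coding
substitutions are in scope: no indels, no non-coding variants. Scores are
naive Bayes posteriors under strong independence assumptions and should
be treated as rankings rather than calibrated probabilities.
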