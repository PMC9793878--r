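---
title: "Methods: cross-cohort microbiome meta-analysis with crossbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort microbiome meta-analysis with crossbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbiome)
```

`crossbiome` implements a complete meta-analysis workflow for multi-cohort
case–control amplicon surveys: data preparation, confounder quantification,
compositional differential abundance, biomarker identification, and
cohort-aware validation of random-forest classifiers. This vignette explains
the statistical choices, the synthetic data model the test suite rests on,
and the limitations of both.

## Data model and preparation

The central object is a genus- (or ASV-) level count table — taxa in rows,
samples in columns, with a semicolon-delimited lineage per taxon — paired
with per-sample metadata (`study`, `group` ∈ {normal, benign, cancer,
cancer_adjacent}, `sample_type` ∈ {tissue, stool}, `age`, `bmi`). Both stay
ordinary tibbles so the whole dplyr vocabulary applies.

Preparation is three deterministic steps, in a fixed order:

1. `filter_taxa()` removes chloroplast and mitochondrial sequences (at any
   rank) and taxa unclassified at kingdom level. Host organelles are
   amplified by universal 16S primers but carry no community information.
2. `drop_unmapped_samples()` removes samples whose counts are all zero after
   the taxonomy filter — the operational reading of "samples that could not
   be mapped": nothing classifiable remained.
3. `aggregate_to_genus()` sums counts over shared genus labels. Taxa with an
   empty genus are dropped by default, because downstream results are
   reported per named genus; `keep_unclassified = TRUE` retains them as
   `unclassified_<family>` bins when their mass matters.

Counts only ever decrease through this pipeline (a property the tests
assert), and `merge_tables()` unions taxa across cohorts with explicit zeros
— a zero in a merged table means "not observed", never "not measured",
which is the correct semantics for presence-aware statistics downstream.

## Compositional and rank transforms

Sequencing depth is arbitrary, so all abundance testing happens on
centered-log-ratio values: `clr(x)_i = log(x_i + c) − mean_j log(x_j + c)`
with pseudocount `c = 0.5` added to **all** counts. A uniform pseudocount
(rather than zero-replacement) keeps within-sample rank order, handles the
heavy zero-inflation of genus tables without special cases, and makes the
transform exactly scale-invariant in the limit `c → 0` on positive counts
(a property the tests verify). The pseudocount is configurable everywhere it
appears. CLR rows sum to zero by construction; note that CLR and genus
aggregation do not commute, so the package always aggregates counts first
and transforms second.

Variance decomposition operates on mid-ranks of the CLR values instead of
the values themselves, because genus abundances are far from Gaussian:
ranks make η² comparable across features with wildly different zero
fractions. Ranks are recomputed over exactly the samples entering each
decomposition (after removing samples missing that confounder), so excluded
samples cannot distort the included ones.

## Confounder analysis

For one feature and one confounder, `decompose_feature()` reports

- `eta2_disease` and `eta2_confounder`: one-way η² of the ranks against each
  factor separately — "variance explained by X alone", the quantity plotted
  on the classic confounder scatter;
- `p_disease`: the disease main-effect p-value from a two-way ANOVA
  (disease + confounder, no interaction) with **Type II** sums of squares.
  Cohort designs are unbalanced by nature, and Type II tests each main
  effect after the other without an interaction term, which matches the
  additive model actually fitted.

Confounders are categorised the conventional way: `study` and `sample_type`
as given, `age` as quartiles computed within the analysed set, `bmi` cut at
25 and 30 (the conventional overweight/obesity thresholds). The bins carry
neutral labels (`under_25`, `25_to_30`, `over_30`) and any clinical naming
is left to presentation code. Missing `age`/`bmi` values exclude a sample
from that decomposition only — several real cohorts lack these fields
entirely, and imputation would manufacture confounder structure.

Degenerate features (constant over the included samples) return η² = 0 and
p = 1; features where either factor collapses to one level are flagged
`degenerate` and excluded from plots rather than silently dropped.

## Community structure

Beta diversity uses Bray–Curtis dissimilarity on raw counts (backed by
`vegan::vegdist`); CLR values can be negative and are not valid Bray–Curtis
input, and a `proportions = TRUE` switch is available when library-size
differences should be removed from the distance. Principal coordinate
analysis double-centers the squared distances and eigendecomposes; negative
eigenvalues (Bray–Curtis is non-Euclidean) are reported but excluded from
the `proportion_explained` denominator, and each axis is oriented so its
first nonzero coordinate is positive, making ordinations reproducible to
the bit. Per-group means and covariances of the first two axes are exported
for confidence-ellipse drawing; the package does not draw ellipses itself.

## Differential abundance and biomarkers

Five comparison strategies are predefined (cancer vs normal and cancer vs
benign in tissue and stool, plus adjacent vs normal in tissue); each runs
Welch's unequal-variance *t* per genus on CLR values. The operative
significance rule is the raw `p < 0.05`, reflecting how such analyses are
conventionally reported; Benjamini–Hochberg q-values are computed and
carried alongside so the reader can apply the stricter rule, but they do not
drive the flag. Degenerate inputs are resolved explicitly rather than left
to error: equal constant groups give `t = 0, p = 1`; separated constant
groups give `t = ±Inf, p = 0` with a degeneracy flag.

Biomarker identification is deliberately stricter than differential
abundance: a genus qualifies only if its two-sided Wilcoxon rank-sum p-value
(cancer vs healthy controls within one sample type) is below 0.05 **and**
its mean CLR is higher in the cancer group — a one-direction rule, since a
depleted genus is a different kind of marker. The exact null distribution is
used when the smaller group has ≤ 25 samples and no ties; otherwise the
normal approximation with tie and continuity corrections. "Higher abundance"
defaults to the mean CLR (pairing with the Welch analysis); the median is
available via `location = "median"`. `overlap_sets()` intersects biomarker
sets across strata — the tissue/gut overlap question.

## Classification and cohort-aware validation

Classifiers are random forests with the conventional defaults (500 trees,
`mtry = √p`), probabilities as the fraction of trees voting positive, and
permutation importance (mean decrease in accuracy, unscaled) as the ranking
criterion. The positive class is `cancer`; `benign` and `normal` pool into
`non-cancer`.

`fit_topk_model()` ranks features by MDA from a single full-data fit, keeps
the top 30, and re-estimates performance by stratified 10-fold CV restricted
to them. The single ranked list is what an importance figure needs, but
selecting on all data before CV is mildly optimistic; the honest alternative
(`per_fold_selection = TRUE`) re-selects inside every training fold and is
used for the nested-CV transfer diagonal. `select_feature_count()` wraps the
recursive-elimination CV error curve (the `rfcv` procedure) for choosing the
feature count, halving the feature set per step by default.

The generalization machinery never lets selection see test data:

- **LOCO** (`loco_validation()`): for each cohort, feature selection and
  training happen in the pooled remaining cohorts; the held-out cohort is
  scored once. The mean over cohorts summarises cross-study transportability.
- **Cohort-to-cohort** (`cohort_to_cohort()`): entry (i, j) trains (and
  selects) inside cohort i alone and scores cohort j. The diagonal uses
  repeated stratified 70/30 splits (default, 10 repeats, selection inside
  each 70%) or nested CV — both appear in practice, so both are modes.
  Cohorts with a single class are flagged `NA`, never 0.

All AUCs are Mann–Whitney: the probability a random positive outranks a
random negative, ties counting half, which equals the trapezoidal area under
the empirical ROC (asserted in tests). Every single evaluation re-derives
its RNG stream from the classifier seed, so matrices are deterministic and
independent of evaluation order, and train/test sample disjointness is
asserted structurally inside every evaluation.

## The synthetic data generator

`generate_cohorts()` emulates the statistical structure the analysis
assumes, not any particular real cohort. Per sample, taxon log-abundances
are

```
base_t + batch_ct + effect_t(group) + N(0, 1)
```

with `base_t ~ N(0, base_log_mean_sd²)` (default 1: taxa span roughly two
orders of magnitude), `batch_ct ~ N(0, batch_sd²)` per cohort × taxon
(default 0.3: a visible but not overwhelming study effect), and
`effect_t = disease_log2fc · log 2` on the planted taxa in cancer samples
(default 1.5 log2 units on 10 of 200 taxa; `cancer_adjacent` samples carry
the same shift by default, reflecting adjacent tissue resembling tumour —
set `adjacent_log2fc = 0` for the opposite scenario). The composition is the
softmax of these log-abundances; counts are multinomial with lognormal
library sizes (default mean 10⁴, log-sd 0.5, i.e. roughly 3× spread).
The unit-variance sample noise supplies overdispersion and, with the
multinomial, heavy zero inflation — a multinomial-on-softmax model was
chosen over a Dirichlet-multinomial because it produces the needed features
with one fewer shape parameter.

Ages are drawn so the correlation with the cancer indicator matches
`confound_age` (default 0.3) by shifting the cancer group's age mean; BMI is
independent of disease. Group labels cover all four clinical groups so every
comparison strategy is exercised. The generator is deterministic given the
spec (seed included) and restores the caller's RNG state.

What the generator does **not** emulate: phylogenetic correlation between
taxa, taxon-specific dispersion, primer or region effects with taxon bias
structure (batch offsets are i.i.d. across taxa), longitudinal structure,
and any real cohort's composition. Passing tests therefore demonstrate that
the machinery is correct and calibrated under a known truth — not that any
particular biological finding transfers to real data.

## Validation suite and problem sizes

The acceptance tests (and `scripts/acceptance.R`) check, at sizes chosen to
finish in minutes on one CPU:

- **Oracle equivalence**: Bray–Curtis, η², Welch's *t*, exact Wilcoxon and
  Mann–Whitney AUC against brute-force enumeration/reference computations on
  instances of n ≤ 12, at tolerance 1e-10.
- **CLR closure**: row sums below 1e-8 over 100 random tables.
- **Null calibration** (200 taxa, 5 cohorts × 60 samples per group, 10
  seeds): Welch rejects 5% ± 2% at p < 0.05; all 50 null LOCO AUCs inside
  [0.35, 0.65] (the null AUC s.d. with 60/60 test cohorts is ≈ 0.053, so the
  band is ≈ 2.8σ); two-way-ANOVA disease p-values approximately uniform
  (Kolmogorov–Smirnov distance < 0.05 over 2000 p-values).
- **Planted recovery** (10 planted of 200, log2FC 1.5, batch_sd 0.3): ≥ 80%
  of planted genera flagged with the correct direction, ≥ 8/10 in the top-30
  importance list, mean LOCO AUC ≥ 0.8.
- **Batch degradation**: mean off-diagonal transfer AUC non-increasing over
  batch_sd ∈ {0, 1, 2} (5 seeds each, 3 cohorts of 30/30, 150 taxa) with a
  substantive total drop.
- **Leakage audit**: overlapping train/test sets are refused outright;
  20 label permutations of a strongly separable dataset give mean
  out-of-fold AUC in [0.45, 0.55].
- **Determinism**: two pipeline runs with the same config and seed produce
  identical artifact MD5 hashes.

## Known limitations

- The top-30 headline model shares the selection-before-CV optimism of the
  convention it follows; use `per_fold_selection = TRUE` when an unbiased
  pooled estimate matters more than a single ranked list.
- Raw p < 0.05 is the replication-faithful significance rule; for discovery
  work, filter on the reported q-values instead.
- η² on ranks saturates below 1 for clean group splits (a two-group split of
  n = 40 mid-ranks tops out at 0.75) — values are comparable across features,
  not absolute fractions of biological variance.
- Bray–Curtis ordination reports, but does not correct for, negative
  eigenvalues; no PERMANOVA or batch correction is included by design.
- The pipeline stratifies tissue and stool after the sample-type confounder
  check; cross-type pooled analyses beyond that check are intentionally
  unsupported.
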