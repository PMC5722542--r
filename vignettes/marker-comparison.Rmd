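---
title: "Single-gene versus multi-gene markers of drug sensitivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-gene versus multi-gene markers of drug sensitivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxmarkers)
```

## The problem

Large pharmacogenomic screens measure the sensitivity (IC50) of molecularly
profiled cancer cell lines to panels of drugs. The classical way to exploit
such data is the *single-gene marker*: a drug–gene association, established by
a significant p-value on the screen, used as a one-feature classifier — a cell
line carrying the actionable mutation is predicted sensitive, a wild-type line
resistant. The alternative is a *multi-gene* machine-learning classifier that
combines all available mutation features. `pgxmarkers` implements a
head-to-head comparison of the two model types under a *time-stamped*
evaluation: models are selected on the cell lines available in an early data
release and assessed only on lines added in a later release, mimicking a blind
prospective test and avoiding the optimism of reusing cross-validation folds
for both model selection and assessment.

## Data model and the GDSC dialect

A `dataset_release` bundles a binary genomic feature matrix (cell lines ×
features; gene alterations, gene fusions and msi status), a long table of
per-(drug, cell line) log10 IC50 values in micromolar, and optional drug
metadata (compound name, cytotoxic/targeted class). Coverage is deliberately
partial: an unmeasured pair is simply absent, never a sentinel.

The reader understands the screen's CSV conventions: each gene cell holds an
`x::y` annotation where `x` is a coding-variant token and `y` a copy-number
token. A gene is *mutated* iff `x` is neither `wt` nor `na` (case-insensitive)
or `y` differs from the wild-type copy-number token (default `0<cna<8`,
matched literally because the numeric encoding of copy-number bins varies
between exports). Fusion columns carry either a not-detected token or the
fusion's identity; unknown tokens count as detected and are logged rather than
silently dropped. Raw exports report the natural log of IC50 in uM;
`convert_ln_to_log10` rescales so that a difference of 1 is one order of
magnitude in concentration. All layout choices (column names, response scale,
token vocabularies) live in a `gdsc_dialect` object instead of being
hard-coded.

## The synthetic cohort generator

Because the analysis is defined over two versioned releases, the package ships
a generator (`generate_cohort`) producing exactly that structure with known
ground truth:

* per-feature mutation prevalences drawn log-uniformly from
  `prevalence_range` (default 0.02–0.3, the span typical of recurrently
  mutated cancer gene panels), then independent Bernoulli mutations;
* per-drug response `logIC50 = baseline + sum of driver effects + noise`,
  with baselines N(0, 1) log10 uM, a planted effect of `effect_size` (default
  −1.0 log10 uM, i.e. a ten-fold sensitisation) per driver, and Gaussian
  noise (`noise_sd`, default 0.5 log10 uM);
* a drug mix of single-driver, multi-driver (default 3 drivers) and null
  drugs in fractions `drug_mix` (default 0.4/0.4/0.2), allocated
  deterministically by largest-remainder rounding so cohort composition is
  reproducible;
* two releases: the defaults mirror the scale of the public GDSC releases —
  638 first-release cell lines plus 70 new ones, 127 drugs, 71 features,
  57.6% / 80.68% drug–cell coverage — with every release-1 measurement
  retained verbatim in release 2;
* a single seeded generator consumed in a documented order (prevalences,
  mutations, baselines, driver assignment, noise, coverage), so a config is
  bit-reproducible.

What the generator does **not** emulate: tissue-of-origin structure,
linkage between mutations, dose–response curve artefacts, and time-dependent
batch effects between releases. Tests passing on synthetic cohorts therefore
demonstrate the pipeline's correctness and its qualitative behaviour
(recall dominance of multi-gene models, overfitting ordering), not
quantitative performance on any real screen.

## Time-stamped partition and labels

For each drug shared by the releases, the training set is every cell line
with a measured response in release 1 and the test set every line measured in
release 2 that is not in the training set — disjoint by construction. Note
this definition admits an "old" cell line into a drug's test set if the drug
was first measured on it in release 2; only lines in that drug's *training
set* are excluded. The sensitivity threshold is the median training logIC50,
computed once and reused unchanged on the test set, which splits training
lines essentially 50/50. Ties at the threshold are labelled resistant: the
sensitive class is defined by *strictly* lower logIC50, and with continuous
responses the choice is immaterial. Cell lines whose feature profile changed
between releases keep their release-1 snapshot for training (they can never
be test points). Drugs with an empty training or test set, or a test set
below `min_test`, are excluded *and reported* with a reason.

## Single-gene markers

Associations are tested per (drug, feature) on training data with a
pooled-variance two-group comparison of logIC50 between mutant and wild-type
lines — with a single response variable this is exactly a two-group one-way
ANOVA. Features with fewer than `min_mutants` (default 3, the smallest count
permitting any within-group variance estimate) mutants are untestable and
carry p = 1. Multiple testing is corrected across the whole drug × feature
family, either Benjamini–Hochberg at a 20% FDR (default) or a fixed cutoff of
0.00840749 retained as a compatibility mode with the screen's published
adjusted threshold (whether that cutoff transfers to a different test is
doubtful, which is why it is only a labelled mode). The best marker per drug
is the lowest p-value, kept even when not significant (the best case for the
single-gene approach); ties break by larger absolute effect, then feature
name. Prediction is mutation-present ⇒ sensitive regardless of the effect
direction — the worked examples of deployed markers are consistent only with
this rule, since resistance-associated markers still show non-zero precision
on mutants — with a direction-aware mode available but off by default. A
marker absent from every test line makes no prediction: MCC and precision are
assigned 0 and the drug stays in the comparison, flagged.

## Multi-gene markers

Per drug, a random-forest classifier on all common features, 1000 trees by
default. The `mtry` control parameter is selected by 10-fold stratified
cross-validation with the same folds reused for every grid value; the default
selection score is mean out-of-fold MCC (maximised), with RMSE of the
sensitive-vote fraction against the 0/1 label available as an alternative —
the two selection criteria coexist because descriptions of this protocol
disagree between sources, and MCC is the coherent default when the entire
evaluation is MCC-based. Ties go to the smallest `mtry`. A fold losing a
class triggers a logged refold with a shifted seed, up to a retry cap. The
final forest is refit on the full training set; a line is predicted sensitive
iff its sensitive-vote fraction strictly exceeds 0.5 (an exact half-half vote
is resistant). Per-drug seeds are derived from the run seed and the drug id,
so results do not depend on drug processing order. Training-set MCC is
recorded: its gap to test MCC quantifies overfitting.

## Evaluation conventions

With sensitive as the positive class, MCC, precision, recall and F1 are
computed from the confusion matrix with these degenerate conventions: any
zero factor in the MCC denominator gives MCC = 0 (0 is the random baseline,
and the same value is assigned when no prediction is possible); precision and
recall are 0 when their denominators vanish; F1(0, 0) = 0. The cohort summary
reports per-metric win counts (strict inequality, ties separate), the 2×2
sign table of test MCC with exact zeros binned as non-positive and counted
separately as ties, means/medians per model and dataset, overfitting gaps,
and two-tailed Spearman correlations of the forest's test MCC with test-set
class imbalance (n_sensitive − n_resistant) and test-set size, flagged
not-computable when ranks degenerate.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(
  n_cell_lines_release1 = 300, n_new_cell_lines_release2 = 150,
  n_drugs = 20, seed = 1))
run <- run_comparison(co$release1, co$release2,
                      forest = forest_config(n_trees = 200,
                                             mtry_grid = c(2, 8, 26)),
                      seed = 1)
run$summary
export_reports(run$summary, run$comparisons, "reports/")
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at 300 training
and 100–150 new cell lines over 30–50 drugs with 100–200-tree forests and an
`mtry` grid of {2, 8, 26}; these sizes give stable cohort-level statistics
(win fractions, mean MCCs) while keeping a full run in minutes on one core.
The full 1000-tree, 71-point-grid protocol is the package default and scales
linearly. Other fixed choices: p-value ties broken by effect size then name;
coverage masks drawn without replacement to the exact rounded pair count;
thresholds and labels recomputed only from training data on every run.

## Limitations

The association test is univariate and assumes equal group variances; it is a
stand-in for screen-specific multivariate association pipelines, so absolute
p-values are not comparable with published screen outputs. Synthetic cohorts
are exchangeable across cell lines — no tissue or batch structure — so the
generator cannot probe robustness to the time-dependent batch effects a real
two-release comparison may contain. Only median-threshold binarisation is
provided, and only classification forests (no regression forests, alternative
learners, or probability calibration).
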