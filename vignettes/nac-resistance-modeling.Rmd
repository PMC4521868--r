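---
title: "Modeling resistance to neoadjuvant chemotherapy from expression screens and IHC marker pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling resistance to neoadjuvant chemotherapy from expression screens and IHC marker pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacstrat)
```

## The problem

Muscle-invasive bladder cancer (MIBC) treated with neoadjuvant
gemcitabine/cisplatin chemotherapy (NAC) before cystectomy splits sharply by
outcome: responders (`R`, no residual muscle-invasive tumor, <ypT2) have far
better cancer-specific survival than resistant patients (`NR`, >=ypT2).
Because only about half of patients respond, a pre-treatment predictor of
resistance — built from biopsy material with tools a pathology lab already
has — is clinically valuable: resistant patients could move directly to
cystectomy or to an alternative regimen.

`nacstrat` implements that modeling pathway end to end:

1. an **expression screen** that reduces a discovery microarray cohort
   (genes x samples with R/NR labels) to a small signature of robustly
   changed genes, with permutation-based multiple-testing control;
2. **signature clustering** of samples on the screened genes into
   response-graded groups;
3. **marker-pair selection** over binary immunohistochemistry (IHC) calls by
   two-round adaptive boosting, with repeated cross-validation to measure
   how stable the selection is;
4. **classification-tree stratification** combining clinical factors (age,
   clinical T stage) and the selected markers into ordered risk strata;
5. **ordinal statistics** to evaluate the models (Goodman-Kruskal gamma,
   Fisher's exact test, Cohen's kappa, Kruskal-Wallis, multivariable
   logistic regression);
6. a **synthetic-data generator** producing discovery matrices and
   validation cohorts with known ground truth, so every stage is testable
   without any external download.

## The expression screen

The screen runs three gates in sequence, mirroring the funnel a discovery
analysis applies to tens of thousands of probes.

**Signal-window filter.** A gene passes when its mean MAS 5.0-style signal
is below 300 in one response group and above 500 in the other, in either
direction. The window demands an absolute change large enough to survive
translation to a protein-level assay, and shrinking the candidate set before
testing also limits overfitting. Both thresholds are configurable
(`screen_config(low_threshold =, high_threshold =)`); the filter is
symmetric in direction because either direction of change is biologically
admissible.

**Per-gene AUC and groupwise p-value.** Discrimination is measured by the
area under the ROC curve of "higher signal implies NR", computed from
midranks, so `gene_auc` equals the Mann-Whitney U statistic scaled by
`n_R * n_NR`. The groupwise test is the two-sided Mann-Whitney test (exact
for small untied samples, normal approximation with continuity correction
otherwise), chosen because it shares the U statistic with the AUC ranking —
the two gates then order genes consistently. A Welch t-test is available via
`screen_config(test = "welch")` for users who prefer a parametric gate.
Default p cutoff: 0.005.

**Permutation FDR.** Multiple testing is controlled by label permutation
(default 200 draws, seeded). The permutation score is `|AUC - 0.5|`, which
is symmetric in direction and monotone in the evidence. For a gene with
observed score *s*, the FDR estimate is the plug-in tail-count ratio

> mean over permutations of #{null scores >= s} / #{observed scores >= s},

monotone-corrected by a running minimum from the most extreme score down, so
estimates never increase with the score, and capped at 1. The estimate is
computed over the filter survivors only: the filter is part of the screen's
definition, and the null distribution should describe the genes actually
tested. Permutations are drawn uniformly without enforcing distinctness —
200 draws are negligible against the permutation space of a 33-sample label
vector. Genes are selected when they pass all three gates; AUC-ranking ties
break by smaller p-value, then gene id (locale-independent ordering).

Under a global null the fraction of genes with p < 0.005 sits inside the
binomial band around 0.005 (the Mann-Whitney p is discrete, hence slightly
conservative), and planted genes with group means 200 vs 700 at CV 0.2 are
recovered essentially always; the test suite asserts both, at 500 genes x 33
samples with 200 permutations and 50 generator seeds — sizes chosen to
exercise the screen at the discovery cohort's scale.

## Signature clustering

`cluster_samples` uses the conventional expression-heatmap recipe: per-gene
standardization, distance = 1 - Pearson correlation between samples,
average-linkage agglomeration, tree cut at `k`. Neither the metric nor the
linkage is canonical for this kind of figure, so both are configurable; the
defaults are what most published heatmaps of this type use. Group labels
are assigned by observed NR rate, not dendrogram order — `A` for the most
chemo-responsive group, `B` for the most resistant, intermediates `C`,
`D`, ... in ascending rate between them — so the letters mean the same thing
on every run. Constant gene rows are dropped with a warning (their
correlation is undefined); an all-constant selection is an error rather
than a silent degenerate tree.

## Marker-pair selection by two-round boosting

IHC calls are binary: positive means more than 10% of tumor cells at at
least moderate (2 of 0-3) staining intensity (`binarize_ihc`). The base
learner is a one-marker decision stump with an orientation: "positive
implies NR" or "positive implies R", whichever errs less.

Round 1 weighs all samples equally, so the stump error reduces to a
univariate association test; the minimizing marker is selected. Its clipped
error e1 sets the standard boosting vote a1 = log((1 - e1)/e1)/2, samples it
misclassified are up-weighted by exp(a1), weights renormalize, and round 2
selects the distinct marker minimizing the reweighted error. The update is
textbook AdaBoost with decision stumps; any strictly monotone up-weighting
of misclassified samples would produce the same round-2 argmin whenever the
candidate errors are well separated, so the specific update matters only in
near-ties. The clip (`epsilon_clip`, default 1e-6) keeps a perfect stump
from producing an infinite vote. Ties break by smaller round-1 error, then
marker name, making the selection invariant to column order.

**Stability.** `stability_cv` refits the selection on every training fold of
`n_repeats` x `n_folds` stratified partitions (default 100 x 10) and reports
the fraction of fits whose unordered pair equals the full-data pair. Folds
are stratified by response because a 37-patient cohort with ~57% NR easily
produces single-class folds otherwise. The denominator is every fold-level
fit. Note an interpretive caveat: training folds share ~90% of their
patients with the full data, so even uninformative markers yield stability
well above the naive 1/choose(m, 2) chance level; stability is evidence of
robustness, not a calibrated p-value.

## Classification-tree stratification

Three models map each patient to an ordered risk stratum:

- **Clinical**: count of risk factors {age > 60 years, clinical stage >
  cT2}; 0 = low, 1 = intermediate, 2 = high (`clinical_stratify`). Both
  cutoffs are configurable (`tree_config`).
- **IHC**: a tree over GDPD3 and SPRED1 positivity (`ihc_model`).
- **Combined**: a tree over {clinical low risk (age <= 60 and cT <= 2),
  GDPD3 positive, SPRED1 positive}, merged to two strata
  (`combine_models`).

With at most three binary predicates, the whole space of depth-<=2 binary
trees is tiny, so `fit_tree` searches it exhaustively and minimizes total
Gini impurity over leaves; no greedy induction, no pruning. The criterion
barely matters under exhaustive search but resolves ties deterministically:
equal-impurity trees prefer fewer nodes (so vacuous splits are dropped),
then the lexicographically smallest predicate sequence under a
locale-independent ordering. Leaves merge into the requested number of
strata by ascending NR rate — among contiguous groupings in rate order, the
one minimizing the merged weighted Gini — and the fitted topology is part of
the returned model, so it can be inspected rather than trusted. Tree
structures are plain data (no closures): a fitted model serializes to JSON
and applies to any cohort carrying the same fields, and `apply_model`
recomputes stratum sizes and NR rates on the new cohort. Missing predictor
values exclude a patient from that model only, and the exclusion count is
reported. By construction, the n-weighted mean of stratum NR rates equals
the cohort NR rate over complete cases; the suite asserts this conservation
for every model on every cohort it touches.

## Evaluation statistics

- **Goodman-Kruskal gamma** is computed from concordant/discordant pair
  counts via the cross-table (O(rc) cells). The default p-value is the
  asymptotic z = gamma * sqrt((C + D)/(n(1 - gamma^2))); because the method
  behind the published gammas is not stated and n = 37 is small, an exact
  label-permutation p (`p_method = "permutation"`) is provided and
  recommended at that scale. C + D = 0 yields an explicit undefined flag,
  not an exception; |gamma| = 1 yields p = 0 under the asymptotic formula's
  limit.
- **Fisher's exact test** uses the probability-ordering two-sided rule (sum
  over tables no more probable than observed), the convention of mainstream
  statistical software; zero-margin tables are degenerate with p = 1.
- **Cohen's kappa** uses marginal-product expected agreement; two constant,
  identical raters are a degenerate kappa of 1 (flagged).
- **Kruskal-Wallis** is the tie-corrected rank H test; all-tied input
  returns p = 1.
- **Logistic regression** is plain maximum likelihood with Wald p-values.
  Separation is detected from degenerate fitted probabilities or runaway
  coefficients; when flagged, coefficients are suppressed because the MLE
  does not exist. No penalization is applied — none is implied by the
  modeling tradition this follows — so separation is surfaced rather than
  hidden.

## The synthetic-data generator

The generator defines the study conditions the package is tested under.

`simulate_discovery` emulates a 33-sample discovery microarray: log-normal
signals (the conventional positive-support noise model for MAS 5.0-style
units) with coefficient of variation 0.2 by default, baseline gene means
log-uniform over 30-3000, planted genes with group means 200 vs 700 in a
random direction per gene, and a balanced response split (the discovery
cohort's response distribution is described as clearly bimodal; absent a
printed split, balance is the neutral choice).

`simulate_cohort` emulates a 37-patient validation cohort: response is
Bernoulli(21/37) — the resistant fraction implied by the reconstructed
combined-model counts — markers are conditionally Bernoulli given response
(defaults: GDPD3 P(+|R) = 0.8, P(+|NR) = 0.15; SPRED1 mirrored; six
companion markers response-independent with varied base rates), ages are
normal around 60 (R) / 65 (NR) years truncated to 40-85, and stage is drawn
per response class to give roughly the 60/35/5 cT2/cT3/cT4 mix reported for
such cohorts.

`fixture_cohort` is a deterministic 37-row cohort engineered so the
combined model stratifies it exactly into the reconstructed halves: 19
low-risk patients with 5 resistant (26%) and 18 high-risk with 16 resistant
(89%), Fisher p = 0.0002 at printed precision. Within each stratum the three
combined-model predicates are constant (clinically low risk, GDPD3+,
SPRED1- versus the complement), which pins the fitted tree's partition
regardless of tie-breaking. It is a synthetic stand-in constrained only to
those margins — not a reconstruction of any real patient-level table — and
its per-patient ages, stages, and companion-marker calls are arbitrary
within the stratum constraints.

What the generator does **not** emulate: probe-level correlation structure
and batch effects in the expression data; correlation between markers
beyond what response induces; inter-pathologist scoring disagreement;
survival endpoints. Passing tests therefore demonstrate that the algorithms
do what they claim under their stated generative assumptions, not that the
biological signature generalizes.

## Reproducibility and numerical choices

Every stochastic operation takes an explicit integer seed through its
config or spec object and is a pure function of (inputs, config, seed); the
suite asserts bit-reproducibility for the permutation FDR, the generators,
and the cross-validation. All ordering tie-breaks use radix (C-locale)
string comparison so results do not depend on the session locale.
`result_bundle`/`write_results` attach input paths, the config, its hash,
and the seed to every exported result.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_discovery(discovery_spec(n_genes = 1000, n_planted = 15,
                                        seed = 1))
scr <- screen_targets(sim$matrix, screen_config(seed = 2))
scr            # 15 selected at FDR < 10%

fx <- fixture_cohort()
sel <- select_pair_adaboost(fx)
sel            # GDPD3 (positive -> R) + SPRED1

cm <- combine_models(fx)
ap <- apply_model(cm, fx)
ap$strata      # low: n 19, NR 26%; high: n 18, NR 89%
fisher_exact_2x2(cbind(ap$strata$n - ap$strata$n_NR, ap$strata$n_NR))
```

## Known limitations

- The discovery screen cannot be checked against the original 21-gene
  signature (the underlying raw microarray cohort has no public accession),
  so screen guarantees are stated against synthetic ground truth only.
- Verifying the published cohort-level statistics (IHC gamma 0.85, clinical
  tiers 27/62/77%, combined 26%/89%) requires the de-identified cohort
  export, which is not redistributable with the package; the corresponding
  acceptance test documents the expected values and runs when the export is
  supplied.
- Trees are limited to binary predicates at depth <= 2 — the regime the
  exhaustive search is designed for; continuous splits and deeper trees are
  out of scope.
- The boosting selector returns exactly one pair; selecting more markers
  would require different stability machinery and is deliberately not
  offered.
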