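---
title: "Rank-based miRNA-pair models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based miRNA-pair models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

## The problem and the model

Circulating miRNA profiles are attractive diagnostic material for chronic
obstructive pulmonary disease (COPD), but absolute abundance values do not
transfer across measurement platforms: microarray intensities, sequencing
counts and qPCR cycle thresholds (Ct) live on different, nonlinearly related
scales, and a cutoff fitted on one platform is meaningless on another.
`mirpair` therefore discards absolute values entirely and works with
**within-sample orderings**. For an ordered pair of miRNAs (A, B) the pair
score in a sample is

$$s_{AB} = \begin{cases} 0 & \text{if } x_A < x_B \\ 1 & \text{otherwise,}\end{cases}$$

with $x$ on the expression scale. On the Ct scale the comparison is
inverted ($s_{AB} = 0$ iff $Ct_A > Ct_B$), because a lower cycle threshold
means a more abundant transcript. Since any admissible platform distortion
is strictly increasing in true abundance, the pair score — and everything
computed from it — is invariant to the platform. That is the package's core
contract, asserted in the test suite as bit-identity of pair matrices under
log-affine, affine and monotone-spline transforms, in either scale
orientation.

Ties score 1 ("otherwise" covers equality). This makes the tie case
orientation-dependent, so pairs are always enumerated in a fixed canonical
orientation (lexicographically smaller name first) before scoring.

## Pipeline

1. **Harmonize and intersect** (`read_cohort()`, `harmonize_names()`,
   `intersect_features()`): per-cohort matrices are renamed via a
   user-supplied alias table and restricted to the common feature set in
   sorted order. Name collisions are an error, never silently averaged —
   probe merging is a curation decision.
2. **Preprocess** (`impute_missing()`, `filter_low_abundance()`): missing
   entries denote below-detection measurements and are replaced by the
   cohort-wide minimum (maximum for Ct cohorts, where undetected = highest
   cycle). Features whose values sit at that sentinel in strictly more than
   70% of the healthy group *or* of the COPD group are removed; such
   features carry no ordering information where they are pinned. The
   sentinel is the global matrix extreme, not a per-feature one, and
   equality is tested to 1e-12 relative tolerance so that CSV round-trips
   do not change decisions.
3. **Pair transform and merge** (`build_pair_matrix()`,
   `merge_pair_matrices()`): all $n(n-1)/2$ unordered pairs are scored;
   cohorts become directly comparable after this step and are concatenated
   over their shared pairs. A zero-variance pair drop exists
   (`drop_zero_variance_pairs()`) but is off by default: enumeration is the
   contract, variance filtering an explicit opt-in.
4. **Feature selection** (`run_consensus()`): four selectors run
   independently — an ROC filter (direction-corrected AUC strictly above
   0.7), information gain (top 20), greedy MRMR (MID scheme, top 20) and a
   Boruta shadow-feature procedure — and the **key pairs** are the pairs
   selected by all four.
5. **Modeling** (`stratified_split()`, `train_classifier()`,
   `evaluate_classifier()`): a stratified 70/30 split (per-class training
   count `floor(0.7 * n)`, which reproduces the canonical 121/52 partition
   of a 63 + 110 cohort with 19 + 33 test samples), grid search scored by
   mean 10-fold CV AUC on the training partition only, refit of the winner,
   and a single evaluation of the held-out 30%: confusion counts,
   sensitivity, specificity, PPV, NPV, accuracy, and AUC with a DeLong 95%
   CI. Both the CV estimate and the held-out estimate are reported and
   labelled; they answer different questions and are never mixed.
6. **Single-patient prediction** (`predict_patient()`): raw expression or
   Ct values are converted to the fitted model's pair schema and scored;
   predictions are therefore invariant to any strictly increasing transform
   of the patient's measurements.

## Selector details and defaults

* **ROC filter.** For a binary feature the tie-aware rank AUC reduces to
  $(TPR + TNR)/2$. The filter ranks by the direction-corrected value
  $\max(\mathrm{AUC}, 1-\mathrm{AUC})$ so an informative pair is not lost to
  its arbitrary canonical orientation; the raw AUC is kept in the report.
  The 0.7 cutoff is strict.
* **Information gain.** $IG = H(Y) - H(Y\,|\,X)$ in bits. The logarithm
  base cancels in rankings but is fixed (base 2) so reported scores are
  reproducible. Top-k ties break by canonical pair order.
* **MRMR.** The MID (difference) scheme: pick
  $\arg\max_X I(X;Y) - \frac{1}{|S|}\sum_{Z \in S} I(X;Z)$ greedily. The
  difference form is well-defined at zero redundancy, which the quotient
  form is not.
* **Boruta.** Each iteration fits a random forest on the not-yet-rejected
  features plus independently permuted shadow copies of each; a feature
  scores a hit when its importance beats the best shadow. Hits are tested
  against Binomial(iterations, 0.5), two-sided, Bonferroni-corrected over
  the initial feature count at $\alpha = 0.05$. Tentative features at
  termination are reported but never selected.

The Boruta importance estimator deserves a note, because it is where naive
settings fail. With large forests and in-sample (impurity) importance, a
feature that is correlated with the labels *by chance in this sample* beats
freshly permuted shadows in almost every iteration and ends up confirmed:
on label-shuffled null data (n = 100, 20 binary features) roughly two
thirds of runs confirmed at least one spurious feature. The package instead
uses out-of-bag permutation importance scaled by its standard error, from
deliberately small forests (`max(30, p/8)` trees), with at least three
shadow copies per feature and at least ~120 shadows in total (small feature
spaces get extra copies so the shadow maximum is a stable reference). The
per-iteration noise of that estimator is the point: a
merely chance-correlated feature cannot beat the maximum of many noisy
shadows consistently, so the binomial test rejects it, while a genuinely
predictive feature wins every round regardless of forest size. Under these
defaults the same null experiment confirms nothing in ≥95% of runs and a
perfectly predictive pair is confirmed essentially always. The consensus
driver `run_consensus()` caps Boruta at 50 iterations; `boruta_select()`
itself defaults to 100.

## The seven classifiers

k-nearest neighbours (`class`), radial-kernel SVM (`e1071`), random forest
(`randomForest`), naive Bayes (`e1071`), decision tree (`rpart`), gradient
boosted trees (`xgboost`) and elastic-net logistic regression (`glmnet`)
round out the roster of seven. Each ships a small default grid
(`default_grid()`); grids are user-replaceable data frames. Grid ties break
to the first-listed row, and all stochastic steps are seeded. For the SVM,
class probabilities come from the decision value through a logistic link
rather than Platt scaling, whose sigmoid fit is unstable (and can even
invert orientation) on the small or separable folds that arise in 10-fold
tuning on ~100 samples. The boosted-tree model plays the role of the
headline model in the package's own experiments. The positive class is
COPD throughout and class assignment uses the 0.5 probability threshold.

## The synthetic two-platform generator

`generate_latent()` draws log-normal baseline abundances (per-feature
log-mean uniform on [4, 10], unit log-sd) and plants disease signal as
**rank reversals**: for each planted pair (A, B) a healthy sample shows
A < B and a COPD sample A > B, each with probability `1 - p_flip`, enforced
by swapping the two values within the sample. The two members of a planted
pair share their baseline log-mean; otherwise the swap would shift the
members' class-conditional marginal means, turning an ordering signal into
a mean-shift signal and leaking information into pairs that merely contain
one planted member. With the shared mean, swapping exchangeable values
leaves marginals untouched and the planted pair's direction-corrected AUC
has the closed form $1 - p_{\mathrm{flip}}$ (TPR = TNR = $1-p$). A separate
`n_shifted`/`shift` option adds classical mean shifts for testing the
expression-level baseline.

`render_platform()` then imitates a measurement platform: a strictly
increasing transform (log-affine, affine, or a random monotone spline),
additive technical noise, Ct-orientation negation where requested, and
detection-limit censoring of the least abundant fraction of measurements
(low values on the expression scale, high cycle numbers on the Ct scale),
which downstream imputation resolves to the sentinel.
`simulate_two_platform_study()` splits one latent cohort into two disjoint
sample sets rendered on a microarray-like and a qPCR-like platform — the
structure of a two-cohort cross-platform study.

What the generator does *not* emulate: realistic miRNA abundance
distributions fitted to real data, probe-level artifacts, correlated
technical error, or batch structure within a platform. Passing tests
demonstrate the pipeline's statistical behaviour under its own assumptions,
not clinical performance on real cohorts.

## The expression-level baseline

`differential_expression()` is the comparator the pair method argues
against: per-feature Welch t-tests on the cohort's working scale (assumed
log2-like; Ct cohorts are negated first), with logFC as the mean
difference, BH-adjusted p-values reported, and flagging on raw p (< 0.05)
plus, in stringent mode, |logFC| > 1.5. Zero-variance features with equal
means get p = 1 by convention. The suite's contrast test renders one latent
state on two platforms and shows the DE flag sets differ while pair-based
selections are identical — the instability that motivates the rank
representation.

## Numerical and interface choices

* Pair identifiers are `"A|B"` strings; a trained model stores its ordered
  schema and refuses inputs that do not cover it (exit code 3 in the CLI).
* Ct input to `predict_patient()` inverts comparisons by default
  (`ct_invert = FALSE` opts out), matching the qPCR semantics above; this
  is the single most consequential convention and is surfaced in the
  function documentation.
* All entropies are computed from empirical frequencies with the
  `0 log 0 = 0` convention; MRMR ties, top-k ties and AUC-rank ties all
  break by canonical pair order for determinism.
* The DeLong CI is truncated to [0, 1]; constant score vectors yield AUC
  0.5 with a flagged degenerate CI rather than an error.

## Problem sizes in the test suite

The end-to-end experiments run at n = 60 + 60 samples, 40 features (780
pairs), 5 planted pairs at `p_flip` = 0.1, with 50 seeds for the recovery
and null-calibration experiments, 50 seeds for the Boruta calibration
study (n = 100, 20 pairs), and 25 seeds for the boosted-tree power
experiment. These sizes keep every Monte-Carlo estimate's sampling error
well below the margins asserted while the full suite completes in minutes.

## Known limitations

* The pair transform discards all magnitude information; diseases that
  shift many miRNAs coherently without reordering them are invisible to it.
* Tie handling (score 1) is asymmetric by construction; on
  heavily-discretized data with many exact ties, canonical orientation
  matters and is therefore fixed package-wide.
* Boruta's all-relevant semantics confirm any feature genuinely correlated
  with the labels *in the given sample*; with small cohorts that can
  include lucky noise. The four-way consensus, not Boruta alone, is the
  selection contract.
* The alias table for name harmonization is user-supplied; the package
  does not derive mappings between miRBase releases.
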