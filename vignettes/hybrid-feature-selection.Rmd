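---
title: "Hybrid feature selection for FOI hand readings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid feature selection for FOI hand readings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foiselect)
```

## The problem

Fluorescence optical imaging (FOI) of the hands produces, per patient, three
phase-summed images of indocyanine-green dynamics. A reader annotates each
phase image with findings from a 20-acronym catalogue (joint signals D, P, M,
C, O; finger signals r, R; nail signals a, I; the venous signal V; connective
tissue signals E, B, Y; skin signals F, W; and the newer codes H, S, T, U, Z),
separately for the left and right hand. Encoding each acronym per phase gives
60 binary feature-phase indicators such as `P2` per patient, plus a diagnosis
label (here rheumatoid arthritis, osteoarthritis, or connective tissue
disease). The analysis question is which small subset of these indicators
suffices for each pairwise (One-vs-One) and one-against-the-rest (One-vs-Rest)
differential diagnosis, and in what order of importance.

`foiselect` implements a two-step hybrid answer:

1. **Filter and rank.** Four importance estimates are computed per binary
   problem — the phi coefficient of each feature with the diagnosis,
   MultiSURF relief weights, and mean-decrease-impurity (MDI) and
   mean-decrease-AUC (MDA) from a gradient-boosted tree ensemble trained on
   all features under repeated cross-validation. Each metric yields a ranked
   *candidate list* containing the features that pass its inclusion
   criterion (phi: two-sided significance p < 0.05; the others: score > 0).
2. **Wrap.** Sequential forward selection: each step evaluates at most four
   candidates (the best-ranked not-yet-selected feature from each list,
   deduplicated) by mean CV AUC of a gradient-boosted model on the
   already-selected features plus the candidate; the best candidate is
   added; losers stay eligible. The loop runs until every list feature has
   been included, and a *transition point* is determined afterwards: the
   smallest step whose mean CV AUC is never later exceeded by more than a
   tolerance (default 0.01) and whose immediate successor is not better.
   Because one feature enters per step, the transition index equals the
   number of features needed for (near-)maximal performance.

Combining a univariate filter, a multivariate relief filter, and two
embedded tree measures guards against the blind spots of any single method:
phi cannot see interactions, relief sees 2- and 3-way interactions but not
model-conditional usefulness, and the embedded measures reflect one specific
fitted ensemble.

## Data model and preprocessing

A *reading table* holds one row per (patient, hand, phase) with the set of
annotated acronyms. Preprocessing follows the clinical logic that the
diagnosis does not depend on which hand is affected:

- `fuse_hands()` takes the per-phase union across hands;
- `encode_features()` produces the 60-column binary matrix;
- `filter_feature_table()` removes featureless patients first, then
  never-observed (all-zero) feature columns;
- `build_problems()` derives all k(k−1)/2 OvO and k OvR binary problems.
  Columns constant within a problem's training rows (for instance a feature
  never present in either of the two diagnoses being contrasted) are
  excluded per problem and recorded in its spec;
- `split_holdout()` sets aside a 10% holdout before any selection. The
  split is stratified by class — the protocol only says "random", but an
  unstratified 10% draw at these class sizes can lose a class from the
  holdout, so stratification is the default and the per-problem alternative
  is a configuration switch (`split_mode = "per_problem"`);
- `oversample()` balances classes by duplicating uniformly drawn minority
  rows. During CV this happens *inside each training fold only*: duplicating
  before the fold split would place copies of the same patient on both
  sides of the fold boundary and inflate validation AUC. The label-permuted
  null test in the suite is the canary for this placement.

## The metrics

**Phi coefficient.** Pearson correlation of two 0/1 encodings, computed from
the 2×2 table, with a two-sided t-test (`t = r sqrt((n−2)/(1−r²))`,
n−2 degrees of freedom). Candidate ranking uses |r|: the sign says which
diagnosis the feature points to, not how informative it is. The same
statistic powers the pairwise collinearity matrix; variance inflation
factors come from a least-squares regression of each feature column on all
others (`VIF = 1/(1−R²)`), with perfectly collinear columns reported as
infinite and flagged rather than failing the run.

**MultiSURF.** Deterministic relief weighting in which every instance is a
target. Distance is the mean per-feature absolute difference (the Hamming
fraction for binary features, which is the standard discrete diff). For a
target, neighbours nearer than `T − D` are "near", where `T` is the mean
distance to all other instances and `D` half their standard deviation (a
dead-band that suppresses borderline neighbours). Near misses with a
differing feature value push that feature's weight up; near hits push it
down; contributions are normalised per target by its near-hit and near-miss
counts and by the number of instances, which keeps the weights stable under
class imbalance. Two conventions the algorithm family leaves open are fixed
here and recorded in the output (`neighbor_definition`): the sample standard
deviation is used for the dead-band, and the threshold comparison is strict
(`<`). Targets with no near neighbours contribute nothing and are counted.

**MDI and MDA.** The ensemble engine is xgboost (binary logistic objective,
single-threaded for determinism). MDI is each feature's total split-gain
share, read from the ensemble dump and normalised to sum to one — the
tree-native impurity-decrease measure; features never split on score 0.
MDA permutes one validation column at a time (default 10 permutations) and
records the drop in validation AUC from baseline. Both are averaged over
the `folds × repeats` CV models; MDA is evaluated on each model's own
validation fold, never on training rows.

**AUC.** Rank-based (normalised Mann–Whitney U, ties counted ½), so it is
invariant under monotone transforms of the scores and equals the
probability that a random positive outscores a random negative.

## Cross-validation, tuning, and the selection loop

The study protocol's CV sizes are 3 folds × 10 repeats (30 models) for
step 1 and 5 folds × 20 repeats (100 models) for step 2; both are the
package defaults (`run_config()`). Folds are stratified. Hyperparameters
(tree count, depth, learning rate; default grid 3×3×2) are tuned by grid
search on the all-features model of step 1 and reused during stepping — the
protocol states that tuning occurred but not at which granularity, so
per-step re-tuning is available (`tune = "per_step"`) but is not the
default, mainly because its cost grows with grid × candidates × steps.

Two details of the selection loop deserve justification:

- **Candidate deduplication.** When several lists nominate the same
  feature, the step evaluates it once; lists do not substitute their
  next-ranked feature. This mirrors the worked protocol example in which a
  step has three candidates because two metrics agree, and keeps the
  maximum at four.
- **Per-step fold re-drawing.** Folds are shared across the candidates
  within a step (so candidates are compared on identical splits) but
  re-drawn between steps, deterministically from the step index. If one
  fixed set of folds were reused for the entire selection, every step would
  retain the candidate that happens to look best *on those folds*, and the
  retained luck compounds: the mean CV AUC curve creeps upward for several
  steps after the real signal is exhausted, dragging the transition point
  late. Re-drawing folds per step removes the compounding while preserving
  within-step fairness.

Ties between candidates (mean AUC within 1e−9) go to the earlier list in
the fixed order phi, multisurf, MDI, MDA, then to the lexicographically
smaller feature name — deterministic and documented, since the protocol is
silent on ties.

The transition rule is taken non-strictly on its second condition: step m
is the transition point if no later step exceeds `AUC_m + tol` *and*
`AUC_{m+1} ≤ AUC_m`. On the sequence 0.60, 0.70, 0.75, 0.755, 0.752, 0.751
with tol = 0.01 this yields step 4: step 3 fails the second condition
because its successor is higher. One consequence worth knowing: the rule's
resolution is bounded by the CV noise of the step means. When the standard
error of a step mean approaches the tolerance (e.g. at 9 CV splits on a
400-patient problem it is ≈0.01), the transition index inherits that noise;
the 100-model step-2 protocol keeps the SE well below the tolerance.

## The synthetic cohort generator

No reading data are distributed, so `generate_cohort()` produces cohorts
with the statistical structure the pipeline assumes, and the test-suite
works entirely on them:

- **Planted univariate effects**: a feature-phase gets a class-conditional
  Bernoulli prevalence. `expected_univariate_auc()` gives the analytic
  single-feature AUC (e.g. prevalences 0.8 vs 0.2 → 0.80) used by the
  recovery tests.
- **Planted interactions**: 2- or 3-feature XOR parity with balanced
  marginals — each involved feature is individually independent of the
  class (expected phi 0) while the parity follows a class-conditional law.
  This is the canonical structure a relief filter can see and a univariate
  filter cannot.
- **Inter-phase correlation** by copy-with-flip links: the child
  feature-phase copies its parent with probability φ and is redrawn at the
  parent's prevalence otherwise, which makes the population phi between
  parent and child exactly φ. Links are expressed parent→child (e.g.
  D1→D2 at 0.73, P2→P3 at 0.70 in the default configuration) because the
  two reference pairs differ in which phase is the base, and the closed
  form stays exact even when the parent carries a planted effect.
- **Never-observed features** (forced all-zero columns) and **featureless
  patients**. The default study-shaped configuration (`foi_config()`)
  designates exactly 2 RA and 2 OA patients featureless, matching the
  reference cohort's exclusions, rather than drawing a Binomial count; all
  other patients are guaranteed at least one annotation by redrawing
  all-zero draws. Featureless-ness is thereby a controlled property of the
  configuration, and the retained-patient count is deterministic.
- **Per-hand assignment**: each annotated feature lands on the left hand,
  right hand, or both with equal probability, so hand fusion is exercised
  non-trivially.

Everything is driven by one integer seed; the same seed reproduces the
cohort bit for bit.

Default effect strengths in `foi_config()` (five moderate class-specific
prevalence effects on Y1, P2, M3, I1, C3, one XOR pair B3/F2, background
prevalence 0.08) are conventions: per-feature disease prevalences are not
published, so these were chosen once to give a few clearly informative
features over a noise floor, in line with the observation that only a few
features carry high importance. What the generator does *not* emulate:
reader disagreement and annotation noise, correlations between different
acronyms (only between phases of one acronym), hand-specific disease
patterns, and any image-level structure. Passing recovery tests therefore
show that the pipeline finds planted structure of the kinds above — not
that the clinical feature lists themselves are reproduced.

## Problem sizes used by the tests and the acceptance script

The suite and `scripts/acceptance.R` scale the protocol down so a run
completes on a desk machine: cohorts of 120–609 patients, candidate-list
CV at 3×3 to 3×10, selection CV at 3×5 to 5×5, singleton or two-point
grids, and 3–5 MDA permutations. The acceptance script runs the full
pipeline stage by stage on the 609-patient study-shaped cohort and reports
the structural counts (60 encoded columns, 605 retained patients, 15
dropped columns, 6 problems, 30 and 100 CV models at the two protocol CV
settings), the measured inter-phase correlations and maximum VIF, and the
RA-vs-OA selection outcome (transition feature count, mean CV AUC and
holdout AUC at the transition), plus a label-permutation null AUC.

## Known limitations

- The transition rule's resolution is bounded by CV noise, as discussed;
  with few CV models it can land a few steps after the true signal
  plateau.
- Greedy one-at-a-time selection can add pure-interaction partners late:
  an XOR member adds nothing until its partner is present, so pairs enter
  only when list pressure keeps nominating them. The tests assert the
  weaker, reliable property: relief ranks such pairs above noise and they
  are selected before noise exhausts.
- MDI is the engine's split-gain share; like all impurity importances it
  splits credit between correlated features (the duplicated-feature test
  asserts exactly this conservation).
- With fewer than three classes the OvR decomposition collapses into the
  single OvO problem and is skipped.
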