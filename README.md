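# foiselect

Hybrid feature selection and differential-diagnosis modelling for binary
fluorescence-optical-imaging (FOI) feature readings of the hands.

FOI visualises inflammation-induced microcirculation changes after an
indocyanine-green injection; a reader annotates 20 image-feature acronyms in
each of three contrast phases, yielding 60 binary feature-phase indicators
(e.g. `P2` = proximal interphalangeal joint signal in phase 2) per patient,
plus a diagnosis such as rheumatoid arthritis (RA), osteoarthritis (OA), or
connective tissue disease (CTD). The scientific question: which small,
ordered subset of indicators suffices for each One-vs-One and One-vs-Rest
differential diagnosis?

`foiselect` answers it in two steps, per binary problem:

1. **Filter & rank** — four importance estimates, each yielding a ranked
   *candidate list* of features passing its inclusion criterion:
   - phi coefficient *r*<sub>φ</sub> (Pearson correlation of 0/1 encodings)
     with a two-sided *t*-test, kept if *p* < 0.05, ranked by |*r*<sub>φ</sub>|;
   - MultiSURF relief weights *W* (adaptive per-instance distance threshold
     with dead-band; detects univariate plus 2-/3-way interaction effects),
     kept if *W* > 0;
   - mean decrease impurity *I*<sub>I</sub> (split-gain share) and mean
     decrease AUC *I*<sub>A</sub> (permutation importance) from a
     gradient-boosted tree ensemble trained on all features under
     stratified repeated CV with grid-search tuning, kept if > 0.
2. **Wrap** — sequential forward selection: each step evaluates at most
   four candidates (the best-ranked not-yet-selected feature from each
   list, deduplicated) by mean CV AUC of a gradient-boosted model on
   selected ∪ {candidate}; the winner is added, losers stay eligible, and
   the loop runs until every list feature has entered. The *transition
   point* — the smallest step never later beaten by more than a tolerance
   (default 0.01) and not beaten by its immediate successor — gives the
   number of features needed for near-maximal performance.

Class imbalance is handled by random minority oversampling *inside each CV
training fold* (never in validation or test data); a 10% stratified holdout
is set aside before any selection. A collinearity screen (pairwise phi
matrix, variance inflation factors) accompanies step 1.

Because no clinical reading data are distributed, the package includes a
fully seeded synthetic cohort generator (`generate_cohort()`) with planted
class-specific prevalences, XOR-parity interactions that are univariately
invisible, exact inter-phase correlations, never-observed features, and
featureless patients — the entire test-suite runs against it. See the
vignette `vignettes/hybrid-feature-selection.Rmd` for the methods account.

## Worked example

```r
library(foiselect)

cfg      <- foi_config(seed = 7)                    # study-shaped synthetic cohort
readings <- generate_cohort(cfg)                    # per-hand, per-phase reading table
filt     <- filter_feature_table(encode_features(fuse_hands(readings)))
filt$table
#> feature_table: 605 patients x 45 features; classes: CTD=141, OA=229, RA=235

sp <- split_holdout(filt$table, 0.9, seed = 8)      # stratified 90/10 split
pr <- build_problems(sp$train, holdout = sp$test)[["RA-vs-OA"]]
pr
#> problem_data RA-vs-OA: 418 obs (212 positive) x 45 features; holdout 46 obs

grid <- data.frame(nrounds = 40L, max_depth = 3L, eta = 0.3)
cl <- build_candidate_lists(pr, cv_config(3, 3, seed = 1), grid, permutations = 5)
cl
#> candidate_lists:
#>   phi       (p < 0.05, ranked by |r_phi|): 7 feature(s) — top: M3, Y1, P3, P2, C3
#>   multisurf (W > 0): 7 feature(s) — top: Y1, M3, P3, C3, P2
#>   mdi       (I_I > 0): 45 feature(s) — top: M3, Y1, P3, C3, B3
#>   mda       (mean I_A > 0): 14 feature(s) — top: Y1, M3, P3, C3, F2

tr <- forward_select(pr, cl, cv_config(3, 5, seed = 2), grid)
tr$transition_index
#> [1] 5
head(tr$summary, 6)
#>   step winner mean_cv_auc sd_cv_auc holdout_auc post_transition
#> 1    1     Y1       0.702    0.0326       0.761           FALSE
#> 2    2     M3       0.789    0.0322       0.781           FALSE
#> 3    3     P3       0.821    0.0238       0.848           FALSE
#> 4    4     C3       0.844    0.0261       0.850           FALSE
#> 5    5     P2       0.847    0.0270       0.850           FALSE
#> 6    6     F2       0.846    0.0232       0.849            TRUE
```

Reading: the cohort's planted RA/OA-discriminating features (the generator
plants class-specific prevalences on Y1, P2, M3, C3 among others) are
recovered in the first steps; the mean CV AUC rises steeply, plateaus near
0.85, and the transition rule stops the useful list at 5 features. Columns:
per-step winner, mean and sd of the CV AUC distribution, and the AUC of a
per-step final model on the untouched holdout.

The whole workflow (all six problems, reports, manifest) is one call:

```r
run <- run_pipeline(foi_config(seed = 7), run_config(seed = 7), "runs/demo")
render_reports("runs/demo")
```

or from the shell via the thin wrapper `inst/scripts/foi-pipeline.R`.

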