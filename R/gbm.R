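# Gradient-boosted tree engine: rank-based AUC, stratified repeated CV with
# grid-search hyperparameter tuning and in-fold oversampling, final-model
# fitting, split-gain (MDI) and permutation (MDA) importance.

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic with ties counted one half: the probability that a randomly
#' chosen positive instance outscores a randomly chosen negative one.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 labels, both values present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both label values must be present",
                               call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validation configuration
#'
#' The study protocol uses 3-fold CV repeated 10 times (30 models) for the
#' step-1 importance estimates and 5-fold CV repeated 20 times (100 models)
#' for step-2 forward selection; `folds * repeats` models are fitted.
#' Folds are stratified by class, and random minority oversampling is applied
#' inside each training fold only (never to validation data), so duplicated
#' minority rows cannot leak across the fold boundary.
#'
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeats (>= 1).
#' @param seed Integer seed for fold assignment and in-fold oversampling.
#' @param oversample Apply in-fold minority oversampling (default TRUE).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 3L, repeats = 10L, seed = 1L,
                      oversample = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), oversample = isTRUE(oversample)),
            class = "cv_config")
}

#' Default hyperparameter grid
#'
#' Tree count x maximum depth x learning rate (3 x 3 x 2 = 18 settings), a
#' documented convention for binary feature tables of this size.
#'
#' @return data.frame with columns `nrounds`, `max_depth`, `eta`.
#' @export
default_grid <- function() {
  expand.grid(nrounds = c(30L, 60L, 120L), max_depth = c(2L, 3L, 4L),
              eta = c(0.1, 0.3), KEEP.OUT.ATTRS = FALSE)
}

# fit one xgboost model; deterministic for fixed data and parameters
fit_gbm <- function(x, y, hp) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, nthread = 1),
    data = dtrain, nrounds = hp$nrounds, verbose = 0)
}

score_gbm <- function(model, x) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
}

# stratified fold assignment: within each class, shuffled indices dealt
# round-robin over folds
stratified_folds <- function(y, folds) {
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds) {
      stop("class with fewer observations than folds", call. = FALSE)
    }
    fold_of[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

# run repeated stratified CV for one hyperparameter setting; returns the
# per-split AUC vector and (optionally) per-model importance accumulators
run_cv <- function(x, y, cv, hp, collect = FALSE, permutations = 10L) {
  set.seed(cv$seed)
  aucs <- numeric(0)
  mdi_acc <- NULL
  mda_acc <- NULL
  n_models <- 0L
  for (rep_i in seq_len(cv$repeats)) {
    fold_of <- stratified_folds(y, cv$folds)
    for (f in seq_len(cv$folds)) {
      tr <- fold_of != f
      xtr <- x[tr, , drop = FALSE]
      ytr <- y[tr]
      if (cv$oversample) {
        os <- oversample_xy(xtr, ytr)
        xtr <- os$x
        ytr <- os$y
      }
      model <- fit_gbm(xtr, ytr, hp)
      xval <- x[!tr, , drop = FALSE]
      yval <- y[!tr]
      sc <- score_gbm(model, xval)
      aucs <- c(aucs, auc(sc, yval))
      if (collect) {
        n_models <- n_models + 1L
        fm <- structure(list(model = model, features = colnames(x)),
                        class = "fitted_gbm")
        ii <- mdi(fm)$I_I
        ia <- mda(fm, list(x = xval, y = yval),
                  permutations = permutations)$I_A
        mdi_acc <- if (is.null(mdi_acc)) ii else mdi_acc + ii
        mda_acc <- if (is.null(mda_acc)) ia else mda_acc + ia
      }
    }
  }
  out <- list(aucs = aucs)
  if (collect) {
    out$mean_mdi <- mdi_acc / n_models
    out$mean_mda <- mda_acc / n_models
  }
  out
}

# in-fold oversampling on raw matrices; uses the current RNG stream
oversample_xy <- function(x, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == n0) return(list(x = x, y = y))
  minority <- which(y == (if (n1 < n0) 1L else 0L))
  extra <- minority[sample.int(length(minority), abs(n1 - n0),
                               replace = TRUE)]
  list(x = rbind(x, x[extra, , drop = FALSE]), y = c(y, y[extra]))
}

#' Repeated cross-validated evaluation with grid search
#'
#' Runs stratified repeated CV for every hyperparameter setting in the grid,
#' with minority oversampling applied inside each training fold only, and
#' selects the setting with the highest mean validation AUC. The per-split
#' AUCs of the winning setting are reported. With a singleton grid this is
#' plain repeated CV.
#'
#' @param problem A `problem_data` (or list with `x`, `y`).
#' @param features Character vector of feature columns to use (non-empty).
#' @param cv A [cv_config()].
#' @param grid data.frame of hyperparameter settings (see [default_grid()]).
#' @return List of class `cv_result` with `auc_per_split`, `mean_auc`,
#'   `sd_auc`, `best_hyperparameters`, `grid_mean_auc`.
#' @export
cv_evaluate <- function(problem, features, cv, grid = default_grid()) {
  stopifnot(length(features) >= 1, inherits(cv, "cv_config"))
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("hyperparameter grid is empty", call. = FALSE)
  }
  miss <- setdiff(features, colnames(problem$x))
  if (length(miss)) {
    stop("feature(s) not in problem: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- problem$x[, features, drop = FALSE]
  y <- problem$y
  grid_means <- numeric(nrow(grid))
  per_split <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    res <- run_cv(x, y, cv, grid[g, ])
    per_split[[g]] <- res$aucs
    grid_means[g] <- mean(res$aucs)
  }
  best <- which.max(grid_means)
  aucs <- per_split[[best]]
  structure(list(auc_per_split = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs),
                 best_hyperparameters = as.list(grid[best, ]),
                 grid_mean_auc = cbind(grid, mean_auc = grid_means)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d splits, mean AUC %.4f (sd %.4f); best: %s\n",
              length(x$auc_per_split), x$mean_auc, x$sd_auc,
              paste(names(x$best_hyperparameters),
                    unlist(x$best_hyperparameters),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fit the final model on the full training data
#'
#' Trains one gradient-boosted tree model with the chosen hyperparameters on
#' all training rows (minority-oversampled by default, mirroring the
#' training-set protocol); the untouched holdout is scored with it.
#'
#' @param problem A `problem_data`.
#' @param features Feature subset to use.
#' @param hyperparameters Named list with `nrounds`, `max_depth`, `eta`.
#' @param seed Integer seed (drives the oversampling draw).
#' @param oversample Balance classes before fitting (default TRUE).
#' @return Object of class `fitted_gbm` with elements `model`, `features`,
#'   and `score(newx)` behaviour via [predict.fitted_gbm()].
#' @export
fit_final <- function(problem, features, hyperparameters, seed = 1L,
                      oversample = TRUE) {
  stopifnot(all(c("nrounds", "max_depth", "eta") %in% names(hyperparameters)))
  x <- problem$x[, features, drop = FALSE]
  y <- problem$y
  set.seed(seed)
  if (oversample) {
    os <- oversample_xy(x, y)
    x <- os$x
    y <- os$y
  }
  structure(list(model = fit_gbm(x, y, hyperparameters),
                 features = features,
                 hyperparameters = hyperparameters),
            class = "fitted_gbm")
}

#' @export
#' @rdname fit_final
#' @param object A `fitted_gbm`.
#' @param newdata Matrix containing at least the model's feature columns.
#' @param ... Unused.
predict.fitted_gbm <- function(object, newdata, ...) {
  score_gbm(object$model, newdata[, object$features, drop = FALSE])
}

#' Mean decrease impurity (split-gain importance)
#'
#' Per feature, the total loss reduction contributed by all splits on that
#' feature across the ensemble, normalised to sum to one — the tree-native
#' impurity-decrease importance. Features never split on score exactly 0.
#'
#' @param model A `fitted_gbm`.
#' @return List of class `importance_scores` with `I_I` (named, >= 0).
#' @export
mdi <- function(model) {
  stopifnot(inherits(model, "fitted_gbm"))
  ii <- setNames(numeric(length(model$features)), model$features)
  dump <- xgboost::xgb.dump(model$model, with_stats = TRUE)
  splits <- grep("gain=", dump, fixed = TRUE, value = TRUE)
  if (length(splits)) {
    feat <- sub("^.*\\[([^<]+)<.*$", "\\1", splits)
    gain <- as.numeric(sub("^.*gain=([-0-9.eE+]+),.*$", "\\1", splits))
    if (!all(feat %in% model$features) && all(grepl("^f[0-9]+$", feat))) {
      feat <- model$features[as.integer(sub("^f", "", feat)) + 1L]
    }
    agg <- tapply(gain, feat, sum)
    ii[names(agg)] <- pmax(agg, 0)
    total <- sum(ii)
    if (total > 0) ii <- ii / total
  }
  structure(list(I_I = ii), class = "importance_scores")
}

#' Mean decrease AUC (permutation importance)
#'
#' `I_A(f)` = baseline validation AUC minus the mean AUC over random
#' permutations of column `f` within the validation data, other columns
#' untouched. May be negative for harmful or unused features.
#'
#' @param model A `fitted_gbm`.
#' @param validation List with `x` (matrix containing the model features) and
#'   binary `y`.
#' @param permutations Number of permutations per feature (default 10).
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used (so CV-level callers control the stream).
#' @return List of class `importance_scores` with `I_A` (named) and
#'   `baseline_auc`.
#' @export
mda <- function(model, validation, permutations = 10L, seed = NULL) {
  stopifnot(inherits(model, "fitted_gbm"), permutations >= 1)
  if (!is.null(seed)) set.seed(seed)
  xv <- validation$x[, model$features, drop = FALSE]
  yv <- validation$y
  base_scores <- score_gbm(model$model, xv)
  baseline <- auc(base_scores, yv)
  ia <- setNames(numeric(length(model$features)), model$features)
  n <- nrow(xv)
  for (f in model$features) {
    drop_sum <- 0
    for (k in seq_len(permutations)) {
      xp <- xv
      xp[, f] <- xv[sample.int(n), f]
      drop_sum <- drop_sum + auc(score_gbm(model$model, xp), yv)
    }
    ia[f] <- baseline - drop_sum / permutations
  }
  structure(list(I_A = ia, baseline_auc = baseline),
            class = "importance_scores")
}

#' Cross-validated importance scores
#'
#' Runs stratified repeated CV at fixed hyperparameters and averages MDI over
#' the fitted models and MDA over their validation folds — the step-1
#' embedded importance estimates.
#'
#' @param problem A `problem_data`.
#' @param features Feature subset (default: all problem features).
#' @param cv A [cv_config()].
#' @param hyperparameters Named list with `nrounds`, `max_depth`, `eta`.
#' @param permutations MDA permutations per feature per model.
#' @return List of class `cv_importance` with `I_I`, `I_A` (named means over
#'   models), and `auc_per_split`.
#' @export
cv_importance <- function(problem, features = colnames(problem$x), cv,
                          hyperparameters, permutations = 10L) {
  x <- problem$x[, features, drop = FALSE]
  res <- run_cv(x, problem$y, cv, hyperparameters, collect = TRUE,
                permutations = permutations)
  structure(list(I_I = res$mean_mdi, I_A = res$mean_mda,
                 auc_per_split = res$aucs),
            class = "cv_importance")
}
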