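# Step 1: per-metric candidate-list construction. Step 2: multi-list
# sequential forward selection with transition-point determination.

METRIC_ORDER <- c("phi", "multisurf", "mdi", "mda")

#' Build the four per-metric candidate lists
#'
#' Step-1 filtering and ranking. Four importance estimates are computed on
#' the training data: the phi coefficient of each feature with the
#' diagnosis, MultiSURF relief weights, and the two embedded measures (MDI
#' and MDA) from a gradient-boosted ensemble trained on *all* features under
#' repeated CV. The candidate lists keep features meeting the inclusion
#' criteria — phi: significant association (p < 0.05), ranked by `|r_phi|`
#' descending; MultiSURF: `W > 0` ranked by `W`; MDI: `I_I > 0` ranked by
#' `I_I`; MDA: mean `I_A > 0` ranked by `I_A`. A list may be empty (with a
#' message); all four empty is an error since nothing would be selectable.
#'
#' @param problem A `problem_data` of training observations.
#' @param cv A [cv_config()] (protocol: 3 folds x 10 repeats).
#' @param grid Hyperparameter grid for tuning the all-features ensemble.
#' @param permutations MDA permutations per feature per CV model.
#' @param alpha Phi significance level (default 0.05).
#' @return Object of class `candidate_lists`: per-metric `rankings`
#'   (data.frames with `feature`, `score`), the `criterion` applied, the
#'   tuned `best_hyperparameters`, and the all-features `cv_result`.
#' @export
build_candidate_lists <- function(problem, cv, grid = default_grid(),
                                  permutations = 10L, alpha = 0.05) {
  x <- problem$x
  y <- problem$y
  feats <- colnames(x)

  # phi filter (constant columns within this data get no p-value, excluded)
  phi_rows <- lapply(feats, function(f) {
    if (length(unique(x[, f])) < 2) return(NULL)
    res <- phi_coefficient(x[, f], y)
    data.frame(feature = f, score = res$r_phi, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  phi_df <- do.call(rbind, phi_rows)
  phi_keep <- phi_df[!is.na(phi_df$p_value) & phi_df$p_value < alpha, ,
                     drop = FALSE]
  phi_keep <- phi_keep[order(-abs(phi_keep$score)), , drop = FALSE]

  # relief filter
  w <- multisurf(problem)$W
  ms <- data.frame(feature = names(w), score = unname(w),
                   stringsAsFactors = FALSE)
  ms <- ms[ms$score > 0, , drop = FALSE]
  ms <- ms[order(-ms$score), , drop = FALSE]

  # embedded metrics from the all-features tuned ensemble
  tuned <- cv_evaluate(problem, feats, cv, grid)
  imp <- cv_importance(problem, feats, cv,
                       tuned$best_hyperparameters, permutations)
  mk <- function(v) {
    d <- data.frame(feature = names(v), score = unname(v),
                    stringsAsFactors = FALSE)
    d <- d[d$score > 0, , drop = FALSE]
    d[order(-d$score), , drop = FALSE]
  }
  rankings <- list(
    phi = phi_keep[, c("feature", "score")],
    multisurf = ms,
    mdi = mk(imp$I_I),
    mda = mk(imp$I_A)
  )
  rankings <- lapply(rankings, function(d) {
    rownames(d) <- NULL
    d
  })
  empty <- names(rankings)[vapply(rankings, nrow, 0L) == 0L]
  if (length(empty) == length(rankings)) {
    stop("all four candidate lists are empty: nothing selectable",
         call. = FALSE)
  }
  if (length(empty)) {
    message("empty candidate list(s): ", paste(empty, collapse = ", "))
  }
  structure(list(
    rankings = rankings,
    criterion = c(phi = sprintf("p < %g, ranked by |r_phi|", alpha),
                  multisurf = "W > 0", mdi = "I_I > 0",
                  mda = "mean I_A > 0"),
    best_hyperparameters = tuned$best_hyperparameters,
    all_features_cv = tuned),
    class = "candidate_lists")
}

#' @export
print.candidate_lists <- function(x, ...) {
  cat("candidate_lists:\n")
  for (m in names(x$rankings)) {
    d <- x$rankings[[m]]
    cat(sprintf("  %-9s (%s): %d feature(s)%s\n", m, x$criterion[[m]],
                nrow(d),
                if (nrow(d)) paste0(" — top: ",
                                    paste(utils::head(d$feature, 5),
                                          collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Multi-list sequential forward selection
#'
#' Step 2. Starting from an empty model, each step's candidate set is the
#' best-ranked not-yet-selected feature from each of the four candidate
#' lists (deduplicated — at most four distinct candidates). Each candidate
#' is evaluated by repeated-CV AUC of a gradient-boosted model on the
#' already-selected features plus the candidate; the candidate with the
#' highest mean CV AUC is added. Losing candidates stay eligible in later
#' steps. The loop runs until the union of all list features is exhausted
#' (no early stop), so no potentially performance-increasing feature is
#' missed; the transition point is determined afterwards. CV folds are
#' re-drawn at every step (deterministically from the config seed) but
#' shared across the candidates within a step, so candidates are compared
#' on identical splits while fold-specific luck cannot accumulate over the
#' course of the selection. Ties within 1e-9
#' go to the candidate supplied by the earlier list in the fixed order phi,
#' multisurf, mdi, mda, then to the lexicographically smaller name.
#'
#' @param problem A `problem_data` of training observations (its `holdout`,
#'   when present, is scored with a per-step final model).
#' @param lists A `candidate_lists`.
#' @param cv A [cv_config()] (protocol: 5 folds x 20 repeats).
#' @param grid Hyperparameter grid; used per step when
#'   `tune = "per_step"`.
#' @param tune `"once"` (default): reuse the hyperparameters tuned on the
#'   all-features model during list construction; `"per_step"`: re-run the
#'   grid search at every candidate evaluation.
#' @param tolerance Transition-point tolerance on mean CV AUC (default 0.01).
#' @param final_seed Seed for per-step final-model oversampling.
#' @return Object of class `selection_trace`: `steps` (list of per-step
#'   records), `summary` (data.frame: step, winner, mean/sd CV AUC, holdout
#'   AUC), `transition_index`, `tolerance`.
#' @export
forward_select <- function(problem, lists, cv, grid = default_grid(),
                           tune = c("once", "per_step"), tolerance = 0.01,
                           final_seed = 1L) {
  tune <- match.arg(tune)
  stopifnot(inherits(lists, "candidate_lists"))
  rankings <- lists$rankings[METRIC_ORDER]
  pool <- unique(unlist(lapply(rankings, function(d) d$feature)))
  if (!length(pool)) stop("no candidate features", call. = FALSE)
  hp <- lists$best_hyperparameters
  selected <- character(0)
  steps <- list()
  while (length(selected) < length(pool)) {
    # fresh folds per step (shared across the step's candidates): candidates
    # are compared fairly within a step, while fold-specific luck retained by
    # earlier winners cannot compound across steps into a creeping optimism
    # of the selection curve
    cv_step <- cv_config(cv$folds, cv$repeats,
                         seed = stage_seed(cv$seed, 131L * length(selected)),
                         oversample = cv$oversample)
    cand <- character(0)
    cand_metric <- character(0)
    for (m in METRIC_ORDER) {
      remaining <- setdiff(rankings[[m]]$feature, selected)
      if (length(remaining) && !(remaining[1] %in% cand)) {
        cand <- c(cand, remaining[1])
        cand_metric <- c(cand_metric, m)
      }
    }
    evals <- vector("list", length(cand))
    for (k in seq_along(cand)) {
      feats_k <- c(selected, cand[k])
      evals[[k]] <- if (tune == "per_step") {
        cv_evaluate(problem, feats_k, cv_step, grid)
      } else {
        cv_evaluate(problem, feats_k, cv_step,
                    as.data.frame(hp, stringsAsFactors = FALSE))
      }
    }
    means <- vapply(evals, `[[`, 0, "mean_auc")
    best_mean <- max(means)
    contenders <- which(means >= best_mean - 1e-9)
    if (length(contenders) > 1) {
      nm <- cand[contenders]
      contenders <- contenders[order(match(cand_metric[contenders],
                                           METRIC_ORDER), nm)]
    }
    win <- contenders[1]
    selected <- c(selected, cand[win])
    step_hp <- evals[[win]]$best_hyperparameters
    holdout_auc <- NA_real_
    if (!is.null(problem$holdout)) {
      fm <- fit_final(problem, selected, step_hp, seed = final_seed)
      holdout_auc <- auc(predict(fm, problem$holdout$x),
                         problem$holdout$y)
    }
    steps[[length(steps) + 1L]] <- list(
      step_index = length(steps) + 1L,
      candidates_evaluated = data.frame(
        feature = cand, metric = cand_metric, mean_auc = means,
        sd_auc = vapply(evals, `[[`, 0, "sd_auc"),
        stringsAsFactors = FALSE),
      winner = cand[win],
      cv_result = evals[[win]],
      cumulative_features = selected,
      holdout_auc = holdout_auc)
  }
  means <- vapply(steps, function(s) s$cv_result$mean_auc, 0)
  trace <- structure(list(
    steps = steps,
    summary = data.frame(
      step = seq_along(steps),
      winner = vapply(steps, `[[`, "", "winner"),
      mean_cv_auc = means,
      sd_cv_auc = vapply(steps, function(s) s$cv_result$sd_auc, 0),
      holdout_auc = vapply(steps, `[[`, 0, "holdout_auc"),
      stringsAsFactors = FALSE),
    tolerance = tolerance),
    class = "selection_trace")
  trace$transition_index <- transition_point(trace, tolerance)
  trace$summary$post_transition <-
    trace$summary$step > trace$transition_index
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("selection_trace:", nrow(x$summary), "steps; transition at step",
      x$transition_index, sprintf("(tolerance %g)\n", x$tolerance))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Transition point of a forward-selection trace
#'
#' The smallest step index m such that (a) no later step's mean CV AUC
#' exceeds `AUC_m + tolerance`, and (b) the immediately succeeding model is
#' not better (`AUC_{m+1} <= AUC_m`, non-strict; vacuous at the last step).
#' Since each step adds exactly one feature, the returned index equals the
#' number of features in the transition-point model.
#'
#' @param trace A `selection_trace`, or a numeric vector of per-step mean CV
#'   AUCs.
#' @param tolerance Tolerance on later improvement (default 0.01).
#' @return Integer step index (= feature count at the transition point).
#' @export
transition_point <- function(trace, tolerance = 0.01) {
  means <- if (inherits(trace, "selection_trace")) {
    vapply(trace$steps, function(s) s$cv_result$mean_auc, 0)
  } else {
    as.numeric(trace)
  }
  n <- length(means)
  stopifnot(n >= 1)
  for (m in seq_len(n)) {
    later_ok <- m == n || max(means[(m + 1):n]) <= means[m] + tolerance
    next_ok <- m == n || means[m + 1] <= means[m]
    if (later_ok && next_ok) return(m)
  }
  n
}
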