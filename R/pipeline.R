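# End-to-end pipeline: fuse -> encode -> filter -> split -> collinearity ->
# candidate lists -> forward selection -> transition point, per problem, with
# all artifacts written under a run directory and a manifest for exact
# reruns.

#' Run configuration
#'
#' Defaults reproduce the study protocol constants: 90/10 train/holdout
#' split, 3-fold x 10-repeat CV for step 1, 5-fold x 20-repeat CV for step
#' 2, transition tolerance 0.01, and at most four candidates per selection
#' step (a structural property of the four candidate lists).
#'
#' @param holdout_fraction Training fraction of the split (default 0.9).
#' @param cv_step1,cv_step2 [cv_config()]s for candidate-list construction
#'   and forward selection.
#' @param grid Hyperparameter grid.
#' @param tolerance Transition tolerance (default 0.01).
#' @param seed Root integer seed; stage seeds (synthesis, split,
#'   oversampling, folds, permutations) are derived from it as fixed-offset
#'   substreams so each stage is independently reproducible.
#' @param problems Optional character vector restricting which problems are
#'   analysed (e.g. `"RA-vs-OA"`).
#' @param split_mode `"shared"` (default): one stratified split of the
#'   multi-class table so all problems share the same holdout patients;
#'   `"per_problem"`: split each binary problem separately.
#' @param tune Hyperparameter handling during selection (see
#'   [forward_select()]).
#' @param mda_permutations MDA permutations per feature per CV model.
#' @return Object of class `run_config`.
#' @export
run_config <- function(holdout_fraction = 0.9,
                       cv_step1 = NULL, cv_step2 = NULL,
                       grid = default_grid(), tolerance = 0.01,
                       seed = 1L, problems = NULL,
                       split_mode = c("shared", "per_problem"),
                       tune = c("once", "per_step"),
                       mda_permutations = 10L) {
  split_mode <- match.arg(split_mode)
  tune <- match.arg(tune)
  seed <- as.integer(seed)
  if (is.null(cv_step1)) cv_step1 <- cv_config(3L, 10L,
                                               seed = stage_seed(seed, 3L))
  if (is.null(cv_step2)) cv_step2 <- cv_config(5L, 20L,
                                               seed = stage_seed(seed, 4L))
  structure(list(holdout_fraction = holdout_fraction, cv_step1 = cv_step1,
                 cv_step2 = cv_step2, grid = grid, tolerance = tolerance,
                 seed = seed, problems = problems, split_mode = split_mode,
                 tune = tune, mda_permutations = as.integer(mda_permutations)),
            class = "run_config")
}

# fixed-offset substream seeds below 2^31
stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 10007 + offset * 97) %% 2147483647)
}

#' Run the full pipeline
#'
#' Executes the whole workflow on a reading table (or a synthetic
#' configuration, which is generated first) and writes all artifacts under
#' `out_dir`: the drop report, the collinearity screen, and per-problem
#' candidate lists and selection traces, plus a manifest recording the seed,
#' configuration hash and package version. A rerun with the same inputs and
#' seed reproduces every artifact.
#'
#' @param input A `reading_table`, a `synthetic_config`, or a path to a
#'   reading-table CSV.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`table`, `drops`,
#'   `collinearity`, `problems`, per-problem `lists` and `traces`).
#' @export
run_pipeline <- function(input, config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- list(stage = name, message = conditionMessage(e))
      if (!missing(out_dir)) {
        jsonlite::write_json(err, file.path(out_dir, "error.json"),
                             auto_unbox = TRUE)
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  readings <- stage("input", {
    if (inherits(input, "synthetic_config")) generate_cohort(input)
    else if (inherits(input, "reading_table")) input
    else read_reading_table(input)
  })
  fused <- stage("fuse", fuse_hands(readings))
  encoded <- stage("encode", encode_features(fused))
  filt <- stage("filter", filter_feature_table(encoded))
  jsonlite::write_json(
    list(dropped_features = filt$dropped_features,
         dropped_patients = filt$dropped_patients,
         n_retained = nrow(filt$table$x)),
    file.path(out_dir, "drops.json"), auto_unbox = FALSE, pretty = TRUE)

  coll <- stage("collinearity", collinearity(filt$table))
  write_collinearity(coll, out_dir)

  split <- NULL
  problems <- stage("problems", {
    if (config$split_mode == "shared") {
      split <- split_holdout(filt$table, config$holdout_fraction,
                             seed = stage_seed(config$seed, 1L))
      build_problems(split$train, holdout = split$test)
    } else {
      pr <- build_problems(filt$table)
      lapply(pr, function(p) {
        sp <- split_holdout(p, config$holdout_fraction,
                            seed = stage_seed(config$seed, 1L))
        problem_data(sp$train$x, sp$train$y, p$spec,
                     holdout = list(x = sp$test$x, y = sp$test$y))
      })
    }
  })
  if (!is.null(config$problems)) {
    unknown <- setdiff(config$problems, names(problems))
    if (length(unknown)) {
      stop("unknown problem(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    problems <- problems[config$problems]
  }

  lists <- list()
  traces <- list()
  for (pn in names(problems)) {
    pdir <- file.path(out_dir, pn)
    dir.create(pdir, showWarnings = FALSE)
    message("problem ", pn, ": candidate lists")
    lists[[pn]] <- stage(paste0(pn, "/candidate_lists"),
                         build_candidate_lists(problems[[pn]],
                                               config$cv_step1, config$grid,
                                               config$mda_permutations))
    write_candidate_lists(lists[[pn]], pdir)
    message("problem ", pn, ": forward selection")
    traces[[pn]] <- stage(paste0(pn, "/forward_select"),
                          forward_select(problems[[pn]], lists[[pn]],
                                         config$cv_step2, config$grid,
                                         tune = config$tune,
                                         tolerance = config$tolerance,
                                         final_seed = stage_seed(config$seed,
                                                                 2L)))
    write_trace(traces[[pn]], pdir)
  }

  manifest <- list(
    package = "foiselect",
    version = as.character(utils::packageVersion("foiselect")),
    seed = config$seed,
    config = config_fingerprint(config),
    problems = names(problems),
    n_patients = nrow(filt$table$x),
    n_features = ncol(filt$table$x))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = filt$table, drops = filt[c("dropped_features",
                                                    "dropped_patients")],
                 collinearity = coll, problems = problems, lists = lists,
                 traces = traces, manifest = manifest))
}

# flat, deterministic description of a run_config for the manifest
config_fingerprint <- function(config) {
  list(holdout_fraction = config$holdout_fraction,
       cv_step1 = unclass(config$cv_step1),
       cv_step2 = unclass(config$cv_step2),
       grid = as.list(config$grid), tolerance = config$tolerance,
       split_mode = config$split_mode, tune = config$tune,
       mda_permutations = config$mda_permutations)
}

write_collinearity <- function(coll, out_dir) {
  utils::write.table(coll$phi_matrix,
                     file.path(out_dir, "phi_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(coll$p_value_matrix,
                     file.path(out_dir, "phi_p_values.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(max_vif = max(coll$vif[is.finite(coll$vif)]),
         max_vif_feature = names(which.max(
           replace(coll$vif, !is.finite(coll$vif), -Inf))),
         flagged_infinite_vif = coll$flagged,
         high_pairs = coll$high_pairs,
         report_threshold = coll$report_threshold),
    file.path(out_dir, "collinearity.json"), auto_unbox = TRUE,
    pretty = TRUE)
}

write_candidate_lists <- function(lists, pdir) {
  for (m in names(lists$rankings)) {
    utils::write.table(lists$rankings[[m]],
                       file.path(pdir, paste0("candidates_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(rankings = lists$rankings, criterion = as.list(lists$criterion),
         best_hyperparameters = lists$best_hyperparameters),
    file.path(pdir, "candidate_lists.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
}

write_trace <- function(trace, pdir) {
  utils::write.table(trace$summary, file.path(pdir, "selection_steps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = trace$summary,
         transition_index = trace$transition_index,
         tolerance = trace$tolerance,
         auc_per_split = lapply(trace$steps,
                                function(s) s$cv_result$auc_per_split)),
    file.path(pdir, "selection_trace.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  splits <- do.call(rbind, lapply(trace$steps, function(s) {
    data.frame(step = s$step_index, winner = s$winner,
               auc = s$cv_result$auc_per_split, stringsAsFactors = FALSE)
  }))
  utils::write.table(splits, file.path(pdir, "cv_auc_per_split.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Render human-readable summary reports for a completed run
#'
#' Reads the artifacts under a run directory and writes (and returns) the
#' cross-problem summaries: a per-problem ordered feature-importance table
#' (winners up to the transition point), the per-step performance table with
#' the transition marker, and the collinearity summary.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return List with `importance_lists`, `step_table`, `collinearity`
#'   data.frames (also written as TSV under `run_dir`).
#' @export
render_reports <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing artifact: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  rows <- list()
  steps <- list()
  for (pn in manifest$problems) {
    tp <- file.path(run_dir, pn, "selection_trace.json")
    cl <- file.path(run_dir, pn, "candidate_lists.json")
    if (!file.exists(tp) || !file.exists(cl)) {
      stop("missing artifact for problem ", pn, ": ",
           if (!file.exists(tp)) tp else cl, call. = FALSE)
    }
    trace <- jsonlite::read_json(tp, simplifyVector = TRUE)
    s <- trace$summary
    lists <- jsonlite::read_json(cl, simplifyVector = TRUE)
    n_cand <- sum(vapply(lists$rankings,
                         function(d) if (is.data.frame(d)) nrow(d) else 0L,
                         0L))
    rows[[pn]] <- data.frame(
      problem = pn,
      importance_list = if (n_cand == 0) "no candidates"
        else paste(s$winner[seq_len(trace$transition_index)],
                   collapse = " "),
      n_features = trace$transition_index,
      mean_cv_auc = s$mean_cv_auc[trace$transition_index],
      holdout_auc = s$holdout_auc[trace$transition_index],
      stringsAsFactors = FALSE)
    s$problem <- pn
    steps[[pn]] <- s
  }
  importance_lists <- do.call(rbind, rows)
  rownames(importance_lists) <- NULL
  step_table <- do.call(rbind, steps)
  rownames(step_table) <- NULL
  coll <- jsonlite::read_json(file.path(run_dir, "collinearity.json"),
                              simplifyVector = TRUE)
  coll_df <- data.frame(max_vif = coll$max_vif,
                        max_vif_feature = coll$max_vif_feature,
                        n_high_pairs = if (is.data.frame(coll$high_pairs))
                          nrow(coll$high_pairs) else 0L,
                        stringsAsFactors = FALSE)
  utils::write.table(importance_lists,
                     file.path(run_dir, "importance_lists.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(step_table, file.path(run_dir, "step_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(importance_lists = importance_lists, step_table = step_table,
       collinearity = coll_df)
}
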