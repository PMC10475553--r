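# Binary problem construction (One-vs-One / One-vs-Rest), stratified holdout
# splitting, and random minority oversampling.

#' Stratified holdout split
#'
#' Splits a multi-class `feature_table` (stratified by diagnosis) or a binary
#' `problem_data` (stratified by target) into train and test parts. Per
#' stratum the test count is `round half up` of `(1 - fraction) * n`, with a
#' minimum of one test and one train observation, so both classes appear on
#' both sides at study sizes. Splitting the full multi-class table once, so
#' all derived problems share the same holdout patients, is the default
#' pipeline behaviour; per-problem splitting is available via the run
#' configuration.
#'
#' @param data A `feature_table` or `problem_data`.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.9).
#' @param seed Integer seed.
#' @return List with `train` and `test` of the same class as `data`.
#' @export
split_holdout <- function(data, fraction = 0.9, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  strata <- if (inherits(data, "feature_table")) data$labels
            else if (inherits(data, "problem_data")) data$y
            else stop("unsupported input", call. = FALSE)
  n <- length(strata)
  test_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_s <- length(idx)
    if (n_s < 2) stop("stratum '", s, "' has fewer than 2 observations",
                      call. = FALSE)
    n_test <- floor((1 - fraction) * n_s + 0.5 + 1e-9)  # round half up
    n_test <- min(max(n_test, 1L), n_s - 1L)
    test_idx <- c(test_idx, idx[sample.int(n_s, n_test)])
  }
  take <- function(d, idx) {
    if (inherits(d, "feature_table")) {
      feature_table(d$x[idx, , drop = FALSE], d$labels[idx])
    } else {
      problem_data(d$x[idx, , drop = FALSE], d$y[idx], d$spec,
                   check_variation = FALSE)
    }
  }
  keep <- setdiff(seq_len(n), test_idx)
  list(train = take(data, keep), test = take(data, sort(test_idx)))
}

#' Problem specification and data containers
#'
#' A `problem_spec` records how a binary problem was derived from the
#' multi-class table: One-vs-One (one negative class, the third excluded) or
#' One-vs-Rest (both other classes negative), plus the feature columns
#' excluded because they are constant within the problem's training rows.
#'
#' @param mode `"OvO"` or `"OvR"`.
#' @param positive_class,negative_classes,excluded_classes Class labels.
#' @param excluded_features Feature names constant within the problem.
#' @return An object of class `problem_spec`.
#' @export
problem_spec <- function(mode, positive_class, negative_classes,
                         excluded_classes = character(0),
                         excluded_features = character(0)) {
  stopifnot(mode %in% c("OvO", "OvR"))
  structure(list(mode = mode, positive_class = positive_class,
                 negative_classes = negative_classes,
                 excluded_classes = excluded_classes,
                 excluded_features = excluded_features),
            class = "problem_spec")
}

problem_name <- function(spec) {
  if (spec$mode == "OvR") paste0(spec$positive_class, "-vs-Rest")
  else paste0(spec$positive_class, "-vs-", spec$negative_classes)
}

#' @rdname problem_spec
#' @param x Binary feature matrix (rows already restricted to the problem's
#'   classes, excluded columns removed).
#' @param y Integer 0/1 target, 1 = positive class.
#' @param spec The `problem_spec`.
#' @param holdout Optional list with `x`, `y` for the holdout rows.
#' @param check_variation Verify every retained column varies (disable for
#'   mechanically derived subsets such as CV folds).
#' @return `problem_data()` returns an object of class `problem_data`.
#' @export
problem_data <- function(x, y, spec, holdout = NULL, check_variation = TRUE) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (check_variation) {
    if (length(unique(y)) < 2) {
      stop("target has a single class", call. = FALSE)
    }
    cs <- colSums(x)
    if (any(cs == 0L | cs == nrow(x))) {
      stop("constant column(s) retained: ",
           paste(colnames(x)[cs == 0L | cs == nrow(x)], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(x = x, y = as.integer(y), spec = spec, holdout = holdout),
            class = "problem_data")
}

#' @export
print.problem_data <- function(x, ...) {
  cat("problem_data ", problem_name(x$spec), ": ", nrow(x$x), " obs (",
      sum(x$y), " positive) x ", ncol(x$x), " features",
      if (!is.null(x$holdout)) sprintf("; holdout %d obs", nrow(x$holdout$x)),
      "\n", sep = "")
  invisible(x)
}

#' Build all One-vs-One and One-vs-Rest problems
#'
#' For k classes, emits all k(k-1)/2 OvO problems (dropping the excluded
#' class's rows) and k OvR problems. Columns constant within a problem's
#' training rows are excluded from that problem and recorded in its spec;
#' when a holdout table is supplied, its rows are subset per problem with the
#' training-derived column exclusions applied, so the holdout never
#' influences feature handling.
#'
#' @param train A `feature_table` of training patients.
#' @param holdout Optional `feature_table` of holdout patients.
#' @return Named list of `problem_data`, OvO problems first.
#' @export
build_problems <- function(train, holdout = NULL) {
  stopifnot(inherits(train, "feature_table"))
  classes <- unique(train$labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  counts <- table(train$labels)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  specs <- list()
  if (length(classes) >= 2) {
    for (i in seq_along(classes)) {
      for (j in seq_along(classes)) {
        if (j <= i) next
        specs[[length(specs) + 1L]] <-
          problem_spec("OvO", classes[i], classes[j],
                       excluded_classes = setdiff(classes,
                                                  classes[c(i, j)]))
      }
    }
  }
  if (length(classes) > 2) {
    for (cl in classes) {
      specs[[length(specs) + 1L]] <-
        problem_spec("OvR", cl, setdiff(classes, cl))
    }
  }
  out <- list()
  for (spec in specs) {
    keep_cls <- c(spec$positive_class, spec$negative_classes)
    tr_rows <- train$labels %in% keep_cls
    x <- train$x[tr_rows, , drop = FALSE]
    y <- as.integer(train$labels[tr_rows] == spec$positive_class)
    cs <- colSums(x)
    const <- cs == 0L | cs == nrow(x)
    spec$excluded_features <- colnames(x)[const]
    x <- x[, !const, drop = FALSE]
    ho <- NULL
    if (!is.null(holdout)) {
      ho_rows <- holdout$labels %in% keep_cls
      ho <- list(x = holdout$x[ho_rows, !const, drop = FALSE],
                 y = as.integer(holdout$labels[ho_rows] ==
                                  spec$positive_class))
    }
    out[[problem_name(spec)]] <- problem_data(x, y, spec, holdout = ho)
  }
  out
}

#' Random minority oversampling
#'
#' Duplicates uniformly sampled minority-class rows (with replacement) until
#' both classes are equally large. All original rows are retained and the
#' majority class is untouched. Applied to training data only — never to
#' validation or test data.
#'
#' @param problem A `problem_data` (or a plain list with `x`, `y`).
#' @param seed Integer seed.
#' @return Same shape as the input, with balanced classes.
#' @export
oversample <- function(problem, seed = 1L) {
  x <- problem$x
  y <- problem$y
  stopifnot(length(unique(y)) == 2)
  set.seed(seed)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 != n0) {
    minority <- which(y == (if (n1 < n0) 1L else 0L))
    extra <- minority[sample.int(length(minority), abs(n1 - n0),
                                 replace = TRUE)]
    x <- rbind(x, x[extra, , drop = FALSE])
    y <- c(y, y[extra])
  }
  if (inherits(problem, "problem_data")) {
    problem_data(x, y, problem$spec, holdout = problem$holdout,
                 check_variation = FALSE)
  } else {
    list(x = x, y = y)
  }
}
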