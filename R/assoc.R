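# Filter metrics: phi coefficient with t-test significance, pairwise phi /
# VIF collinearity screen, and the MultiSURF relief algorithm.

#' Phi coefficient between two binary vectors
#'
#' The phi coefficient equals the Pearson correlation of the 0/1 encodings
#' and is computed from the 2x2 contingency table as
#' `(n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)`. Significance is a
#' two-sided t-test on `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom, as for an ordinary correlation coefficient.
#'
#' @param x,y Binary 0/1 vectors of equal length >= 3, neither constant.
#' @return List of class `phi_result` with `r_phi`, `p_value`, `n`.
#' @export
phi_coefficient <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(x %in% c(0, 1)), all(y %in% c(0, 1)))
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("phi undefined for a constant vector", call. = FALSE)
  }
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  r <- (n11 * n00 - n10 * n01) /
    sqrt(as.numeric(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r_phi = r, p_value = p, n = n), class = "phi_result")
}

#' Collinearity screen: pairwise phi matrix and variance inflation factors
#'
#' Computes every pairwise [phi_coefficient()] among the feature columns and,
#' per feature, the VIF `1 / (1 - R^2)` from a least-squares regression of
#' that column on all the others. A perfectly collinear feature is reported
#' with an infinite VIF and flagged rather than erroring.
#'
#' @param table A `feature_table` whose columns are all non-constant.
#' @param report_threshold Absolute phi above which a pair is listed in the
#'   summary (default 0.5).
#' @return List of class `collinearity_report` with `phi_matrix`,
#'   `p_value_matrix`, `vif` (named vector), `flagged` (features with
#'   non-finite VIF), `high_pairs` (data.frame of pairs above the threshold).
#' @export
collinearity <- function(table, report_threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  p <- ncol(x)
  if (p < 2) stop("need at least 2 features", call. = FALSE)
  cs <- colSums(x)
  if (any(cs == 0L | cs == nrow(x))) {
    stop("constant column(s): ",
         paste(colnames(x)[cs == 0L | cs == nrow(x)], collapse = ", "),
         call. = FALSE)
  }
  phi_m <- diag(1, p)
  p_m <- diag(0, p)
  dimnames(phi_m) <- dimnames(p_m) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      res <- phi_coefficient(x[, i], x[, j])
      phi_m[i, j] <- phi_m[j, i] <- res$r_phi
      p_m[i, j] <- p_m[j, i] <- res$p_value
    }
  }
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(x)
  hi <- which(abs(phi_m) >= report_threshold & upper.tri(phi_m),
              arr.ind = TRUE)
  high_pairs <- data.frame(
    feature_a = colnames(x)[hi[, 1]], feature_b = colnames(x)[hi[, 2]],
    r_phi = phi_m[hi], stringsAsFactors = FALSE)
  high_pairs <- high_pairs[order(-abs(high_pairs$r_phi)), , drop = FALSE]
  rownames(high_pairs) <- NULL
  structure(list(phi_matrix = phi_m, p_value_matrix = p_m, vif = vif,
                 flagged = names(vif)[!is.finite(vif)],
                 high_pairs = high_pairs,
                 report_threshold = report_threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  off <- x$phi_matrix[upper.tri(x$phi_matrix)]
  cat("collinearity_report:", ncol(x$phi_matrix), "features; max |phi| =",
      signif(max(abs(off)), 3), "; max VIF =",
      signif(max(x$vif[is.finite(x$vif)]), 3), "\n")
  if (length(x$flagged)) {
    cat("  perfectly collinear (VIF = Inf):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' MultiSURF relief weights
#'
#' Deterministic relief-family feature weighting: every instance acts as a
#' target. For target `i`, the distance to every other instance is the mean
#' per-feature absolute difference (the Hamming fraction on binary data);
#' `T_i` is the mean of those distances and `D_i` half their standard
#' deviation; "near" neighbours are those with `d_ij < T_i - D_i` (strict,
#' dead-band excluded). Each near hit (same class) with a differing feature
#' value decrements that feature's weight and each near miss increments it,
#' with per-target contributions normalised by the target's near-hit and
#' near-miss counts and by the number of instances. MultiSURF with this
#' adaptive threshold detects univariate associations as well as 2- and
#' 3-way interactions that are univariately invisible.
#'
#' @param problem A `problem_data` (or list with binary matrix `x` and
#'   target `y`), at least 3 instances, both classes present.
#' @return List of class `relief_weights` with `W` (named weight vector),
#'   `n_instances`, `neighbor_definition`, and `n_no_neighbors` (targets
#'   that had no near neighbours and contributed nothing).
#' @export
multisurf <- function(problem) {
  x <- problem$x
  y <- problem$y
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n >= 3, length(unique(y)) == 2)
  storage.mode(x) <- "double"
  # pairwise Hamming fraction via cross products of x and 1-x
  d10 <- x %*% t(1 - x)
  dist <- (d10 + t(d10)) / p
  w <- numeric(p)
  n_no_neighbors <- 0L
  for (i in seq_len(n)) {
    d_i <- dist[i, -i]
    thr <- mean(d_i) - stats::sd(d_i) / 2
    near <- which(dist[i, ] < thr)
    near <- near[near != i]
    if (!length(near)) {
      n_no_neighbors <- n_no_neighbors + 1L
      next
    }
    hits <- near[y[near] == y[i]]
    misses <- near[y[near] != y[i]]
    if (length(hits)) {
      diff_h <- colSums(abs(x[hits, , drop = FALSE] -
                              rep(x[i, ], each = length(hits))))
      w <- w - diff_h / length(hits) / n
    }
    if (length(misses)) {
      diff_m <- colSums(abs(x[misses, , drop = FALSE] -
                              rep(x[i, ], each = length(misses))))
      w <- w + diff_m / length(misses) / n
    }
  }
  structure(list(W = setNames(w, colnames(x)), n_instances = n,
                 neighbor_definition = list(
                   distance = "mean per-feature absolute difference",
                   threshold = "T_i - D_i, T_i = mean distance, D_i = sd/2 (sample sd), strict <"),
                 n_no_neighbors = n_no_neighbors),
            class = "relief_weights")
}
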