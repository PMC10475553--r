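# Independent oracles and small fixture builders. The oracles are written
# naively (literal loops, textbook formulas) and never share code with the
# package implementations they check.

# O(n^2) AUC by pair counting, ties worth one half
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# literal per-target MultiSURF re-implementation: per-instance mean distance
# threshold with sd/2 dead band, strict <, per-target normalisation by
# near-hit and near-miss counts and by n
naive_multisurf <- function(x, y) {
  n <- nrow(x)
  p <- ncol(x)
  d <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i != j) d[i, j] <- mean(abs(x[i, ] - x[j, ]))
    }
  }
  w <- numeric(p)
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    thr <- mean(d[i, others]) - sd(d[i, others]) / 2
    near <- others[d[i, others] < thr]
    if (!length(near)) next
    hits <- near[y[near] == y[i]]
    misses <- near[y[near] != y[i]]
    for (f in 1:p) {
      if (length(hits)) {
        w[f] <- w[f] - sum(x[hits, f] != x[i, f]) / length(hits) / n
      }
      if (length(misses)) {
        w[f] <- w[f] + sum(x[misses, f] != x[i, f]) / length(misses) / n
      }
    }
  }
  setNames(w, colnames(x))
}

# binary matrix with named informative features (class-conditional
# prevalences) and uniform noise columns; returns a problem_data
make_binary_problem <- function(n_pos, n_neg, p_informative = numeric(0),
                                p_informative_neg = NULL, n_noise = 5,
                                noise_p = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  cols <- list()
  for (k in seq_along(p_informative)) {
    pp <- p_informative[k]
    pn <- if (is.null(p_informative_neg)) 1 - pp else p_informative_neg[k]
    cols[[paste0("inf", k)]] <- c(rbinom(n_pos, 1, pp), rbinom(n_neg, 1, pn))
  }
  for (k in seq_len(n_noise)) {
    cols[[paste0("noise", k)]] <- rbinom(n, 1, noise_p)
  }
  x <- do.call(cbind, cols)
  storage.mode(x) <- "integer"
  # ensure no constant columns (resample degenerate noise columns)
  for (j in seq_len(ncol(x))) {
    while (length(unique(x[, j])) < 2) x[, j] <- rbinom(n, 1, 0.5)
  }
  problem_data(x, y, problem_spec("OvO", "pos", "neg"))
}

# tiny singleton hyperparameter setting used throughout the tests
test_grid <- function(nrounds = 30L, max_depth = 3L, eta = 0.3) {
  data.frame(nrounds = nrounds, max_depth = max_depth, eta = eta)
}

# candidate_lists object built directly from ranked feature vectors
manual_lists <- function(phi = character(0), multisurf = character(0),
                         mdi = character(0), mda = character(0),
                         hyperparameters = as.list(test_grid())) {
  mk <- function(f) data.frame(feature = f,
                               score = rev(seq_along(f)) / 10,
                               stringsAsFactors = FALSE)
  structure(list(rankings = list(phi = mk(phi), multisurf = mk(multisurf),
                                 mdi = mk(mdi), mda = mk(mda)),
                 criterion = c(phi = "manual", multisurf = "manual",
                               mdi = "manual", mda = "manual"),
                 best_hyperparameters = hyperparameters),
            class = "candidate_lists")
}

# exhaustive best-subset CV sweep: mean CV AUC of every non-empty feature
# subset, via the same cv_evaluate engine the forward search uses
exhaustive_subset_sweep <- function(problem, cv, grid) {
  feats <- colnames(problem$x)
  p <- length(feats)
  out <- list()
  for (mask in 1:(2^p - 1)) {
    subset <- feats[as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))]
    res <- cv_evaluate(problem, subset, cv, grid)
    out[[mask]] <- data.frame(size = length(subset),
                              mean_auc = res$mean_auc,
                              features = paste(subset, collapse = ","),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
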