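test_that("rank-based AUC matches pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 20), rep(c(1, 0), 10)), 0.5)
  set.seed(14)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    scores <- sample(0:5, n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    expect_equal(auc(scores, labels), naive_auc(scores, labels))
  }
  expect_error(auc(1:5, rep(1, 5)), "both label values")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  s <- rnorm(60)
  l <- rbinom(60, 1, 0.5)
  l[1:2] <- c(0L, 1L)
  expect_equal(auc(s, l), auc(exp(s), l))
  expect_equal(auc(s, l), auc(rank(s), l))
})

test_that("repeated CV produces folds x repeats models and finds separating features", {
  pr <- make_binary_problem(60, 60, p_informative = 1.0, n_noise = 3,
                            seed = 3)
  res <- cv_evaluate(pr, colnames(pr$x), cv_config(2, 2, seed = 1),
                     test_grid())
  expect_length(res$auc_per_split, 4L)
  expect_equal(res$mean_auc, mean(res$auc_per_split))
  expect_equal(res$sd_auc, sd(res$auc_per_split))
  # a single perfectly separating feature reaches AUC 1 regardless of grid
  res1 <- cv_evaluate(pr, "inf1", cv_config(3, 2, seed = 2),
                      test_grid(nrounds = 10L))
  expect_equal(res1$mean_auc, 1.0)
  expect_error(cv_evaluate(pr, "inf1", cv_config(3, 2, seed = 2),
                           data.frame()), "empty")
  expect_error(cv_evaluate(pr, "absent", cv_config(3, 2, seed = 2),
                           test_grid()), "not in problem")
})

test_that("grid search returns a grid member and a singleton grid equals plain CV", {
  pr <- make_binary_problem(50, 50, p_informative = 0.8, n_noise = 3,
                            seed = 4)
  grid <- rbind(test_grid(nrounds = 10L), test_grid(nrounds = 25L))
  res <- cv_evaluate(pr, colnames(pr$x), cv_config(3, 2, seed = 5), grid)
  expect_true(res$best_hyperparameters$nrounds %in% grid$nrounds)
  expect_identical(nrow(res$grid_mean_auc), 2L)
  single <- cv_evaluate(pr, colnames(pr$x), cv_config(3, 2, seed = 5),
                        test_grid(nrounds = 10L))
  idx <- which(res$grid_mean_auc$nrounds == 10L)
  expect_equal(single$mean_auc, res$grid_mean_auc$mean_auc[idx])
})

test_that("final model fitting is deterministic and scores are probabilities", {
  pr <- make_binary_problem(80, 50, p_informative = 0.85, n_noise = 4,
                            seed = 6)
  fm1 <- fit_final(pr, colnames(pr$x), as.list(test_grid()), seed = 9)
  fm2 <- fit_final(pr, colnames(pr$x), as.list(test_grid()), seed = 9)
  s1 <- predict(fm1, pr$x)
  expect_identical(s1, predict(fm2, pr$x))
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("MDI reflects split usage: unused features get zero, dominant features dominate", {
  set.seed(7)
  n <- 200
  y <- rep(c(1L, 0L), n / 2)
  x <- cbind(label_copy = y, noise = rbinom(n, 1, 0.5), unused = 0L)
  pr <- problem_data(x, y, problem_spec("OvO", "a", "b"),
                     check_variation = FALSE)
  fm <- fit_final(pr, colnames(x), as.list(test_grid()), seed = 1)
  ii <- mdi(fm)$I_I
  expect_identical(unname(ii["unused"]), 0)
  expect_gt(ii[["label_copy"]], ii[["noise"]])
  expect_true(all(ii >= 0))
  # single-feature model carries all normalized impurity decrease
  fm1 <- fit_final(pr, "label_copy", as.list(test_grid()), seed = 1)
  expect_equal(unname(mdi(fm1)$I_I["label_copy"]), 1)
})

test_that("duplicated features split the impurity importance of the single copy", {
  pr <- make_binary_problem(150, 150, p_informative = 0.85, n_noise = 4,
                            seed = 5)
  fm0 <- fit_final(pr, colnames(pr$x), as.list(test_grid()), seed = 1)
  control <- mdi(fm0)$I_I[["inf1"]]
  x2 <- cbind(pr$x, inf1b = pr$x[, "inf1"])
  pr2 <- problem_data(x2, pr$y, pr$spec, check_variation = FALSE)
  fm1 <- fit_final(pr2, colnames(x2), as.list(test_grid()), seed = 1)
  ii <- mdi(fm1)$I_I
  expect_equal(ii[["inf1"]] + ii[["inf1b"]], control, tolerance = 0.1)
})

test_that("permutation importance separates used from unused features", {
  set.seed(9)
  x <- cbind(inf = c(rbinom(150, 1, 0.95), rbinom(150, 1, 0.05)),
             unused = 0L)
  y <- rep(1:0, each = 150)
  pr <- problem_data(x, y, problem_spec("OvO", "a", "b"),
                     check_variation = FALSE)
  fm <- fit_final(pr, colnames(x), as.list(test_grid()), seed = 1)
  m <- mda(fm, list(x = x, y = y), permutations = 20, seed = 2)
  expect_equal(unname(m$I_A["unused"]), 0, tolerance = 1e-12)
  # permuting the only informative feature drops performance to chance
  expect_equal(m$baseline_auc - m$I_A[["inf"]], 0.5, tolerance = 0.05)
  # more permutations: same sign, averaged estimate stays close
  m1 <- mda(fm, list(x = x, y = y), permutations = 1, seed = 3)
  expect_identical(sign(m1$I_A[["inf"]]), sign(m$I_A[["inf"]]))
})

test_that("cross-validated importance averages over the CV models", {
  pr <- make_binary_problem(80, 80, p_informative = 0.9, n_noise = 3,
                            seed = 10)
  imp <- cv_importance(pr, colnames(pr$x), cv_config(3, 2, seed = 4),
                       as.list(test_grid()), permutations = 3)
  expect_length(imp$auc_per_split, 6L)
  expect_identical(names(which.max(imp$I_I)), "inf1")
  expect_identical(names(which.max(imp$I_A)), "inf1")
  expect_true(all(imp$I_I >= 0))
})
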