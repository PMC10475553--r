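make_readings <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], diagnosis = r[[2]], hand = r[[3]],
               phase = as.integer(r[[4]]), features = r[[5]],
               stringsAsFactors = FALSE)
  }))
  reading_table(df)
}

test_that("hand fusion takes the per-phase union and drops hand information", {
  rt <- make_readings(list(
    list("p1", "RA", "left", 2, "D"),
    list("p1", "RA", "right", 2, "P"),
    list("p2", "OA", "left", 1, "D"),
    list("p2", "OA", "right", 1, "D"),
    list("p3", "CTD", "left", 3, ""),
    list("p3", "CTD", "right", 3, "")))
  fused <- fuse_hands(rt)
  expect_false("hand" %in% names(fused))
  expect_identical(fused$features[fused$patient_id == "p1"], "D;P")
  expect_identical(fused$features[fused$patient_id == "p2"], "D")
  expect_identical(fused$features[fused$patient_id == "p3"], "")
  expect_identical(nrow(fused), 3L)
})

test_that("fuse-then-encode is invariant to swapping hand labels", {
  rt <- generate_cohort(synthetic_config(class_sizes = c(A = 40L, B = 40L),
                                         noise_p = 0.15, seed = 8))
  swapped <- rt
  swapped$hand <- ifelse(rt$hand == "left", "right", "left")
  expect_identical(encode_features(fuse_hands(rt))$x,
                   encode_features(fuse_hands(reading_table(swapped)))$x)
})

test_that("encoding yields the 60 feature-phase columns with correct placement", {
  rt <- make_readings(list(
    list("p1", "RA", "left", 1, "Y"),
    list("p1", "RA", "right", 1, "")))
  enc <- encode_features(fuse_hands(rt))
  expect_identical(ncol(enc$x), 60L)
  expect_identical(unname(enc$x["p1", "Y1"]), 1L)
  expect_identical(sum(enc$x), 1L)
  # empty table encodes to a 0 x 60 matrix
  empty <- reading_table(data.frame(patient_id = character(0),
                                    diagnosis = character(0),
                                    phase = integer(0),
                                    features = character(0)))
  expect_identical(dim(encode_features(empty)$x), c(0L, 60L))
  expect_error(reading_table(data.frame(patient_id = "p1", diagnosis = "RA",
                                        phase = 1L, features = "Q")),
               "unknown feature")
})

test_that("filtering drops featureless patients then never-observed columns, idempotently", {
  x <- rbind(c(1L, 0L, 1L), c(0L, 0L, 0L), c(1L, 0L, 0L))
  colnames(x) <- c("D1", "D2", "P1")
  rownames(x) <- paste0("p", 1:3)
  ft <- feature_table(x, c("RA", "RA", "OA"))
  res <- filter_feature_table(ft)
  expect_identical(res$dropped_patients, "p2")
  expect_identical(res$dropped_features, "D2")
  expect_identical(dim(res$table$x), c(2L, 2L))
  # idempotent
  res2 <- filter_feature_table(res$table)
  expect_identical(res2$table$x, res$table$x)
  expect_length(res2$dropped_features, 0)
  expect_length(res2$dropped_patients, 0)
  # empty after filtering errors
  allzero <- feature_table(matrix(0L, 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("D1", "D2"))),
                           c("RA", "OA"))
  expect_error(filter_feature_table(allzero), "empty")
})

test_that("three classes yield six problems with the expected row counts", {
  cfg <- synthetic_config(class_sizes = c(RA = 235L, OA = 229L, CTD = 141L),
                          noise_p = 0.2, seed = 12)
  filt <- filter_feature_table(encode_features(fuse_hands(
    generate_cohort(cfg))))
  pr <- build_problems(filt$table)
  expect_identical(length(pr), 6L)
  expect_setequal(names(pr), c("RA-vs-OA", "RA-vs-CTD", "OA-vs-CTD",
                               "RA-vs-Rest", "OA-vs-Rest", "CTD-vs-Rest"))
  expect_identical(nrow(pr[["RA-vs-OA"]]$x), 464L)
  expect_identical(nrow(pr[["RA-vs-Rest"]]$x), 605L)
  expect_identical(sum(pr[["RA-vs-Rest"]]$y), 235L)
  # each row appears in exactly k-1 = 2 OvO problems
  ovo <- pr[1:3]
  ids <- unlist(lapply(ovo, function(p) rownames(p$x)))
  expect_true(all(table(ids) == 2L))
})

test_that("columns constant within a problem are excluded and recorded", {
  x <- cbind(B1 = c(0L, 0L, 0L, 0L, 1L, 1L), D1 = c(1L, 0L, 1L, 0L, 1L, 0L),
             P1 = c(0L, 1L, 1L, 0L, 0L, 1L))
  rownames(x) <- paste0("p", 1:6)
  ft <- feature_table(x, c("RA", "RA", "CTD", "CTD", "OA", "OA"))
  pr <- build_problems(ft)
  expect_identical(pr[["RA-vs-CTD"]]$spec$excluded_features, "B1")
  expect_false("B1" %in% colnames(pr[["RA-vs-CTD"]]$x))
  expect_true("B1" %in% colnames(pr[["RA-vs-OA"]]$x))
  expect_error(build_problems(feature_table(x[1:3, , drop = FALSE],
                                            c("RA", "RA", "CTD"))),
               "fewer than 2")
})

test_that("holdout split is stratified, reproducible, and respects the rounding rule", {
  cfg <- synthetic_config(class_sizes = c(RA = 235L, OA = 229L),
                          noise_p = 0.2, seed = 4)
  ft <- filter_feature_table(encode_features(fuse_hands(
    generate_cohort(cfg))))$table
  sp1 <- split_holdout(ft, 0.9, seed = 21)
  sp2 <- split_holdout(ft, 0.9, seed = 21)
  expect_identical(sp1$train$x, sp2$train$x)
  expect_identical(sp1$test$x, sp2$test$x)
  # round-half-up per stratum: test 24 RA + 23 OA -> train 417
  expect_identical(nrow(sp1$train$x), 417L)
  expect_setequal(unique(sp1$test$labels), c("RA", "OA"))
  # fraction 0.5 on balanced data: both classes on both sides, equal halves
  sp3 <- split_holdout(ft, 0.5, seed = 3)
  expect_identical(sort(unique(sp3$train$labels)), sort(unique(ft$labels)))
  expect_equal(nrow(sp3$train$x) + nrow(sp3$test$x), nrow(ft$x))
})

test_that("oversampling balances classes while preserving originals", {
  pr <- make_binary_problem(100, 60, n_noise = 4, seed = 6)
  os <- oversample(pr, seed = 2)
  expect_identical(sum(os$y == 1L), sum(os$y == 0L))
  expect_identical(nrow(os$x), 200L)
  # original rows retained in order, majority untouched
  expect_identical(os$x[1:160, ], pr$x)
  # duplicated rows are copies of minority rows
  expect_true(all(os$y[161:200] == 0L))
  # already balanced -> unchanged
  prb <- make_binary_problem(50, 50, n_noise = 4, seed = 7)
  expect_identical(oversample(prb, seed = 1)$x, prb$x)
  # degenerate single minority row duplicated to parity
  x <- cbind(f1 = c(rep(1L, 10), 0L), f2 = c(rep(c(0L, 1L), 5), 1L))
  pr1 <- problem_data(x, c(rep(0L, 10), 1L), problem_spec("OvO", "a", "b"),
                      check_variation = FALSE)
  os1 <- oversample(pr1, seed = 3)
  expect_identical(sum(os1$y == 1L), 10L)
  expect_true(all(os1$x[os1$y == 1L, "f1"] == 0L))
})

test_that("reading tables round-trip through the CSV dialect", {
  rt <- generate_cohort(synthetic_config(class_sizes = c(A = 20L, B = 20L),
                                         noise_p = 0.2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reading_table(rt, path)
  rt2 <- read_reading_table(path)
  expect_identical(as.data.frame(rt), as.data.frame(rt2))
})
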