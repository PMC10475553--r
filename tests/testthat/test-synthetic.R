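test_that("cohort generation is seed-deterministic and study-shaped", {
  cfg <- foi_config(seed = 31)
  rt1 <- generate_cohort(cfg)
  rt2 <- generate_cohort(cfg)
  expect_identical(rt1, rt2)
  expect_identical(length(unique(rt1$patient_id)), 609L)
  expect_identical(nrow(rt1), 609L * 6L)  # 2 hands x 3 phases per patient
  counts <- table(rt1$diagnosis[!duplicated(rt1$patient_id)])
  expect_identical(as.integer(counts[c("RA", "OA", "CTD")]),
                   c(237L, 231L, 141L))
  rt3 <- generate_cohort(foi_config(seed = 32))
  expect_false(identical(rt1$features, rt3$features))
})

test_that("declared zero features are never annotated and featureless counts are exact", {
  enc <- encode_features(fuse_hands(generate_cohort(foi_config(seed = 5))))
  expect_identical(dim(enc$x), c(609L, 60L))
  expect_true(all(colSums(enc$x[, foi_zero_features()]) == 0L))
  empty <- rowSums(enc$x) == 0L
  expect_identical(sum(empty), 4L)
  expect_identical(as.vector(table(enc$labels[empty])[c("OA", "RA")]),
                   c(2L, 2L))
})

test_that("degenerate all-zero config yields an entirely featureless cohort", {
  cfg <- synthetic_config(class_sizes = c(A = 5L, B = 5L), noise_p = 0,
                          seed = 1)
  rt <- generate_cohort(cfg)
  expect_true(all(rt$features == ""))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(planted_effect("Q1", c(A = 0.5)), "unknown feature")
  expect_error(planted_effect("P4", c(A = 0.5)), "unknown feature")
  expect_error(
    synthetic_config(class_sizes = c(A = 5L),
                     effects = list(planted_effect("P2", c(A = 0.5))),
                     zero_features = "P2"),
    "overlap")
  expect_error(
    synthetic_config(class_sizes = c(A = 5L, B = 5L),
                     effects = list(planted_effect("P2", c(A = 0.5)))),
    "lacks probabilities")
})

test_that("analytic single-feature AUC matches the closed form", {
  e <- planted_effect("P2", c(pos = 0.8, neg = 0.2, same = 0.8))
  expect_equal(expected_univariate_auc(e, "pos", "neg"), 0.80)
  expect_equal(expected_univariate_auc(e, "same", "pos"), 0.50)
  e2 <- planted_effect("P2", c(pos = 1.0, neg = 0.0))
  expect_equal(expected_univariate_auc(e2, "pos", "neg"), 1.00)
  expect_error(expected_univariate_auc(e, "pos", "absent"), "missing")
})

test_that("planted prevalences, phase-link phi, and interaction invisibility hold empirically", {
  cfg <- synthetic_config(
    class_sizes = c(A = 400L, B = 400L),
    effects = list(planted_effect("Y1", c(A = 0.8, B = 0.2))),
    interactions = list(planted_interaction(c("B3", "F2"),
                                            c(A = 0.15, B = 0.85))),
    phase_correlation = data.frame(feature_from = "D1", feature_to = "D2",
                                   phi = 0.7),
    noise_p = 0.1, seed = 77)
  enc <- encode_features(fuse_hands(generate_cohort(cfg)))
  y <- as.integer(enc$labels == "A")

  # class-conditional frequencies within 3 binomial SE
  for (cl in c("A", "B")) {
    p_true <- c(A = 0.8, B = 0.2)[[cl]]
    p_hat <- mean(enc$x[enc$labels == cl, "Y1"])
    se <- sqrt(p_true * (1 - p_true) / 400)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }

  # phase-link phi within 0.1 of target at n >= 500
  expect_lt(abs(phi_coefficient(enc$x[, "D1"], enc$x[, "D2"])$r_phi - 0.7),
            0.1)

  # interaction features univariately invisible, jointly informative
  for (f in c("B3", "F2")) {
    expect_lt(abs(phi_coefficient(enc$x[, f], y)$r_phi), 0.1)
  }
  parity <- (enc$x[, "B3"] + enc$x[, "F2"]) %% 2
  joint_auc <- auc(ave(y, parity), y)  # per-pattern class-frequency scorer
  expect_gt(joint_auc, 0.65)
})

test_that("per-hand assignment is exercised and fusion is the set union", {
  rt <- generate_cohort(foi_config(seed = 3))
  fused <- fuse_hands(rt)
  split_sets <- function(s) lapply(strsplit(s, ";", fixed = TRUE),
                                   function(v) sort(v[nzchar(v)]))
  key <- paste(rt$patient_id, rt$phase)
  fkey <- paste(fused$patient_id, fused$phase)
  sets <- split_sets(rt$features)
  fsets <- split_sets(fused$features)
  one_handed <- FALSE
  for (k in unique(key)[1:200]) {
    idx <- which(key == k)
    expect_identical(sort(unique(unlist(sets[idx]))),
                     fsets[[match(k, fkey)]])
    if (!identical(sets[[idx[1]]], sets[[idx[2]]])) one_handed <- TRUE
  }
  expect_true(one_handed)  # hand fusion must be a non-trivial union
})

test_that("synthetic config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "class_sizes: {A: 30, B: 20}",
    "effects:",
    "  - feature: Y1",
    "    p_given_class: {A: 0.9, B: 0.1}",
    "interactions:",
    "  - features: [B3, F2]",
    "    p_parity_given_class: {A: 0.2, B: 0.8}",
    "phase_correlation:",
    "  - {feature_from: D1, feature_to: D2, phi: 0.7}",
    "zero_features: [E1, O1]",
    "noise_p: 0.1",
    "seed: 4"), path)
  cfg <- read_synthetic_config(path)
  expect_s3_class(cfg, "synthetic_config")
  expect_identical(cfg$seed, 4L)
  rt <- generate_cohort(cfg)
  expect_identical(length(unique(rt$patient_id)), 50L)
})
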