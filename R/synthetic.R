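# Synthetic reading-cohort generator. Emulates the statistical structure the
# downstream pipeline assumes: 60 binary feature-phase indicators, three
# diagnosis classes, planted univariate prevalence effects, XOR-parity
# interactions that are univariately invisible, inter-phase correlation via
# copy-with-flip links, never-observed features, and featureless patients.

#' Planted univariate effect
#'
#' Declares a feature-phase whose Bernoulli prevalence depends on the
#' diagnosis class, planting a univariate association for the pipeline to
#' recover.
#'
#' @param feature Feature-phase id, e.g. \code{"P2"}.
#' @param p_given_class Named numeric vector mapping class label to prevalence
#'   in `[0, 1]`.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(feature, p_given_class) {
  parse_feature_id(feature)
  stopifnot(is.numeric(p_given_class), !is.null(names(p_given_class)),
            all(p_given_class >= 0 & p_given_class <= 1))
  structure(list(feature = feature, p_given_class = p_given_class),
            class = "planted_effect")
}

#' Planted XOR-parity interaction
#'
#' Declares a 2- or 3-way interaction: the XOR parity of the involved
#' feature-phases follows a class-conditional Bernoulli law while every
#' involved feature has marginal prevalence 1/2 in every class, so each is
#' individually uninformative (expected univariate phi of 0) but the joint
#' pattern carries class information. This is the canonical structure a
#' relief-family filter detects and a univariate filter cannot.
#'
#' @param features Character vector of 2 or 3 feature-phase ids.
#' @param p_parity_given_class Named numeric vector mapping class label to
#'   `P(XOR parity = 1 | class)`.
#' @return An object of class `planted_interaction`.
#' @export
planted_interaction <- function(features, p_parity_given_class) {
  stopifnot(length(features) %in% c(2L, 3L), !anyDuplicated(features))
  parse_feature_id(features)
  stopifnot(is.numeric(p_parity_given_class),
            !is.null(names(p_parity_given_class)),
            all(p_parity_given_class >= 0 & p_parity_given_class <= 1))
  structure(list(features = features,
                 p_parity_given_class = p_parity_given_class),
            class = "planted_interaction")
}

#' Synthetic cohort configuration
#'
#' @param class_sizes Named integer vector of patients per diagnosis class;
#'   the name order fixes the class order used throughout.
#' @param effects List of [planted_effect()] objects.
#' @param interactions List of [planted_interaction()] objects.
#' @param phase_correlation `NULL` or a data.frame with columns
#'   `feature_from`, `feature_to`, `phi`: the child feature-phase is a copy of
#'   the parent with probability `phi` and an independent redraw at the
#'   parent's prevalence otherwise, which makes the population phi between the
#'   two exactly `phi`. Parent and child must share an acronym and differ in
#'   phase; a child may not itself carry an effect, interaction, or second
#'   link.
#' @param zero_features Feature-phase ids forced all-zero (never observed);
#'   must be disjoint from effect, interaction, and link features.
#' @param featureless_rate Probability that a patient is designated
#'   featureless (no annotations on either hand). Ignored when
#'   `featureless_counts` is given.
#' @param featureless_counts `NULL` or a named integer vector giving the exact
#'   number of featureless patients per class.
#' @param noise_p Background Bernoulli prevalence for unplanted, non-zero
#'   features.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(class_sizes,
                             effects = list(),
                             interactions = list(),
                             phase_correlation = NULL,
                             zero_features = character(0),
                             featureless_rate = 0,
                             featureless_counts = NULL,
                             noise_p = 0.08,
                             seed = 1L) {
  stopifnot(is.numeric(class_sizes), !is.null(names(class_sizes)),
            all(class_sizes >= 0), length(class_sizes) >= 1)
  classes <- names(class_sizes)
  for (e in effects) {
    stopifnot(inherits(e, "planted_effect"))
    missing_cls <- setdiff(classes, names(e$p_given_class))
    if (length(missing_cls)) {
      stop("effect on ", e$feature, " lacks probabilities for class(es): ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
  }
  for (ia in interactions) stopifnot(inherits(ia, "planted_interaction"))
  if (length(zero_features)) parse_feature_id(zero_features)

  eff_feats <- vapply(effects, `[[`, "", "feature")
  int_feats <- unlist(lapply(interactions, `[[`, "features"))
  planted <- c(eff_feats, int_feats)
  if (anyDuplicated(planted)) {
    stop("a feature may carry at most one planted effect or interaction",
         call. = FALSE)
  }
  if (length(intersect(zero_features, planted))) {
    stop("zero_features overlap planted features: ",
         paste(intersect(zero_features, planted), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(phase_correlation)) {
    stopifnot(is.data.frame(phase_correlation),
              all(c("feature_from", "feature_to", "phi") %in%
                    names(phase_correlation)))
    pf <- parse_feature_id(phase_correlation$feature_from)
    pt <- parse_feature_id(phase_correlation$feature_to)
    stopifnot(all(pf$acronym == pt$acronym), all(pf$phase != pt$phase),
              all(phase_correlation$phi >= 0 & phase_correlation$phi < 1))
    children <- phase_correlation$feature_to
    if (anyDuplicated(children) ||
        length(intersect(children, c(planted, zero_features,
                                     phase_correlation$feature_from)))) {
      stop("phase_correlation children must be unique and free of effects, ",
           "interactions, zero columns, and parent roles", call. = FALSE)
    }
    if (length(intersect(phase_correlation$feature_from, zero_features))) {
      stop("phase_correlation parents may not be zero features", call. = FALSE)
    }
  }
  if (!is.null(featureless_counts)) {
    stopifnot(is.numeric(featureless_counts),
              all(names(featureless_counts) %in% classes),
              all(featureless_counts <=
                    class_sizes[names(featureless_counts)]))
  }
  stopifnot(featureless_rate >= 0, featureless_rate < 1,
            noise_p >= 0, noise_p <= 1)
  structure(list(class_sizes = class_sizes, effects = effects,
                 interactions = interactions,
                 phase_correlation = phase_correlation,
                 zero_features = zero_features,
                 featureless_rate = featureless_rate,
                 featureless_counts = featureless_counts,
                 noise_p = noise_p, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Study-shaped default configuration
#'
#' A `synthetic_config` mirroring the shape of the reference FOI reading
#' cohort: classes RA/OA/CTD with 237/231/141 patients, the 15 never-observed
#' feature-phases, exactly 2 RA and 2 OA featureless patients, inter-phase
#' links D1~D2 (phi 0.73) and P2~P3 (phi 0.70), and a handful of planted
#' class-specific prevalence effects plus one 2-way XOR interaction. Effect
#' strengths are conventions (the underlying per-feature disease prevalences
#' are not published), chosen so that a few features carry clear class
#' information while most are background noise.
#'
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
foi_config <- function(seed = 1L) {
  synthetic_config(
    class_sizes = c(RA = 237L, OA = 231L, CTD = 141L),
    effects = list(
      planted_effect("Y1", c(RA = 0.15, OA = 0.55, CTD = 0.18)),
      planted_effect("P2", c(RA = 0.45, OA = 0.20, CTD = 0.62)),
      planted_effect("M3", c(RA = 0.50, OA = 0.18, CTD = 0.22)),
      planted_effect("I1", c(RA = 0.12, OA = 0.14, CTD = 0.38)),
      planted_effect("C3", c(RA = 0.30, OA = 0.12, CTD = 0.35))
    ),
    interactions = list(
      planted_interaction(c("B3", "F2"),
                          c(RA = 0.35, OA = 0.65, CTD = 0.50))
    ),
    phase_correlation = data.frame(
      feature_from = c("D1", "P2"),
      feature_to = c("D2", "P3"),
      phi = c(0.73, 0.70)
    ),
    zero_features = foi_zero_features(),
    featureless_counts = c(RA = 2L, OA = 2L),
    noise_p = 0.08,
    seed = seed
  )
}

# per-class prevalence vector over the 60 feature-phases (interaction and
# link-child columns are handled separately and set NA here)
class_prevalences <- function(config, class) {
  feats <- foi_feature_names()
  p <- setNames(rep(config$noise_p, length(feats)), feats)
  p[config$zero_features] <- 0
  for (e in config$effects) p[e$feature] <- e$p_given_class[[class]]
  int_feats <- unlist(lapply(config$interactions, `[[`, "features"))
  p[int_feats] <- NA_real_
  if (!is.null(config$phase_correlation)) {
    p[config$phase_correlation$feature_to] <- NA_real_
  }
  p
}

# draw an n x 60 binary matrix for one class; consumes the current RNG stream
draw_class_matrix <- function(n, class, config) {
  feats <- foi_feature_names()
  p <- class_prevalences(config, class)
  x <- matrix(0L, n, length(feats), dimnames = list(NULL, feats))
  plain <- names(p)[!is.na(p)]
  x[, plain] <- matrix(
    rbinom(n * length(plain), 1L, rep(p[plain], each = n)),
    n, length(plain))
  for (ia in config$interactions) {
    b <- rbinom(n, 1L, ia$p_parity_given_class[[class]])
    k <- length(ia$features)
    free <- matrix(rbinom(n * (k - 1L), 1L, 0.5), n, k - 1L)
    last <- (rowSums(free) + b) %% 2L
    x[, ia$features] <- cbind(free, last)
  }
  if (!is.null(config$phase_correlation)) {
    pc <- config$phase_correlation
    for (i in seq_len(nrow(pc))) {
      parent <- x[, pc$feature_from[i]]
      p_parent <- p[pc$feature_from[i]]
      if (is.na(p_parent)) {
        stop("phase link parent may not be an interaction or link child",
             call. = FALSE)
      }
      copy <- runif(n) < pc$phi[i]
      fresh <- rbinom(n, 1L, p_parent)
      x[, pc$feature_to[i]] <- ifelse(copy, parent, fresh)
    }
  }
  x
}

#' Generate a synthetic reading cohort
#'
#' Draws a per-hand, per-phase reading table from a [synthetic_config()].
#' Feature values are generated at patient level, then each annotated feature
#' is assigned to the left hand, the right hand, or both (uniformly), so that
#' hand fusion downstream is a non-trivial union. Patients designated
#' featureless get no annotations on either hand; every other patient is
#' guaranteed at least one annotation (all-zero draws are redrawn), so the
#' featureless set is exactly the designated one. The same seed reproduces
#' the table bit for bit.
#'
#' @param config A `synthetic_config`.
#' @return A `reading_table` (see [reading_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  classes <- names(config$class_sizes)
  n_total <- sum(config$class_sizes)
  labels <- rep(classes, times = config$class_sizes)
  x <- matrix(0L, n_total, 60L, dimnames = list(NULL, foi_feature_names()))
  offset <- 0L
  for (cl in classes) {
    n_cl <- config$class_sizes[[cl]]
    if (n_cl > 0) {
      x[offset + seq_len(n_cl), ] <- draw_class_matrix(n_cl, cl, config)
    }
    offset <- offset + n_cl
  }

  # designate featureless patients
  featureless <- rep(FALSE, n_total)
  if (!is.null(config$featureless_counts)) {
    for (cl in names(config$featureless_counts)) {
      idx <- which(labels == cl)
      k <- config$featureless_counts[[cl]]
      if (k > 0) featureless[idx[sample.int(length(idx), k)]] <- TRUE
    }
  } else if (config$featureless_rate > 0) {
    featureless <- runif(n_total) < config$featureless_rate
  }
  x[featureless, ] <- 0L

  # guarantee annotated patients really have >= 1 annotation (classes whose
  # prevalences are identically zero cannot be redrawn and stay featureless)
  class_positive <- vapply(classes, function(cl) {
    sum(class_prevalences(config, cl) > 0, na.rm = TRUE) > 0 ||
      length(config$interactions) > 0
  }, TRUE)
  repeat {
    empty <- which(!featureless & rowSums(x) == 0L &
                     class_positive[labels])
    if (!length(empty)) break
    for (i in empty) x[i, ] <- draw_class_matrix(1L, labels[i], config)
  }

  # hand assignment: 1 = left, 2 = right, 3 = both
  assign <- matrix(0L, n_total, 60L)
  ones <- which(x == 1L)
  assign[ones] <- sample(3L, length(ones), replace = TRUE)

  ids <- sprintf("PT%04d", seq_len(n_total))
  feats <- foi_feature_names()
  info <- parse_feature_id(feats)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    recs <- expand.grid(hand = c("left", "right"), phase = 1:3,
                        stringsAsFactors = FALSE)
    recs$features <- vapply(seq_len(nrow(recs)), function(r) {
      want <- if (recs$hand[r] == "left") c(1L, 3L) else c(2L, 3L)
      sel <- info$phase == recs$phase[r] & assign[i, ] %in% want &
        x[i, ] == 1L
      paste(info$acronym[sel], collapse = ";")
    }, "")
    rows[[i]] <- data.frame(patient_id = ids[i], diagnosis = labels[i],
                            hand = recs$hand, phase = recs$phase,
                            features = recs$features,
                            stringsAsFactors = FALSE)
  }
  reading_table(do.call(rbind, rows))
}

#' Analytic single-feature AUC for a planted effect
#'
#' For a binary feature with prevalence `p_pos` in the positive class and
#' `p_neg` in the negative class, the rank-based AUC of the feature as a
#' classifier is `P(X_pos > X_neg) + P(X_pos = X_neg) / 2` for independent
#' Bernoulli draws.
#'
#' @param effect A `planted_effect`.
#' @param pos,neg Class labels present in `effect$p_given_class`.
#' @return A probability.
#' @export
expected_univariate_auc <- function(effect, pos, neg) {
  stopifnot(inherits(effect, "planted_effect"))
  p <- effect$p_given_class
  if (!all(c(pos, neg) %in% names(p))) {
    stop("class(es) missing from effect: ",
         paste(setdiff(c(pos, neg), names(p)), collapse = ", "),
         call. = FALSE)
  }
  pp <- p[[pos]]
  pn <- p[[neg]]
  pp * (1 - pn) + 0.5 * (pp * pn + (1 - pp) * (1 - pn))
}

#' Read a synthetic configuration from YAML or JSON
#'
#' Key-value file with fields matching [synthetic_config()]; `effects` is a
#' list of `{feature, p_given_class}` records, `interactions` a list of
#' `{features, p_parity_given_class}` records, and `phase_correlation` a list
#' of `{feature_from, feature_to, phi}` records.
#'
#' @param path File path (`.yaml`, `.yml`, or `.json`).
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_num <- function(x) setNames(as.numeric(unlist(x)), names(unlist(x)))
  effects <- lapply(raw$effects %||% list(), function(e) {
    planted_effect(e$feature, as_num(e$p_given_class))
  })
  interactions <- lapply(raw$interactions %||% list(), function(ia) {
    planted_interaction(unlist(ia$features), as_num(ia$p_parity_given_class))
  })
  pc <- NULL
  if (!is.null(raw$phase_correlation)) {
    pc <- do.call(rbind, lapply(raw$phase_correlation, function(l) {
      data.frame(feature_from = l$feature_from, feature_to = l$feature_to,
                 phi = as.numeric(l$phi), stringsAsFactors = FALSE)
    }))
  }
  synthetic_config(
    class_sizes = as_num(raw$class_sizes),
    effects = effects,
    interactions = interactions,
    phase_correlation = pc,
    zero_features = as.character(raw$zero_features %||% character(0)),
    featureless_rate = raw$featureless_rate %||% 0,
    featureless_counts = if (!is.null(raw$featureless_counts))
      as_num(raw$featureless_counts),
    noise_p = raw$noise_p %||% 0.08,
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
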