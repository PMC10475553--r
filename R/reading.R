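# Reading-table data model and preprocessing: per-hand/per-phase annotation
# records -> hand-fused records -> binary feature-phase matrix -> filtered
# analysis table.

#' Construct and validate a reading table
#'
#' A reading table holds one row per (patient, hand, phase) with the set of
#' annotated feature acronyms as a semicolon-joined string (empty string =
#' featureless phase image). Hand-fused tables (see [fuse_hands()]) carry one
#' row per (patient, phase) and no `hand` column.
#'
#' @param df data.frame with columns `patient_id`, `diagnosis`, `hand`
#'   (optional for fused tables), `phase`, `features`.
#' @return The validated data.frame with class `reading_table`.
#' @export
reading_table <- function(df) {
  stopifnot(is.data.frame(df))
  fused <- !("hand" %in% names(df))
  need <- c("patient_id", "diagnosis", "phase", "features")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("reading table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$phase <- as.integer(df$phase)
  if (!all(df$phase %in% 1:3)) stop("phase must be 1, 2, or 3", call. = FALSE)
  if (!fused && !all(df$hand %in% c("left", "right"))) {
    stop("hand must be 'left' or 'right'", call. = FALSE)
  }
  df$features[is.na(df$features)] <- ""
  key <- if (fused) paste(df$patient_id, df$phase)
         else paste(df$patient_id, df$hand, df$phase)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, hand, phase) records", call. = FALSE)
  }
  acros <- unique(unlist(split_features(df$features)))
  bad <- setdiff(acros, foi_acronyms())
  if (length(bad)) {
    stop("unknown feature acronym(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  diag_map <- tapply(df$diagnosis, df$patient_id, function(d) length(unique(d)))
  if (any(diag_map > 1)) {
    stop("a patient carries more than one diagnosis", call. = FALSE)
  }
  class(df) <- c("reading_table", "data.frame")
  df
}

split_features <- function(s) {
  out <- strsplit(s, ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

#' Read / write the reading-table CSV dialect
#'
#' Columns `patient_id,diagnosis,hand,phase,features` with `features` a
#' semicolon-joined acronym list (empty allowed).
#'
#' @param path File path.
#' @return `read_reading_table()` returns a `reading_table`.
#' @export
read_reading_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$phase <- as.integer(df$phase)
  reading_table(df)
}

#' @rdname read_reading_table
#' @param readings A `reading_table`.
#' @export
write_reading_table <- function(readings, path) {
  utils::write.csv(as.data.frame(readings), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Fuse per-hand annotations
#'
#' The clinical diagnosis is independent of which hand is affected, so the
#' per-hand annotation sets are fused per (patient, phase) by set union and
#' the hand information is discarded.
#'
#' @param readings A per-hand `reading_table`.
#' @return A hand-fused `reading_table` (no `hand` column).
#' @export
fuse_hands <- function(readings) {
  stopifnot(inherits(readings, "reading_table"))
  if (!("hand" %in% names(readings))) return(readings)
  key <- paste(readings$patient_id, readings$phase, sep = "\r")
  sets <- split_features(readings$features)
  fused_sets <- tapply(sets, key, function(l) sort(unique(unlist(l))),
                       simplify = FALSE)
  first <- !duplicated(key)
  out <- data.frame(patient_id = readings$patient_id[first],
                    diagnosis = readings$diagnosis[first],
                    phase = readings$phase[first],
                    stringsAsFactors = FALSE)
  out$features <- vapply(paste(out$patient_id, out$phase, sep = "\r"),
                         function(k) paste(fused_sets[[k]], collapse = ";"),
                         "")
  out <- out[order(match(out$patient_id, unique(readings$patient_id)),
                   out$phase), ]
  rownames(out) <- NULL
  reading_table(out)
}

#' Encode a fused reading table as a binary feature matrix
#'
#' Produces the 20 acronyms x 3 phases = 60 binary feature-phase columns
#' (named acronym + phase, e.g. `"Y2"`), one row per patient, cell 1 iff the
#' feature was annotated in that phase.
#'
#' @param readings A hand-fused `reading_table`.
#' @return A `feature_table`: list with `x` (binary integer matrix with
#'   patient ids as rownames), `labels` (diagnosis per patient).
#' @export
encode_features <- function(readings) {
  stopifnot(inherits(readings, "reading_table"))
  if ("hand" %in% names(readings)) {
    stop("encode_features() expects a hand-fused table; call fuse_hands() first",
         call. = FALSE)
  }
  ids <- unique(readings$patient_id)
  feats <- foi_feature_names()
  x <- matrix(0L, length(ids), length(feats),
              dimnames = list(ids, feats))
  sets <- split_features(readings$features)
  for (r in seq_len(nrow(readings))) {
    acros <- sets[[r]]
    if (!length(acros)) next
    bad <- setdiff(acros, foi_acronyms())
    if (length(bad)) {
      stop("unknown feature acronym(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x[readings$patient_id[r], paste0(acros, readings$phase[r])] <- 1L
  }
  labels <- readings$diagnosis[!duplicated(readings$patient_id)]
  feature_table(x, setNames(labels, ids))
}

#' Feature-table container
#'
#' @param x Binary integer matrix, patients in rows (rownames = patient ids),
#'   feature-phase columns.
#' @param labels Diagnosis label per patient.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, labels) {
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)),
            length(labels) == nrow(x), !is.null(colnames(x)),
            !anyDuplicated(colnames(x)))
  structure(list(x = x, labels = as.character(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$x), "patients x", ncol(x$x), "features;",
      "classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Filter featureless patients and never-observed features
#'
#' Removes all-zero rows (patients with no annotation in any phase) first,
#' then all-zero columns (feature-phases never observed in the remaining
#' patients), mirroring the study's exclusions.
#'
#' @param table A `feature_table`.
#' @return List with `table` (filtered `feature_table`), `dropped_features`,
#'   `dropped_patients`.
#' @export
filter_feature_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  empty_rows <- rowSums(x) == 0L
  x2 <- x[!empty_rows, , drop = FALSE]
  labels2 <- table$labels[!empty_rows]
  empty_cols <- colSums(x2) == 0L
  x3 <- x2[, !empty_cols, drop = FALSE]
  if (nrow(x3) == 0L || ncol(x3) == 0L) {
    stop("feature table is empty after filtering", call. = FALSE)
  }
  list(table = feature_table(x3, labels2),
       dropped_features = colnames(x2)[empty_cols],
       dropped_patients = rownames(x)[empty_rows])
}

#' Write a feature table as TSV
#'
#' Columns: `patient_id`, `diagnosis`, then one 0/1 column per feature-phase.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(patient_id = rownames(table$x),
                   diagnosis = table$labels,
                   table$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
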