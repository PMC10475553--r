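# Feature universe for FOI hand readings: 20 one-letter acronyms read in each
# of three contrast-agent phases. Acronyms are case-sensitive ("r" and "R" are
# distinct findings, as are "a"/"A"-style codes in the source nomenclature).

#' Feature acronym universe
#'
#' The 20 one-letter codes for FOI image findings: joint-related (D, P, M, C,
#' O), finger-related (r, R), nail (a, I), venous vessel (V), connective
#' tissue (E, B, Y), skin (F, W), and the five additional reading codes
#' (H, S, T, U, Z). Codes are case-sensitive.
#'
#' @return Character vector of length 20.
#' @export
foi_acronyms <- function() {
  c("D", "P", "M", "C", "O", "r", "R", "a", "I", "V",
    "E", "B", "Y", "F", "W", "H", "S", "T", "U", "Z")
}

#' All feature-phase column names
#'
#' Each acronym is read in phases 1-3, giving 60 binary indicators named
#' acronym + phase digit (e.g. \code{"P2"}), ordered acronym-major.
#'
#' @return Character vector of length 60.
#' @export
foi_feature_names <- function() {
  as.vector(t(outer(foi_acronyms(), 1:3, paste0)))
}

#' Feature-phases never observed in the reference reading
#'
#' The 15 feature-phase indicators that were never annotated in the study
#' cohort and are dropped by filtering.
#'
#' @return Character vector of length 15.
#' @export
foi_zero_features <- function() {
  c("E1", "H1", "H2", "H3", "O1", "r2", "r3", "S2", "S3",
    "T1", "T2", "T3", "W1", "W2", "W3")
}

# split "P2" -> acronym "P", phase 2; vectorized, errors on unknown ids
parse_feature_id <- function(ids) {
  acro <- sub("[1-3]$", "", ids)
  phase <- suppressWarnings(as.integer(substr(ids, nchar(ids), nchar(ids))))
  bad <- !(acro %in% foi_acronyms()) | is.na(phase) | !(phase %in% 1:3) |
    nchar(ids) != nchar(acro) + 1L
  if (any(bad)) {
    stop("unknown feature id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(id = ids, acronym = acro, phase = phase,
             stringsAsFactors = FALSE)
}
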