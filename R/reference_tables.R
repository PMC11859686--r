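#' Bundled reference tables
#'
#' The package ships four small plain-text tables from a published Ayurvedic
#' formula screen, used as worked-example inputs and as fixtures for the
#' candidate-selection and overlap logic:
#'
#' * `reference_network_candidates()` — the network-branch candidate list
#'   (plant, formula-count support). Transcribed verbatim, including one
#'   duplicated plant name; deduplication is deliberately left to the
#'   normalizing intersection step.
#' * `reference_ml_importances()` — the ML-branch importance ranking (plant,
#'   permutation-importance weight).
#' * `reference_overlap_plants()` — the plants reported as nominated by both
#'   branches, used as the audit reference of [intersect_candidates()].
#' * `reference_plant_frequencies()` — the 40 most frequent plants with their
#'   formula counts, characterising the heavy-tailed frequency profile the
#'   synthetic generator emulates.
#'
#' @return A data frame (see above).
#' @name reference_tables
NULL

extdata <- function(name) {
  path <- system.file("extdata", name, package = "ayurnet")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  path
}

#' @rdname reference_tables
#' @export
reference_network_candidates <- function() {
  utils::read.delim(extdata("candidates_network.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_ml_importances <- function() {
  out <- utils::read.delim(extdata("candidates_ml.tsv"), stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @rdname reference_tables
#' @export
reference_overlap_plants <- function() {
  utils::read.delim(extdata("overlap_reference.tsv"), stringsAsFactors = FALSE)$plant_name
}

#' @rdname reference_tables
#' @export
reference_plant_frequencies <- function() {
  utils::read.delim(extdata("plant_frequencies.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
default_synonyms <- function() {
  df <- utils::read.csv(extdata("plant_synonyms.csv"), stringsAsFactors = FALSE)
  stats::setNames(df$canonical, df$variant)
}
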