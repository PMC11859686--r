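#' Plant-name normalizer
#'
#' Botanical names in compiled formula corpora arrive with inconsistent case,
#' stray whitespace and outright misspellings (the bundled candidate tables
#' contain, e.g., "Tenninalia chebula" for *Terminalia chebula*). The
#' normalizer case-folds to "Genus species" form, collapses whitespace, and
#' applies an explicit synonym/typo map. It is idempotent: canonical forms
#' normalize to themselves.
#'
#' @param synonyms Named character vector mapping folded variant -> canonical
#'   form; defaults to the map shipped in `extdata/plant_synonyms.csv`.
#' @return An object of class `name_normalizer`.
#' @export
name_normalizer <- function(synonyms = default_synonyms()) {
  canon <- vapply(unname(synonyms), fold_name, character(1))
  names(canon) <- vapply(names(synonyms), fold_name, character(1))
  # idempotence requires canonical forms not to map onwards
  chained <- intersect(names(canon), unname(canon))
  chained <- chained[canon[chained] != chained]
  if (length(chained)) {
    stop("synonym map is not idempotent; chained variants: ",
         paste(chained, collapse = ", "))
  }
  structure(list(synonyms = canon), class = "name_normalizer")
}

fold_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x <- tolower(x)
  if (nchar(x) > 0) {
    substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  }
  x
}

#' Normalize a plant name
#'
#' Collapses whitespace, folds case to "Genus species" form, then applies the
#' normalizer's synonym map. Unknown names pass through folded.
#'
#' @param raw Character vector of raw names.
#' @param normalizer A [name_normalizer()].
#' @return Canonical character vector, same length as `raw`.
#' @export
normalize_name <- function(raw, normalizer = name_normalizer()) {
  folded <- vapply(raw, fold_name, character(1), USE.NAMES = FALSE)
  hit <- folded %in% names(normalizer$synonyms)
  folded[hit] <- unname(normalizer$synonyms[folded[hit]])
  folded
}

#' Intersect the network- and ML-branch candidate tables
#'
#' Final candidates are the plants nominated by both branches. Names are
#' canonicalized before matching; duplicated names within one input (possible
#' in verbatim transcriptions of published tables) are collapsed to their
#' maximum support. When a `reference` plant list is supplied, an
#' `in_reference` column flags intersection members absent from it — such
#' members are surfaced for audit, never silently dropped.
#'
#' @param network Data frame with `plant_name` and `support` (formula counts).
#' @param ml Data frame with `plant_name` and `support` or `weight`
#'   (importance weights).
#' @param normalizer A [name_normalizer()].
#' @param reference Optional character vector of expected overlap plants
#'   (normalized with the same normalizer before comparison).
#' @return Data frame of class `overlap_table`: `plant_name`,
#'   `network_support`, `ml_weight`, `branch = "overlap"`, and `in_reference`
#'   when a reference was given; sorted by decreasing ML weight.
#' @export
intersect_candidates <- function(network, ml, normalizer = name_normalizer(),
                                 reference = NULL) {
  if (nrow(network) == 0 || nrow(ml) == 0) stop("both candidate tables must be non-empty")
  get_support <- function(tbl) {
    if ("support" %in% names(tbl)) tbl$support else tbl$weight
  }
  collapse <- function(tbl) {
    nm <- normalize_name(tbl$plant_name, normalizer)
    sup <- get_support(tbl)
    agg <- tapply(sup, nm, max)
    data.frame(plant_name = names(agg), support = as.numeric(agg),
               stringsAsFactors = FALSE)
  }
  a <- collapse(network)
  b <- collapse(ml)
  common <- intersect(a$plant_name, b$plant_name)
  out <- data.frame(
    plant_name = common,
    network_support = a$support[match(common, a$plant_name)],
    ml_weight = b$support[match(common, b$plant_name)],
    branch = if (length(common)) "overlap" else character(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    out$in_reference <- out$plant_name %in% normalize_name(reference, normalizer)
  }
  out <- out[order(-out$ml_weight, out$plant_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("overlap_table", "data.frame")
  out
}
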