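#' Construct a formula dataset
#'
#' The central data container of the package: a binary incidence matrix of
#' traditional-medicine formulae (rows) by medicinal plants (columns), plus a
#' binary class label per formula (1 = formula indicated for bacterial
#' infection, the "antibiotic class"; 0 otherwise).
#'
#' @param matrix Integer or logical matrix with entries in \{0, 1\}; row names
#'   are formula ids, column names plant names.
#' @param labels Integer vector of 0/1 labels, one per row of `matrix`, named
#'   by formula id (names optional; matched positionally if absent).
#' @param provenance Free-text description of where the data came from
#'   (generator configuration digest or source file path).
#' @param signal_plants Optional character vector of planted "signal" plant
#'   names (known ground truth, only meaningful for synthetic data).
#'
#' @return An object of class `formula_dataset`: a list with elements
#'   `matrix`, `labels`, `plant_names`, `formula_ids`, `provenance`,
#'   `signal_plants`.
#' @export
formula_dataset <- function(matrix, labels, provenance = "",
                            signal_plants = character()) {
  if (!is.matrix(matrix)) stop("`matrix` must be a matrix")
  storage.mode(matrix) <- "integer"
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- sprintf("F%04d", seq_len(nrow(matrix)))
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("plant_%03d", seq_len(ncol(matrix)))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix)) {
    stop("`labels` must have one entry per formula (row)")
  }
  names(labels) <- rownames(matrix)
  ds <- structure(
    list(
      matrix = matrix,
      labels = labels,
      plant_names = colnames(matrix),
      formula_ids = rownames(matrix),
      provenance = provenance,
      signal_plants = signal_plants
    ),
    class = "formula_dataset"
  )
  validate_formula_dataset(ds)
  ds
}

#' Validate a formula dataset's invariants
#'
#' Checks binarity, label completeness, duplicate plant names and the
#' requirement that every formula contains at least one plant.
#'
#' @param ds A `formula_dataset`.
#' @return `ds`, invisibly; stops on violation.
#' @export
validate_formula_dataset <- function(ds) {
  if (!inherits(ds, "formula_dataset")) stop("not a formula_dataset")
  m <- ds$matrix
  if (!all(m %in% c(0L, 1L))) stop("matrix entries must be 0 or 1")
  if (anyNA(ds$labels) || !all(ds$labels %in% c(0L, 1L))) {
    stop("every formula needs a 0/1 class label")
  }
  if (anyDuplicated(ds$plant_names)) stop("duplicate plant names")
  if (anyDuplicated(ds$formula_ids)) stop("duplicate formula ids")
  if (any(rowSums(m) < 1)) stop("every formula must contain at least one plant")
  invisible(ds)
}

#' @export
print.formula_dataset <- function(x, ...) {
  cat(sprintf(
    "<formula_dataset> %d formulae x %d plants; %d in antibiotic class (%.1f%%)\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$labels),
    100 * mean(x$labels)
  ))
  if (length(x$signal_plants)) {
    cat(sprintf("  planted signal plants: %d\n", length(x$signal_plants)))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Per-plant occurrence frequencies
#'
#' Counts, for each plant, the number of formulae containing it — the
#' frequency-distribution summary used to characterise how heavy-tailed a
#' formula corpus is (a few staple plants appear in a large share of
#' formulae, most appear rarely).
#'
#' @param dataset A `formula_dataset`.
#' @return A data frame with columns `plant_name` and `frequency`, sorted by
#'   decreasing frequency (ties broken alphabetically).
#' @export
plant_frequency <- function(dataset) {
  validate_formula_dataset(dataset)
  freq <- colSums(dataset$matrix)
  out <- data.frame(
    plant_name = names(freq),
    frequency = as.integer(freq),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$plant_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
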