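#' Score a cluster by antibiotic-class composition
#'
#' The cluster score is the fraction of its member formulae labelled
#' antibiotic class: n_class1 / n_members. Clusters with a high score are
#' candidates for nominating antibacterial plants.
#'
#' @param members Character vector of formula ids (one cluster's members).
#' @param labels Named 0/1 vector of formula labels.
#' @return A one-row data frame: `score`, `n_members`, `n_class1`.
#' @export
cluster_score <- function(members, labels) {
  if (!all(members %in% names(labels))) {
    stop("cluster member without a label: ",
         paste(setdiff(members, names(labels)), collapse = ", "))
  }
  n1 <- sum(labels[members] == 1L)
  data.frame(score = n1 / length(members), n_members = length(members),
             n_class1 = n1)
}

#' Score all clusters and select the antibiotic-dominant ones
#'
#' Applies [cluster_score()] to every cluster and keeps those with
#' score strictly above `min_score` and at least `min_size` members, sorted by
#' score, then size, then generation index. The default `min_score = 0.5`
#' reads dominance as a strict class-1 majority vote.
#'
#' @param clustering A `dpcluso_clustering`.
#' @param labels Named 0/1 label vector covering all members.
#' @param min_score Strict lower bound on the score. Default 0.5.
#' @param min_size Minimum cluster size. Default 2.
#' @return Data frame with columns `cluster`, `score`, `n_members`,
#'   `n_class1` and a list-column `members`; zero rows if nothing qualifies.
#' @export
select_dominant <- function(clustering, labels, min_score = 0.5, min_size = 2L) {
  mem <- cluster_members(clustering)
  sc <- do.call(rbind, lapply(mem, cluster_score, labels = labels))
  sc$cluster <- seq_along(mem)
  sc$members <- mem
  keep <- sc$score > min_score & sc$n_members >= min_size
  out <- sc[keep, c("cluster", "score", "n_members", "n_class1", "members"),
            drop = FALSE]
  out <- out[order(-out$score, -out$n_members, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract network-branch candidate plants from dominant clusters
#'
#' For every plant, the support is the number of distinct formulae belonging
#' to at least one dominant cluster that contain the plant. Plants with
#' support >= `min_formula_count` become network-branch candidates — recurring
#' presence across several formulae of antibiotic-dominant clusters, rather
#' than a single co-occurrence, is what nominates a plant.
#'
#' @param dominant Output of [select_dominant()].
#' @param dataset The `formula_dataset` the clusters refer to.
#' @param min_formula_count Minimum distinct-formula support. Default 2.
#' @return A [candidate_table()] with `branch = "network"`.
#' @export
extract_network_candidates <- function(dominant, dataset, min_formula_count = 2L) {
  validate_formula_dataset(dataset)
  ids <- unique(unlist(dominant$members))
  if (length(ids) == 0) {
    return(candidate_table(character(), numeric(), "network"))
  }
  if (!all(ids %in% dataset$formula_ids)) {
    stop("dominant clusters reference formulae absent from the dataset")
  }
  support <- colSums(dataset$matrix[ids, , drop = FALSE])
  keep <- support >= min_formula_count
  candidate_table(names(support)[keep], as.numeric(support[keep]), "network")
}

#' Filter a network-branch candidate table by support
#'
#' Keeps rows whose formula-count support meets `min_formula_count`. Accepts
#' any data frame with `plant_name` and `support` columns (including verbatim
#' transcriptions of published candidate lists, which may contain duplicated
#' names); rows are returned in decreasing support order without
#' deduplication.
#'
#' @param tbl Data frame with `plant_name` and `support`.
#' @param min_formula_count Minimum support to retain. Default 2.
#' @return The filtered data frame.
#' @export
select_network_candidates <- function(tbl, min_formula_count = 2L) {
  stopifnot(all(c("plant_name", "support") %in% names(tbl)))
  out <- tbl[tbl$support >= min_formula_count, , drop = FALSE]
  out <- out[order(-out$support, out$plant_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
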