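#' Minkowski distance between two vectors
#'
#' d_p(x, y) = (sum_i |x_i - y_i|^p)^(1/p). p = 1 gives Manhattan distance,
#' p = 2 Euclidean. On binary presence/absence vectors this equals
#' H^(1/p) where H is the Hamming distance, which is why a distance
#' threshold of 1.5 at p = 2 connects exactly the formula pairs differing in
#' at most two plants (sqrt(2) < 1.5 < sqrt(3)).
#'
#' @param x,y Numeric vectors of equal length.
#' @param p Order, a real number >= 1.
#' @return Non-negative scalar distance.
#' @export
minkowski_distance <- function(x, y, p = 2) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (!is.numeric(p) || length(p) != 1 || p < 1) stop("p must be a single real >= 1")
  sum(abs(x - y)^p)^(1 / p)
}

#' Build the formula-similarity network
#'
#' Computes all pairwise Minkowski distances between the binary formula rows
#' and places an edge between every pair whose distance falls strictly below
#' the threshold. The node set is all formulae; isolates are kept (the
#' clustering stage guarantees every node a cluster). Edges carry weight 1 by
#' default; the `"similarity"` weighting sets weight = threshold - distance,
#' making near-duplicate formulae heavier for seed selection.
#'
#' @param dataset A `formula_dataset`.
#' @param p Minkowski order (default 2, Euclidean).
#' @param threshold Strict distance cutoff for an edge (default 1.5).
#' @param edge_weighting `"unit"` (default) or `"similarity"`.
#' @return An undirected igraph whose vertices are formula ids, with a
#'   `weight` edge attribute and graph attributes `p` and `threshold`.
#' @export
build_network <- function(dataset, p = 2, threshold = 1.5,
                          edge_weighting = c("unit", "similarity")) {
  validate_formula_dataset(dataset)
  edge_weighting <- match.arg(edge_weighting)
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (nrow(dataset$matrix) == 0) stop("empty dataset")
  d <- stats::dist(dataset$matrix, method = "minkowski", p = p)
  n <- nrow(dataset$matrix)
  ids <- dataset$formula_ids
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  dm <- as.matrix(d)
  hit <- which(upper.tri(dm) & dm < threshold, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    w <- if (edge_weighting == "unit") rep(1, nrow(hit)) else threshold - dm[hit]
    g <- igraph::add_edges(g, rbind(ids[hit[, 1]], ids[hit[, 2]]), weight = w)
  }
  g <- igraph::set_graph_attr(g, "p", p)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}
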