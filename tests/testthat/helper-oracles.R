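# Independent oracles and small fixture builders shared across tests.

# Minkowski distance evaluated term by term, independent of the package path.
brute_minkowski <- function(x, y, p) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[[i]] - y[[i]])^p
  s^(1 / p)
}

random_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p_edge)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    g
  })
}

# two 4-cliques sharing node "d"
two_clique_graph <- function() {
  pairs <- rbind(t(utils::combn(c("a", "b", "c", "d"), 2)),
                 t(utils::combn(c("d", "e", "f", "g"), 2)))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::simplify(g)
}

small_graph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (!is.null(nodes)) {
    g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                              name = setdiff(nodes, igraph::V(g)$name))
  }
  g
}

# dataset with hand-set incidence and labels
toy_dataset <- function(mat, labels, plants = NULL, ids = NULL) {
  if (!is.null(plants)) colnames(mat) <- plants
  if (!is.null(ids)) rownames(mat) <- ids
  formula_dataset(mat, labels)
}

write_formula_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
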