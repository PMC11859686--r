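#' Clustering parameters for the overlapping density clustering
#'
#' @param density_threshold Minimum density a cluster must keep while growing,
#'   in (0, 1]. Default 0.5.
#' @param cp_threshold Minimum cluster property a node must have to be
#'   admitted, in (0, 1]. Default 0.4.
#' @param overlap_threshold Maximum allowed overlap fraction between a new
#'   cluster and any accepted cluster, in [0, 1). Default 0.1.
#' @param min_cluster_size Smallest acceptable grown cluster. Default 2.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(density_threshold = 0.5,
                              cp_threshold = 0.4,
                              overlap_threshold = 0.1,
                              min_cluster_size = 2L) {
  if (density_threshold <= 0 || density_threshold > 1) stop("density_threshold must be in (0,1]")
  if (cp_threshold <= 0 || cp_threshold > 1) stop("cp_threshold must be in (0,1]")
  if (overlap_threshold < 0 || overlap_threshold >= 1) stop("overlap_threshold must be in [0,1)")
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  structure(
    list(density_threshold = density_threshold, cp_threshold = cp_threshold,
         overlap_threshold = overlap_threshold,
         min_cluster_size = as.integer(min_cluster_size)),
    class = "clustering_params"
  )
}

#' Density of a node set in a graph
#'
#' 2|E_in| / (|N| (|N| - 1)) where E_in are the edges with both endpoints in
#' the set; 1 by convention for singletons.
#'
#' @param members Character vector of node names.
#' @param graph An igraph.
#' @return Density in [0, 1].
#' @export
cluster_density <- function(members, graph) {
  if (length(members) == 0) stop("empty member set")
  if (length(members) == 1) return(1)
  sub <- igraph::induced_subgraph(graph, members)
  n <- length(members)
  2 * igraph::ecount(sub) / (n * (n - 1))
}

#' Cluster property of a node relative to a cluster
#'
#' The number of edges from `node` into `members`, normalized by cluster
#' density times cluster size: |E_node->members| / (density(members) * |N|).
#' Gates the admission of periphery nodes during cluster growth.
#'
#' @param node A node name, not already a member.
#' @param members Non-empty character vector of member node names.
#' @param graph An igraph.
#' @return Non-negative real.
#' @export
cluster_property <- function(node, members, graph) {
  if (node %in% members) stop("node is already a cluster member")
  if (length(members) == 0) stop("empty member set")
  nbrs <- igraph::neighbors(graph, node)$name
  k <- sum(members %in% nbrs)
  k / (cluster_density(members, graph) * length(members))
}

#' Overlap fraction between a candidate cluster and an existing one
#'
#' |candidate intersect existing| / |candidate|.
#'
#' @param candidate,existing Character vectors of node names.
#' @return Fraction in [0, 1].
#' @export
overlap_fraction <- function(candidate, existing) {
  length(intersect(candidate, existing)) / length(candidate)
}

#' Overlapping density-based graph clustering (DPClusO)
#'
#' Grows clusters from high-weight seeds and removes covered edges until none
#' remain, guaranteeing every node at least one cluster. The procedure, on
#' the remaining graph (edges inside accepted clusters are deleted as they
#' are covered):
#'
#' 1. **Seed.** Among nodes incident to remaining edges — preferring nodes not
#'    yet in any cluster while such candidates exist — pick the node with the
#'    largest total incident remaining edge weight; ties by remaining degree,
#'    then lexicographically by node id. (With unit weights the weight rule
#'    and the degree rule coincide.)
#' 2. **Grow.** Rank the cluster's outside neighbours by total connection
#'    weight to members, ties by remaining degree, then node id; admit the
#'    first whose admission keeps density >= `density_threshold` and whose
#'    cluster property is >= `cp_threshold`; repeat until no neighbour is
#'    admissible.
#' 3. **Accept or reject.** Accept the grown cluster iff its overlap fraction
#'    with every accepted cluster is <= `overlap_threshold` (and it reaches
#'    `min_cluster_size`); on acceptance delete every remaining edge with both
#'    endpoints inside it. On rejection the seed loses eligibility for the
#'    current round.
#' 4. **Termination guard.** If a whole round of eligible seeds produces only
#'    rejections (possible when all remaining structure overlaps accepted
#'    clusters beyond the threshold), the internal remaining edges of that
#'    round's rejected candidates are deleted before the next round, so the
#'    edge count strictly decreases and the loop always terminates.
#' 5. When no edges remain, every never-clustered node is emitted as a
#'    singleton cluster (density 1 by convention).
#'
#' The output is deterministic: all tie-breaks are total orders.
#'
#' @param graph An undirected igraph with named vertices; an optional `weight`
#'   edge attribute is used for seeding and growth priorities.
#' @param params A [clustering_params()].
#' @return An object of class `dpcluso_clustering`: list with `clusters` (each
#'   a list with `members`, `density` — on the remaining graph at acceptance
#'   time —, `seed`, `order`), `params`, and `graph_digest`.
#' @export
run_dpcluso <- function(graph, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) stop("graph vertices must be named")
  n <- length(nodes)
  # dense symmetric weight matrix of the remaining graph; fine at pipeline scale
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(graph)
  if (nrow(el) > 0) {
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    W[cbind(el[, 1], el[, 2])] <- w
    W[cbind(el[, 2], el[, 1])] <- w
  }
  diag(W) <- 0
  lex <- order(nodes)                     # lex rank used for final tie-breaks
  lexrank <- integer(n); lexrank[lex] <- seq_len(n)

  dens <- function(idx) {                 # density on remaining graph
    k <- length(idx)
    if (k == 1) return(1)
    sum(W[idx, idx] > 0) / (k * (k - 1))  # symmetric matrix counts each edge twice
  }

  clustered <- rep(FALSE, n)
  clusters <- list()
  ord <- 0L

  while (any(W > 0)) {
    round_ineligible <- rep(FALSE, n)
    rejected <- list()
    accepted_this_round <- FALSE
    repeat {
      strength <- rowSums(W)
      degree <- rowSums(W > 0)
      elig <- strength > 0 & !round_ineligible
      if (!any(elig)) break
      cand <- which(elig & !clustered)
      if (length(cand) == 0) cand <- which(elig)
      # highest weight, then highest degree, then lexicographically first id
      o <- cand[order(-strength[cand], -degree[cand], lexrank[cand])]
      seed <- o[1]

      members <- seed
      repeat {
        conn <- colSums(W[members, , drop = FALSE])
        nbr <- setdiff(which(conn > 0), members)
        if (length(nbr) == 0) break
        nbr <- nbr[order(-conn[nbr], -degree[nbr], lexrank[nbr])]
        cur_dens <- dens(members)
        admitted <- FALSE
        for (v in nbr) {
          cp <- sum(W[v, members] > 0) / (cur_dens * length(members))
          if (cp < params$cp_threshold) next
          if (dens(c(members, v)) < params$density_threshold) next
          members <- c(members, v)
          admitted <- TRUE
          break
        }
        if (!admitted) break
      }

      ok <- length(members) >= params$min_cluster_size &&
        all(vapply(clusters, function(cl) {
          overlap_fraction(nodes[members], cl$members) <= params$overlap_threshold
        }, logical(1)))
      if (ok) {
        ord <- ord + 1L
        clusters[[ord]] <- list(
          members = sort(nodes[members]),
          density = dens(members),
          seed = nodes[seed],
          order = ord
        )
        W[members, members] <- 0
        clustered[members] <- TRUE
        accepted_this_round <- TRUE
        break                            # edge removal ends the round
      } else {
        round_ineligible[seed] <- TRUE
        rejected[[length(rejected) + 1L]] <- members
      }
    }
    if (!accepted_this_round) {
      if (length(rejected) == 0) break   # cannot happen: edges imply eligible seeds
      for (m in rejected) W[m, m] <- 0   # guard: drop redundant covered structure
    }
  }

  for (v in which(!clustered)) {
    ord <- ord + 1L
    clusters[[ord]] <- list(members = nodes[v], density = 1,
                            seed = nodes[v], order = ord)
  }

  structure(
    list(clusters = clusters, params = params,
         graph_digest = rlang::hash(list(sort(nodes), el_canonical(graph)))),
    class = "dpcluso_clustering"
  )
}

el_canonical <- function(graph) {
  el <- igraph::as_edgelist(graph)
  if (nrow(el) == 0) return(el)
  swap <- el[, 1] > el[, 2]
  tmp <- el[swap, 1]; el[swap, 1] <- el[swap, 2]; el[swap, 2] <- tmp
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

#' @export
print.dpcluso_clustering <- function(x, ...) {
  sizes <- lengths(lapply(x$clusters, `[[`, "members"))
  cat(sprintf("<dpcluso_clustering> %d clusters (%d multi-node, %d singletons)\n",
              length(x$clusters), sum(sizes > 1), sum(sizes == 1)))
  invisible(x)
}

#' Members of every cluster
#'
#' @param clustering A `dpcluso_clustering`.
#' @return List of character vectors of node ids.
#' @export
cluster_members <- function(clustering) {
  lapply(clustering$clusters, `[[`, "members")
}
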