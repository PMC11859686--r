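#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations with a single global seed. The seed
#' is expanded into fixed per-stage substreams (simulation, ML, importance
#' permutations) so each stage is reproducible independently of execution
#' order.
#'
#' @param generator A [generator_config()]; its own seed is overridden by the
#'   pipeline substream.
#' @param network List with `p`, `threshold`, `edge_weighting`.
#' @param clustering A [clustering_params()].
#' @param voting List with `min_score`, `min_size`, `min_formula_count`.
#' @param ml An [ml_config()]; its seed is overridden by the pipeline
#'   substream.
#' @param rf_params Random-forest parameters for the importance ranking
#'   (defaults: 50 trees, depth 15, min leaf 5, min split 5); set
#'   `tune = TRUE` to grid-search them instead.
#' @param tune Run [tune_rf()] over `ml$rf_grid` before ranking. Default
#'   FALSE.
#' @param compare Run the full seven-model comparison (slowest stage).
#'   Default FALSE.
#' @param output_dir Directory for stage artifacts.
#' @param seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            network = list(p = 2, threshold = 1.5,
                                           edge_weighting = "unit"),
                            clustering = clustering_params(),
                            voting = list(min_score = 0.5, min_size = 2L,
                                          min_formula_count = 2L),
                            ml = ml_config(),
                            rf_params = list(n_trees = 50L, max_depth = 15L,
                                             min_leaf = 5L, min_split = 5L),
                            tune = FALSE,
                            compare = FALSE,
                            output_dir = tempfile("ayurnet_run_"),
                            seed = 1L) {
  structure(
    list(generator = generator, network = network, clustering = clustering,
         voting = voting, ml = ml, rf_params = rf_params, tune = tune,
         compare = compare, output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}

#' Run the full two-branch screening pipeline
#'
#' Executes, in order: data simulation (or ingestion), similarity-network
#' construction, overlapping clustering, cluster voting and network-branch
#' candidate extraction, the ML branch (optional tuning/model comparison,
#' permutation-importance ranking, threshold selection), and the final
#' normalized intersection of the two branches. Every artifact is written to
#' `config$output_dir` as delimited text and checksummed; identical
#' config + seed reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional pre-loaded `formula_dataset`; when supplied the
#'   simulation stage is skipped.
#' @return A list of class `pipeline_manifest`: artifact paths and MD5
#'   checksums, per-stage summaries, the seed, and the resolved parameters.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  save_art <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    art[[name]] <<- path
    path
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------------
  ds <- run_stage("simulate", {
    if (is.null(dataset)) {
      gc_ <- config$generator
      gc_$seed <- stage_seed(config$seed, 101L)
      generate_dataset(gc_)
    } else {
      validate_formula_dataset(dataset)
      dataset
    }
  })
  save_art("dataset.csv", function(p) write_formula_table(ds, p))

  # -- network ----------------------------------------------------------------
  net <- run_stage("network", build_network(
    ds, p = config$network$p, threshold = config$network$threshold,
    edge_weighting = config$network$edge_weighting %||% "unit"
  ))
  save_art("network.adj", function(p) write_adjacency_list(net, p))

  # -- cluster ----------------------------------------------------------------
  clustering <- run_stage("cluster", run_dpcluso(net, config$clustering))
  save_art("clusters.tsv", function(p) {
    df <- data.frame(
      cluster = vapply(clustering$clusters, `[[`, integer(1), "order"),
      density = vapply(clustering$clusters, `[[`, numeric(1), "density"),
      seed = vapply(clustering$clusters, `[[`, character(1), "seed"),
      members = vapply(clustering$clusters,
                       function(cl) paste(cl$members, collapse = " "),
                       character(1))
    )
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- vote -------------------------------------------------------------------
  dominant <- run_stage("vote", select_dominant(
    clustering, ds$labels,
    min_score = config$voting$min_score, min_size = config$voting$min_size
  ))
  net_candidates <- run_stage("vote", extract_network_candidates(
    dominant, ds, min_formula_count = config$voting$min_formula_count
  ))
  save_art("candidates_network.csv",
           function(p) write_candidate_table(net_candidates, p))

  # -- ml ---------------------------------------------------------------------
  mlc <- config$ml
  mlc$seed <- stage_seed(config$seed, 211L)
  comparison <- if (isTRUE(config$compare)) {
    run_stage("ml", compare_models(ds, mlc))
  } else NULL
  rf_params <- if (isTRUE(config$tune)) {
    run_stage("ml", tune_rf(ds, mlc))$params
  } else config$rf_params
  importances <- run_stage("ml", importance_ranking(ds, rf_params, mlc))
  save_art("importances.csv",
           function(p) utils::write.csv(importances, p, row.names = FALSE))
  ml_candidates <- run_stage("ml", select_ml_candidates(
    importances, threshold = mlc$importance_threshold
  ))
  save_art("candidates_ml.csv",
           function(p) write_candidate_table(ml_candidates, p))
  sensitivity <- run_stage("ml", threshold_sensitivity(importances, config = mlc))
  save_art("threshold_sensitivity.csv",
           function(p) utils::write.csv(sensitivity, p, row.names = FALSE))

  # -- overlap ----------------------------------------------------------------
  overlap <- run_stage("overlap", {
    if (nrow(net_candidates) == 0 || nrow(ml_candidates) == 0) {
      data.frame(plant_name = character(), network_support = numeric(),
                 ml_weight = numeric(), branch = character())
    } else {
      intersect_candidates(net_candidates, ml_candidates)
    }
  })
  save_art("candidates_overlap.csv",
           function(p) utils::write.csv(overlap, p, row.names = FALSE))

  checksums <- tools::md5sum(unlist(art))
  structure(
    list(
      artifacts = unlist(art),
      checksums = checksums,
      seed = config$seed,
      params_digest = rlang::hash(config[setdiff(names(config), "output_dir")]),
      summary = list(
        n_formulae = nrow(ds$matrix),
        n_plants = ncol(ds$matrix),
        n_edges = igraph::ecount(net),
        n_clusters = length(clustering$clusters),
        n_multinode_clusters = sum(lengths(cluster_members(clustering)) > 1),
        n_dominant = nrow(dominant),
        n_network_candidates = nrow(net_candidates),
        n_ml_candidates = nrow(ml_candidates),
        n_overlap = nrow(overlap)
      ),
      comparison = comparison,
      rf_params = rf_params,
      dataset = ds,
      network_candidates = net_candidates,
      ml_candidates = ml_candidates,
      importances = importances,
      overlap = overlap
    ),
    class = "pipeline_manifest"
  )
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<pipeline_manifest> seed %d\n",
           "  %d formulae x %d plants; %d edges; %d clusters (%d multi-node, %d dominant)\n",
           "  candidates: %d network, %d ml, %d overlap\n"),
    x$seed, s$n_formulae, s$n_plants, s$n_edges, s$n_clusters,
    s$n_multinode_clusters, s$n_dominant,
    s$n_network_candidates, s$n_ml_candidates, s$n_overlap
  ))
  invisible(x)
}
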