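#' Machine-learning branch configuration
#'
#' Gathers every tunable of the ML arm: feature filtering, PCA, SMOTE,
#' cross-validated model comparison, random-forest grid search and
#' permutation-importance candidate selection.
#'
#' @param variance_min Columns with variance below this are dropped by
#'   [filter_features()]. Default 0.005 — for a 0/1 column this removes plants
#'   present in roughly one formula in several hundred, the "little predictive
#'   power" tail.
#' @param missing_cap Columns with a higher fraction of missing cells are
#'   dropped. Default 0.5 (binary incidence data normally has none).
#' @param pca_variance_target Retain the smallest number of principal
#'   components whose cumulative explained variance reaches this. Default 0.95.
#' @param pca_components Optional fixed component count overriding the
#'   variance target (e.g. 146, about half the default plant vocabulary).
#' @param smote_k Number of minority-class nearest neighbours SMOTE
#'   interpolates towards. Default 5.
#' @param cv_folds Stratified cross-validation folds. Default 5.
#' @param cv_repeats Repeats of the whole CV split. Default 1.
#' @param rf_grid Data frame of random-forest configurations with columns
#'   `n_trees`, `max_depth`, `min_leaf`, `min_split`. The default grid spans
#'   50/100 trees, depth 10/15, leaf 1/5, split 2/5.
#' @param importance_threshold Strict lower bound on permutation-importance
#'   weight for a plant to become an ML candidate. Default 0.01.
#' @param sensitivity_range Threshold interval swept by
#'   [threshold_sensitivity()]; must contain `importance_threshold`.
#'   Default c(0.005, 0.02).
#' @param importance_repeats Permutations per column when estimating
#'   importance. Default 5.
#' @param importance_trees Minimum ensemble size for the importance fit.
#'   Default 500. Tree count is not a tuned complexity parameter — growing
#'   more trees never overfits a random forest — but small ensembles make
#'   permutation importances noisy, so the importance stage enlarges the
#'   tuned forest to at least this many trees.
#' @param seed Integer RNG seed for folds, SMOTE, model fits and permutations.
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(variance_min = 0.005,
                      missing_cap = 0.5,
                      pca_variance_target = 0.95,
                      pca_components = NULL,
                      smote_k = 5L,
                      cv_folds = 5L,
                      cv_repeats = 1L,
                      rf_grid = expand.grid(n_trees = c(50L, 100L),
                                            max_depth = c(10L, 15L),
                                            min_leaf = c(1L, 5L),
                                            min_split = c(2L, 5L)),
                      importance_threshold = 0.01,
                      sensitivity_range = c(0.005, 0.02),
                      importance_repeats = 5L,
                      importance_trees = 500L,
                      seed = 1L) {
  if (variance_min < 0) stop("variance_min must be >= 0")
  if (pca_variance_target <= 0 || pca_variance_target > 1) {
    stop("pca_variance_target must be in (0, 1]")
  }
  if (smote_k < 1) stop("smote_k must be >= 1")
  if (importance_threshold <= 0) stop("importance_threshold must be positive")
  if (importance_threshold < sensitivity_range[1] ||
      importance_threshold > sensitivity_range[2]) {
    stop("sensitivity_range must contain importance_threshold")
  }
  structure(
    list(variance_min = variance_min, missing_cap = missing_cap,
         pca_variance_target = pca_variance_target,
         pca_components = pca_components,
         smote_k = as.integer(smote_k), cv_folds = as.integer(cv_folds),
         cv_repeats = as.integer(cv_repeats), rf_grid = rf_grid,
         importance_threshold = importance_threshold,
         sensitivity_range = sensitivity_range,
         importance_repeats = as.integer(importance_repeats),
         importance_trees = as.integer(importance_trees),
         seed = as.integer(seed)),
    class = "ml_config"
  )
}

#' Drop low-variance or missing-ridden plant columns
#'
#' Removes plant columns whose variance falls below `config$variance_min` or
#' whose missing-value fraction exceeds `config$missing_cap`. Labels are never
#' dropped. Filtered datasets may contain formulae with no remaining plants;
#' they are kept so that row indexing stays aligned with the labels.
#'
#' @param dataset A `formula_dataset`.
#' @param config An [ml_config()].
#' @return A `formula_dataset` on the surviving columns, with attribute
#'   `dropped` listing removed plant names.
#' @export
filter_features <- function(dataset, config = ml_config()) {
  validate_formula_dataset(dataset)
  m <- dataset$matrix
  v <- apply(m, 2, stats::var)
  miss <- colMeans(is.na(m))
  keep <- v >= config$variance_min & miss <= config$missing_cap
  if (!any(keep)) stop("feature filtering dropped every column")
  out <- structure(
    list(matrix = m[, keep, drop = FALSE], labels = dataset$labels,
         plant_names = colnames(m)[keep], formula_ids = dataset$formula_ids,
         provenance = paste0(dataset$provenance, " | variance-filtered"),
         signal_plants = intersect(dataset$signal_plants, colnames(m)[keep])),
    class = "formula_dataset"
  )
  attr(out, "dropped") <- colnames(m)[!keep]
  out
}

#' Principal-component reduction
#'
#' Centres the feature matrix and projects it onto its leading principal
#' components: either the smallest set explaining at least
#' `config$pca_variance_target` of the total variance, or exactly
#' `config$pca_components` components when a fixed count is configured.
#'
#' @param x A numeric matrix or a `formula_dataset` (its incidence matrix is
#'   used).
#' @param config An [ml_config()].
#' @return List of class `pca_reduction`: `scores` (n x k), `k`,
#'   `explained` (per-component variance proportions, non-increasing),
#'   `cumulative` (cumulative proportion at k), and `fit` (the `prcomp`
#'   object, usable to project new data).
#' @export
reduce_pca <- function(x, config = ml_config()) {
  if (inherits(x, "formula_dataset")) x <- x$matrix
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  total <- sum(vars)
  if (total <= 0) stop("degenerate data: zero total variance")
  prop <- vars / total
  if (!is.null(config$pca_components)) {
    k <- as.integer(config$pca_components)
    if (k < 1 || k > ncol(fit$x)) {
      stop(sprintf("requested %d components but only %d are available",
                   k, ncol(fit$x)))
    }
  } else {
    k <- which(cumsum(prop) >= config$pca_variance_target)[1]
    if (is.na(k)) stop("variance target unreachable")
  }
  structure(
    list(scores = fit$x[, seq_len(k), drop = FALSE], k = k,
         explained = prop[seq_len(k)], cumulative = sum(prop[seq_len(k)]),
         fit = fit),
    class = "pca_reduction"
  )
}

project_pca <- function(reduction, newdata) {
  stats::predict(reduction$fit, newdata)[, seq_len(reduction$k), drop = FALSE]
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: new minority-class rows are convex
#' combinations x_i + u (x_j - x_i), u ~ U(0,1), of a minority sample x_i and
#' one of its `k` nearest minority neighbours x_j (Euclidean). Original rows
#' are preserved verbatim and classes end exactly balanced. Already-balanced
#' input is returned unchanged.
#'
#' @param features Numeric matrix.
#' @param labels 0/1 vector, one per row.
#' @param k Number of nearest neighbours. Default 5.
#' @param seed Optional seed making the augmentation deterministic.
#' @return List with `features`, `labels` and logical `synthetic` marking
#'   generated rows (originals first, in input order).
#' @export
balance_smote <- function(features, labels, k = 5L, seed = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (counts[1] == counts[2]) {
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features))))
  }
  minority <- as.integer(names(counts)[which.min(counts)])
  n_syn <- abs(diff(as.integer(counts)))
  idx_min <- which(labels == minority)
  if (length(idx_min) < k + 1) {
    stop(sprintf(
      "minority class has %d samples; SMOTE with k = %d needs at least %d. Use a smaller k.",
      length(idx_min), k, k + 1
    ))
  }
  xm <- features[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  ord <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)

  synth <- function() {
    base <- rep(seq_len(nrow(xm)), length.out = n_syn)
    pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  newx <- if (is.null(seed)) synth() else withr::with_seed(seed, synth())
  rownames(newx) <- NULL  # original rows keep their names/values verbatim
  list(
    features = rbind(features, newx),
    labels = c(labels, rep(minority, n_syn)),
    synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, n_syn))
  )
}

# deterministic stratified fold assignment: per class, shuffle and deal into k
stratified_folds <- function(labels, k, repeats, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep(seq_len(k), length.out = length(idx))
      }
      lapply(seq_len(k), function(f) which(fold == f))
    })
  })
}

ml_model_names <- function() {
  c("decision_tree", "naive_bayes", "gradient_boosting", "k_neighbors",
    "logistic_regression", "mlp", "random_forest")
}

# Fit one classifier and return 0/1 predictions for x_test. All models see
# the same numeric feature space (PC scores or binary incidence columns).
fit_and_predict <- function(model, x_train, y_train, x_test, seed = 1L,
                            rf_params = NULL) {
  y <- factor(y_train, levels = c(0L, 1L))
  pred <- withr::with_seed(seed, switch(
    model,
    decision_tree = {
      df <- data.frame(x_train); df$.y <- y
      fit <- rpart::rpart(.y ~ ., df, method = "class")
      stats::predict(fit, data.frame(x_test), type = "class")
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x_train, y)
      stats::predict(fit, x_test, type = "class")
    },
    gradient_boosting = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = xgboost::xgb.DMatrix(x_train, label = as.integer(y_train)),
        nrounds = 100, verbose = 0
      )
      as.integer(stats::predict(fit, xgboost::xgb.DMatrix(x_test)) > 0.5)
    },
    k_neighbors = class::knn(x_train, x_test, cl = y, k = 5),
    logistic_regression = {
      df <- data.frame(x_train); df$.y <- y
      fit <- suppressWarnings(stats::glm(.y ~ ., df, family = stats::binomial()))
      as.integer(suppressWarnings(
        stats::predict(fit, data.frame(x_test), type = "response")
      ) > 0.5)
    },
    mlp = {
      fit <- nnet::nnet(x_train, nnet::class.ind(y), size = 8, decay = 0.1,
                        maxit = 200, trace = FALSE, MaxNWts = 50000,
                        softmax = TRUE)
      c("0", "1")[max.col(stats::predict(fit, x_test))]
    },
    random_forest = {
      rp <- rf_params %||% list(n_trees = 100L, max_depth = 0L,
                                min_leaf = 1L, min_split = 1L)
      fit <- ranger::ranger(
        x = x_train, y = y, num.trees = rp$n_trees,
        max.depth = rp$max_depth, min.bucket = rp$min_leaf,
        min.node.size = rp$min_split, seed = seed, num.threads = 1
      )
      # predict is seeded: forest vote ties are otherwise broken with an
      # RNG draw, making repeated runs data-dependently nondeterministic
      stats::predict(fit, x_test, num.threads = 1, seed = seed)$predictions
    },
    stop("unknown model: ", model)
  ))
  as.integer(as.character(factor(pred, levels = c(0, 1), labels = c("0", "1"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fold preprocessing: variance filter and PCA are fitted on the
# training rows only; SMOTE augments only the training partition.
prepare_fold <- function(m, labels, train, test, variant, config) {
  xtr <- m[train, , drop = FALSE]
  xte <- m[test, , drop = FALSE]
  if (variant %in% c("filtering", "both")) {
    v <- apply(xtr, 2, stats::var)
    keep <- which(v >= config$variance_min)
    if (length(keep) < 2) keep <- order(-v)[1:2]
    xtr <- xtr[, keep, drop = FALSE]
    xte <- xte[, keep, drop = FALSE]
  }
  red <- reduce_pca(xtr, config)
  xtr <- red$scores
  xte <- project_pca(red, xte)
  ytr <- labels[train]
  if (variant %in% c("smote", "both")) {
    bal <- balance_smote(xtr, ytr, k = config$smote_k,
                         seed = config$seed + 7L * length(train))
    xtr <- bal$features
    ytr <- bal$labels
  }
  list(x_train = xtr, y_train = ytr, x_test = xte, y_test = labels[test])
}

#' Compare seven classifiers under three preprocessing variants
#'
#' Evaluates decision tree, naive Bayes, gradient boosting, k-nearest
#' neighbours, logistic regression, a multilayer perceptron and a random
#' forest by repeated stratified cross-validation under the preprocessing
#' variants `filtering` (variance filter + PCA), `smote` (PCA + SMOTE) and
#' `both`. By default all preprocessing is fitted inside training folds so
#' synthetic minority samples never leak into evaluation folds;
#' `leakage_safe = FALSE` reproduces the simpler (optimistically biased)
#' protocol of balancing the full dataset once before cross-validation.
#'
#' @param dataset A `formula_dataset`.
#' @param config An [ml_config()].
#' @param variants Subset of `c("filtering", "smote", "both")`.
#' @param models Subset of the seven model names (see `ml_model_names`).
#' @param leakage_safe Fit SMOTE inside training folds only. Default TRUE.
#' @return Data frame of class `accuracy_report`: `model`, `variant`,
#'   `mean_accuracy`, `sd_accuracy`, `n_evals` (folds x repeats).
#' @export
compare_models <- function(dataset, config = ml_config(),
                           variants = c("filtering", "smote", "both"),
                           models = ml_model_names(),
                           leakage_safe = TRUE) {
  validate_formula_dataset(dataset)
  variants <- match.arg(variants, c("filtering", "smote", "both"),
                        several.ok = TRUE)
  models <- match.arg(models, ml_model_names(), several.ok = TRUE)
  m <- dataset$matrix
  labels <- dataset$labels
  rows <- list()
  for (variant in variants) {
    if (leakage_safe) {
      folds <- stratified_folds(labels, config$cv_folds, config$cv_repeats,
                                config$seed)
      acc <- array(
        NA_real_, c(length(models), config$cv_folds * config$cv_repeats),
        dimnames = list(models, NULL)
      )
      i <- 0L
      for (rep_folds in folds) {
        for (test in rep_folds) {
          i <- i + 1L
          fold <- prepare_fold(m, labels, setdiff(seq_along(labels), test),
                               test, variant, config)
          for (mod in models) {
            pr <- fit_and_predict(mod, fold$x_train, fold$y_train,
                                  fold$x_test, seed = config$seed + i)
            acc[mod, i] <- mean(pr == fold$y_test)
          }
        }
      }
    } else {
      # global preprocessing before CV: historically common, leaks SMOTE rows
      xa <- m
      if (variant %in% c("filtering", "both")) {
        v <- apply(xa, 2, stats::var)
        xa <- xa[, v >= config$variance_min, drop = FALSE]
      }
      xa <- reduce_pca(xa, config)$scores
      ya <- labels
      if (variant %in% c("smote", "both")) {
        bal <- balance_smote(xa, ya, k = config$smote_k, seed = config$seed)
        xa <- bal$features
        ya <- bal$labels
      }
      folds <- stratified_folds(ya, config$cv_folds, config$cv_repeats,
                                config$seed)
      acc <- array(
        NA_real_, c(length(models), config$cv_folds * config$cv_repeats),
        dimnames = list(models, NULL)
      )
      i <- 0L
      for (rep_folds in folds) {
        for (test in rep_folds) {
          i <- i + 1L
          tr <- setdiff(seq_along(ya), test)
          for (mod in models) {
            pr <- fit_and_predict(mod, xa[tr, , drop = FALSE], ya[tr],
                                  xa[test, , drop = FALSE],
                                  seed = config$seed + i)
            acc[mod, i] <- mean(pr == ya[test])
          }
        }
      }
    }
    rows[[variant]] <- data.frame(
      model = models, variant = variant,
      mean_accuracy = rowMeans(acc),
      sd_accuracy = apply(acc, 1, stats::sd),
      n_evals = ncol(acc),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Grid-search tuning of the random forest
#'
#' Exhaustive search over `config$rf_grid` by stratified cross-validation
#' under the `both` preprocessing variant (variance filter + PCA + SMOTE in
#' training folds). Ties in mean accuracy are broken towards the smaller
#' model: fewer trees, then shallower depth, then larger leaf size.
#'
#' @param dataset A `formula_dataset`.
#' @param config An [ml_config()].
#' @return List with `params` (the best row, as a list), `cv_accuracy`, and
#'   `results` (the full grid with mean accuracies).
#' @export
tune_rf <- function(dataset, config = ml_config()) {
  validate_formula_dataset(dataset)
  grid <- config$rf_grid
  if (is.null(grid) || nrow(grid) == 0) stop("empty rf_grid")
  m <- dataset$matrix
  labels <- dataset$labels
  folds <- stratified_folds(labels, config$cv_folds, config$cv_repeats,
                            config$seed)
  prep <- list()
  i <- 0L
  for (rep_folds in folds) {
    for (test in rep_folds) {
      i <- i + 1L
      prep[[i]] <- prepare_fold(m, labels, setdiff(seq_along(labels), test),
                                test, "both", config)
    }
  }
  grid$mean_accuracy <- vapply(seq_len(nrow(grid)), function(g) {
    rp <- as.list(grid[g, c("n_trees", "max_depth", "min_leaf", "min_split")])
    mean(vapply(seq_along(prep), function(i) {
      f <- prep[[i]]
      pr <- fit_and_predict("random_forest", f$x_train, f$y_train, f$x_test,
                            seed = config$seed + i, rf_params = rp)
      mean(pr == f$y_test)
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-grid$mean_accuracy, grid$n_trees, grid$max_depth,
               -grid$min_leaf)
  best <- grid[ord[1], , drop = FALSE]
  list(
    params = list(n_trees = best$n_trees, max_depth = best$max_depth,
                  min_leaf = best$min_leaf, min_split = best$min_split),
    cv_accuracy = best$mean_accuracy,
    results = grid
  )
}

#' Permutation-importance ranking of plants
#'
#' Fits a random forest on the variance-filtered plant-level binary matrix
#' (not on principal components — weights must map back to plant names) and
#' scores each plant by the mean drop in accuracy when its column is randomly
#' permuted, averaged over `config$importance_repeats` permutations. The
#' importance fit enlarges the tuned forest to at least
#' `config$importance_trees` trees: ensemble size only stabilises the
#' estimates, it does not change the model class selected by tuning.
#' Correlated plant columns share importance credit, so near-duplicate
#' ingredients can individually look weaker than they jointly are.
#'
#' @param dataset A `formula_dataset`.
#' @param rf_params List with `n_trees`, `max_depth`, `min_leaf`, `min_split`
#'   (e.g. the output of [tune_rf()]). Default: 50 trees, depth 15, leaf 5,
#'   split 5.
#' @param config An [ml_config()].
#' @param mode `"classifier"` (default) fits a classification forest;
#'   `"regressor"` fits a regression forest on the numeric 0/1 label and
#'   thresholds its predictions at 0.5, for comparison with workflows that
#'   rank features with a regression forest.
#' @return Data frame of class `importance_table`: `plant_name`, `weight`
#'   (mean accuracy drop), `sd_weight`, sorted by decreasing weight.
#' @export
importance_ranking <- function(dataset,
                               rf_params = list(n_trees = 50L, max_depth = 15L,
                                                min_leaf = 5L, min_split = 5L),
                               config = ml_config(),
                               mode = c("classifier", "regressor")) {
  validate_formula_dataset(dataset)
  mode <- match.arg(mode)
  filtered <- filter_features(dataset, config)
  x <- filtered$matrix
  storage.mode(x) <- "double"
  y <- filtered$labels

  n_trees <- max(rf_params$n_trees, config$importance_trees %||% rf_params$n_trees)
  resp <- if (mode == "classifier") factor(y, levels = c(0L, 1L)) else as.numeric(y)
  fit <- ranger::ranger(x = x, y = resp,
                        num.trees = n_trees, max.depth = rf_params$max_depth,
                        min.bucket = rf_params$min_leaf,
                        min.node.size = rf_params$min_split,
                        seed = config$seed, num.threads = 1)
  acc <- function(xx) {
    # seeded for deterministic vote tie-breaking
    p <- stats::predict(fit, xx, num.threads = 1, seed = config$seed)$predictions
    if (mode == "regressor") p <- as.integer(p > 0.5)
    mean(as.integer(as.character(p)) == y)
  }
  baseline <- acc(x)
  drops <- withr::with_seed(config$seed, {
    vapply(seq_len(ncol(x)), function(j) {
      vapply(seq_len(config$importance_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        baseline - acc(xp)
      }, numeric(1))
    }, numeric(config$importance_repeats))
  })
  drops <- matrix(drops, nrow = config$importance_repeats)
  out <- data.frame(
    plant_name = colnames(x),
    weight = colMeans(drops),
    sd_weight = apply(drops, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$weight, out$plant_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Select ML-branch candidates by importance threshold
#'
#' Keeps plants whose permutation-importance weight strictly exceeds the
#' threshold.
#'
#' @param importances An `importance_table` (or any data frame with
#'   `plant_name` and `weight`).
#' @param threshold Strict lower bound on weight. Default 0.01.
#' @return A [candidate_table()] with `branch = "ml"`.
#' @export
select_ml_candidates <- function(importances, threshold = 0.01) {
  stopifnot(all(c("plant_name", "weight") %in% names(importances)))
  keep <- importances$weight > threshold
  candidate_table(importances$plant_name[keep], importances$weight[keep], "ml")
}

#' Candidate counts across a sweep of importance thresholds
#'
#' Reports how many plants survive `weight > t` for each threshold `t`; the
#' count is non-increasing in `t`, so a flat stretch around the working
#' threshold indicates the selection is not knife-edge.
#'
#' @param importances An `importance_table`.
#' @param thresholds Numeric vector of thresholds; default: seven equally
#'   spaced values spanning `config$sensitivity_range`.
#' @param config An [ml_config()].
#' @return Data frame with `threshold` and `n_candidates`.
#' @export
threshold_sensitivity <- function(importances, thresholds = NULL,
                                  config = ml_config()) {
  if (is.null(thresholds)) {
    thresholds <- seq(config$sensitivity_range[1], config$sensitivity_range[2],
                      length.out = 7)
  }
  data.frame(
    threshold = thresholds,
    n_candidates = vapply(thresholds,
                          function(t) sum(importances$weight > t), numeric(1))
  )
}
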