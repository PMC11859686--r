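test_that("variance filtering matches a brute-force scan and keeps labels intact", {
  ds <- generate_dataset(generator_config(n_formulae = 80, n_plants = 50,
                                          plants_per_formula_range = c(2, 10),
                                          seed = 51))
  cfg <- ml_config(variance_min = 0.02)
  f <- filter_features(ds, cfg)
  keep <- character()
  for (p in colnames(ds$matrix)) {
    if (stats::var(ds$matrix[, p]) >= 0.02) keep <- c(keep, p)
  }
  expect_identical(colnames(f$matrix), keep)
  expect_identical(f$labels, ds$labels)
  # a constant column is dropped at any positive cutoff
  m2 <- cbind(ds$matrix, zero_col = 0L)
  ds2 <- formula_dataset(m2, ds$labels)
  expect_false("zero_col" %in% colnames(filter_features(ds2, cfg)$matrix))
  # variance_min = 0 is the identity on columns
  expect_identical(colnames(filter_features(ds, ml_config(variance_min = 0))$matrix),
                   colnames(ds$matrix))
})

test_that("PCA retains the analytically expected component counts", {
  withr::with_seed(52, {
    # rank-1 data: one component explains everything
    u <- rnorm(100)
    x1 <- cbind(u, 2 * u, -u, 0.5 * u)
    r1 <- reduce_pca(x1, ml_config())
    expect_identical(r1$k, 1L)
    expect_equal(r1$cumulative, 1, tolerance = 1e-9)
    # 4 iid columns: near-equal eigenvalues, ~25% each, so 95% needs all 4
    x4 <- matrix(rnorm(500 * 4), 500)
    r4 <- reduce_pca(x4, ml_config())
    expect_identical(r4$k, 4L)
    # explained variance is non-increasing and cumulative meets the target
    expect_true(all(diff(r4$explained) <= 1e-12))
    expect_gte(r4$cumulative, 0.95)
  })
})

test_that("fixed-count PCA returns exactly the requested width on the reference shape", {
  ds <- generate_dataset(generator_config(seed = 53))
  red <- reduce_pca(ds, ml_config(pca_components = 146))
  expect_identical(ncol(red$scores), 146L)
  expect_error(reduce_pca(ds$matrix[1:10, ], ml_config(pca_components = 146)),
               "available")
})

test_that("SMOTE balances classes exactly while preserving originals", {
  withr::with_seed(54, {
    x <- matrix(rnorm(100 * 6), 100)
    y <- c(rep(1L, 30), rep(0L, 70))   # 0.3 / 0.7 split
    out <- balance_smote(x, y, k = 5, seed = 99)
    expect_identical(sum(out$labels == 1L), sum(out$labels == 0L))
    expect_identical(out$features[1:100, ], x)
    expect_identical(out$labels[1:100], y)
    expect_identical(sum(out$synthetic), 40L)
    # deterministic under a fixed seed
    out2 <- balance_smote(x, y, k = 5, seed = 99)
    expect_identical(out, out2)
    # balanced input returned unchanged
    yb <- rep(c(0L, 1L), 50)
    expect_identical(balance_smote(x, yb)$features, x)
  })
})

test_that("SMOTE interpolates on the segment between minority neighbours", {
  x <- rbind(c(0, 0), c(1, 2), matrix(5 + stats::runif(20), ncol = 2))
  y <- c(1L, 1L, rep(0L, 10))
  out <- balance_smote(x, y, k = 1, seed = 3)
  syn <- out$features[out$synthetic, , drop = FALSE]
  # convex combinations of (0,0) and (1,2): inside the bounding box, on the line
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
  expect_true(all(abs(syn[, 2] - 2 * syn[, 1]) < 1e-12))
  expect_error(balance_smote(x, y, k = 5), "smaller k")
})

test_that("the model comparison reports 7 models x 3 variants", {
  ds <- generate_dataset(generator_config(n_formulae = 90, n_plants = 40,
                                          class1_fraction = 0.4,
                                          plants_per_formula_range = c(2, 10),
                                          seed = 55))
  rep_ <- compare_models(ds, ml_config(seed = 55, cv_folds = 3))
  expect_identical(nrow(rep_), 21L)
  expect_setequal(unique(rep_$variant), c("filtering", "smote", "both"))
  expect_true(all(rep_$mean_accuracy >= 0 & rep_$mean_accuracy <= 1))
  expect_true(all(rep_$sd_accuracy >= 0))
  expect_identical(unique(rep_$n_evals), 3L)
})

test_that("strongly separable data yields high accuracy with the forest near the top", {
  ds <- generate_dataset(generator_config(n_formulae = 250, n_plants = 100,
                                          n_signal_plants = 15,
                                          signal_enrichment = 20,
                                          class1_fraction = 0.5,
                                          plants_per_formula_range = c(3, 15),
                                          seed = 3))
  rep_ <- compare_models(ds, ml_config(seed = 3))
  agg <- tapply(rep_$mean_accuracy, rep_$model, mean)
  expect_true(all(agg > 0.7))
  expect_true("random_forest" %in% names(sort(agg, decreasing = TRUE))[1:3])
})

test_that("grid search returns the best configuration with small-model tie-breaking", {
  # the label equals the only varying direction in the data, so a depth-1
  # stump is already perfect; every grid point ties at accuracy 1 and the
  # tie-break takes the fewest trees, then the shallowest depth
  withr::with_seed(56, {
    n <- 120
    decisive <- rbinom(n, 1, 0.5)
    m <- cbind(base = 1L, matrix(rep(decisive, 6), n,
                                 dimnames = list(NULL, paste0("d", 1:6))))
    storage.mode(m) <- "integer"
    ds <- formula_dataset(m, decisive)
  })
  grid <- expand.grid(n_trees = c(50L, 100L), max_depth = c(1L, 15L),
                      min_leaf = 1L, min_split = 2L)
  tuned <- tune_rf(ds, ml_config(seed = 56, rf_grid = grid, variance_min = 0))
  expect_identical(nrow(tuned$results), 4L)
  expect_equal(tuned$cv_accuracy, 1)
  expect_identical(tuned$params$n_trees, 50L)
  expect_identical(tuned$params$max_depth, 1L)
  # a one-point grid returns that point
  g1 <- grid[2, , drop = FALSE]
  t1 <- tune_rf(ds, ml_config(seed = 56, rf_grid = g1, variance_min = 0))
  expect_identical(t1$params$n_trees, g1$n_trees)
  expect_error(tune_rf(ds, ml_config(rf_grid = grid[0, ])), "empty")
})

test_that("permutation importance: null features score near zero, duplicated signal shares credit", {
  withr::with_seed(57, {
    n <- 200
    a <- rbinom(n, 1, 0.5)
    m <- cbind(sig = a, sig_copy = a, matrix(rbinom(n * 8, 1, 0.4), n))
    colnames(m) <- c("sig", "sig_copy", sprintf("null%02d", 1:8))
    m[rowSums(m) == 0, 3] <- 1L
    storage.mode(m) <- "integer"
    ds <- formula_dataset(m, a)
  })
  imp <- importance_ranking(ds, config = ml_config(seed = 57, variance_min = 0))
  w <- stats::setNames(imp$weight, imp$plant_name)
  null_w <- w[grepl("^null", names(w))]
  expect_true(all(abs(null_w) < 0.05))
  # the duplicated decisive pair jointly dominates every null column
  expect_gt(w["sig"] + w["sig_copy"], max(null_w) + 0.05)
})

test_that("permutation importance agrees with an independent OOB-based estimator", {
  ds <- generate_dataset(generator_config(n_formulae = 300, n_plants = 60,
                                          n_signal_plants = 6,
                                          signal_enrichment = 10,
                                          plants_per_formula_range = c(3, 12),
                                          seed = 59))
  imp <- importance_ranking(ds, config = ml_config(seed = 59))
  # independent route: ranger's internal OOB permutation importance
  f <- filter_features(ds, ml_config(seed = 59))
  x <- f$matrix; storage.mode(x) <- "double"
  fit <- ranger::ranger(x = x, y = factor(f$labels, levels = c(0L, 1L)),
                        num.trees = 500, importance = "permutation",
                        seed = 59, num.threads = 1)
  oob <- sort(fit$variable.importance, decreasing = TRUE)
  # the two estimators must broadly agree on who carries the signal
  expect_gte(length(intersect(imp$plant_name[1:10], names(oob)[1:10])), 6)
  merged <- merge(imp, data.frame(plant_name = names(oob), oob = unname(oob)))
  expect_gt(stats::cor(merged$weight, merged$oob, method = "spearman"), 0.5)
})

test_that("threshold selection is a strict cut and anti-monotone", {
  imp <- reference_ml_importances()
  sel <- select_ml_candidates(imp, threshold = 0.01)
  expect_identical(nrow(sel), 32L)
  expect_identical(nrow(select_ml_candidates(imp, threshold = max(imp$weight))), 0L)
  # strictness at the boundary
  expect_identical(nrow(select_ml_candidates(imp, threshold = min(imp$weight))),
                   31L)
  withr::with_seed(58, {
    rnd <- data.frame(plant_name = sprintf("p%03d", 1:50),
                      weight = stats::runif(50, 0, 0.03))
    for (t in c(0.005, 0.01, 0.02)) {
      brute <- 0L
      for (k in 1:50) if (rnd$weight[k] > t) brute <- brute + 1L
      expect_identical(nrow(select_ml_candidates(rnd, t)), brute)
    }
  })
})

test_that("threshold sensitivity counts are non-increasing and match the strict cut", {
  imp <- reference_ml_importances()
  sens <- threshold_sensitivity(imp, thresholds = c(0.005, 0.01, 0.02))
  expect_true(all(diff(sens$n_candidates) <= 0))
  expect_identical(sens$n_candidates[sens$threshold == 0.01],
                   as.numeric(nrow(select_ml_candidates(imp, 0.01))))
  one <- data.frame(plant_name = "a", weight = 0.012)
  s1 <- threshold_sensitivity(one, thresholds = c(0.005, 0.02))
  expect_identical(s1$n_candidates, c(1, 0))
})
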