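test_that("generated datasets satisfy shape and binarity invariants across configs", {
  configs <- list(
    generator_config(seed = 1),
    generator_config(n_formulae = 40, n_plants = 30, n_signal_plants = 3,
                     plants_per_formula_range = c(1, 10), seed = 2),
    generator_config(n_formulae = 500, n_plants = 50, class1_fraction = 0.2,
                     plants_per_formula_range = c(2, 8), variant_rate = 0.6, seed = 3),
    generator_config(n_signal_plants = 0, signal_enrichment = 1, seed = 4)
  )
  for (cfg in configs) {
    ds <- generate_dataset(cfg)
    expect_s3_class(ds, "formula_dataset")
    expect_identical(dim(ds$matrix), c(cfg$n_formulae, cfg$n_plants))
    expect_true(all(ds$matrix %in% c(0L, 1L)))
    expect_true(all(rowSums(ds$matrix) >= cfg$plants_per_formula_range[1]))
    expect_true(all(rowSums(ds$matrix) <= cfg$plants_per_formula_range[2]))
    expect_length(ds$labels, cfg$n_formulae)
    expect_setequal(unique(ds$labels), c(0L, 1L))
    expect_length(ds$signal_plants, cfg$n_signal_plants)
  }
})

test_that("default configuration matches the reference corpus shape", {
  ds <- generate_dataset(generator_config(seed = 8))
  expect_identical(dim(ds$matrix), c(285L, 293L))
})

test_that("fixing the seed fixes the dataset bit-for-bit", {
  a <- generate_dataset(generator_config(seed = 123))
  b <- generate_dataset(generator_config(seed = 123))
  expect_identical(a, b)
  c_ <- generate_dataset(generator_config(seed = 124))
  expect_false(identical(a$matrix, c_$matrix))
})

test_that("plant frequencies are heavy-tailed: frequency decreases with weight rank", {
  rhos <- vapply(1:20, function(s) {
    ds <- generate_dataset(generator_config(seed = s))
    freq <- colSums(ds$matrix)
    stats::cor(seq_along(freq), as.numeric(freq), method = "spearman")
  }, numeric(1))
  # rank 1 carries the largest sampling weight, so rank vs frequency is negative
  expect_true(all(rhos < 0))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(class1_fraction = 1), "class1_fraction")
  expect_error(generator_config(n_signal_plants = 500), "n_signal_plants")
  expect_error(generator_config(plants_per_formula_range = c(0, 5)),
               "plants_per_formula_range")
  expect_error(generator_config(signal_enrichment = 0.5), "signal_enrichment")
  expect_error(generator_config(variant_rate = 1), "variant_rate")
})

test_that("planted plants are class-associated under strong enrichment", {
  ds <- generate_dataset(generator_config(n_formulae = 400, n_signal_plants = 10,
                                          signal_enrichment = 8, seed = 5))
  aud <- association_audit(ds)
  sig <- aud[aud$is_signal, ]
  expect_identical(nrow(sig), 10L)
  # direct contingency computation: every planted plant enriched in class 1
  expect_true(all(sig$odds_ratio > 1))
})

test_that("association audit reproduces the hand-computed contingency table", {
  m <- matrix(0L, 8, 2, dimnames = list(sprintf("F%d", 1:8), c("pa", "pb")))
  # pa present in 3 of 4 class-1 and 1 of 4 class-0 formulae
  m[c(1, 2, 3, 5), 1] <- 1L
  m[, 2] <- 1L  # keeps every formula non-empty; pb present everywhere
  ds <- formula_dataset(m, labels = c(1, 1, 1, 1, 0, 0, 0, 0))
  aud <- association_audit(ds)
  # Haldane-Anscombe: (3.5/1.5)/(1.5/3.5)
  expect_equal(aud$odds_ratio[aud$plant_name == "pa"], (3.5 / 1.5) / (1.5 / 3.5),
               tolerance = 1e-12)
  expect_identical(aud$count_in_class1[aud$plant_name == "pa"], 3L)
  expect_identical(aud$count_in_class0[aud$plant_name == "pa"], 1L)
})

test_that("a plant absent everywhere audits to zero counts", {
  m <- cbind(pa = c(1L, 1L), pb = c(0L, 0L))
  rownames(m) <- c("F1", "F2")
  aud <- association_audit(formula_dataset(m, c(1, 0)))
  expect_identical(aud$count_in_class1[aud$plant_name == "pb"], 0L)
  expect_identical(aud$count_in_class0[aud$plant_name == "pb"], 0L)
})

test_that("without enrichment, planted plants show no class association beyond chance", {
  # independent sampling (variant_rate 0): formulae are exchangeable, so the
  # chi-square independence test is calibrated
  passes <- 0L
  medians <- numeric(20)
  for (s in 1:20) {
    ds <- generate_dataset(generator_config(signal_enrichment = 1,
                                            variant_rate = 0, seed = s))
    aud <- association_audit(ds)
    sig <- aud[aud$is_signal, ]
    n1 <- sum(ds$labels == 1L)
    n0 <- sum(ds$labels == 0L)
    pv <- vapply(seq_len(nrow(sig)), function(i) {
      tb <- matrix(c(sig$count_in_class1[i], n1 - sig$count_in_class1[i],
                     sig$count_in_class0[i], n0 - sig$count_in_class0[i]), 2)
      suppressWarnings(stats::chisq.test(tb)$p.value)
    }, numeric(1))
    if (min(stats::p.adjust(pv, "bonferroni")) > 0.01) passes <- passes + 1L
    medians[s] <- stats::median(aud$odds_ratio)
  }
  expect_gte(passes, 18L)
  # per-plant odds ratios are centred at 1 under the null
  expect_true(all(medians > 2 / 3 & medians < 3 / 2))
})
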