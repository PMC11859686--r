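test_that("minkowski distance matches its closed form on hand cases", {
  x <- c(1, 0, 1, 0, 1)
  expect_identical(minkowski_distance(x, x, 2), 0)
  y <- c(0, 0, 1, 1, 1)     # differs in exactly 2 positions
  expect_equal(minkowski_distance(x, y, 2), sqrt(2), tolerance = 1e-12)
  expect_equal(minkowski_distance(x, y, 1), 2)      # Manhattan
  expect_equal(minkowski_distance(x, y, 3), 2^(1 / 3), tolerance = 1e-12)
})

test_that("minkowski distance rejects invalid input", {
  expect_error(minkowski_distance(c(1, 0), c(1, 0, 1), 2), "length mismatch")
  expect_error(minkowski_distance(c(1, 0), c(0, 1), 0.5), "p must be")
})

test_that("on binary vectors d_p equals Hamming^(1/p) and the brute-force sum", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(5:40, 1)
      x <- rbinom(n, 1, 0.4)
      y <- rbinom(n, 1, 0.4)
      h <- sum(x != y)
      for (p in c(1, 2, 3)) {
        expect_equal(minkowski_distance(x, y, p), brute_minkowski(x, y, p),
                     tolerance = 1e-12)
        expect_equal(minkowski_distance(x, y, p), h^(1 / p), tolerance = 1e-12)
      }
    }
  })
})

test_that("d_p is a metric: symmetric, with the triangle inequality", {
  withr::with_seed(32, {
    for (rep in 1:20) {
      p <- sample(c(1, 1.5, 2, 3), 1)
      x <- rbinom(15, 1, 0.5); y <- rbinom(15, 1, 0.5); z <- rbinom(15, 1, 0.5)
      expect_identical(minkowski_distance(x, y, p), minkowski_distance(y, x, p))
      expect_lte(minkowski_distance(x, z, p),
                 minkowski_distance(x, y, p) + minkowski_distance(y, z, p) + 1e-12)
    }
  })
})

test_that("edges require distance strictly below the threshold", {
  m <- rbind(
    F1 = c(1L, 1L, 1L, 0L, 0L, 0L),
    F2 = c(1L, 1L, 1L, 0L, 0L, 0L),  # identical to F1
    F3 = c(1L, 1L, 0L, 1L, 0L, 0L),  # differs from F1 in 2
    F4 = c(0L, 0L, 0L, 1L, 1L, 1L)   # differs from F1 in 6
  )
  colnames(m) <- paste0("p", 1:6)
  net <- build_network(formula_dataset(m, c(1, 0, 1, 0)), p = 2, threshold = 1.5)
  expect_true(igraph::are_adjacent(net, "F1", "F2"))   # d = 0
  expect_true(igraph::are_adjacent(net, "F1", "F3"))   # sqrt(2) < 1.5
  expect_false(igraph::are_adjacent(net, "F1", "F4"))  # sqrt(6) > 1.5
  # boundary: distance exactly at the threshold is NOT an edge
  net_b <- build_network(formula_dataset(m, c(1, 0, 1, 0)), p = 2,
                         threshold = sqrt(2))
  expect_false(igraph::are_adjacent(net_b, "F1", "F3"))
})

test_that("the edge set equals a brute-force all-pairs scan", {
  ds <- generate_dataset(generator_config(n_formulae = 20, n_plants = 30,
                                          n_signal_plants = 0,
                                          plants_per_formula_range = c(2, 10),
                                          seed = 33))
  net <- build_network(ds, p = 2, threshold = 1.8)
  for (i in 1:19) {
    for (j in (i + 1):20) {
      d <- brute_minkowski(ds$matrix[i, ], ds$matrix[j, ], 2)
      expect_identical(
        igraph::are_adjacent(net, ds$formula_ids[i], ds$formula_ids[j]),
        d < 1.8
      )
    }
  }
})

test_that("raising the threshold never removes an edge", {
  ds <- generate_dataset(generator_config(n_formulae = 60, n_plants = 40,
                                          plants_per_formula_range = c(2, 10),
                                          seed = 34))
  e_lo <- igraph::as_edgelist(build_network(ds, threshold = 1.2))
  net_hi <- build_network(ds, threshold = 2.3)
  if (nrow(e_lo) > 0) {
    for (k in seq_len(nrow(e_lo))) {
      expect_true(igraph::are_adjacent(net_hi, e_lo[k, 1], e_lo[k, 2]))
    }
  }
  expect_gte(igraph::ecount(net_hi), nrow(e_lo))
})

test_that("p = 1 at threshold t matches p = 2 at sqrt(t) on binary data", {
  ds <- generate_dataset(generator_config(n_formulae = 50, n_plants = 30,
                                          plants_per_formula_range = c(2, 8),
                                          seed = 35))
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1,
               paste, collapse = "-"))
  }
  g1 <- build_network(ds, p = 1, threshold = 3)
  g2 <- build_network(ds, p = 2, threshold = sqrt(3))
  expect_identical(canon(g1), canon(g2))
})

test_that("similarity weighting records positive threshold-minus-distance weights", {
  m <- rbind(F1 = c(1L, 1L, 0L), F2 = c(1L, 1L, 0L), F3 = c(1L, 0L, 1L))
  colnames(m) <- paste0("p", 1:3)
  net <- build_network(formula_dataset(m, c(1, 0, 1)), threshold = 1.5,
                       edge_weighting = "similarity")
  w <- igraph::E(net)$weight
  expect_true(all(w > 0))
  expect_true(any(abs(w - 1.5) < 1e-12))  # the identical pair: 1.5 - 0
})
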