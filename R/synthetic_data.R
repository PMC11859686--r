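#' Configuration for the synthetic formula generator
#'
#' Defines the statistical structure of a simulated formula corpus: its shape,
#' the class imbalance, the heavy-tailed marginal plant frequencies, and a
#' planted set of "signal" plants whose inclusion odds are multiplied in
#' antibiotic-class formulae. Defaults describe the reference study
#' conditions this package targets: 285 formulae over a 293-plant vocabulary,
#' a minority antibiotic class, a power-law frequency profile whose top plant
#' appears in roughly a third of formulae, and 10 signal plants with an
#' eight-fold inclusion-odds multiplier.
#'
#' @param n_formulae Number of formulae (rows). Default 285.
#' @param n_plants Size of the plant vocabulary (columns). Default 293.
#' @param n_signal_plants Number of planted true-signal plants. Default 10.
#' @param class1_fraction Probability that a formula is antibiotic class
#'   (label 1). Must lie strictly in (0, 1). Default 0.35.
#' @param base_frequency_decay Power-law exponent: the sampling weight of the
#'   plant of frequency rank r is r^(-base_frequency_decay). Default 0.5,
#'   which reproduces a top-plant frequency near 1/3 of formulae and a
#'   rank-40 frequency near 6% under the default shape.
#' @param signal_enrichment Multiplier (>= 1) applied to a signal plant's
#'   sampling weight inside class-1 formulae. 1 = no signal. Default 8.
#' @param plants_per_formula_range Integer pair (min, max): per-formula plant
#'   counts are drawn uniformly from this range. Default c(3, 25).
#' @param variant_rate Probability in [0, 1) that a formula is generated as a
#'   single-edit variant (one ingredient swapped, added or removed) of a
#'   previously generated formula, inheriting its class label. Recipe
#'   families of this kind are what give real formula corpora pairs within
#'   small Hamming distance of each other; without them a strict
#'   distance-threshold network is empty. Default 0.35.
#' @param seed Integer RNG seed; fixing it fixes the dataset bit-for-bit.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_formulae = 285,
                             n_plants = 293,
                             n_signal_plants = 10,
                             class1_fraction = 0.35,
                             base_frequency_decay = 0.5,
                             signal_enrichment = 8,
                             plants_per_formula_range = c(3, 25),
                             variant_rate = 0.35,
                             seed = 1L) {
  cfg <- structure(
    list(
      n_formulae = as.integer(n_formulae),
      n_plants = as.integer(n_plants),
      n_signal_plants = as.integer(n_signal_plants),
      class1_fraction = class1_fraction,
      base_frequency_decay = base_frequency_decay,
      signal_enrichment = signal_enrichment,
      plants_per_formula_range = as.integer(plants_per_formula_range),
      variant_rate = variant_rate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator config: `%s` %s", field, why), call. = FALSE)
  }
  if (is.na(cfg$n_formulae) || cfg$n_formulae < 1) bad("n_formulae", "must be a positive integer")
  if (is.na(cfg$n_plants) || cfg$n_plants < 1) bad("n_plants", "must be a positive integer")
  if (is.na(cfg$n_signal_plants) || cfg$n_signal_plants < 0) bad("n_signal_plants", "must be non-negative")
  if (cfg$n_signal_plants > cfg$n_plants) bad("n_signal_plants", "cannot exceed n_plants")
  if (!is.numeric(cfg$class1_fraction) || cfg$class1_fraction <= 0 ||
      cfg$class1_fraction >= 1) bad("class1_fraction", "must lie strictly in (0, 1)")
  if (!is.numeric(cfg$base_frequency_decay) || cfg$base_frequency_decay <= 0) {
    bad("base_frequency_decay", "must be positive")
  }
  if (!is.numeric(cfg$signal_enrichment) || cfg$signal_enrichment < 1) {
    bad("signal_enrichment", "must be >= 1")
  }
  r <- cfg$plants_per_formula_range
  if (length(r) != 2 || anyNA(r) || r[1] < 1 || r[2] < r[1] || r[2] > cfg$n_plants) {
    bad("plants_per_formula_range", "must be (min >= 1, max <= n_plants) with min <= max")
  }
  if (!is.numeric(cfg$variant_rate) || cfg$variant_rate < 0 || cfg$variant_rate >= 1) {
    bad("variant_rate", "must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Generate a synthetic formula-by-plant dataset
#'
#' Simulates a corpus of multi-plant formulae. A *fresh* formula draws a
#' class label Bernoulli(class1_fraction) and a plant count uniform over
#' `plants_per_formula_range`, then samples that many distinct plants with
#' probability proportional to a rank-based power-law weight
#' r^(-base_frequency_decay). In class-1 formulae the weights of the planted
#' signal plants are multiplied by `signal_enrichment`, so signal is encoded
#' in the sampling process itself and per-formula plant counts stay in range.
#'
#' With probability `variant_rate` a formula is instead a *variant* of a
#' uniformly chosen earlier formula: it inherits the parent's composition and
#' class label and differs by exactly one edit — an ingredient swap (Hamming
#' distance 2 from the parent), addition or removal (Hamming distance 1),
#' respecting the size range. The added ingredient is drawn from the same
#' label-dependent weights as fresh sampling. Variants emulate the recipe
#' families of real corpora (one base prescription recorded with small
#' ingredient substitutions) and are what gives the similarity network its
#' edges at a strict distance threshold.
#'
#' If a draw produces a corpus with only one class (possible at small
#' `n_formulae`), generation is retried with a fresh substream, up to 10
#' times, with a warning per retry.
#'
#' @param config A `generator_config`.
#' @return A [formula_dataset()] with `signal_plants` recording the planted
#'   plant names; deterministic for a fixed `config$seed`.
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    for (attempt in 1:10) {
      ds <- generate_once(config, attempt)
      if (!is.null(ds)) return(ds)
      warning(sprintf(
        "generated corpus had a single class on attempt %d; retrying", attempt
      ), call. = FALSE)
    }
    stop("could not generate a two-class corpus in 10 attempts; ",
         "check class1_fraction and n_formulae")
  })
}

generate_once <- function(config, attempt) {
  n <- config$n_formulae
  p <- config$n_plants
  plant_names <- sprintf("plant_%03d", seq_len(p))
  # rank r carries weight r^(-decay): plant_001 is the staple, tail is rare
  base_w <- seq_len(p)^(-config$base_frequency_decay)
  signal_idx <- if (config$n_signal_plants > 0) {
    sort(sample.int(p, config$n_signal_plants))
  } else integer()

  smin <- config$plants_per_formula_range[1]
  smax <- config$plants_per_formula_range[2]
  m <- matrix(0L, n, p, dimnames = list(sprintf("F%04d", seq_len(n)), plant_names))
  labels <- integer(n)
  w1 <- base_w
  w1[signal_idx] <- w1[signal_idx] * config$signal_enrichment

  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) < config$variant_rate) {
      j <- sample.int(i - 1L, 1)
      labels[i] <- labels[j]
      row <- m[j, ]
      w <- if (labels[i] == 1L) w1 else base_w
      size <- sum(row)
      move <- sample(c("swap", "add", "remove"), 1)
      if (move == "remove" && size <= smin) move <- "swap"
      if (move == "add" && size >= smax) move <- "swap"
      if (move %in% c("swap", "remove")) {
        present <- which(row == 1L)
        row[present[sample.int(length(present), 1)]] <- 0L
      }
      if (move %in% c("swap", "add")) {
        absent <- which(row == 0L)
        row[absent[sample.int(length(absent), 1, prob = w[absent])]] <- 1L
      }
      m[i, ] <- row
    } else {
      labels[i] <- stats::rbinom(1, 1, config$class1_fraction)
      w <- if (labels[i] == 1L) w1 else base_w
      m[i, sample.int(p, sample(smin:smax, 1), prob = w)] <- 1L
    }
  }
  if (length(unique(labels)) < 2 && n > 1) return(NULL)
  formula_dataset(
    m, labels,
    provenance = sprintf(
      "synthetic: n=%d p=%d class1=%.2f decay=%.2f signal=%dx%.1f range=%d-%d variants=%.2f seed=%d attempt=%d",
      n, p, config$class1_fraction, config$base_frequency_decay,
      config$n_signal_plants, config$signal_enrichment,
      config$plants_per_formula_range[1], config$plants_per_formula_range[2],
      config$variant_rate, config$seed, attempt
    ),
    signal_plants = plant_names[signal_idx]
  )
}

#' Audit per-plant association with the antibiotic class
#'
#' For every plant, tabulates the 2x2 contingency table of plant presence
#' against the formula class label and reports the odds ratio. The
#' Haldane–Anscombe correction (adding 0.5 to every cell) is applied
#' throughout, keeping the estimator finite when a cell is empty.
#'
#' @param dataset A `formula_dataset`.
#' @return Data frame with one row per plant: `plant_name`, `count_in_class1`,
#'   `count_in_class0`, `odds_ratio`, `is_signal` (TRUE for planted plants).
#' @export
association_audit <- function(dataset) {
  validate_formula_dataset(dataset)
  m <- dataset$matrix
  y <- dataset$labels
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  a <- colSums(m[y == 1L, , drop = FALSE])   # present in class 1
  b <- colSums(m[y == 0L, , drop = FALSE])   # present in class 0
  c_ <- n1 - a                               # absent in class 1
  d <- n0 - b                                # absent in class 0
  or <- ((a + 0.5) / (c_ + 0.5)) / ((b + 0.5) / (d + 0.5))
  data.frame(
    plant_name = colnames(m),
    count_in_class1 = as.integer(a),
    count_in_class0 = as.integer(b),
    odds_ratio = unname(or),
    is_signal = colnames(m) %in% dataset$signal_plants,
    stringsAsFactors = FALSE
  )
}
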