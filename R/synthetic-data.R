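# Ground-truth generator for the factorial stimulus-response design. Each
# synthetic feature is assigned an interaction class, a theoretical
# expression pattern admissible for that class, and true condition means in
# {0, +effect_size, -effect_size}; replicate fold changes are the means
# plus Gaussian noise. Because effects take only those three values, the
# truth-to-pattern map is unambiguous and downstream classification
# recovery can be scored exactly.

#' Configuration for the synthetic fold-change generator
#'
#' Defaults emulate the motivating proteomics study: three replicates per
#' condition, replicate noise 0.2 on the log2 scale (typical of iTRAQ
#' fold-change scatter), unit effect size (a two-fold change), and a class
#' mix matching the study's observed class frequencies
#' (41:30:121:175:41:58 over 466 proteins for non-responder, A-dominant,
#' B-dominant, NER, discordant, suppression).
#'
#' @param n_features Number of features to generate.
#' @param class_mix Named nonnegative proportions over the six generative
#'   classes (`NON_RESPONDER`, `A_DOMINANT`, `B_DOMINANT`, `NER`,
#'   `DISCORDANT`, `SUPPRESSION`), summing to 1 within 1e-9.
#' @param effect_size Magnitude of a nonzero true mean (log2 units).
#' @param noise_sd Replicate standard deviation (log2 units), > 0.
#' @param n_replicates Replicates per condition, >= 2.
#' @param seed Integer RNG seed; all draws flow from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_features = 500,
                             class_mix = c(NON_RESPONDER = 41, A_DOMINANT = 30,
                                           B_DOMINANT = 121, NER = 175,
                                           DISCORDANT = 41, SUPPRESSION = 58) / 466,
                             effect_size = 1.0, noise_sd = 0.2,
                             n_replicates = 3, seed = 1L) {
  classes <- c("NON_RESPONDER", "A_DOMINANT", "B_DOMINANT", "NER",
               "DISCORDANT", "SUPPRESSION")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes))
    stop("class_mix must be named with the generative classes: ",
         paste(classes, collapse = ", "))
  mix <- setNames(numeric(length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0)) stop("class_mix proportions must be nonnegative")
  if (abs(sum(mix) - 1) > 1e-9)
    stop("class_mix must sum to 1 (got ", format(sum(mix)), ")")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (effect_size <= 0) stop("effect_size must be > 0")
  structure(list(n_features = as.integer(n_features), class_mix = mix,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Largest-remainder apportionment of n among proportions.
largest_remainder <- function(n, proportions) {
  exact <- n * proportions
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- exact - counts
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Draw a ground-truth table of per-feature condition means
#'
#' Class counts follow `class_mix` by largest-remainder rounding; within a
#' class the theoretical pattern is sampled uniformly over that class's
#' admissible patterns (2 for NER, 4 per dominance class, 8 each for
#' discordant and suppression, 1 for non-responders). True means are 0,
#' `+effect_size` or `-effect_size` as the pattern dictates; the epistatic
#' flag is computed from the means, never sampled.
#'
#' @param config A [generator_config()].
#' @return Data frame of class `synthetic_truth`: `feature_id`,
#'   `class_label`, `pattern_id`, `mu_A`, `mu_B`, `mu_AB`, `epistatic`.
#' @export
generate_truth_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pt <- pattern_table()
  counts <- largest_remainder(config$n_features, config$class_mix)
  names(counts) <- names(config$class_mix)
  withr::local_seed(config$seed)
  rows <- unlist(mapply(function(cls, k) {
    if (k == 0) return(integer())
    admissible <- pt$pattern_id[pt$class == cls]
    admissible[sample.int(length(admissible), k, replace = TRUE)]
  }, names(counts), counts, SIMPLIFY = FALSE), use.names = FALSE)
  chosen <- pt[rows, ]
  mu <- function(state) ifelse(state == "up", config$effect_size,
                               ifelse(state == "down", -config$effect_size, 0))
  truth <- data.frame(
    feature_id = sprintf("F%0*d", nchar(config$n_features), seq_along(rows)),
    class_label = chosen$class,
    pattern_id = chosen$pattern_id,
    mu_A = mu(chosen$state_A), mu_B = mu(chosen$state_B),
    mu_AB = mu(chosen$state_AB),
    row.names = NULL)
  truth$epistatic <- abs(truth$mu_AB - truth$mu_A - truth$mu_B) > 1e-12
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

# Assemble the standard sample sheet for n replicates per condition.
replicate_samples <- function(n_replicates, stimulus_names = c("HT", "G")) {
  labs <- condition_labels(stimulus_names)
  data.frame(
    sample_id = paste0(rep(labs, each = n_replicates), "_r",
                       rep(seq_len(n_replicates), 3)),
    stimulus_a = rep(c(1, 0, 1), each = n_replicates),
    stimulus_b = rep(c(0, 1, 1), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 3))
}

#' Simulate replicate fold changes from a truth table
#'
#' Every replicate observation is its feature's true condition mean plus
#' independent Gaussian noise of standard deviation `noise_sd`. The sample
#' layout is `n_replicates` per condition in the order A, B, AB.
#'
#' @param truth A `synthetic_truth` table from [generate_truth_table()].
#' @param config The matching [generator_config()]; its `seed` (offset to
#'   decouple it from the truth draw) makes the matrix reproducible.
#' @param stimulus_names Stimulus labels for the sample sheet.
#' @return A [fold_change_matrix()]; the truth is attached as attribute
#'   `"truth"` for convenience.
#' @export
simulate_fold_changes <- function(truth, config,
                                  stimulus_names = c("HT", "G")) {
  stopifnot(nrow(truth) > 0)
  nr <- config$n_replicates
  samples <- replicate_samples(nr, stimulus_names)
  mu <- cbind(matrix(truth$mu_A, nrow(truth), nr),
              matrix(truth$mu_B, nrow(truth), nr),
              matrix(truth$mu_AB, nrow(truth), nr))
  withr::local_seed(config$seed + 104729L)  # decoupled stream from the truth draw
  vals <- mu + matrix(rnorm(length(mu), sd = config$noise_sd),
                      nrow(mu), ncol(mu))
  rownames(vals) <- truth$feature_id
  fc <- fold_change_matrix(vals, samples, stimulus_names = stimulus_names)
  attr(fc, "truth") <- truth
  fc
}

#' Simulate a strictly additive (non-epistatic) null data set
#'
#' Single-stimulus means are drawn from `Uniform(effect_range)` and the
#' concurrent mean is exactly their sum, so no feature is epistatic by
#' construction. Used to calibrate the type-I error of [epistasis_test()].
#'
#' @param n_features Number of features.
#' @param noise_sd Replicate standard deviation (log2 units).
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @param effect_range Range of the uniform draw for `mu_A` and `mu_B`;
#'   `c(0, 0)` gives the all-null data set.
#' @return A [fold_change_matrix()] with a `synthetic_truth`-style
#'   attribute `"truth"` (`class_label` is `NA`; `epistatic` all `FALSE`).
#' @export
simulate_additive_null <- function(n_features, noise_sd = 0.2,
                                   n_replicates = 3, seed = 1L,
                                   effect_range = c(-1, 1)) {
  if (n_features < 1) stop("n_features must be >= 1")
  withr::local_seed(seed)
  mu_a <- runif(n_features, effect_range[1], effect_range[2])
  mu_b <- runif(n_features, effect_range[1], effect_range[2])
  truth <- data.frame(
    feature_id = sprintf("N%0*d", nchar(n_features), seq_len(n_features)),
    class_label = NA_character_, pattern_id = NA_integer_,
    mu_A = mu_a, mu_B = mu_b, mu_AB = mu_a + mu_b, epistatic = FALSE)
  samples <- replicate_samples(n_replicates)
  mu <- cbind(matrix(truth$mu_A, n_features, n_replicates),
              matrix(truth$mu_B, n_features, n_replicates),
              matrix(truth$mu_AB, n_features, n_replicates))
  vals <- mu + matrix(rnorm(length(mu), sd = noise_sd), nrow(mu), ncol(mu))
  rownames(vals) <- truth$feature_id
  fc <- fold_change_matrix(vals, samples)
  attr(fc, "truth") <- truth
  fc
}

#' Simulate an exponential growth curve
#'
#' Optical density holds at `od0` through the lag phase, doubles every
#' `doubling_time` minutes afterwards, and saturates at `plateau_od`.
#' Optional multiplicative log-normal noise perturbs log OD.
#'
#' @param doubling_time Doubling time in minutes, > 0.
#' @param od0 Initial OD, > 0.
#' @param lag Lag-phase duration in minutes, >= 0.
#' @param duration Total duration in minutes.
#' @param interval Sampling interval in minutes (3 min emulates a plate
#'   reader).
#' @param noise_sd Standard deviation of Gaussian noise added to log OD.
#' @param plateau_od Stationary-phase ceiling.
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @param condition_label Label for the curve.
#' @return A [growth_curve()].
#' @export
simulate_growth_curves <- function(doubling_time = 90, od0 = 0.01, lag = 0,
                                   duration = 600, interval = 3,
                                   noise_sd = 0, plateau_od = 1.0,
                                   seed = NULL,
                                   condition_label = NA_character_) {
  if (doubling_time <= 0) stop("doubling_time must be > 0")
  if (od0 <= 0 || duration <= 0 || interval <= 0 || lag < 0 || noise_sd < 0)
    stop("invalid growth-curve parameters")
  times <- seq(0, duration, by = interval)
  od <- pmin(od0 * 2^(pmax(0, times - lag) / doubling_time), plateau_od)
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    od <- od * exp(rnorm(length(od), sd = noise_sd))
  }
  growth_curve(times, od, condition_label)
}

#' Write a synthetic data set (fold changes plus truth sidecar)
#'
#' @param fc A simulated [fold_change_matrix()] carrying a `"truth"`
#'   attribute.
#' @param path Output TSV path for the matrix; the truth table goes to
#'   `<path base>_truth.tsv`.
#' @return Paths written, invisibly.
#' @export
write_synthetic_dataset <- function(fc, path) {
  truth <- attr(fc, "truth")
  if (is.null(truth)) stop("fold-change matrix carries no truth attribute")
  write_fold_change_matrix(fc, path)
  truth_path <- paste0(sub("\\.tsv$", "", path), "_truth.tsv")
  write_tsv_det(as.data.frame(truth), truth_path)
  invisible(c(path, truth_path))
}
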