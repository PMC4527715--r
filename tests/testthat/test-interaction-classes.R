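# States are written as triples over (A, B, AB); "up"/"down" mean a
# significant change in that direction, "ns" no significant change.

state_fit <- function(state, alpha = 0.05) {
  beta <- ifelse(state == "up", 1, ifelse(state == "down", -1, 0.01))
  p <- ifelse(state == "ns", 0.5, 0.001)
  make_fit_row(beta, p)
}

classify_state <- function(state, responder = TRUE) {
  fits <- state_fit(state)
  calls <- suppressWarnings(classify_interactions(fits, responder))
  as.character(calls$class)
}

test_that("canonical patterns map to their interaction classes", {
  expect_equal(classify_state(c("up", "down", "up")), "A_DOMINANT")
  expect_equal(classify_state(c("down", "up", "up")), "B_DOMINANT")
  expect_equal(classify_state(c("up", "up", "up")), "NER")
  expect_equal(classify_state(c("down", "down", "down")), "NER")
  expect_equal(classify_state(c("up", "ns", "ns")), "SUPPRESSION")
  expect_equal(classify_state(c("ns", "ns", "down")), "DISCORDANT")
  expect_equal(classify_state(c("down", "down", "up")), "DISCORDANT")
  expect_equal(classify_state(c("up", "up", "up"), responder = FALSE),
               "NON_RESPONDER")
})

test_that("exhaustive pattern enumeration reproduces the theoretical counts", {
  pt <- pattern_table()
  expect_equal(nrow(pt), 27)
  counts <- table(pt$class)
  expect_equal(counts[["NER"]], 2)
  expect_equal(counts[["A_DOMINANT"]], 4)
  expect_equal(counts[["B_DOMINANT"]], 4)
  expect_equal(counts[["DISCORDANT"]], 8)
  expect_equal(counts[["SUPPRESSION"]], 8)
  expect_equal(counts[["NON_RESPONDER"]], 1)
})

test_that("rules are mutually exclusive and exhaustive over every state", {
  states <- c("up", "down", "ns")
  grid <- expand.grid(a = states, b = states, ab = states,
                      responder = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    cls <- classify_state(c(grid$a[i], grid$b[i], grid$ab[i]),
                          grid$responder[i])
    expect_length(cls, 1)
    expect_true(cls %in% c("NON_RESPONDER", "NER", "A_DOMINANT", "B_DOMINANT",
                           "DISCORDANT", "SUPPRESSION", "UNCLASSIFIED"))
    if (!grid$responder[i]) expect_equal(cls, "NON_RESPONDER")
    # structural invariants of the rules
    sig_ab <- grid$ab[i] != "ns"
    if (cls %in% c("A_DOMINANT", "B_DOMINANT", "DISCORDANT", "NER"))
      expect_true(sig_ab)
    if (cls == "SUPPRESSION") expect_false(sig_ab)
  }
  # the only responder state outside the five classes is all-non-significant
  expect_equal(classify_state(c("ns", "ns", "ns")), "UNCLASSIFIED")
})

test_that("pattern ids index the pattern table consistently", {
  pt <- pattern_table()
  expect_equal(envepi:::pattern_id_lookup(pt$state_A, pt$state_B, pt$state_AB),
               pt$pattern_id)
  # observed pattern ids agree with the truth whenever the observed
  # significance/direction state reproduces the generating pattern
  cfg <- generator_config(n_features = 200, seed = 13)
  truth <- generate_truth_table(cfg)
  fc <- simulate_fold_changes(truth, cfg)
  res <- run_interaction_pipeline(fc)
  match_frac <- mean(res$calls$pattern_id == truth$pattern_id)
  expect_gte(match_frac, 0.85)
})

test_that("epistasis statistic follows the combined-standard-error formula", {
  fits <- make_fit_row(c(1, 1, 2), c(0.001, 0.001, 0.001))
  epi <- epistasis_test(fits)
  expect_equal(epi$t_stat, 0)
  expect_equal(epi$p, 1)
  expect_false(epi$epistatic)
  expect_equal(epi$se_sum, sqrt(0.02))
  fits2 <- make_fit_row(c(1, 1, 2.6), c(0.001, 0.001, 0.001))
  epi2 <- epistasis_test(fits2)
  expect_equal(epi2$t_stat, -0.6 / sqrt(0.03), tolerance = 1e-12)
  expect_equal(abs(epi2$t_stat), 3.4641, tolerance = 1e-4)
  expect_equal(epi2$p, 2 * pt(-3.4641, 6), tolerance = 1e-4)
  expect_true(epi2$epistatic)
})

test_that("epistasis call is invariant under swapping the stimulus labels", {
  set.seed(44)
  for (i in 1:20) {
    beta <- runif(3, -2, 2); se <- runif(3, 0.05, 0.3)
    f1 <- make_fit_row(beta, c(0.01, 0.01, 0.01), se)
    f2 <- make_fit_row(beta[c(2, 1, 3)], c(0.01, 0.01, 0.01), se[c(2, 1, 3)])
    expect_equal(epistasis_test(f1)$t_stat, epistasis_test(f2)$t_stat)
  }
})

test_that("zero-standard-error epistasis uses the exact-additivity convention", {
  f_add <- make_fit_row(c(1, -1, 0), c(0, 0, 1), se = c(0, 0, 0))
  epi <- suppressWarnings(epistasis_test(f_add))
  expect_false(epi$epistatic)
  expect_equal(epi$p, 1)
  f_epi <- make_fit_row(c(1, 1, 0), c(0, 0, 1), se = c(0, 0, 0))
  epi2 <- suppressWarnings(epistasis_test(f_epi))
  expect_true(epi2$epistatic)
  expect_equal(epi2$p, 0)
  expect_warning(epistasis_test(f_add), "zero combined standard error")
})

test_that("class and epistasis summaries partition the feature set", {
  cfg <- generator_config(n_features = 150, seed = 14)
  fc <- simulate_fold_changes(generate_truth_table(cfg), cfg)
  res <- run_interaction_pipeline(fc)
  s <- res$summary
  expect_equal(sum(unlist(s$class_counts)), 150)
  expect_equal(sum(unlist(s$epistasis_counts)), 150)
  # mismatched feature sets are refused
  expect_error(summarize_classes(res$calls[-1, ], res$epistasis),
               "different features")
})

test_that("classification recovers generator truth with high fidelity", {
  cfg <- generator_config(n_features = 200, effect_size = 1, noise_sd = 0.2,
                          n_replicates = 3, seed = 15)
  truth <- generate_truth_table(cfg)
  fc <- simulate_fold_changes(truth, cfg)
  res <- run_interaction_pipeline(fc)
  acc <- mean(as.character(res$calls$class) == truth$class_label)
  expect_gte(acc, 0.9)
})
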