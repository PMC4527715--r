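test_that("PQN removes a constructed dilution factor", {
  set.seed(51)
  x1 <- runif(40, 0.5, 2)
  x <- cbind(s1 = x1, s2 = 2 * x1, s3 = x1)
  out <- pqn_normalize(x)
  expect_equal(out[, "s2"], out[, "s1"], tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical columns are left unchanged
  same <- cbind(x1, x1, x1)
  expect_equal(unname(pqn_normalize(same)), unname(same), tolerance = 1e-12,
               ignore_attr = TRUE)
  # definitional property: per-sample median quotient against the original
  # reference profile equals 1 after normalization
  y <- matrix(runif(200, 0.1, 5), 50, 4)
  ny <- pqn_normalize(y)
  ref <- apply(y, 1, median)
  quot <- apply(ny / ref, 2, median)
  expect_equal(unname(quot), rep(1, 4), tolerance = 1e-10)
  expect_error(pqn_normalize(matrix(0, 5, 3)), "below eps")
})

test_that("generalized log transform has its defining properties", {
  expect_equal(glog_transform(0, 1), log(0.5))
  set.seed(52)
  x <- sort(runif(50, -10, 10))
  g <- glog_transform(x, 2)
  expect_true(all(diff(g) > 0))          # strictly increasing, negatives ok
  expect_equal(glog_transform(1e6, 1) / log(1e6), 1, tolerance = 1e-6)
  expect_error(glog_transform(1, lambda = 0), "lambda")
})

test_that("standardization yields exact zero mean and unit sd per feature", {
  set.seed(53)
  x <- matrix(rnorm(60, 5, 3), 6, 10)
  z <- standardize_features(x)
  expect_equal(rowMeans(z), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 6), tolerance = 1e-12)
  expect_equal(standardize_features(z), z, tolerance = 1e-12)  # idempotent
  single <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(unname(standardize_features(single)), rbind(c(-1, 0, 1)))
  xz <- rbind(x, 0)
  expect_error(standardize_features(xz), "zero-variance")
})

test_that("partial-correlation estimator has its limiting behaviours", {
  set.seed(54)
  # p = 2, no penalty: the partial correlation is the correlation
  x2 <- standardize_features(matrix(rnorm(100), 2, 50))
  pc2 <- space_partial_correlations(x2, tuning = 0)
  expect_equal(pc2[1, 2], cor(x2[1, ], x2[2, ]), tolerance = 1e-8)
  # heavy penalty: empty off-diagonal
  x5 <- standardize_features(matrix(rnorm(250), 5, 50))
  pc_big <- space_partial_correlations(x5, tuning = 1e6)
  expect_true(all(pc_big[upper.tri(pc_big)] == 0))
  # symmetry and boundedness at the default tuning
  pc5 <- space_partial_correlations(x5)
  expect_equal(pc5, t(pc5), tolerance = 1e-10)
  expect_true(all(abs(pc5) <= 1 + 1e-9))
})

test_that("unpenalized estimate equals sample partial correlation (inversion)", {
  set.seed(55)
  x <- matrix(rnorm(600), 3, 200) + rep(rnorm(200), each = 3) * 0.8
  x <- standardize_features(x)
  pc <- space_partial_correlations(x, tuning = 0, outer_iter = 10)
  P <- -stats::cov2cor(solve(cov(t(x))))
  diag(P) <- 1
  expect_equal(unname(pc), unname(P), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("chain-graph structure is recovered at the default tuning", {
  set.seed(56)
  Om <- chain_precision(10, 0.4)
  x <- standardize_features(t(rmvnorm_prec(500, Om)))
  pc <- space_partial_correlations(x)
  adjacent <- row(Om) == col(Om) - 1
  # every true conditional dependency detected, with the correct sign
  expect_true(all(pc[adjacent] > 0))
  # true-edge estimates dominate any spurious nonzeros, so the mean-|pcorr|
  # edge rule reproduces the chain exactly
  net <- build_network(pc)
  expect_equal(nrow(net$edges), 9)
  expect_equal(sort(paste(net$edges$node1, net$edges$node2)),
               sort(paste0("V", 1:9, " V", 2:10)))
})

test_that("edge rule thresholds at the mean absolute off-diagonal value", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.8
  m[1, 3] <- m[3, 1] <- 0.1
  m[2, 3] <- m[3, 2] <- -0.3
  net <- build_network(m)        # mean |offdiag| = 0.4, one edge above it
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.8)
  expect_equal(unname(net$degrees), c(1, 1, 0))
  expect_equal(net$n_connected, 2)
  flat <- diag(3); flat[upper.tri(flat)] <- 0.5
  flat[lower.tri(flat)] <- 0.5
  expect_equal(nrow(build_network(flat)$edges), 0)  # strict inequality
  expect_equal(nrow(build_network(diag(3))$edges), 0)
})

test_that("in-package Hurwitz zeta agrees with the reference Riemann zeta", {
  skip_if_not_installed("pracma")
  for (s in c(1.5, 2, 3, 4.5))
    expect_equal(envepi:::hurwitz_zeta(s, 1), pracma::zeta(s),
                 tolerance = 1e-10)
  # shifting q drops leading terms of the series
  expect_equal(envepi:::hurwitz_zeta(3, 3),
               envepi:::hurwitz_zeta(3, 1) - 1 - 2^-3, tolerance = 1e-10)
})

test_that("power-law MLE recovers a known exponent; degenerate input flagged", {
  set.seed(57)
  d <- rpowerlaw(5000, alpha = 3)
  fit <- fit_power_law(d)
  expect_equal(fit$alpha, 3, tolerance = 0.15)
  expect_false(fit$poor_fit)
  expect_error(fit_power_law(rep(2, 50)), "all degrees equal")
  two_vals <- c(rep(1, 40), rep(2, 10))
  expect_true(fit_power_law(two_vals)$poor_fit)
  expect_error(fit_power_law(1:5), "at least 10 nodes")
})

test_that("preferential-attachment-like degrees give a plausible exponent", {
  set.seed(58)
  # grow a 1000-node graph, each new node attaching proportionally to degree
  deg <- c(1, 1)
  targets <- c(1, 2)
  for (v in 3:1000) {
    t <- targets[sample.int(length(targets), 1)]
    deg[t] <- deg[t] + 1
    deg <- c(deg, 1)
    targets <- c(targets, t, v)
  }
  fit <- fit_power_law(deg)
  expect_gte(fit$alpha, 2)
  expect_lte(fit$alpha, 4)
})

test_that("hub detection, stability and significance behave as defined", {
  # star graph: the center is the unique hub at hub_fraction 1%
  p <- 100
  m <- diag(p)
  m[1, 2:p] <- m[2:p, 1] <- 0.9
  dimnames(m) <- list(paste0("n", 1:p), paste0("n", 1:p))
  net <- build_network(m)
  hubs <- find_hubs(net, hub_fraction = 0.01)
  expect_equal(hubs$hubs, "n1")
  expect_equal(hubs$jaccard, 1.0)       # single network: identity convention
  expect_lt(hubs$wilcoxon_p, 0.05)
  # identical grid networks keep Jaccard at 1; disjoint hub sets give 0
  expect_equal(find_hubs(net, 0.01, list(net, net))$jaccard, 1.0)
  m2 <- diag(p)
  m2[2, 3:p] <- m2[3:p, 2] <- 0.9
  dimnames(m2) <- dimnames(m)
  net2 <- build_network(m2)
  expect_equal(find_hubs(net, 0.01, list(net2))$jaccard, 0.0)
  edgeless <- build_network(diag(3))
  expect_error(find_hubs(edgeless), "no edges")
})

test_that("edge tallies form two partitions of the edge set", {
  set.seed(59)
  p <- 30
  m <- diag(p)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  sel <- pairs[sample.int(nrow(pairs), 60), ]
  m[sel] <- runif(60, 0.5, 1)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(paste0("f", 1:p), paste0("f", 1:p))
  ann <- data.frame(feature_id = paste0("f", 1:p),
                    class = sample(c("NER", "SUPPRESSION", "A_DOMINANT"), p,
                                   replace = TRUE),
                    epistatic = sample(c(TRUE, FALSE), p, replace = TRUE))
  net <- build_network(m, annotations = ann)
  tal <- classify_edges(net)
  expect_equal(sum(tal$epistasis_tally), tal$n_edges)
  expect_equal(sum(tal$class_tally), tal$n_edges)
  # all-epistatic annotation forces the degenerate tally
  ann2 <- ann; ann2$epistatic <- TRUE
  tal2 <- classify_edges(build_network(m, annotations = ann2))
  expect_equal(unname(tal2$epistasis_tally[c("neither", "mixed")]), c(0, 0))
  ann3 <- ann[-1, ]
  expect_error(classify_edges(build_network(m, annotations = ann3)),
               "unannotated")
})
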