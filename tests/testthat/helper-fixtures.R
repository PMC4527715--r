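# Shared fixture builders. All synthetic data is generated in code at test
# time; no files are stored.

# Minimal fold-change matrix from explicit condition blocks.
make_fc <- function(a, b, ab, feature_ids = NULL) {
  a <- rbind(a); b <- rbind(b); ab <- rbind(ab)
  vals <- cbind(a, b, ab)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(vals)))
  rownames(vals) <- feature_ids
  samples <- data.frame(
    sample_id = paste0("s", seq_len(ncol(vals))),
    stimulus_a = rep(c(1, 0, 1), c(ncol(a), ncol(b), ncol(ab))),
    stimulus_b = rep(c(0, 1, 1), c(ncol(a), ncol(b), ncol(ab))),
    replicate = c(seq_len(ncol(a)), seq_len(ncol(b)), seq_len(ncol(ab))))
  fold_change_matrix(vals, samples)
}

# One-row fits table built directly from estimates and p-values, for
# exercising the classification rules without fitting.
make_fit_row <- function(beta, p, se = c(0.1, 0.1, 0.1), df = 6,
                         feature_id = "f1") {
  data.frame(feature_id = feature_id,
             beta_A = beta[1], beta_B = beta[2], beta_AB = beta[3],
             se_A = se[1], se_B = se[2], se_AB = se[3],
             p_A = p[1], p_B = p[2], p_AB = p[3],
             dir_A = sign(beta[1]), dir_B = sign(beta[2]),
             dir_AB = sign(beta[3]),
             n_A = 3, n_B = 3, n_AB = 3, df_resid = df,
             f_stat = NA_real_, anova_p = NA_real_, zero_variance = FALSE,
             q = NA_real_)
}

# Independent brute-force BH step-up, the oracle for adjust_fdr_bh.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[ord[k]] / k)
    adj[ord[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Sample n observations from N(0, solve(precision)) via Cholesky.
rmvnorm_prec <- function(n, precision) {
  L <- chol(solve(precision))
  matrix(rnorm(n * nrow(precision)), n) %*% L
}

# Tridiagonal chain-graph precision matrix with off-diagonal -rho.
chain_precision <- function(p, rho = 0.4) {
  Om <- diag(p)
  for (i in seq_len(p - 1)) Om[i, i + 1] <- Om[i + 1, i] <- -rho
  Om
}
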