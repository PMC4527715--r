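# Per-feature factorial model of log2 fold change under the 2x2 stimulus
# design, in the cell-means parameterization: one coefficient per test
# condition (A alone, B alone, A+B concurrent), no intercept. Because the
# response is a fold change relative to the unstimulated baseline, the
# baseline mean is identically zero and the cell-means model is the
# saturated main-effects + interaction factorial model refit to condition
# means; the third coefficient is the concurrent-condition mean itself, not
# the interaction contrast, which is what the interaction-class rules and
# the epistasis test threshold.

#' Fit the factorial response model for every feature
#'
#' For each feature the three condition means are estimated jointly with a
#' pooled residual variance:
#' \deqn{\hat\beta_c = \bar y_c, \quad s^2 = SS_{within}/(n-3), \quad
#'       se_c = s/\sqrt{n_c}}
#' Coefficient p-values come from \eqn{t_c = \hat\beta_c / se_c} on
#' \eqn{n-3} df; the overall ANOVA tests all three condition means jointly
#' zero with the no-intercept F statistic
#' \eqn{F = [\sum_c n_c \hat\beta_c^2 / 3] / s^2} on \eqn{(3, n-3)} df.
#' Overall p-values are Benjamini-Hochberg adjusted across all features
#' (`q`); coefficient p-values are left raw.
#'
#' Replicate counts may be unbalanced, but every condition needs at least
#' two samples. Features with exactly zero residual variance (possible for
#' noiseless synthetic input) use the convention p = 0 for a nonzero
#' estimate and p = 1 for a zero estimate, and are flagged in the
#' `zero_variance` column.
#'
#' @param fc A [fold_change_matrix()].
#' @return A data frame of class `feature_model_fits`, one row per feature:
#'   `beta_A`, `beta_B`, `beta_AB` (log2 units), `se_*`, `p_*`, `dir_*`
#'   (sign of the estimate), `n_*`, `df_resid`, `f_stat`, `anova_p`, `q`,
#'   `zero_variance`.
#' @seealso [fit_feature_model()] for a single feature,
#'   [call_responders()], [classify_interactions()], [epistasis_test()].
#' @export
fit_models <- function(fc) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  vals <- fc$values
  cols <- lapply(c(A = "A", B = "B", AB = "AB"), condition_columns, fc = fc)
  n_c <- vapply(cols, length, 1L)
  short <- names(n_c)[n_c < 2]
  if (length(short))
    stop("insufficient replication: condition(s) ",
         paste(short, collapse = ", "), " have fewer than 2 samples")
  n <- sum(n_c)
  df_resid <- n - 3L

  nf <- nrow(vals)
  beta <- vapply(cols, function(ix) rowMeans(vals[, ix, drop = FALSE]),
                 numeric(nf))
  if (nf == 1) beta <- matrix(beta, 1, dimnames = list(NULL, names(cols)))
  ss_mat <- vapply(names(cols), function(cc) {
    rowSums((vals[, cols[[cc]], drop = FALSE] - beta[, cc])^2)
  }, numeric(nf))
  if (nf == 1) ss_mat <- matrix(ss_mat, 1)
  ss_within <- rowSums(ss_mat)
  s2 <- ss_within / df_resid
  zero_var <- s2 == 0

  se <- sqrt(outer(s2, 1 / n_c))
  colnames(se) <- names(cols)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_resid)
  # zero-residual-variance convention: certain calls, flagged
  if (any(zero_var)) {
    pval[zero_var, ] <- ifelse(beta[zero_var, , drop = FALSE] != 0, 0, 1)
  }
  f_num <- as.vector(beta^2 %*% n_c) / 3
  f_stat <- f_num / s2
  anova_p <- pf(f_stat, 3, df_resid, lower.tail = FALSE)
  if (any(zero_var)) {
    all_null <- rowSums(beta[zero_var, , drop = FALSE] != 0) == 0
    anova_p[zero_var] <- ifelse(all_null, 1, 0)
    f_stat[zero_var] <- ifelse(all_null, 0, Inf)
  }

  fits <- data.frame(
    feature_id = fc$feature_ids,
    beta_A = beta[, "A"], beta_B = beta[, "B"], beta_AB = beta[, "AB"],
    se_A = se[, "A"], se_B = se[, "B"], se_AB = se[, "AB"],
    p_A = pval[, "A"], p_B = pval[, "B"], p_AB = pval[, "AB"],
    dir_A = sign(beta[, "A"]), dir_B = sign(beta[, "B"]),
    dir_AB = sign(beta[, "AB"]),
    n_A = n_c[["A"]], n_B = n_c[["B"]], n_AB = n_c[["AB"]],
    df_resid = df_resid, f_stat = f_stat, anova_p = anova_p,
    zero_variance = zero_var,
    row.names = NULL)
  fits$q <- adjust_fdr_bh(fits$anova_p)
  if (any(zero_var))
    warning(sum(zero_var), " feature(s) had zero residual variance; ",
            "p-values use the degenerate-variance convention")
  class(fits) <- c("feature_model_fits", "data.frame")
  fits
}

#' Fit the factorial model for a single feature
#'
#' Convenience wrapper around the same closed-form cell-means fit as
#' [fit_models()], for replicate vectors grouped by condition. The returned
#' row has no `q` column (BH adjustment is only meaningful across a feature
#' family).
#'
#' @param a_values,b_values,ab_values Numeric replicate fold changes for
#'   stimulus A alone, stimulus B alone, and the concurrent condition; each
#'   of length >= 2.
#' @param feature_id Feature identifier for the output row.
#' @return One-row data frame with the [fit_models()] columns except `q`.
#' @export
fit_feature_model <- function(a_values, b_values, ab_values,
                              feature_id = "feature") {
  vals <- matrix(c(a_values, b_values, ab_values), nrow = 1,
                 dimnames = list(feature_id, NULL))
  samples <- data.frame(
    sample_id = paste0("s", seq_len(ncol(vals))),
    stimulus_a = rep(c(1, 0, 1), c(length(a_values), length(b_values),
                                   length(ab_values))),
    stimulus_b = rep(c(0, 1, 1), c(length(a_values), length(b_values),
                                   length(ab_values))),
    replicate = c(seq_along(a_values), seq_along(b_values),
                  seq_along(ab_values)))
  fit <- suppressWarnings(fit_models(fold_change_matrix(vals, samples)))
  fit$q <- NULL
  fit
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone in rank, capped at 1),
#' returned in the input order. Input values must lie in `[0, 1]`.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr_bh <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

#' Call responders from BH-adjusted overall p-values
#'
#' A feature responds to the stimulus design if its BH-adjusted overall
#' ANOVA p-value is at or below `q_threshold`; otherwise it is a
#' non-responder. The boundary value counts as a responder.
#'
#' @param fits A `feature_model_fits` table with a `q` column.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Named logical vector (feature ids), with attribute `counts`
#'   giving the responder / non-responder totals.
#' @export
call_responders <- function(fits, q_threshold = 0.05) {
  if (is.null(fits$q)) stop("fits must carry BH-adjusted q-values")
  resp <- fits$q <= q_threshold
  names(resp) <- fits$feature_id
  attr(resp, "counts") <- c(responders = sum(resp),
                            non_responders = sum(!resp))
  resp
}

#' Per-stimulus differential-expression calls
#'
#' A responder is differentially expressed in a condition when that
#' condition's coefficient p-value is strictly below `alpha`; non-responders
#' are never called, whatever their coefficient p-values.
#'
#' @param fits A `feature_model_fits` table.
#' @param responders Logical vector from [call_responders()].
#' @param alpha Coefficient significance level (default 0.05, strict `<`).
#' @return Data frame `feature_id`, `de_A`, `de_B`, `de_AB` with attribute
#'   `totals` (per-condition DE counts).
#' @export
stimulus_de_calls <- function(fits, responders, alpha = 0.05) {
  stopifnot(length(responders) == nrow(fits))
  de <- data.frame(feature_id = fits$feature_id,
                   de_A = responders & fits$p_A < alpha,
                   de_B = responders & fits$p_B < alpha,
                   de_AB = responders & fits$p_AB < alpha,
                   row.names = NULL)
  attr(de, "totals") <- c(A = sum(de$de_A), B = sum(de$de_B),
                          AB = sum(de$de_AB))
  de
}
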