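# Environmental interaction classes, by analogy with gene interaction.
# Each feature's state is a triple over {significant up, significant down,
# non-significant} for the three test conditions (A, B, AB). The classes:
#   NER          all three significant, same direction (non-specific
#                environmental response)
#   A_DOMINANT   A and AB significant and concordant; B absent or overridden
#   B_DOMINANT   mirror image
#   SUPPRESSION  a single-stimulus response abolished in the concurrent
#                condition (AB non-significant, A or B significant)
#   DISCORDANT   significant concurrent response matched in direction by
#                neither single stimulus
# plus NON_RESPONDER (failed the overall-FDR gate) and UNCLASSIFIED
# (responder with no coefficient-level support; possible because the joint
# F can fire when no single t does).

INTERACTION_CLASSES <- c("NON_RESPONDER", "NER", "A_DOMINANT", "B_DOMINANT",
                         "DISCORDANT", "SUPPRESSION", "UNCLASSIFIED")

# Core decision rules on significance flags and directions of change.
# Evaluated in fixed order; NER precedes dominance to resolve their only
# overlap (all-significant, all-concordant).
classify_triple <- function(responder, sig_a, sig_b, sig_ab,
                            dir_a, dir_b, dir_ab) {
  if (!responder) return("NON_RESPONDER")
  if (sig_a && sig_b && sig_ab && dir_a == dir_ab && dir_b == dir_ab)
    return("NER")
  if (sig_a && sig_ab && dir_a == dir_ab && (!sig_b || dir_b != dir_ab))
    return("A_DOMINANT")
  if (sig_b && sig_ab && dir_b == dir_ab && (!sig_a || dir_a != dir_ab))
    return("B_DOMINANT")
  if (!sig_ab && (sig_a || sig_b))
    return("SUPPRESSION")
  if (sig_ab && (!sig_a || dir_a != dir_ab) && (!sig_b || dir_b != dir_ab))
    return("DISCORDANT")
  "UNCLASSIFIED"
}

state_from_sig_dir <- function(sig, dir) {
  ifelse(sig & dir > 0, "up", ifelse(sig & dir < 0, "down", "ns"))
}

#' The theoretical expression-pattern table
#'
#' Enumerates all 27 states a feature can occupy — each of the three test
#' conditions significantly up, significantly down, or unchanged — and the
#' interaction class each state implies. The class sizes over this table
#' are a structural property of the rules: 2 non-specific-response
#' patterns, 4 per dominance class, 8 discordant, 8 suppression, and the
#' single all-unchanged pattern (a non-responder).
#'
#' @return Data frame with `pattern_id` (1-27), `state_A`, `state_B`,
#'   `state_AB` (each `"up"`, `"down"` or `"ns"`) and `class`.
#' @export
pattern_table <- function() {
  states <- c("up", "down", "ns")
  grid <- expand.grid(state_A = states, state_B = states, state_AB = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sig <- function(s) s != "ns"
  dir <- function(s) ifelse(s == "up", 1L, ifelse(s == "down", -1L, 0L))
  cls <- mapply(function(a, b, ab) {
    if (!sig(a) && !sig(b) && !sig(ab)) return("NON_RESPONDER")
    classify_triple(TRUE, sig(a), sig(b), sig(ab), dir(a), dir(b), dir(ab))
  }, grid$state_A, grid$state_B, grid$state_AB, USE.NAMES = FALSE)
  data.frame(pattern_id = seq_len(nrow(grid)), grid, class = cls)
}

pattern_id_lookup <- function(state_a, state_b, state_ab) {
  states <- c("up", "down", "ns")
  ia <- match(state_a, states); ib <- match(state_b, states)
  iab <- match(state_ab, states)
  ia + 3L * (ib - 1L) + 9L * (iab - 1L)
}

#' Classify features into environmental interaction classes
#'
#' Applies the decision rules to each fitted feature: significance of a
#' condition's estimate means coefficient p-value strictly below `alpha`,
#' direction is the sign of the estimate, and the overall responder gate
#' comes from `responders`. Non-responders are labelled before any pattern
#' rule is consulted. `UNCLASSIFIED` responders (no coefficient support)
#' trigger a warning, since a coherent factorial data set should have none.
#'
#' @param fits A `feature_model_fits` table from [fit_models()].
#' @param responders Logical vector from [call_responders()].
#' @param alpha Coefficient-level significance threshold (strict `<`).
#' @return Data frame of class `interaction_calls`: `feature_id`, `class`,
#'   `pattern_id` (index into [pattern_table()]), `ner_direction`
#'   (`"up"`/`"down"` for NER features, `NA` otherwise).
#' @export
classify_interactions <- function(fits, responders, alpha = 0.05) {
  stopifnot(length(responders) == nrow(fits))
  sig_a <- fits$p_A < alpha; sig_b <- fits$p_B < alpha
  sig_ab <- fits$p_AB < alpha
  cls <- character(nrow(fits))
  for (i in seq_len(nrow(fits)))
    cls[i] <- classify_triple(responders[i], sig_a[i], sig_b[i], sig_ab[i],
                              fits$dir_A[i], fits$dir_B[i], fits$dir_AB[i])
  st_a <- state_from_sig_dir(sig_a, fits$dir_A)
  st_b <- state_from_sig_dir(sig_b, fits$dir_B)
  st_ab <- state_from_sig_dir(sig_ab, fits$dir_AB)
  calls <- data.frame(
    feature_id = fits$feature_id,
    class = factor(cls, levels = INTERACTION_CLASSES),
    pattern_id = pattern_id_lookup(st_a, st_b, st_ab),
    ner_direction = ifelse(cls == "NER",
                           ifelse(fits$dir_AB > 0, "up", "down"),
                           NA_character_),
    row.names = NULL)
  if (any(cls == "UNCLASSIFIED"))
    warning(sum(cls == "UNCLASSIFIED"),
            " responder(s) matched no interaction pattern (UNCLASSIFIED)")
  class(calls) <- c("interaction_calls", "data.frame")
  calls
}

#' Test features for environmental epistasis
#'
#' Environmental epistasis is non-independence of the two stimulus effects:
#' the concurrent-condition response differs from the sum of the
#' single-stimulus responses. For each feature the single-stimulus
#' estimates are summed, the combined standard error is the square root of
#' the sum of the squared standard errors, and a two-sample t statistic
#' compares the sum to the concurrent estimate:
#' \deqn{t = \frac{(\hat\beta_A + \hat\beta_B) - \hat\beta_{AB}}
#'             {\sqrt{se_A^2 + se_B^2 + se_{AB}^2}}}
#' Two-sided p-values use the feature's residual df by default
#' (`df_method = "residual"`; the three standard errors share one pooled
#' variance, making the statistic exactly t-distributed under additivity)
#' or a Welch-Satterthwaite approximation on the per-condition df. The test
#' applies to every feature, responder or not. Features whose standard
#' errors are all zero use the convention: epistatic iff the additive
#' deviation exceeds 1e-9, with p set to 0 or 1 accordingly.
#'
#' @param fits A `feature_model_fits` table.
#' @param alpha Significance threshold; epistatic iff `p <= alpha`.
#' @param df_method `"residual"` (default) or `"satterthwaite"`.
#' @return Data frame of class `epistasis_results`: `feature_id`,
#'   `sum_effect`, `se_sum`, `t_stat`, `df`, `p`, `epistatic`,
#'   `zero_se` flag.
#' @export
epistasis_test <- function(fits, alpha = 0.05,
                           df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  sum_effect <- fits$beta_A + fits$beta_B
  se_sum <- sqrt(fits$se_A^2 + fits$se_B^2)
  se_tot <- sqrt(fits$se_A^2 + fits$se_B^2 + fits$se_AB^2)
  delta <- sum_effect - fits$beta_AB
  if (df_method == "residual") {
    df <- fits$df_resid
  } else {
    df <- se_tot^4 / (fits$se_A^4 / (fits$n_A - 1) +
                      fits$se_B^4 / (fits$n_B - 1) +
                      fits$se_AB^4 / (fits$n_AB - 1))
  }
  zero_se <- se_tot == 0
  t_stat <- ifelse(zero_se, ifelse(abs(delta) > 1e-9, Inf, 0), delta / se_tot)
  p <- ifelse(zero_se, ifelse(abs(delta) > 1e-9, 0, 1),
              2 * pt(-abs(delta / se_tot), df))
  if (any(zero_se))
    warning(sum(zero_se), " feature(s) had zero combined standard error; ",
            "epistasis calls use the degenerate-variance convention")
  res <- data.frame(feature_id = fits$feature_id, sum_effect = sum_effect,
                    se_sum = se_sum, t_stat = t_stat, df = df, p = p,
                    epistatic = p <= alpha, zero_se = zero_se,
                    row.names = NULL)
  class(res) <- c("epistasis_results", "data.frame")
  res
}

#' Summarise interaction classes and epistasis calls
#'
#' Tallies features per interaction class and per epistasis flag and checks
#' the conservation identities: classes partition the feature set, and
#' epistatic plus non-epistatic features equal the total.
#'
#' @param calls An `interaction_calls` table.
#' @param epi An `epistasis_results` table over the same features.
#' @return List with `n_features`, `class_counts` (named integer vector
#'   over all class labels), `epistasis_counts` (`epistatic`,
#'   `non_epistatic`), and `class_by_epistasis` (cross-tabulation).
#' @export
summarize_classes <- function(calls, epi) {
  if (!setequal(calls$feature_id, epi$feature_id) ||
      nrow(calls) != nrow(epi))
    stop("interaction calls and epistasis results cover different features")
  epi <- epi[match(calls$feature_id, epi$feature_id), ]
  class_counts <- table(factor(calls$class, levels = INTERACTION_CLASSES))
  epi_counts <- c(epistatic = sum(epi$epistatic),
                  non_epistatic = sum(!epi$epistatic))
  stopifnot(sum(class_counts) == nrow(calls),
            sum(epi_counts) == nrow(calls))
  list(n_features = nrow(calls),
       class_counts = setNames(as.integer(class_counts),
                               names(class_counts)),
       epistasis_counts = epi_counts,
       class_by_epistasis = table(class = calls$class,
                                  epistatic = epi$epistatic))
}
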