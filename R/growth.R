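# Doubling times from OD time series and additivity testing of stimulus
# effects on growth. Doubling time is 1/slope of log2(OD) vs time over the
# log-growth phase; the log phase is found as the sliding window of fixed
# duration maximizing the slope subject to a linearity (R^2) floor, which
# excludes lag and stationary plateau automatically.

#' Estimate doubling time from a growth curve
#'
#' Regresses log2(OD) on time within every sliding window of
#' `window_minutes` along the curve, keeps windows with at least
#' `min_points` observations and R^2 of at least `r2_floor`, and selects
#' the one with the steepest slope as the log-growth phase. Doubling time
#' is the reciprocal of that slope (minutes per doubling).
#'
#' @param curve A [growth_curve()].
#' @param window_minutes Window length in minutes (default 90).
#' @param min_points Minimum observations per window (default 10).
#' @param r2_floor Minimum R^2 for a window to qualify (default 0.98).
#' @return List of class `doubling_time_result`: `doubling_time` (minutes;
#'   `NA` for non-growing cultures), `slope` (log2 OD per minute),
#'   `window` (start/end minutes), `r_squared`, `n_points`, `non_growing`
#'   flag, `condition_label`.
#' @export
estimate_doubling_time <- function(curve, window_minutes = 90,
                                   min_points = 10, r2_floor = 0.98) {
  times <- curve$time
  y <- log2(curve$od)
  n <- length(times)
  best <- NULL
  for (start in seq_len(n)) {
    in_win <- which(times >= times[start] & times <= times[start] + window_minutes)
    if (length(in_win) < min_points) next
    tt <- times[in_win]; yy <- y[in_win]
    tc <- tt - mean(tt); yc <- yy - mean(yy)
    sxx <- sum(tc^2); sxy <- sum(tc * yc); syy <- sum(yc^2)
    slope <- sxy / sxx
    # an exactly flat window is a perfect zero-slope fit, so it qualifies
    # (and yields the non-growing flag if no steeper window exists)
    r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
    if (r2 < r2_floor) next
    if (is.null(best) || slope > best$slope)
      best <- list(slope = slope, r2 = r2,
                   window = c(start = tt[1], end = tt[length(tt)]),
                   n_points = length(in_win))
  }
  if (is.null(best))
    stop("no window of ", window_minutes, " min meets the R^2 floor of ",
         r2_floor, "; no log-growth phase found")
  non_growing <- best$slope <= 0
  structure(list(
    doubling_time = if (non_growing) NA_real_ else 1 / best$slope,
    slope = best$slope, window = best$window, r_squared = best$r2,
    n_points = best$n_points, non_growing = non_growing,
    condition_label = attr(curve, "condition_label")),
    class = "doubling_time_result")
}

#' Stimulus effects on doubling time
#'
#' For each test condition the effect is the mean doubling time minus the
#' control mean; its `sd` is the standard error of that difference of
#' means, \eqn{\sqrt{s_c^2/n_c + s_0^2/n_0}}, propagated from the
#' replicate scatter in both groups.
#'
#' @param doubling_times Data frame with columns `condition` and
#'   `doubling_time`, one row per replicate culture.
#' @param control_label Condition treated as the unstimulated control.
#' @return Data frame of class `growth_effects`: `stimulus`, `effect`
#'   (minutes), `sd` (standard error of the effect), `n`, `control_mean`,
#'   `df` (Welch degrees of freedom of the difference).
#' @export
stimulus_effects <- function(doubling_times, control_label = "control") {
  d <- as.data.frame(doubling_times)
  if (!all(c("condition", "doubling_time") %in% names(d)))
    stop("doubling_times needs columns `condition` and `doubling_time`")
  ctrl <- d$doubling_time[d$condition == control_label]
  if (length(ctrl) < 2) stop("control condition needs n >= 2 replicates")
  conds <- setdiff(unique(d$condition), control_label)
  m0 <- mean(ctrl); v0 <- var(ctrl); n0 <- length(ctrl)
  rows <- lapply(conds, function(cc) {
    x <- d$doubling_time[d$condition == cc]
    if (length(x) < 2) stop("condition '", cc, "' needs n >= 2 replicates")
    nc <- length(x); vc <- var(x)
    se2 <- vc / nc + v0 / n0
    df <- se2^2 / ((vc / nc)^2 / (nc - 1) + (v0 / n0)^2 / (n0 - 1))
    data.frame(stimulus = cc, effect = mean(x) - m0, sd = sqrt(se2),
               n = nc, control_mean = m0, df = df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_effects", "data.frame")
  out
}

#' Test additivity of concurrent stimulus effects on growth
#'
#' The expected concurrent effect is the sum of the single-stimulus
#' effects, with combined standard error the square root of the sum of
#' their squared `sd`s. A two-sample t statistic compares the observed
#' concurrent effect to that expectation, with Welch degrees of freedom
#' propagated from the components; the two-sided p-value is Bonferroni
#' corrected for `n_comparisons` (11 in the motivating 8-condition growth
#' design: 7 control contrasts, 3 two-stimulus additivity contrasts, 1
#' three-stimulus additivity contrast). Any number of single stimuli >= 2
#' is supported, so three-way designs test the same way.
#'
#' @param single_effects A `growth_effects` data frame (or compatible) with
#'   one row per single stimulus.
#' @param concurrent_effect One-row data frame for the concurrent
#'   condition (columns `effect`, `sd`, `df`).
#' @param n_comparisons Bonferroni family size (default 11).
#' @return List of class `additivity_test`: `observed`, `expected`,
#'   `combined_sd` (standard error of the expected sum,
#'   \eqn{\sqrt{\sum sd_i^2}}), `t_stat`, `df`, `p`, `p_adjusted`,
#'   `additive` (TRUE when the adjusted p exceeds 0.05).
#' @export
additivity_test <- function(single_effects, concurrent_effect,
                            n_comparisons = 11) {
  se_df <- as.data.frame(single_effects)
  if (nrow(se_df) < 2) stop("need at least 2 single-stimulus effects")
  conc <- as.data.frame(concurrent_effect)
  if (nrow(conc) != 1) stop("exactly one concurrent effect is required")
  expected <- sum(se_df$effect)
  sd_sum <- sqrt(sum(se_df$sd^2))
  se_tot2 <- conc$sd^2 + sd_sum^2
  if (se_tot2 == 0) {
    t_stat <- 0; df <- Inf; p <- 1
  } else {
    t_stat <- (conc$effect - expected) / sqrt(se_tot2)
    comp_var <- c(se_df$sd^2, conc$sd^2)
    comp_df <- c(se_df$df, conc$df)
    df <- se_tot2^2 / sum(comp_var^2 / comp_df)
    p <- 2 * pt(-abs(t_stat), df)
  }
  p_adj <- min(1, p * n_comparisons)
  structure(list(observed = conc$effect, expected = expected,
                 combined_sd = sd_sum, t_stat = t_stat, df = df,
                 p = p, p_adjusted = p_adj, additive = p_adj > 0.05,
                 n_comparisons = n_comparisons),
            class = "additivity_test")
}
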