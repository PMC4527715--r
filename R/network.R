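# Epistasis-aware coexpression network: probabilistic quotient
# normalization, generalized-log scaling, unit-variance standardization,
# sparse symmetric partial-correlation estimation by joint lasso
# regression, mean-of-matrix edge thresholding, power-law degree
# diagnostics, hub detection and edge-class tallies.

#' Network construction configuration
#'
#' @param glog_lambda Generalized-log transform parameter, > 0.
#' @param tuning L1 penalty for the partial-correlation estimator; `NULL`
#'   uses the canonical default [space_default_tuning()].
#' @param tuning_multipliers Multipliers around the tuning value at which
#'   the network is re-estimated for hub-stability (Jaccard) analysis.
#' @param hub_fraction Top fraction of nodes by degree called hubs,
#'   in (0, 0.5].
#' @param edge_rule `"mean_abs_offdiag"` (edge iff the absolute partial
#'   correlation exceeds the mean absolute off-diagonal value, zeros
#'   included) or `"fixed_threshold"`.
#' @param fixed_threshold Threshold used when `edge_rule =
#'   "fixed_threshold"`.
#' @param use_pqn,use_glog Toggle the two normalization steps.
#' @param seed Optional seed recorded in the run log.
#' @return List of class `network_config`.
#' @export
network_config <- function(glog_lambda = 1.0, tuning = NULL,
                           tuning_multipliers = c(0.7, 1, 1.3),
                           hub_fraction = 0.01,
                           edge_rule = c("mean_abs_offdiag", "fixed_threshold"),
                           fixed_threshold = NULL,
                           use_pqn = TRUE, use_glog = TRUE, seed = NULL) {
  edge_rule <- match.arg(edge_rule)
  if (glog_lambda <= 0) stop("glog_lambda must be > 0")
  if (!is.null(tuning) && tuning < 0) stop("tuning must be >= 0")
  if (hub_fraction <= 0 || hub_fraction > 0.5)
    stop("hub_fraction must lie in (0, 0.5]")
  structure(list(glog_lambda = glog_lambda, tuning = tuning,
                 tuning_multipliers = tuning_multipliers,
                 hub_fraction = hub_fraction, edge_rule = edge_rule,
                 fixed_threshold = fixed_threshold,
                 use_pqn = use_pqn, use_glog = use_glog, seed = seed),
            class = "network_config")
}

#' Probabilistic quotient normalization
#'
#' Per-sample dilution correction: the reference profile is the
#' feature-wise median across samples, each sample's dilution factor is the
#' median of its quotients against the reference (over features whose
#' reference value exceeds `eps` in magnitude), and the sample is divided
#' by its factor. Designed for positive intensity data; on signed
#' fold-change data the eps guard keeps the quotients defined, but the
#' step can be disabled via [network_config()].
#'
#' @param x Numeric matrix, features x samples, or a
#'   [fold_change_matrix()].
#' @param eps Reference magnitude below which a feature is excluded from
#'   the quotient median.
#' @return Same shape as the input, normalized; factors in attribute
#'   `"pqn_factors"`.
#' @export
pqn_normalize <- function(x, eps = 1e-8) {
  fc <- NULL
  if (inherits(x, "fold_change_matrix")) { fc <- x; x <- x$values }
  if (ncol(x) < 2) stop("PQN needs at least 2 samples")
  ref <- apply(x, 1, median)
  keep <- abs(ref) > eps
  if (!any(keep))
    stop("all reference (feature-median) values are below eps; cannot normalize")
  factors <- apply(x[keep, , drop = FALSE] / ref[keep], 2, median)
  if (any(factors == 0)) stop("a sample has zero dilution factor")
  out <- sweep(x, 2, factors, "/")
  attr(out, "pqn_factors") <- factors
  if (!is.null(fc)) { fc$values <- out; attr(fc, "pqn_factors") <- factors; return(fc) }
  out
}

#' Generalized logarithm transform
#'
#' `g(x) = ln((x + sqrt(x^2 + lambda)) / 2)`: behaves like `ln(x)` for
#' large positive `x`, stays defined and strictly increasing for negative
#' arguments, and damps variance near zero.
#'
#' @param x Numeric vector or matrix.
#' @param lambda Transform parameter, > 0.
#' @return Transformed values, same shape.
#' @export
glog_transform <- function(x, lambda = 1.0) {
  if (lambda <= 0) stop("lambda must be > 0")
  log((x + sqrt(x^2 + lambda)) / 2)
}

#' Standardize features to zero mean, unit variance
#'
#' @param x Numeric matrix, features x samples.
#' @return Matrix with every row centered and scaled to sd 1.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 1, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(rownames(x)[zero] %||% which(zero), collapse = ", "))
  (x - rowMeans(x)) / sds
}

#' Canonical default tuning for the sparse partial-correlation estimator
#'
#' `sqrt(n) * qnorm(1 - alpha / (2 p^2))`: the penalty level at which, under
#' independence, spurious pairwise associations are excluded at family
#' level `alpha` over all p^2 comparisons.
#'
#' @param n Number of samples.
#' @param p Number of features.
#' @param alpha Family-wise exclusion level (default 0.1).
#' @return The penalty value.
#' @export
space_default_tuning <- function(n, p, alpha = 0.1) {
  sqrt(n) * qnorm(1 - alpha / (2 * p^2))
}

#' Sparse partial correlations by joint symmetric lasso regression
#'
#' Estimates the partial-correlation matrix by regressing every feature on
#' all others simultaneously with a shared symmetric coefficient for each
#' pair: minimize
#' \deqn{\tfrac12 \sum_i w_i \| x_i - \sum_{j \ne i}
#'       \rho_{ij} \sqrt{d_j / d_i}\, x_j \|^2
#'       + \lambda \sum_{i<j} |\rho_{ij}|}
#' over symmetric \eqn{\rho}, solved by cyclic coordinate descent with
#' soft-thresholding. The weights \eqn{w_i} and scale factors \eqn{d_i}
#' are iteratively set to the estimated residual precisions
#' (\eqn{d_i = n / \|r_i\|^2}), which at \eqn{\lambda = 0} (and p < n)
#' makes the solution exactly the sample partial-correlation matrix from
#' inversion of the sample covariance.
#'
#' @param x Numeric matrix, features x samples (standardize first; see
#'   [standardize_features()]). At least 3 samples.
#' @param tuning L1 penalty \eqn{\lambda \ge 0}; `NULL` uses
#'   [space_default_tuning()].
#' @param outer_iter Number of weight-update (outer) iterations.
#' @param max_iter Maximum coordinate-descent sweeps per outer iteration.
#' @param tol Convergence threshold on the largest coefficient change.
#' @return p x p symmetric partial-correlation matrix with unit diagonal;
#'   attributes `tuning`, `converged`, `precisions`.
#' @export
space_partial_correlations <- function(x, tuning = NULL, outer_iter = 3,
                                       max_iter = 2000, tol = 1e-6) {
  x <- as.matrix(x)
  p <- nrow(x); n <- ncol(x)
  if (n < 3) stop("at least 3 samples are required")
  if (is.null(tuning)) tuning <- space_default_tuning(n, p)
  ids <- rownames(x) %||% paste0("V", seq_len(p))
  X <- t(x)                                   # n x p, column j = feature j
  ss <- colSums(X^2)
  rho <- matrix(0, p, p)
  d <- rep(1, p)                              # residual precisions
  R <- X + 0                                  # residuals given rho = 0 (fresh copy)
  converged <- FALSE

  for (outer in seq_len(outer_iter)) {
    # weights normalized to mean 1: relative precisions matter, a global
    # weight scale would silently rescale the penalty
    w <- d / mean(d)
    state <- .space_cd_sweeps(X, ss, rho, R, d, w, tuning, max_iter, tol)
    converged <- state$max_delta < tol
    if (outer < outer_iter) {          # "dew" update: reweight by residual precision
      d <- n / colSums(R^2)
      # rebuild residuals under the new scale factors
      B <- rho * sqrt(outer(1 / d, d)) # B[i, j] = rho_ij * sqrt(d_j / d_i)
      diag(B) <- 0
      R[] <- X - X %*% t(B)
    }
  }
  if (!converged)
    warning("partial-correlation estimator did not converge in ", max_iter,
            " sweeps; returning best iterate")
  dimnames(rho) <- list(ids, ids)
  diag(rho) <- 1
  attr(rho, "tuning") <- tuning
  attr(rho, "converged") <- converged
  attr(rho, "precisions") <- d
  rho
}

#' Threshold a partial-correlation matrix into a coexpression network
#'
#' Under the default rule an edge joins two features when the absolute
#' partial correlation between them exceeds the mean absolute off-diagonal
#' value of the matrix (zeros included; strict inequality). Isolated nodes
#' stay in the node list and are reported separately.
#'
#' @param pcorr Symmetric partial-correlation matrix (unit diagonal).
#' @param annotations Optional data frame `feature_id`, `class`,
#'   `epistatic` used by [classify_edges()].
#' @param config A [network_config()] (edge rule and threshold).
#' @return Object of class `coexpression_network`: `node_ids`, `pcorr`,
#'   `edges` (data frame `node1`, `node2`, `weight`, with `node1 < node2`),
#'   `degrees`, `annotations`, `threshold`, `n_connected`.
#' @export
build_network <- function(pcorr, annotations = NULL,
                          config = network_config()) {
  p <- nrow(pcorr)
  if (!isTRUE(all.equal(pcorr, t(pcorr), tolerance = 1e-10)))
    stop("pcorr must be symmetric")
  ids <- rownames(pcorr) %||% paste0("V", seq_len(p))
  off <- abs(pcorr[upper.tri(pcorr)])
  threshold <- if (config$edge_rule == "mean_abs_offdiag") mean(off)
               else config$fixed_threshold %||% stop("fixed_threshold not set")
  sel <- which(upper.tri(pcorr) & abs(pcorr) > threshold, arr.ind = TRUE)
  edges <- data.frame(node1 = ids[sel[, 1]], node2 = ids[sel[, 2]],
                      weight = pcorr[sel])
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  degrees <- setNames(integer(p), ids)
  if (nrow(edges)) {
    tab <- table(c(edges$node1, edges$node2))
    degrees[names(tab)] <- as.integer(tab)
  }
  structure(list(node_ids = ids, pcorr = pcorr, edges = edges,
                 degrees = degrees, annotations = annotations,
                 threshold = threshold,
                 n_connected = sum(degrees > 0)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network: ", length(x$node_ids), " nodes (",
      x$n_connected, " with >= 1 neighbor), ", nrow(x$edges),
      " edges; |pcorr| threshold ", format(x$threshold, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Hurwitz zeta via truncated sum plus Euler-Maclaurin tail; accurate to
# well below 1e-10 for s > 1, q >= 0.5 with K = 1000.
hurwitz_zeta <- function(s, q = 1, K = 1000) {
  k <- 0:(K - 1)
  head_sum <- sum((k + q)^(-s))
  a <- K + q
  tail <- a^(1 - s) / (s - 1) + a^(-s) / 2 + s * a^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * a^(-s - 3) / 720
  head_sum + tail
}

#' Fit a discrete power law to a degree distribution
#'
#' Maximum-likelihood estimate of the exponent of
#' \eqn{P(k) \propto k^{-\alpha}} over degrees \eqn{\ge x_{min}},
#' maximizing \eqn{-n \log \zeta(\alpha, x_{min}) - \alpha \sum \log k_i}
#' numerically. A log-log regression of the degree frequencies is reported
#' as a diagnostic (the historically common but biased estimator).
#'
#' @param degrees Positive integer degrees; nodes below `xmin` are
#'   discarded before fitting.
#' @param xmin Minimum degree included (default 1).
#' @return List of class `power_law_fit`: `alpha` (MLE), `loglik`,
#'   `alpha_loglog` (regression diagnostic, `NA` when fewer than 3 distinct
#'   degrees), `xmin`, `n`, `poor_fit` flag.
#' @export
fit_power_law <- function(degrees, xmin = 1) {
  x <- degrees[degrees >= xmin]
  if (length(x) < 10) stop("need at least 10 nodes with degree >= xmin")
  if (length(unique(x)) == 1)
    stop("degenerate fit: all degrees equal (", x[1], ")")
  slx <- sum(log(x)); n <- length(x)
  nll <- function(alpha) n * log(hurwitz_zeta(alpha, xmin)) + alpha * slx
  opt <- optimize(nll, interval = c(1.01, 25))
  tab <- table(x)
  poor_fit <- length(tab) < 3
  alpha_ll <- NA_real_
  if (!poor_fit) {
    deg <- as.numeric(names(tab))
    fit <- lm(log(as.numeric(tab)) ~ log(deg))
    alpha_ll <- -unname(coef(fit)[2])
  }
  structure(list(alpha = opt$minimum, loglik = -opt$objective,
                 alpha_loglog = alpha_ll, xmin = xmin, n = n,
                 poor_fit = poor_fit),
            class = "power_law_fit")
}

#' Sample from a discrete power law
#'
#' @param n Number of draws.
#' @param alpha Exponent, > 1.
#' @param xmin Minimum value (default 1).
#' @param max_x Truncation point of the support used for sampling; the
#'   omitted tail mass is negligible for `alpha` >= 2.
#' @return Integer vector of draws.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1, max_x = 1e5) {
  k <- xmin:max_x
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Identify hub nodes with stability and significance diagnostics
#'
#' Hubs are the `ceiling(hub_fraction * n_nodes)` highest-degree nodes
#' (ties broken by feature id). Stability is the mean pairwise Jaccard
#' index between the hub sets recomputed on networks re-estimated across
#' the tuning grid (1.0 by convention for a single network). Significance
#' compares hub degrees against non-hub degrees with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param network A `coexpression_network` with at least one edge.
#' @param hub_fraction Top fraction of nodes called hubs.
#' @param grid_networks Optional list of `coexpression_network`s estimated
#'   at other tuning values.
#' @return List of class `hub_analysis`: `hubs`, `n_hubs`, `jaccard`,
#'   `wilcoxon_p`, `grid_hub_sets`.
#' @export
find_hubs <- function(network, hub_fraction = 0.01, grid_networks = NULL) {
  if (nrow(network$edges) == 0) stop("network has no edges")
  top_ids <- function(net) {
    ord <- order(-net$degrees, net$node_ids)
    k <- ceiling(hub_fraction * length(net$node_ids))
    net$node_ids[ord[seq_len(k)]]
  }
  hubs <- top_ids(network)
  sets <- c(list(hubs), lapply(grid_networks, top_ids))
  jaccard <- 1.0
  if (length(sets) > 1) {
    pairs <- combn(length(sets), 2)
    jac <- apply(pairs, 2, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      length(intersect(a, b)) / length(union(a, b))
    })
    jaccard <- mean(jac)
  }
  is_hub <- network$node_ids %in% hubs
  wp <- suppressWarnings(
    wilcox.test(network$degrees[is_hub], network$degrees[!is_hub],
                alternative = "two.sided", exact = FALSE)$p.value)
  structure(list(hubs = hubs, n_hubs = length(hubs), jaccard = jaccard,
                 wilcoxon_p = wp, grid_hub_sets = sets),
            class = "hub_analysis")
}

#' Tally edges by epistasis status and interaction class of their endpoints
#'
#' Two partitions of the edge set: (i) both endpoints epistatic / neither /
#' mixed, and (ii) endpoints in the same interaction class / different
#' classes. Each partition sums to the edge count.
#'
#' @param network A `coexpression_network` whose `annotations` cover every
#'   node incident to an edge (columns `feature_id`, `class`, `epistatic`).
#' @return List with `n_edges`, `epistasis_tally` (`both`, `neither`,
#'   `mixed`) and `class_tally` (`within`, `between`).
#' @export
classify_edges <- function(network) {
  ann <- network$annotations
  if (is.null(ann)) stop("network has no node annotations")
  edges <- network$edges
  need <- unique(c(edges$node1, edges$node2))
  missing_ann <- setdiff(need, ann$feature_id)
  if (length(missing_ann))
    stop("unannotated node(s) incident to an edge: ",
         paste(head(missing_ann, 5), collapse = ", "))
  epi <- setNames(ann$epistatic, ann$feature_id)
  cls <- setNames(as.character(ann$class), ann$feature_id)
  e1 <- epi[edges$node1]; e2 <- epi[edges$node2]
  epistasis_tally <- c(both = sum(e1 & e2), neither = sum(!e1 & !e2),
                       mixed = sum(xor(e1, e2)))
  class_tally <- c(within = sum(cls[edges$node1] == cls[edges$node2]),
                   between = sum(cls[edges$node1] != cls[edges$node2]))
  stopifnot(sum(epistasis_tally) == nrow(edges),
            sum(class_tally) == nrow(edges))
  list(n_edges = nrow(edges), epistasis_tally = epistasis_tally,
       class_tally = class_tally)
}
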