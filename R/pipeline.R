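# End-to-end orchestration: ingest -> model -> responder gate -> class
# calls -> epistasis -> summaries, and the normalization -> estimation ->
# thresholding -> hub/edge-tally network chain. Both runs are deterministic
# for fixed inputs and write stable tables plus a run log.

#' Run the environmental-interaction pipeline
#'
#' Fits the factorial model to every feature, gates responders at the BH
#' FDR threshold, classifies responders into interaction classes, tests all
#' features for environmental epistasis, and assembles the summary counts.
#' When `out_dir` is given, all tables, a JSON summary and a run log are
#' written deterministically.
#'
#' @param fc A [fold_change_matrix()].
#' @param alpha_coef Coefficient-level significance threshold (strict `<`).
#' @param q_threshold Responder FDR gate on the BH-adjusted overall p
#'   (`<=`).
#' @param epistasis_alpha Epistasis significance threshold (`<=`).
#' @param epistasis_df `"residual"` or `"satterthwaite"`, see
#'   [epistasis_test()].
#' @param out_dir Optional output directory.
#' @return List of class `interaction_results`: `fits`, `responders`,
#'   `de_calls`, `calls`, `epistasis`, `summary`, `thresholds`.
#' @export
run_interaction_pipeline <- function(fc, alpha_coef = 0.05,
                                     q_threshold = 0.05,
                                     epistasis_alpha = 0.05,
                                     epistasis_df = "residual",
                                     out_dir = NULL) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  fits <- fit_models(fc)
  responders <- call_responders(fits, q_threshold)
  de_calls <- stimulus_de_calls(fits, responders, alpha_coef)
  calls <- classify_interactions(fits, responders, alpha_coef)
  epistasis <- epistasis_test(fits, epistasis_alpha, epistasis_df)
  summary <- summarize_classes(calls, epistasis)
  summary$de_totals <- as.list(attr(de_calls, "totals"))
  summary$responder_counts <- as.list(attr(responders, "counts"))
  results <- structure(
    list(fits = fits, responders = responders, de_calls = de_calls,
         calls = calls, epistasis = epistasis,
         summary = list(
           n_features = summary$n_features,
           class_counts = as.list(summary$class_counts),
           epistasis_counts = as.list(summary$epistasis_counts),
           de_totals = summary$de_totals,
           responder_counts = summary$responder_counts),
         class_by_epistasis = summary$class_by_epistasis,
         thresholds = list(alpha_coef = alpha_coef,
                           q_threshold = q_threshold,
                           epistasis_alpha = epistasis_alpha)),
    class = "interaction_results")
  if (!is.null(out_dir)) {
    write_results(results, out_dir)
    write_run_log(out_dir, fc, results$thresholds)
  }
  results
}

#' Run the coexpression-network pipeline
#'
#' Applies the fixed normalization chain (probabilistic quotient
#' normalization, generalized-log scaling, unit-variance standardization —
#' the first two toggleable in [network_config()]), estimates the sparse
#' partial-correlation matrix at the configured tuning value, thresholds it
#' into a network, re-estimates across the tuning grid for hub stability,
#' fits the degree power law, and tallies edges by epistasis status and
#' interaction class when interaction results are supplied.
#'
#' @param fc A [fold_change_matrix()].
#' @param interaction_results Optional `interaction_results` providing node
#'   annotations (class, epistasis flag).
#' @param config A [network_config()].
#' @param out_dir Optional output directory for edge/node tables.
#' @return List of class `network_results`: `network`, `hubs`,
#'   `power_law`, `edge_tallies`, `grid_networks`, `config`.
#' @export
run_network_pipeline <- function(fc, interaction_results = NULL,
                                 config = network_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  x <- fc$values
  if (config$use_pqn) x <- pqn_normalize(x)
  if (config$use_glog) x <- glog_transform(x, config$glog_lambda)
  x <- standardize_features(x)
  tuning <- config$tuning %||% space_default_tuning(ncol(x), nrow(x))

  annotations <- NULL
  if (!is.null(interaction_results)) {
    epi <- interaction_results$epistasis
    annotations <- data.frame(
      feature_id = interaction_results$calls$feature_id,
      class = as.character(interaction_results$calls$class),
      epistatic = epi$epistatic[match(interaction_results$calls$feature_id,
                                      epi$feature_id)])
  }

  estimate <- function(lam) {
    pc <- space_partial_correlations(x, tuning = lam)
    build_network(pc, annotations, config)
  }
  network <- estimate(tuning)
  grid <- setdiff(config$tuning_multipliers, 1)
  grid_networks <- lapply(tuning * grid, estimate)
  hubs <- if (nrow(network$edges) > 0)
    find_hubs(network, config$hub_fraction, grid_networks) else NULL
  power_law <- NULL
  pos_deg <- network$degrees[network$degrees >= 1]
  if (length(pos_deg) >= 10 && length(unique(pos_deg)) > 1)
    power_law <- fit_power_law(pos_deg)
  edge_tallies <- if (!is.null(annotations) && nrow(network$edges) > 0)
    classify_edges(network) else NULL

  results <- structure(
    list(network = network, hubs = hubs, power_law = power_law,
         edge_tallies = edge_tallies, grid_networks = grid_networks,
         tuning = tuning, config = config),
    class = "network_results")
  if (!is.null(out_dir))
    write_results(list(network = network,
                       summary = list(
                         n_nodes = length(network$node_ids),
                         n_connected = network$n_connected,
                         n_edges = nrow(network$edges),
                         tuning = tuning,
                         threshold = network$threshold,
                         hubs = if (!is.null(hubs)) hubs$hubs else character(),
                         jaccard = if (!is.null(hubs)) hubs$jaccard else NA,
                         power_law_alpha = if (!is.null(power_law)) power_law$alpha else NA,
                         edge_tallies = edge_tallies)),
                  out_dir)
  results
}

# Minimal provenance record; the checksum is a plain sum over the values,
# enough to notice a changed input between reruns.
write_run_log <- function(out_dir, fc, thresholds) {
  log_path <- file.path(out_dir, "run_log.txt")
  lines <- c(
    paste0("envepi version: ", as.character(packageVersion("envepi"))),
    paste0("n_features: ", nrow(fc$values)),
    paste0("n_samples: ", ncol(fc$values)),
    paste0("input_checksum: ", format(sum(fc$values), digits = 17)),
    paste0("thresholds: ",
           paste(names(thresholds), unlist(thresholds), sep = "=",
                 collapse = ", ")))
  writeLines(lines, log_path)
  invisible(log_path)
}
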