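# Container for replicate log2 fold changes under a 2x2 binary stimulus
# design. Three test conditions are encoded internally as "A" (stimulus A
# alone), "B" (stimulus B alone) and "AB" (both concurrently); the baseline
# (0,0) is the fold-change reference, not a sample.

condition_code <- function(stimulus_a, stimulus_b) {
  ifelse(stimulus_a == 1 & stimulus_b == 1, "AB",
         ifelse(stimulus_a == 1, "A", ifelse(stimulus_b == 1, "B", "BASE")))
}

condition_labels <- function(stimulus_names) {
  c(A = stimulus_names[[1]], B = stimulus_names[[2]],
    AB = paste0(stimulus_names[[1]], stimulus_names[[2]]))
}

#' Construct a fold-change matrix with its stimulus design
#'
#' Bundles a features x samples matrix of log2 fold changes with per-sample
#' metadata assigning each sample one of the three test conditions of a 2x2
#' binary stimulus design: stimulus A alone (1,0), stimulus B alone (0,1),
#' or both concurrently (1,1). Fold changes are taken relative to the
#' unstimulated baseline (0,0), so the baseline itself is normally not a
#' sample.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names (or `feature_ids`) identify features.
#' @param samples Data frame with one row per column of `values` and columns
#'   `sample_id`, `stimulus_a` (0/1), `stimulus_b` (0/1), `replicate`.
#' @param feature_ids Optional character vector of unique feature ids;
#'   defaults to `rownames(values)`.
#' @param stimulus_names Length-2 character vector naming the two stimuli
#'   (used for display and TSV headers). Default `c("HT", "G")`, high
#'   temperature and glycerol.
#' @param allow_baseline Permit samples with `(0,0)` design (e.g. raw
#'   expression tables before baseline subtraction). Default `FALSE`.
#' @return An object of class `fold_change_matrix`: a list with elements
#'   `values`, `samples` (with a derived `condition` column of codes
#'   `"A"/"B"/"AB"`), `feature_ids` and `stimulus_names`.
#' @examples
#' vals <- matrix(rnorm(12), 2, 6,
#'                dimnames = list(c("p1", "p2"), NULL))
#' meta <- data.frame(sample_id = paste0("s", 1:6),
#'                    stimulus_a = c(1, 1, 0, 0, 1, 1),
#'                    stimulus_b = c(0, 0, 1, 1, 1, 1),
#'                    replicate  = c(1, 2, 1, 2, 1, 2))
#' fc <- fold_change_matrix(vals, meta)
#' @export
fold_change_matrix <- function(values, samples, feature_ids = rownames(values),
                               stimulus_names = c("HT", "G"),
                               allow_baseline = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(feature_ids)) stop("feature ids are required (rownames or `feature_ids`)")
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(values))
    stop("length of `feature_ids` must equal nrow(values)")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  samples <- as.data.frame(samples)
  required <- c("sample_id", "stimulus_a", "stimulus_b", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("`samples` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("nrow(samples) must equal ncol(values)")
  if (!all(samples$stimulus_a %in% c(0, 1)) || !all(samples$stimulus_b %in% c(0, 1)))
    stop("stimulus indicators must be 0 or 1")
  samples$condition <- condition_code(samples$stimulus_a, samples$stimulus_b)
  if (!allow_baseline && any(samples$condition == "BASE"))
    stop("samples with (0,0) stimulus design are the baseline reference, ",
         "not test samples; set allow_baseline = TRUE to keep them")
  rownames(values) <- feature_ids
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples,
                 feature_ids = feature_ids,
                 stimulus_names = as.character(stimulus_names)),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  tab <- table(factor(x$samples$condition, levels = c("A", "B", "AB", "BASE")))
  labs <- condition_labels(x$stimulus_names)
  cat("fold_change_matrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  conditions: ", labs[["A"]], "=", tab[["A"]], ", ",
      labs[["B"]], "=", tab[["B"]], ", ",
      labs[["AB"]], "=", tab[["AB"]],
      if (tab[["BASE"]] > 0) paste0(", baseline=", tab[["BASE"]]) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.fold_change_matrix <- function(x) dim(x$values)

# Columns (indices into the sample table) belonging to one condition code.
condition_columns <- function(fc, code) which(fc$samples$condition == code)

#' Read a fold-change table from TSV
#'
#' Reads a tab-delimited features x samples table of log2 fold changes and
#' maps its columns onto the 2x2 stimulus design. By default the header is
#' expected to encode condition and replicate as `<label>_r<k>` (e.g.
#' `HT_r1`, `G_r2`, `HTG_r3`, using `stimulus_names` and their
#' concatenation for the concurrent condition); alternatively an explicit
#' schema maps arbitrary column names.
#'
#' Missing values may be encoded as empty cells or `NA`. With
#' `require_complete = TRUE` (the default) only features quantified in every
#' sample are retained — the complete-case filter used to reduce a partially
#' quantified proteome to the fully replicated core — and the number of
#' dropped features is recorded in the `"n_dropped"` attribute.
#'
#' @param path Path to a TSV file. First (or `feature_column`) column holds
#'   feature ids.
#' @param schema Optional column mapping: a data frame with columns
#'   `column`, `stimulus_a`, `stimulus_b`, `replicate`, or the path to a
#'   YAML file with fields `feature_column` and `samples` (a list keyed by
#'   column name with `stimulus_a`, `stimulus_b`, `replicate`). `NULL` uses
#'   the header convention above.
#' @param stimulus_names Stimulus labels used by the header convention.
#' @param require_complete Drop features with any missing value.
#' @param feature_column Name of the feature-id column (default: first).
#' @return A [fold_change_matrix()] with attribute `n_dropped`.
#' @export
read_fold_change_table <- function(path, schema = NULL,
                                   stimulus_names = c("HT", "G"),
                                   require_complete = TRUE,
                                   feature_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (is.character(schema) && length(schema) == 1) {
    cfg <- yaml::read_yaml(schema)
    feature_column <- feature_column %||% cfg$feature_column
    schema <- do.call(rbind, lapply(names(cfg$samples), function(nm) {
      s <- cfg$samples[[nm]]
      data.frame(column = nm, stimulus_a = s$stimulus_a,
                 stimulus_b = s$stimulus_b, replicate = s$replicate)
    }))
  }
  if (is.null(feature_column)) feature_column <- names(raw)[1]
  if (!feature_column %in% names(raw))
    stop("feature column '", feature_column, "' not present in ", path)
  ids <- raw[[feature_column]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  if (is.null(schema)) {
    labs <- condition_labels(stimulus_names)
    value_cols <- setdiff(names(raw), feature_column)
    pat <- paste0("^(", paste(labs, collapse = "|"), ")_r([0-9]+)$")
    m <- regmatches(value_cols, regexec(pat, value_cols))
    bad <- value_cols[vapply(m, length, 1L) == 0]
    if (length(bad))
      stop("cannot map columns to conditions (expected <label>_r<k>): ",
           paste(bad, collapse = ", "))
    cond <- vapply(m, `[`, "", 2)
    code <- names(labs)[match(cond, labs)]
    schema <- data.frame(column = value_cols,
                         stimulus_a = as.integer(code %in% c("A", "AB")),
                         stimulus_b = as.integer(code %in% c("B", "AB")),
                         replicate = as.integer(vapply(m, `[`, "", 3)))
  } else {
    missing_cols <- setdiff(schema$column, names(raw))
    if (length(missing_cols))
      stop("schema maps columns absent from ", path, ": ",
           paste(missing_cols, collapse = ", "))
  }

  vals <- matrix(NA_real_, nrow(raw), nrow(schema))
  for (j in seq_len(nrow(schema))) {
    col <- raw[[schema$column[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", col[bad[1]], "' at row ", bad[1],
           " (feature ", ids[bad[1]], "), column '", schema$column[j], "'")
    vals[, j] <- num
  }
  n_dropped <- 0L
  if (require_complete) {
    keep <- complete.cases(vals)
    n_dropped <- sum(!keep)
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(vals) <- ids
  fc <- fold_change_matrix(
    vals,
    data.frame(sample_id = schema$column, stimulus_a = schema$stimulus_a,
               stimulus_b = schema$stimulus_b, replicate = schema$replicate),
    stimulus_names = stimulus_names)
  attr(fc, "n_dropped") <- n_dropped
  fc
}

#' Write a fold-change matrix as TSV
#'
#' Header encodes condition and replicate as `<label>_r<k>`, the convention
#' [read_fold_change_table()] parses back, so write/read round-trips.
#'
#' @param fc A [fold_change_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fold_change_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  labs <- condition_labels(fc$stimulus_names)
  header <- paste0(labs[fc$samples$condition], "_r", fc$samples$replicate)
  out <- data.frame(feature_id = fc$feature_ids, fc$values,
                    check.names = FALSE)
  names(out) <- c("feature_id", header)
  write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fold changes relative to designated baseline samples
#'
#' Converts a normalised expression table into per-sample log fold changes
#' by subtracting, feature-wise, the mean of the baseline samples — the
#' standard construction for re-analysing expression compendia in which the
#' unstimulated condition was measured as ordinary samples. Replicate counts
#' may be unbalanced across the test conditions.
#'
#' @param expression Numeric matrix, features x samples, with column names.
#' @param baseline_sample_ids Character vector of baseline column names
#'   (the `(0,0)` condition).
#' @param samples Data frame describing the *test* samples (`sample_id`,
#'   `stimulus_a`, `stimulus_b`, `replicate`); every `sample_id` must be a
#'   column of `expression` and disjoint from the baseline ids.
#' @param stimulus_names Stimulus labels for the result.
#' @return A [fold_change_matrix()] containing only the test samples, each
#'   entry `expression - mean(baseline)` for its feature.
#' @export
fold_changes_from_baseline <- function(expression, baseline_sample_ids,
                                       samples,
                                       stimulus_names = c("HT", "G")) {
  expression <- as.matrix(expression)
  if (length(baseline_sample_ids) < 1) stop("at least one baseline sample is required")
  if (is.null(colnames(expression))) stop("`expression` must have column names")
  missing_base <- setdiff(baseline_sample_ids, colnames(expression))
  if (length(missing_base))
    stop("baseline samples absent from expression matrix: ",
         paste(missing_base, collapse = ", "))
  samples <- as.data.frame(samples)
  if (length(intersect(baseline_sample_ids, samples$sample_id)))
    stop("baseline and test sample ids must be disjoint")
  missing_test <- setdiff(samples$sample_id, colnames(expression))
  if (length(missing_test))
    stop("test samples absent from expression matrix: ",
         paste(missing_test, collapse = ", "))
  base_mean <- rowMeans(expression[, baseline_sample_ids, drop = FALSE])
  vals <- expression[, samples$sample_id, drop = FALSE] - base_mean
  fc <- fold_change_matrix(vals, samples, stimulus_names = stimulus_names)
  attr(fc, "baseline_mean") <- base_mean
  fc
}

#' Read / write a growth curve
#'
#' Two-column tab-delimited format: time in minutes, optical density.
#'
#' @param path TSV path.
#' @param condition_label Label attached to the curve.
#' @return A `growth_curve`: data frame with columns `time` (minutes,
#'   strictly increasing) and `od` (positive), attribute `condition_label`.
#' @export
read_growth_curve <- function(path, condition_label = NA_character_) {
  d <- read.delim(path, header = TRUE, sep = "\t")
  growth_curve(d[[1]], d[[2]], condition_label)
}

#' @rdname read_growth_curve
#' @param times,od Numeric vectors of equal length.
#' @export
growth_curve <- function(times, od, condition_label = NA_character_) {
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("od must be positive")
  structure(data.frame(time = times, od = od),
            condition_label = condition_label,
            class = c("growth_curve", "data.frame"))
}

#' @rdname read_growth_curve
#' @param curve A `growth_curve`.
#' @export
write_growth_curve <- function(curve, path) {
  write.table(format(as.data.frame(curve), digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic full-precision TSV writer used for all result tables.
write_tsv_det <- function(df, path) {
  is_num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(is_num))
    out[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis results bundle to TSV/JSON files
#'
#' Writes the per-feature model table, classification table, epistasis
#' table, summary counts (JSON) and — when a network is present — edge and
#' node tables. Output is deterministic: rerunning on the same results
#' yields byte-identical files. Empty result sets produce headers-only
#' tables.
#'
#' @param results A results bundle from [run_interaction_pipeline()] (and
#'   optionally extended by [run_network_pipeline()]).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_det(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$fits)) put(as.data.frame(results$fits), "model_fits.tsv")
  if (!is.null(results$calls)) put(as.data.frame(results$calls), "interaction_classes.tsv")
  if (!is.null(results$epistasis)) put(as.data.frame(results$epistasis), "epistasis.tsv")
  if (!is.null(results$de_calls)) put(as.data.frame(results$de_calls), "de_calls.tsv")
  if (!is.null(results$network)) {
    put(results$network$edges, "network_edges.tsv")
    nodes <- data.frame(feature_id = results$network$node_ids,
                        degree = results$network$degrees)
    if (!is.null(results$network$annotations))
      nodes <- merge(nodes, results$network$annotations, by = "feature_id",
                     sort = FALSE)
    put(nodes[order(nodes$feature_id), , drop = FALSE], "network_nodes.tsv")
  }
  if (!is.null(results$summary)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}
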