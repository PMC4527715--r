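test_that("fold-change matrices round-trip through TSV exactly", {
  cfg <- generator_config(n_features = 6, seed = 21)
  fc <- simulate_fold_changes(generate_truth_table(cfg), cfg)
  path <- file.path(withr::local_tempdir(), "fc.tsv")
  write_fold_change_matrix(fc, path)
  back <- read_fold_change_table(path)
  expect_equal(back$values, fc$values, tolerance = 1e-12)
  expect_equal(back$samples$condition, fc$samples$condition)
  expect_equal(back$samples$replicate, fc$samples$replicate)
  expect_equal(back$feature_ids, fc$feature_ids)
})

test_that("complete-case filtering drops exactly the incomplete features", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "missing.tsv")
  header <- c("feature_id", paste0(rep(c("HT", "G", "HTG"), each = 3),
                                   "_r", 1:3))
  rows <- lapply(1:5, function(i) c(paste0("f", i), format(seq(0.1, 0.9, 0.1) + i)))
  rows[[2]][3] <- "NA"   # f2 missing one value
  rows[[4]][8] <- ""     # f4 missing one value
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  fc <- read_fold_change_table(path, require_complete = TRUE)
  expect_equal(fc$feature_ids, c("f1", "f3", "f5"))
  expect_equal(attr(fc, "n_dropped"), 2L)
  fc_all <- read_fold_change_table(path, require_complete = FALSE)
  expect_equal(nrow(fc_all$values), 5)
})

test_that("reader rejects duplicate ids and locates non-numeric cells", {
  dir <- withr::local_tempdir()
  header <- paste(c("feature_id", paste0(rep(c("HT", "G", "HTG"), each = 2),
                                         "_r", 1:2)), collapse = "\t")
  dup <- file.path(dir, "dup.tsv")
  writeLines(c(header,
               paste(c("f1", rep("0.5", 6)), collapse = "\t"),
               paste(c("f1", rep("0.7", 6)), collapse = "\t")), dup)
  expect_error(read_fold_change_table(dup), "duplicate feature ids")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c(header,
               paste(c("f1", "0.5", "oops", rep("0.1", 4)), collapse = "\t")),
             bad)
  expect_error(read_fold_change_table(bad), "non-numeric value 'oops'")
  expect_error(read_fold_change_table(file.path(dir, "absent.tsv")),
               "file not found")
})

test_that("schema-driven column mapping works, including from YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "odd.tsv")
  writeLines(c("protein\tx1\tx2\tx3\tx4\tx5\tx6",
               paste(c("p1", 1:6 / 10), collapse = "\t")), path)
  schema <- data.frame(column = paste0("x", 1:6),
                       stimulus_a = c(1, 1, 0, 0, 1, 1),
                       stimulus_b = c(0, 0, 1, 1, 1, 1),
                       replicate = rep(1:2, 3))
  fc <- read_fold_change_table(path, schema = schema, feature_column = "protein")
  expect_equal(fc$samples$condition, c("A", "A", "B", "B", "AB", "AB"))
  yml <- file.path(dir, "schema.yaml")
  writeLines(c("feature_column: protein", "samples:",
               vapply(1:6, function(i) paste0(
                 "  x", i, ": {stimulus_a: ", schema$stimulus_a[i],
                 ", stimulus_b: ", schema$stimulus_b[i],
                 ", replicate: ", schema$replicate[i], "}"), "")), yml)
  fc2 <- read_fold_change_table(path, schema = yml)
  expect_equal(fc2$values, fc$values)
  schema_bad <- schema; schema_bad$column[1] <- "nope"
  expect_error(read_fold_change_table(path, schema = schema_bad,
                                      feature_column = "protein"),
               "absent")
})

test_that("baseline subtraction gives fold changes and is invertible", {
  expr <- matrix(c(1.0, 2.0, 2.5, 1.5,
                   0.0, 4.0, 2.0, 6.0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("b1", "b2", "t1", "t2")))
  samples <- data.frame(sample_id = c("t1", "t2"),
                        stimulus_a = c(1, 0), stimulus_b = c(0, 1),
                        replicate = c(1, 1))
  fc <- fold_changes_from_baseline(expr, c("b1", "b2"), samples)
  expect_equal(fc$values["g1", "t1"], 1.0)   # 2.5 - mean(1, 2)
  expect_equal(fc$values["g2", "t1"], 0.0)   # equals the baseline mean
  restored <- fc$values + attr(fc, "baseline_mean")
  expect_equal(restored, expr[, c("t1", "t2")])
  expect_error(fold_changes_from_baseline(expr, character(), samples),
               "baseline")
  expect_error(fold_changes_from_baseline(expr, c("b1", "t1"), samples),
               "disjoint")
})

test_that("unbalanced chemostat-style designs are supported", {
  # 5 baseline + 3/4/3 test samples, the re-analysis replicate structure
  set.seed(31)
  expr <- matrix(rnorm(15 * 30), 30, 15,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:15)))
  samples <- data.frame(
    sample_id = paste0("s", 6:15),
    stimulus_a = rep(c(1, 0, 1), c(3, 4, 3)),
    stimulus_b = rep(c(0, 1, 1), c(3, 4, 3)),
    replicate = c(1:3, 1:4, 1:3))
  fc <- fold_changes_from_baseline(expr, paste0("s", 1:5), samples)
  expect_equal(ncol(fc$values), 10)
  fits <- fit_models(fc)
  expect_equal(unique(fits$df_resid), 10 - 3)
})

test_that("result bundles are written deterministically", {
  cfg <- generator_config(n_features = 30, seed = 22)
  fc <- simulate_fold_changes(generate_truth_table(cfg), cfg)
  res <- run_interaction_pipeline(fc)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results(res, d1)
  write_results(res, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # empty results still produce headers-only tables
  empty <- res
  empty$fits <- res$fits[0, ]; empty$calls <- res$calls[0, ]
  empty$epistasis <- res$epistasis[0, ]; empty$de_calls <- res$de_calls[0, ]
  d3 <- withr::local_tempdir()
  write_results(empty, d3)
  expect_equal(length(readLines(file.path(d3, "model_fits.tsv"))), 1)
})
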