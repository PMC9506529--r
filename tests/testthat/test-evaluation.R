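test_that("stratified splits follow the largest-remainder quota rule", {
  labels <- rep(c("A", "B", "C"), c(10L, 10L, 5L))
  sp <- stratified_split(labels, test_frac = 0.2, seed = 1L)
  got <- table(labels[sp$test_idx])
  expect_identical(as.integer(got[c("A", "B", "C")]), c(2L, 2L, 1L))
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_along(labels))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)

  # same seed reproduces the partition; a different seed moves it
  expect_identical(stratified_split(labels, 0.2, 1L), sp)
  expect_false(identical(stratified_split(labels, 0.2, 2L), sp))

  expect_identical(stratified_split(labels, 0, 1L)$test_idx, integer(0))
  expect_error(stratified_split(c("A", "A", "B"), 0.2, 1L), "'B'")

  # every class keeps at least one training member on the packaged counts
  big <- rep(paste0("class", 1:7), c(38, 36, 34, 32, 30, 28, 24))
  sp2 <- stratified_split(big, 0.2, 5L)
  expect_identical(length(sp2$test_idx), as.integer(round(0.2 * length(big))))
  expect_identical(sort(unique(big[sp2$test_idx])), sort(unique(big)))
})

test_that("confusion counts enumerate one-vs-rest outcomes exactly", {
  cc <- confusion_counts(c("A", "A", "B", "B", "B"),
                         c("A", "B", "B", "B", "A"))
  expect_identical(cc["A", ], c(TP = 1, FP = 1, TN = 2, FN = 1))
  expect_identical(cc["B", ], c(TP = 2, FP = 1, TN = 1, FN = 1))
  expect_identical(unname(rowSums(cc)), c(5, 5))  # TP+FP+TN+FN = n per class

  perfect <- confusion_counts(c("A", "B", "C"), c("A", "B", "C"))
  expect_identical(sum(perfect[, "FP"]), 0)
  expect_identical(sum(perfect[, "FN"]), 0)

  expect_error(confusion_counts(c("A", "B"), c("A", "Z"), classes = c("A", "B")),
               "Z")
  expect_error(confusion_counts(c("A", "B"), "A"), "equal length")
})

test_that("precision/recall/F1/accuracy follow their defining formulas", {
  cc <- confusion_counts(c("A", "A", "B", "B", "B"),
                         c("A", "B", "B", "B", "A"))
  m <- metrics_from_counts(cc)
  a <- m$per_class[m$per_class$class == "A", ]
  expect_equal(a$precision, 0.5)
  expect_equal(a$recall, 0.5)
  expect_equal(a$f1, 0.5)
  expect_equal(m$accuracy, 3 / 5)

  perfect <- metrics_from_counts(confusion_counts(c("A", "B"), c("A", "B")))
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$accuracy, 1)

  # degenerate 0/0 ratios are defined as 0, warning once per metric
  w <- capture_warnings(z <- metrics_from_counts(
    confusion_counts(c("A", "A"), c("B", "B"), classes = c("A", "B"))))
  expect_length(w, 2L)  # precision and recall both degenerate here
  expect_match(w, "defined as 0", all = TRUE)
  expect_equal(z$per_class$f1, c(0, 0))

  # F1 lies between min and max of precision and recall, per class
  y <- withr::with_seed(21L, sample(letters[1:4], 60, replace = TRUE))
  p <- withr::with_seed(22L, sample(letters[1:4], 60, replace = TRUE))
  mm <- suppressWarnings(metrics_from_counts(confusion_counts(y, p)))
  with(mm$per_class, {
    expect_true(all(f1 >= pmin(precision, recall) - 1e-12))
    expect_true(all(f1 <= pmax(precision, recall) + 1e-12))
  })
})

test_that("micro-averaged precision and recall equal accuracy in single-label multiclass", {
  y <- withr::with_seed(23L, sample(letters[1:5], 100, replace = TRUE))
  p <- withr::with_seed(24L, sample(letters[1:5], 100, replace = TRUE))
  cc <- confusion_counts(y, p)
  micro_p <- sum(cc[, "TP"]) / sum(cc[, "TP"] + cc[, "FP"])
  micro_r <- sum(cc[, "TP"]) / sum(cc[, "TP"] + cc[, "FN"])
  acc <- suppressWarnings(metrics_from_counts(cc))$accuracy
  expect_equal(micro_p, acc)
  expect_equal(micro_r, acc)
  expect_equal(acc, mean(y == p))
})

test_that("the benchmark harness covers the full configuration x model grid", {
  ds <- generate_dataset(synthetic_config(
    n_classes = 7L, class_counts = rep(4L, 7L), n_points = 128L, seed = 2L))
  rep <- suppressWarnings(run_benchmark(
    ds, train_cfg = train_config(epochs = 3L), pca_k = 5L, split_seed = 3L))
  expect_identical(nrow(rep$results), 22L * 5L)  # 110 cells
  expect_identical(length(unique(rep$results$config)), 22L)
  expect_true("NO_OP" %in% rep$results$config)
  tab <- report_table(rep)
  expect_identical(nrow(tab), 25L)
  expect_identical(tail(tab$config, 3L), c("Max", "Min", "Avg"))
  for (j in names(tab)[-1L]) {
    v <- tab[[j]]
    ok <- !is.na(v[1:22])
    if (any(ok)) {
      expect_gte(v[23L], v[25L])  # Max >= Avg
      expect_lte(v[24L], v[25L])  # Min <= Avg
      expect_equal(v[23L], max(v[1:22], na.rm = TRUE))
    }
  }
})

test_that("benchmark cells fail independently and are recorded", {
  ds <- generate_dataset(small_cfg())
  ds$X[3L, ] <- 2  # constant spectrum: SNV chains must fail, others survive
  rep <- suppressWarnings(run_benchmark(
    ds,
    configs = list(preproc_config(), preproc_config("SNV")),
    models = c("naive_bayes"),
    train_cfg = train_config(epochs = 2L), pca_k = 4L, split_seed = 1L))
  res <- rep$results
  expect_true(is.na(res$error[res$config == "NO_OP"]))
  expect_match(res$error[res$config == "SNV"], "SNV")
  expect_true(is.na(res$accuracy[res$config == "SNV"]))
})

test_that("benchmark runs are reproducible cell by cell", {
  ds <- generate_dataset(small_cfg())
  cfgs <- list(preproc_config(), preproc_config("SNV"))
  r1 <- run_benchmark(ds, configs = cfgs, models = c("decision_tree", "bp_net"),
                      train_cfg = train_config(epochs = 4L), pca_k = 4L,
                      split_seed = 9L)
  r2 <- run_benchmark(ds, configs = cfgs, models = c("decision_tree", "bp_net"),
                      train_cfg = train_config(epochs = 4L), pca_k = 4L,
                      split_seed = 9L)
  expect_identical(r1$results$accuracy, r2$results$accuracy)
  expect_identical(r1$results$macro_f1, r2$results$macro_f1)
})

test_that("reports render as CSV and an aligned percentage table", {
  ds <- generate_dataset(small_cfg())
  rep <- run_benchmark(ds, configs = list(preproc_config(), preproc_config("SNV")),
                       models = c("naive_bayes", "svm"),
                       train_cfg = train_config(epochs = 2L), pca_k = 4L)
  stem <- file.path(withr::local_tempdir(), "report")
  paths <- render_report(rep, stem)
  expect_true(all(file.exists(paths)))

  long <- data.table::fread(paths[["csv"]])
  expect_identical(nrow(long), 4L)
  expect_identical(sort(unique(long$config)), c("NO_OP", "SNV"))
  expect_equal(long$accuracy, rep$results$accuracy)  # round-trip parse

  txt <- readLines(paths[["txt"]])
  expect_length(txt, 1L + 2L + 3L)  # header + configs + Max/Min/Avg
  expect_match(txt[2L], "\\d+\\.\\d{2}%")  # 97.78%-style accuracy cells

  meta <- jsonlite::read_json(paths[["meta"]])
  expect_identical(meta$n_samples, nrow(ds$X))
  expect_identical(unlist(meta$models), c("naive_bayes", "svm"))
})
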