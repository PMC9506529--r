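# Stratified splitting, one-vs-rest confusion counts, precision /
# recall / F1 / accuracy, the configuration x model benchmark harness,
# and the benchmark-table renderer.

#' Stratified train/test split
#'
#' Splits sample indices into disjoint, exhaustive train and test sets
#' preserving class proportions. The total test size is
#' `round(test_frac * n)`; per-class test counts start from the exact
#' quotas `test_frac * n_c` rounded down and are topped up by largest
#' remainder until the total is reached. Deterministic given the seed.
#'
#' @param labels Class labels (factor or coercible), every class with
#'   >= 2 members.
#' @param test_frac Fraction of samples assigned to the test set.
#' @param seed Integer seed.
#' @return List with integer vectors `train_idx` and `test_idx`.
#' @export
stratified_split <- function(labels, test_frac = 0.2, seed = 1L) {
  labels <- factor(labels)
  if (test_frac < 0 || test_frac > 1) stop("test_frac must be in [0, 1]")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs >= 2 members for a stratified split; class '",
         names(counts)[which(counts < 2L)[1L]], "' has ", min(counts))
  n <- length(labels)
  target <- round(test_frac * n)
  quota <- test_frac * as.numeric(counts)
  take <- floor(quota)
  rem <- quota - take
  short <- target - sum(take)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    take[bump] <- take[bump] + 1L
  } else if (short < 0) {
    drop_from <- order(rem)[seq_len(-short)]
    take[drop_from] <- take[drop_from] - 1L
  }
  take <- pmin(pmax(take, 0L), as.numeric(counts))
  test_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(counts)) {
      members <- which(labels == names(counts)[ci])
      if (take[ci] > 0L)
        test_idx <- c(test_idx, sample(members, take[ci]))
    }
  })
  test_idx <- sort(test_idx)
  list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' One-vs-rest confusion counts
#'
#' Per-class TP/FP/TN/FN counts from true and predicted labels. For
#' each class, TP counts samples of that class predicted as it, FP
#' samples of other classes predicted as it, FN samples of the class
#' predicted as something else, TN the rest.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Optional class set; defaults to the union of levels.
#' @return A `confusion_counts` object: matrix classes x (TP, FP, TN, FN).
#' @export
confusion_counts <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown))
    stop("label(s) outside the known class set: ", paste(unknown, collapse = ", "))
  n <- length(y_true)
  cc <- t(vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    c(TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  }, numeric(4)))
  rownames(cc) <- classes
  structure(cc, class = c("confusion_counts", "matrix"))
}

#' Classification metrics from confusion counts
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and
#' F1 `2PR/(P+R)`; macro averages (unweighted class means); and
#' accuracy (fraction of correct predictions, equivalently
#' `sum(TP)/n`). A 0/0 ratio is defined as 0 with a warning.
#'
#' @param cc A [confusion_counts()] object.
#' @return A `metric_set` list with elements `per_class` (data frame),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `accuracy`.
#' @export
metrics_from_counts <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning("0/0 in ", what, " for class(es) ",
              paste(rownames(cc)[den == 0], collapse = ", "),
              "; defined as 0", call. = FALSE)
    out
  }
  prec <- safe_div(cc[, "TP"], cc[, "TP"] + cc[, "FP"], "precision")
  rec <- safe_div(cc[, "TP"], cc[, "TP"] + cc[, "FN"], "recall")
  pr <- prec + rec
  f1 <- ifelse(pr == 0, 0, 2 * prec * rec / pr)
  n <- sum(cc[1L, ])
  structure(list(
    per_class = data.frame(class = rownames(cc), precision = unname(prec),
                           recall = unname(rec), f1 = unname(f1)),
    macro_precision = mean(prec),
    macro_recall = mean(rec),
    macro_f1 = mean(f1),
    accuracy = sum(cc[, "TP"]) / n
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Convenience: metrics straight from labels
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Optional class set.
#' @return A [metrics_from_counts()] result.
#' @export
evaluate_predictions <- function(y_true, y_pred, classes = NULL) {
  metrics_from_counts(confusion_counts(y_true, y_pred, classes))
}

.BENCH_MODELS <- c("decision_tree", "naive_bayes", "svm", "bp_net", "double_net")

# Build + train + predict one benchmark cell; returns test predictions.
.run_cell <- function(model_name, Xtr, ytr, Xte, train_cfg, cell_seed,
                      model_specs) {
  cfg <- train_cfg
  cfg$seed <- cell_seed
  model <- switch(model_name,
    bp_net = build_bp_net(
      model_specs$bp_net %||% bp_net_spec(input_dim = ncol(Xtr),
                                          n_classes = nlevels(ytr)),
      seed = cell_seed),
    double_net = build_double_net(
      model_specs$double_net %||% double_net_spec(input_dim = ncol(Xtr),
                                                  n_classes = nlevels(ytr)),
      seed = cell_seed),
    make_baseline(model_name, model_specs[[model_name]] %||% list())
  )
  fitted <- train_model(model, Xtr, ytr, cfg)$model
  predict_classes(fitted, Xte)
}

#' Run the pre-processing x model benchmark
#'
#' For each pre-processing configuration: split once (the same
#' stratified split is shared across all configurations so they are
#' comparable), fit and apply the chain (stateful steps fitted on the
#' training partition), route features — PCA scores to the classical
#' learners, full-resolution spectra to the networks — train every
#' requested model, and score test-set accuracy and macro-F1. A failing
#' cell is recorded with its error message and the run continues.
#'
#' @param ds A [spectra_dataset()].
#' @param configs List of [preproc_config()]; default NO_OP + the 21
#'   enumerated chains (22 rows).
#' @param models Character subset of
#'   `c("decision_tree", "naive_bayes", "svm", "bp_net", "double_net")`.
#' @param train_cfg A [train_config()] for the networks.
#' @param split_seed Seed of the shared stratified split.
#' @param test_frac Test fraction of the split.
#' @param pca_k PCA components fed to the classical learners.
#' @param model_specs Optional named list of spec overrides per model.
#' @param fit_on_all Fit stateful pre-processing on train+test
#'   (compatibility mode; default FALSE, leakage-safe).
#' @param verbose Print per-cell progress.
#' @return An `eval_report`: long results data frame plus metadata.
#' @export
run_benchmark <- function(ds,
                          configs = c(list(preproc_config()), enumerate_paper_configs()),
                          models = .BENCH_MODELS,
                          train_cfg = train_config(),
                          split_seed = 1L, test_frac = 0.2,
                          pca_k = 20L, model_specs = list(),
                          fit_on_all = FALSE, verbose = FALSE) {
  stopifnot(inherits(ds, "spectra_dataset"))
  models <- match.arg(models, .BENCH_MODELS, several.ok = TRUE)
  split <- stratified_split(ds$labels, test_frac = test_frac, seed = split_seed)
  ytr <- droplevels(ds$labels[split$train_idx])
  yte <- factor(ds$labels[split$test_idx], levels = levels(ytr))
  classes <- levels(ytr)
  rows <- list()
  for (ci in seq_along(configs)) {
    config <- configs[[ci]]
    label <- config_label(config)
    prep <- tryCatch(
      fit_apply_pipeline(config, ds$X[split$train_idx, , drop = FALSE],
                         ds$X[split$test_idx, , drop = FALSE],
                         fit_on_all = fit_on_all),
      error = function(e) e)
    pca <- NULL
    if (!inherits(prep, "error") &&
        any(models %in% c("decision_tree", "naive_bayes", "svm"))) {
      pca <- tryCatch({
        k <- min(pca_k, nrow(prep$train) - 1L, ncol(prep$train))
        model <- pca_fit(prep$train, k = k)
        list(train = pca_transform(model, prep$train),
             test = pca_transform(model, prep$test))
      }, error = function(e) e)
    }
    for (mi in seq_along(models)) {
      model_name <- models[mi]
      cell_seed <- (train_cfg$seed * 1009L + ci * 101L + mi) %% 2147483647L
      is_net <- model_name %in% c("bp_net", "double_net")
      res <- tryCatch({
        if (inherits(prep, "error")) stop(conditionMessage(prep))
        if (!is_net && inherits(pca, "error")) stop(conditionMessage(pca))
        Xtr <- if (is_net) prep$train else pca$train
        Xte <- if (is_net) prep$test else pca$test
        pred <- .run_cell(model_name, Xtr, ytr, Xte, train_cfg, cell_seed,
                          model_specs)
        m <- suppressWarnings(evaluate_predictions(yte, pred, classes))
        list(accuracy = m$accuracy, f1 = m$macro_f1, error = NA_character_)
      }, error = function(e)
        list(accuracy = NA_real_, f1 = NA_real_, error = conditionMessage(e)))
      if (verbose)
        message(sprintf("[%s | %s] acc=%s f1=%s%s", label, model_name,
                        format(res$accuracy, digits = 4),
                        format(res$f1, digits = 4),
                        if (is.na(res$error)) "" else paste0(" FAILED: ", res$error)))
      rows[[length(rows) + 1L]] <- data.frame(
        config = label, model = model_name, accuracy = res$accuracy,
        macro_f1 = res$f1, seed = cell_seed, error = res$error,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(
    results = results,
    metadata = list(
      n_samples = nrow(ds$X), n_points = ncol(ds$X),
      classes = classes, n_train = length(split$train_idx),
      n_test = length(split$test_idx), split_seed = split_seed,
      test_frac = test_frac, pca_k = pca_k, fit_on_all = fit_on_all,
      train_cfg = unclass(train_cfg),
      configs = vapply(configs, config_label, character(1)),
      models = models, timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "eval_report")
}

#' Wide benchmark table with summary rows
#'
#' Reshapes an [run_benchmark()] report into the benchmark-table layout:
#' one row per configuration, per model an accuracy and a macro-F1
#' column, plus Max / Min / Avg summary rows over the configurations.
#'
#' @param report An `eval_report`.
#' @return Data frame with `length(configs) + 3` rows.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  res <- report$results
  configs <- report$metadata$configs
  models <- report$metadata$models
  out <- data.frame(config = configs, stringsAsFactors = FALSE)
  for (m in models) {
    sub <- res[res$model == m, ]
    out[[paste0(m, "_acc")]] <- sub$accuracy[match(configs, sub$config)]
    out[[paste0(m, "_f1")]] <- sub$macro_f1[match(configs, sub$config)]
  }
  num <- out[, -1L, drop = FALSE]
  summ <- data.frame(config = c("Max", "Min", "Avg"), stringsAsFactors = FALSE)
  for (j in names(num)) {
    v <- num[[j]]
    summ[[j]] <- c(suppressWarnings(max(v, na.rm = TRUE)),
                   suppressWarnings(min(v, na.rm = TRUE)),
                   mean(v, na.rm = TRUE))
  }
  rbind(out, summ)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", length(x$metadata$configs), " configs x ",
      length(x$metadata$models), " models on ", x$metadata$n_samples,
      " samples (", x$metadata$n_train, " train / ", x$metadata$n_test,
      " test)\n", sep = "")
  print(head(report_table(x)))
  invisible(x)
}

#' Render a benchmark report to disk
#'
#' Writes the long-form results as CSV
#' (`config,model,accuracy,f1,seed,error`), an aligned text table in
#' the benchmark-table style (accuracy as percentages with two
#' decimals, e.g. `97.78%`; F1 with two decimals) including the
#' Max/Min/Avg rows, and a JSON metadata sidecar.
#'
#' @param report An `eval_report`.
#' @param path Output path stem; writes `<path>.csv`, `<path>.txt`,
#'   `<path>_meta.json`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  csv_path <- paste0(path, ".csv")
  txt_path <- paste0(path, ".txt")
  meta_path <- paste0(path, "_meta.json")
  long <- report$results
  names(long)[names(long) == "macro_f1"] <- "f1"
  data.table::fwrite(long, csv_path)
  wide <- report_table(report)
  fmt <- wide
  for (j in names(wide)[-1L]) {
    if (grepl("_acc$", j)) {
      fmt[[j]] <- ifelse(is.na(wide[[j]]), "failed",
                         sprintf("%.2f%%", 100 * wide[[j]]))
    } else {
      fmt[[j]] <- ifelse(is.na(wide[[j]]), "failed", sprintf("%.2f", wide[[j]]))
    }
  }
  widths <- vapply(names(fmt), function(j) max(nchar(c(j, fmt[[j]]))), numeric(1))
  pad <- function(v, w) formatC(v, width = w)
  lines <- paste(mapply(pad, names(fmt), widths), collapse = "  ")
  for (i in seq_len(nrow(fmt)))
    lines <- c(lines, paste(mapply(pad, unlist(fmt[i, ]), widths), collapse = "  "))
  writeLines(lines, txt_path)
  jsonlite::write_json(report$metadata, meta_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(csv = csv_path, txt = txt_path, meta = meta_path))
}
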