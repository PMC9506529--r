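# Delimited-text reading/writing of spectral datasets, plus validation
# diagnostics. Matrix CSV: first column sample_id, remaining columns one
# per wavenumber (header = numeric wavenumbers). Labels CSV:
# sample_id,class.

#' Write a spectral dataset to CSV
#'
#' Writes the absorbance matrix (header row of wavenumbers, one row per
#' sample, first column `sample_id`) and a two-column labels file
#' (`sample_id,class`), at full floating-point precision so that
#' [read_spectra_csv()] round-trips within 1e-12 per cell.
#'
#' @param ds A [spectra_dataset()].
#' @param matrix_path,labels_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra_csv <- function(ds, matrix_path, labels_path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (nrow(ds$X) == 0L) stop("refusing to write an empty dataset")
  dt <- data.table::as.data.table(ds$X)
  data.table::setnames(dt, format(ds$grid, digits = 15, trim = TRUE, scientific = FALSE))
  dt <- cbind(data.table::data.table(sample_id = ds$sample_ids), dt)
  data.table::fwrite(dt, matrix_path)
  data.table::fwrite(
    data.table::data.table(sample_id = ds$sample_ids,
                           class = as.character(ds$labels)),
    labels_path)
  invisible(c(matrix = matrix_path, labels = labels_path))
}

#' Read a spectral dataset from CSV
#'
#' Reads the matrix/labels file pair written by [write_spectra_csv()].
#' The wavenumber header must parse as numbers and be strictly
#' descending; an ascending grid is accepted only with
#' `allow_ascending = TRUE`, in which case columns are reversed to the
#' descending convention. Every sample id in the matrix must appear in
#' the labels file. Errors name the offending row, column or id.
#'
#' @param matrix_path,labels_path Input file paths.
#' @param allow_ascending Accept (and reverse) an ascending wavenumber grid.
#' @return A validated [spectra_dataset()].
#' @export
read_spectra_csv <- function(matrix_path, labels_path, allow_ascending = FALSE) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  dt <- data.table::fread(matrix_path, header = TRUE, fill = FALSE)
  if (ncol(dt) < 2L) stop("matrix file must have a sample_id column plus spectral columns")
  ids <- as.character(dt[[1L]])
  grid <- suppressWarnings(as.numeric(names(dt)[-1L]))
  if (anyNA(grid)) {
    bad <- which(is.na(grid))[1L]
    stop("non-numeric wavenumber in matrix header at column ", bad + 1L,
         " ('", names(dt)[bad + 1L], "')")
  }
  num <- !vapply(dt[, -1L, with = FALSE], is.numeric, logical(1))
  if (any(num)) {
    bad <- which(num)[1L]
    stop("non-numeric absorbance values in matrix column ", bad + 1L,
         " (wavenumber ", names(dt)[bad + 1L], ")")
  }
  X <- as.matrix(dt[, -1L, with = FALSE])
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("missing value in matrix at row ", bad[1L], ", column ", bad[2L] + 1L)
  }
  if (length(grid) >= 2L) {
    d <- diff(grid)
    if (all(d > 0)) {
      if (!allow_ascending)
        stop("wavenumber grid is ascending; pass allow_ascending = TRUE ",
             "to reverse it to the descending convention")
      grid <- rev(grid)
      X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
    } else if (any(d >= 0)) {
      stop("wavenumber grid is not strictly monotone")
    }
  }
  lab <- data.table::fread(labels_path, header = TRUE,
                           colClasses = list(character = 1:2))
  if (!all(c("sample_id", "class") %in% names(lab)))
    stop("labels file must have columns sample_id and class")
  missing_ids <- setdiff(ids, lab$sample_id)
  if (length(missing_ids))
    stop("labels file is missing sample id(s): ",
         paste(head(missing_ids, 5L), collapse = ", "))
  labels <- lab$class[match(ids, lab$sample_id)]
  spectra_dataset(X, grid, labels, ids)
}

#' Dataset diagnostics
#'
#' Computes validation diagnostics without mutating or rejecting the
#' input: sample/point/class counts, a per-class histogram, grid
#' monotonicity and the number of missing values.
#'
#' @param ds A [spectra_dataset()] (or a structurally similar list with
#'   elements `X`, `grid`, `labels`).
#' @return A `dataset_diagnostics` list.
#' @export
validate_dataset <- function(ds) {
  X <- as.matrix(ds$X)
  grid <- ds$grid
  structure(list(
    n_samples = nrow(X),
    n_points = ncol(X),
    n_classes = length(unique(as.character(ds$labels))),
    class_histogram = table(as.character(ds$labels)),
    grid_monotone = length(grid) < 2L || all(diff(grid) < 0),
    missing_values = sum(is.na(X))
  ), class = "dataset_diagnostics")
}

#' @export
print.dataset_diagnostics <- function(x, ...) {
  cat("<dataset_diagnostics>\n",
      "  samples: ", x$n_samples, "  points: ", x$n_points,
      "  classes: ", x$n_classes, "\n",
      "  grid strictly descending: ", x$grid_monotone,
      "  missing values: ", x$missing_values, "\n", sep = "")
  print(x$class_histogram)
  invisible(x)
}
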