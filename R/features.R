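# PCA feature extraction for the classical learners (default 20
# components). Economy SVD of the train-centred matrix; sign fixed so
# each component's largest-magnitude loading element is positive.

#' Fit a PCA model
#'
#' Centres on training column means and computes the leading `k`
#' principal components by singular value decomposition. Components are
#' ordered by decreasing explained variance; each component's sign is
#' fixed so its largest-magnitude loading element is positive, making
#' fits reproducible.
#'
#' @param train Training matrix (rows = spectra).
#' @param k Number of components; `k <= min(n_samples - 1, n_points)`.
#' @return A `pca_model` with loadings (k x n_points), training means,
#'   explained variance ratios and `n_components`.
#' @export
pca_fit <- function(train, k = 20L) {
  train <- as.matrix(train)
  n <- nrow(train); p <- ncol(train)
  k <- as.integer(k)
  kmax <- min(n - 1L, p)
  if (k < 1L || k > kmax)
    stop("k = ", k, " out of range; need 1 <= k <= min(n_samples - 1, n_points) = ", kmax)
  means <- colMeans(train)
  Xc <- sweep(train, 2L, means, `-`)
  sv <- svd(Xc, nu = 0L, nv = kmax)
  var_all <- sv$d[seq_len(kmax)]^2 / (n - 1L)
  total_var <- sum(var_all)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])  # k x p
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  structure(list(
    loadings = loadings,
    means = means,
    explained_variance = var_all[seq_len(k)],
    explained_variance_ratio = if (total_var > 0) var_all[seq_len(k)] / total_var
                               else rep(0, k),
    n_components = k
  ), class = "pca_model")
}

#' Project spectra onto a fitted PCA model
#'
#' @param model A [pca_fit()] model.
#' @param X Matrix with the same number of columns as the training data.
#' @return Scores matrix, n_samples x k.
#' @export
pca_transform <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(model$means))
    stop("shape mismatch: model was fitted on ", length(model$means),
         " points but X has ", ncol(X))
  sweep(X, 2L, model$means, `-`) %*% t(model$loadings)
}

#' Explained-variance report
#'
#' Per-component percentage of variance explained, components 1..k.
#'
#' @param model A [pca_fit()] model.
#' @return Data frame with columns `component`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
explained_variance_report <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  pct <- 100 * model$explained_variance_ratio
  data.frame(component = seq_len(model$n_components),
             variance_pct = pct,
             cumulative_pct = cumsum(pct))
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$n_components, " components over ",
      length(x$means), " points; variance explained ",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)), "\n", sep = "")
  invisible(x)
}
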