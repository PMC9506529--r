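# The six spectral pre-processing operators, leakage-safe pipeline
# fitting, and the enumeration of the 21 one- and two-step chains.
# All operators take spectra as matrix rows (or a single vector).

.as_spectra_matrix <- function(X) {
  if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
}

#' Per-spectrum min-max normalisation
#'
#' Rescales each spectrum (row) linearly to the range [0, 1]. A
#' constant row cannot be rescaled and is mapped to all zeros with a
#' warning.
#'
#' @param X Numeric matrix (rows = spectra) or a single spectrum.
#' @return Matrix of the same shape.
#' @export
minmax_norm <- function(X) {
  X <- .as_spectra_matrix(X)
  rmin <- apply(X, 1L, min)
  rmax <- apply(X, 1L, max)
  rng <- rmax - rmin
  flat <- rng == 0
  if (any(flat)) {
    warning("constant spectrum in row(s) ",
            paste(head(which(flat), 5L), collapse = ", "),
            "; mapped to all zeros")
    rng[flat] <- 1
  }
  out <- (X - rmin) / rng
  out[flat, ] <- 0
  out
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the least-squares polynomial smoothing
#' kernel of the given window and order (no derivative). Edges are
#' handled by mirror padding, so the output has the input's length.
#' With `order >= window - 1` the kernel is an interpolator and the
#' input is reproduced exactly.
#'
#' @param X Numeric matrix (rows = spectra) or a single spectrum.
#' @param window Odd kernel width (points), `order < window <= n_points`.
#' @param order Polynomial order of the local fit.
#' @return Matrix of the same shape.
#' @export
savgol_smooth <- function(X, window = 11L, order = 2L) {
  X <- .as_spectra_matrix(X)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd, got ", window)
  if (order >= window) stop("Savitzky-Golay order (", order,
                            ") must be < window (", window, ")")
  if (window > ncol(X)) stop("Savitzky-Golay window (", window,
                             ") exceeds the number of grid points (", ncol(X), ")")
  kernel <- as.numeric(signal::sgolay(p = order, n = window)[(window + 1L) %/% 2L, ])
  h <- (window - 1L) %/% 2L
  p <- ncol(X)
  # mirror padding (edge point not repeated)
  Xp <- cbind(X[, (h + 1L):2L, drop = FALSE], X,
              X[, (p - 1L):(p - h), drop = FALSE])
  out <- matrix(0, nrow = nrow(X), ncol = p)
  for (k in seq_len(window))
    out <- out + kernel[k] * Xp[, k:(k + p - 1L), drop = FALSE]
  dimnames(out) <- dimnames(X)
  out
}

#' Fit / apply per-wavenumber mean centring
#'
#' `mean_center_fit` estimates per-wavenumber (column) means on the
#' training spectra; `mean_center_apply` subtracts them. Centring is
#' variable-wise across samples, the chemometric convention.
#'
#' @param train Training matrix (rows = spectra).
#' @return `mean_center_fit`: a state list with element `means`.
#' @export
mean_center_fit <- function(train) {
  train <- .as_spectra_matrix(train)
  if (nrow(train) == 0L) stop("mean_center_fit requires a non-empty training set")
  structure(list(means = colMeans(train)), class = "mean_center_state")
}

#' @rdname mean_center_fit
#' @param state State from `mean_center_fit`.
#' @param X Matrix to centre (same grid as the training data).
#' @export
mean_center_apply <- function(state, X) {
  X <- .as_spectra_matrix(X)
  if (ncol(X) != length(state$means))
    stop("grid mismatch: state has ", length(state$means),
         " points but X has ", ncol(X))
  sweep(X, 2L, state$means, `-`)
}

#' Standard normal variate (SNV)
#'
#' Standardises each spectrum to mean 0 and standard deviation 1
#' (n-1 denominator), removing additive offsets and multiplicative
#' gains per spectrum.
#'
#' @param X Numeric matrix (rows = spectra) or a single spectrum.
#' @return Matrix of the same shape; each row has mean 0, sd 1.
#' @export
snv <- function(X) {
  X <- .as_spectra_matrix(X)
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  if (any(s == 0))
    stop("SNV undefined for constant spectrum in row(s) ",
         paste(head(which(s == 0), 5L), collapse = ", "))
  (X - mu) / s
}

#' Fit / apply multiplicative scatter correction (MSC)
#'
#' `msc_fit` stores the training mean spectrum as the reference;
#' `msc_apply` least-squares fits each spectrum as
#' `x ~ a + b * reference` and corrects it to `(x - a) / b`.
#'
#' @param train Training matrix with >= 2 rows.
#' @return `msc_fit`: a state list with element `reference`.
#' @export
msc_fit <- function(train) {
  train <- .as_spectra_matrix(train)
  if (nrow(train) < 2L) stop("msc_fit requires at least 2 training spectra")
  structure(list(reference = colMeans(train)), class = "msc_state")
}

#' @rdname msc_fit
#' @param state State from `msc_fit`.
#' @param X Matrix to correct (same grid as the training data).
#' @export
msc_apply <- function(state, X) {
  X <- .as_spectra_matrix(X)
  ref <- state$reference
  if (ncol(X) != length(ref))
    stop("grid mismatch: reference has ", length(ref),
         " points but X has ", ncol(X))
  refc <- ref - mean(ref)
  ss_ref <- sum(refc^2)
  b <- drop(X %*% refc) / ss_ref  # slope of x ~ a + b*ref, closed form
  if (any(abs(b) < 1e-8))
    stop("MSC failed: spectrum uncorrelated with the reference in row(s) ",
         paste(head(which(abs(b) < 1e-8), 5L), collapse = ", "))
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

#' Wavelet denoising
#'
#' Per spectrum: multilevel periodized orthogonal discrete wavelet
#' decomposition, noise-level estimation from the finest detail
#' coefficients (`MAD / 0.6745`), universal threshold
#' `sigma * sqrt(2 ln n)`, soft (or hard) thresholding of all detail
#' levels, and reconstruction. Input length is restored by trimming the
#' mirror padding. With `threshold = 0` the transform round-trips and
#' the input is reproduced.
#'
#' @param X Numeric matrix (rows = spectra) or a single spectrum.
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"` (Daubechies).
#' @param level Decomposition depth; requires `2^level <= n_points`.
#' @param rule Threshold selection; only `"universal"` is implemented.
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @param threshold Optional fixed threshold overriding the rule.
#' @return Matrix of the same shape.
#' @export
wavelet_denoise <- function(X, wavelet = "db4", level = 5L,
                            rule = "universal", mode = c("soft", "hard"),
                            threshold = NULL) {
  X <- .as_spectra_matrix(X)
  mode <- match.arg(mode)
  rule <- match.arg(rule, "universal")
  level <- as.integer(level)
  if (2L^level > ncol(X))
    stop("wavelet level ", level, " too deep for ", ncol(X),
         " grid points (need 2^level <= n_points)")
  f <- .wavelet_filters(wavelet)
  out <- t(apply(X, 1L, .wavelet_denoise_vec,
                 f = f, level = level, mode = mode, threshold = threshold))
  dimnames(out) <- dimnames(X)
  out
}

# ---- configuration chains ---------------------------------------------

.PREPROC_STEPS <- c("Norm", "SG", "MC", "WT", "MSC", "SNV")

#' Pre-processing configuration
#'
#' An ordered chain of pre-processing steps drawn from
#' Norm (min-max normalisation), SG (Savitzky-Golay), MC (mean
#' centring), WT (wavelet denoising), MSC, SNV. An empty chain is the
#' NO_OP identity.
#'
#' @param steps Character vector of step names, no repeats.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param wt_wavelet,wt_level WT parameters.
#' @return A `preproc_config` object.
#' @export
preproc_config <- function(steps = character(0), sg_window = 11L, sg_order = 2L,
                           wt_wavelet = "db4", wt_level = 5L) {
  steps <- as.character(steps)
  unknown <- setdiff(steps, .PREPROC_STEPS)
  if (length(unknown))
    stop("unknown pre-processing step(s): ", paste(unknown, collapse = ", "),
         "; known steps: ", paste(.PREPROC_STEPS, collapse = ", "))
  if (anyDuplicated(steps))
    stop("pre-processing steps must not repeat within a chain")
  structure(list(steps = steps, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order), wt_wavelet = wt_wavelet,
                 wt_level = as.integer(wt_level)),
            class = "preproc_config")
}

#' @export
print.preproc_config <- function(x, ...) {
  cat("<preproc_config> ", config_label(x), "\n", sep = "")
  invisible(x)
}

#' Display label of a configuration
#'
#' `"NO_OP"` for the empty chain, otherwise step names joined with
#' `" + "` (e.g. `"Norm + WT"`), matching the benchmark table rows.
#'
#' @param config A [preproc_config()].
#' @return A single string.
#' @export
config_label <- function(config) {
  if (length(config$steps) == 0L) "NO_OP" else paste(config$steps, collapse = " + ")
}

#' Enumerate the 21 benchmark configurations
#'
#' The 6 single-step chains plus the 15 ordered two-step chains under
#' the canonical step order Norm < SG < MC < WT < MSC < SNV. NO_OP is
#' excluded (the benchmark harness prepends it separately).
#'
#' @param ... Step parameters forwarded to [preproc_config()].
#' @return List of 21 [preproc_config()] objects.
#' @export
enumerate_paper_configs <- function(...) {
  singles <- lapply(.PREPROC_STEPS, function(s) preproc_config(s, ...))
  pairs <- utils::combn(.PREPROC_STEPS, 2L, simplify = FALSE)
  c(singles, lapply(pairs, preproc_config, ...))
}

# Apply one step; `state` NULL for stateless steps.
.apply_step <- function(step, config, state, X) {
  switch(step,
    Norm = minmax_norm(X),
    SG   = savgol_smooth(X, window = config$sg_window, order = config$sg_order),
    MC   = mean_center_apply(state, X),
    WT   = wavelet_denoise(X, wavelet = config$wt_wavelet, level = config$wt_level),
    MSC  = msc_apply(state, X),
    SNV  = snv(X),
    stop("unknown step ", step)
  )
}

#' Fit and apply a pre-processing chain
#'
#' Applies the configured steps left-to-right to the training and test
#' partitions. Stateful steps (MC, MSC) are fitted on the training
#' partition only by default, so no test-set information leaks into the
#' transformation; `fit_on_all = TRUE` fits them on the union instead
#' (compatibility mode). Errors raised by a step are annotated with the
#' step's name and position in the chain.
#'
#' @param config A [preproc_config()].
#' @param train,test Spectral matrices sharing a grid (test may be NULL).
#' @param fit_on_all Fit stateful steps on train and test combined.
#' @return List with elements `train`, `test` (transformed matrices)
#'   and `fitted` (a `fitted_preprocessor` carrying per-step state).
#' @export
fit_apply_pipeline <- function(config, train, test = NULL, fit_on_all = FALSE) {
  stopifnot(inherits(config, "preproc_config"))
  train <- .as_spectra_matrix(train)
  if (!is.null(test)) {
    test <- .as_spectra_matrix(test)
    if (ncol(test) != ncol(train))
      stop("train and test must share a wavenumber grid")
  }
  states <- vector("list", length(config$steps))
  names(states) <- config$steps
  for (i in seq_along(config$steps)) {
    step <- config$steps[i]
    res <- tryCatch({
      state <- NULL
      if (step %in% c("MC", "MSC")) {
        fit_data <- if (fit_on_all && !is.null(test)) rbind(train, test) else train
        state <- if (step == "MC") mean_center_fit(fit_data) else msc_fit(fit_data)
      }
      tr <- .apply_step(step, config, state, train)
      te <- if (is.null(test)) NULL else .apply_step(step, config, state, test)
      list(state = state, train = tr, test = te)
    }, error = function(e) {
      stop("pre-processing step ", i, " (", step, ") failed: ",
           conditionMessage(e), call. = FALSE)
    })
    states[[i]] <- res$state
    train <- res$train
    test <- res$test
  }
  fitted <- structure(list(config = config, states = states,
                           fit_on_all = fit_on_all),
                      class = "fitted_preprocessor")
  list(train = train, test = test, fitted = fitted)
}
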