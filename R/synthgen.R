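# Synthetic ATR-FT-IR dataset generator: Gaussian band mixtures with
# class-dependent amplitude shifts, polynomial baseline drift,
# multiplicative scatter (gain/offset) and additive white noise.

#' Construct a band table
#'
#' A band table describes the Gaussian absorption bands used by the
#' synthetic spectrum generator: band centres (wavenumber, cm^-1),
#' widths (Gaussian sigma, cm^-1) and base amplitudes (absorbance units).
#'
#' @param centers Numeric vector of band centres in cm^-1.
#' @param widths Numeric vector of Gaussian sigmas in cm^-1, all > 0.
#' @param amplitudes Numeric vector of base amplitudes in AU, all >= 0.
#' @return A `band_table` data frame with columns `center`, `width`,
#'   `amplitude`.
#' @export
band_table <- function(centers, widths, amplitudes) {
  if (length(centers) != length(widths) || length(centers) != length(amplitudes))
    stop("centers, widths and amplitudes must have equal length")
  if (any(!is.finite(centers)) || any(!is.finite(widths)) || any(!is.finite(amplitudes)))
    stop("band table entries must be finite")
  if (any(widths <= 0)) stop("band widths must be > 0")
  if (any(amplitudes < 0)) stop("band amplitudes must be >= 0")
  structure(
    data.frame(center = centers, width = widths, amplitude = amplitudes),
    class = c("band_table", "data.frame")
  )
}

#' Default mid-IR band table
#'
#' The default bands place absorption features at the wavenumbers
#' characteristic of dried gentian root material: C-H stretches at 2923
#' and 2850 cm^-1, the ester carbonyl near 1736 cm^-1, free carboxyl /
#' carbohydrate absorption at 1615 cm^-1, methyl bending at 1421 and
#' 1375 cm^-1, and the intense glucose-skeleton band at 1025 cm^-1.
#' A broad O-H/N-H stretch near 3300 cm^-1 and several small
#' fingerprint-region (1300-400 cm^-1) filler bands are added for
#' realism. Deterministic: repeated calls return identical tables.
#'
#' @return A [band_table()].
#' @export
default_band_table <- function() {
  band_table(
    centers    = c(3300, 2923, 2850, 1736, 1615, 1421, 1375, 1150, 1025,
                   920, 860, 780, 650, 530),
    widths     = c(160,   28,   24,   18,   26,   16,   14,   20,   30,
                   16,  14,  15,  18,  20),
    amplitudes = c(0.60, 0.45, 0.35, 0.30, 0.50, 0.25, 0.25, 0.30, 0.90,
                   0.15, 0.12, 0.10, 0.12, 0.10)
  )
}

#' Synthetic dataset configuration
#'
#' Parameters of the synthetic ATR-FT-IR generator. Defaults emulate a
#' field collection of 222 root samples from 7 provinces measured
#' between 4000 and 400 cm^-1 on a 7468-point grid, each spectrum the
#' average of 3 analytical replicates.
#'
#' @param n_classes Number of classes (geographic origins).
#' @param class_counts Integer vector of per-class sample counts; must
#'   have length `n_classes`, each count >= 2.
#' @param grid_start,grid_end Wavenumber span in cm^-1 (descending grid).
#' @param n_points Number of grid points.
#' @param band_table A [band_table()] of Gaussian bands.
#' @param class_effect_sd SD of the per-class multiplicative band
#'   amplitude factors (unitless, around 1).
#' @param n_affected_bands Number of bands receiving a class effect
#'   (>= 3; drawn at random per class).
#' @param sample_effect_sd SD of per-sample multiplicative band factors.
#' @param baseline_poly_degree Degree of the polynomial baseline drift.
#' @param baseline_coeff_sd SD of the baseline polynomial coefficients (AU).
#' @param scatter_gain_sd SD of the multiplicative scatter gain (around 1).
#' @param scatter_offset_sd SD of the additive scatter offset (AU).
#' @param noise_sd SD of the additive white noise (AU).
#' @param n_replicates Analytical replicates per sample.
#' @param replicate_mode `"average"` (default) averages replicates into
#'   one spectrum per sample; `"pool"` keeps every replicate as a row.
#' @param seed Integer seed; identical configurations generate
#'   bit-identical datasets.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_classes = 7,
                             class_counts = c(38, 36, 34, 32, 30, 28, 24),
                             grid_start = 4000, grid_end = 400,
                             n_points = 7468,
                             band_table = default_band_table(),
                             class_effect_sd = 0.15,
                             n_affected_bands = 5,
                             sample_effect_sd = 0.05,
                             baseline_poly_degree = 2,
                             baseline_coeff_sd = 0.01,
                             scatter_gain_sd = 0.10,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.005,
                             n_replicates = 3,
                             replicate_mode = c("average", "pool"),
                             seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes), class_counts = as.integer(class_counts),
    grid_start = grid_start, grid_end = grid_end, n_points = as.integer(n_points),
    band_table = band_table,
    class_effect_sd = class_effect_sd, n_affected_bands = as.integer(n_affected_bands),
    sample_effect_sd = sample_effect_sd,
    baseline_poly_degree = as.integer(baseline_poly_degree),
    baseline_coeff_sd = baseline_coeff_sd,
    scatter_gain_sd = scatter_gain_sd, scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    replicate_mode = match.arg(replicate_mode), seed = as.integer(seed)
  )
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_synthetic_config <- function(cfg) {
  if (cfg$n_classes < 1L) stop("invalid synthetic_config: n_classes must be >= 1")
  if (length(cfg$class_counts) != cfg$n_classes)
    stop("invalid synthetic_config: class_counts must have length n_classes")
  if (any(cfg$class_counts < 2L))
    stop("invalid synthetic_config: class_counts must all be >= 2 ",
         "(a stratified split needs at least one sample per class per partition)")
  if (cfg$n_points < 2L) stop("invalid synthetic_config: n_points must be >= 2")
  sds <- c(class_effect_sd = cfg$class_effect_sd, sample_effect_sd = cfg$sample_effect_sd,
           baseline_coeff_sd = cfg$baseline_coeff_sd, scatter_gain_sd = cfg$scatter_gain_sd,
           scatter_offset_sd = cfg$scatter_offset_sd, noise_sd = cfg$noise_sd)
  bad <- names(sds)[!is.finite(sds) | sds < 0]
  if (length(bad))
    stop("invalid synthetic_config: ", bad[1L], " must be a finite value >= 0")
  if (!inherits(cfg$band_table, "band_table"))
    stop("invalid synthetic_config: band_table must be a band_table object")
  if (cfg$n_replicates < 1L) stop("invalid synthetic_config: n_replicates must be >= 1")
  if (cfg$n_affected_bands < 3L)
    stop("invalid synthetic_config: n_affected_bands must be >= 3")
  if (cfg$baseline_poly_degree < 0L)
    stop("invalid synthetic_config: baseline_poly_degree must be >= 0")
  span <- range(c(cfg$grid_start, cfg$grid_end))
  if (any(cfg$band_table$center < span[1L] | cfg$band_table$center > span[2L]))
    stop("invalid synthetic_config: band_table centers must lie within the grid span")
  invisible(cfg)
}

#' Spectral dataset container
#'
#' Holds an n_samples x n_points absorbance matrix, its wavenumber grid
#' (strictly descending, FT-IR display convention), per-sample class
#' labels and sample identifiers.
#'
#' @param X Numeric matrix, rows = spectra, columns = grid points.
#' @param grid Numeric vector of wavenumbers in cm^-1, strictly
#'   descending, length `ncol(X)`.
#' @param labels Class labels (coerced to factor), length `nrow(X)`.
#' @param sample_ids Character sample identifiers, length `nrow(X)`;
#'   generated as `s0001`, ... when omitted.
#' @return A `spectra_dataset` object.
#' @export
spectra_dataset <- function(X, grid, labels, sample_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%04d", seq_len(nrow(X)))
  if (length(grid) != ncol(X))
    stop("grid length (", length(grid), ") must equal ncol(X) (", ncol(X), ")")
  if (length(labels) != nrow(X) || length(sample_ids) != nrow(X))
    stop("labels and sample_ids must have one entry per row of X")
  if (anyNA(X)) stop("X must not contain missing values")
  if (length(grid) >= 2L && any(diff(grid) >= 0))
    stop("grid must be strictly descending (wavenumber convention 4000 -> 400)")
  rownames(X) <- sample_ids
  structure(list(grid = as.numeric(grid), X = X,
                 labels = factor(labels), sample_ids = as.character(sample_ids)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("<spectra_dataset> ", nrow(x$X), " spectra x ", ncol(x$X), " points, ",
      nlevels(x$labels), " classes; grid ",
      format(x$grid[1L]), " -> ", format(x$grid[length(x$grid)]), " cm^-1\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

# Evaluate the Gaussian band mixture on the grid for one amplitude vector.
.band_mixture <- function(grid, bt, amps) {
  s <- numeric(length(grid))
  for (b in seq_len(nrow(bt)))
    s <- s + amps[b] * exp(-(grid - bt$center[b])^2 / (2 * bt$width[b]^2))
  s
}

#' Generate a synthetic spectral dataset
#'
#' Each spectrum is a Gaussian band mixture whose band amplitudes carry
#' a class-level multiplicative perturbation (drawn once per class, on a
#' random subset of bands) and a sample-level perturbation, plus a
#' random polynomial baseline, a multiplicative scatter distortion
#' `gain * spectrum + offset`, and additive white noise. Baseline,
#' scatter and noise are redrawn per analytical replicate; replicates
#' are averaged (default) or pooled. Identical configurations produce
#' bit-identical datasets.
#'
#' @param cfg A [synthetic_config()].
#' @return A [spectra_dataset()].
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) .validate_synthetic_config(cfg)
  withr::with_seed(cfg$seed, .generate_dataset_impl(cfg))
}

.generate_dataset_impl <- function(cfg) {
  grid <- seq(cfg$grid_start, cfg$grid_end, length.out = cfg$n_points)
  bt <- cfg$band_table
  nb <- nrow(bt)
  n_total <- sum(cfg$class_counts)

  # per-class band amplitude factors on a random subset of >= 3 bands
  class_factors <- matrix(1, nrow = cfg$n_classes, ncol = nb)
  k_aff <- min(cfg$n_affected_bands, nb)
  for (cl in seq_len(cfg$n_classes)) {
    idx <- sample.int(nb, k_aff)
    class_factors[cl, idx] <- rnorm(k_aff, mean = 1, sd = cfg$class_effect_sd)
  }
  class_factors[class_factors < 0] <- 0

  deg <- cfg$baseline_poly_degree
  tpow <- outer(seq(0, 1, length.out = cfg$n_points), 0:deg, `^`)

  rep_rows <- if (cfg$replicate_mode == "pool") n_total * cfg$n_replicates else n_total
  X <- matrix(0, nrow = rep_rows, ncol = cfg$n_points)
  labels <- character(rep_rows)
  ids <- character(rep_rows)

  row <- 0L
  sample_no <- 0L
  for (cl in seq_len(cfg$n_classes)) {
    for (s in seq_len(cfg$class_counts[cl])) {
      sample_no <- sample_no + 1L
      samp_f <- rnorm(nb, mean = 1, sd = cfg$sample_effect_sd)
      amps <- bt$amplitude * class_factors[cl, ] * pmax(samp_f, 0)
      clean <- .band_mixture(grid, bt, amps)
      reps <- matrix(0, nrow = cfg$n_replicates, ncol = cfg$n_points)
      for (r in seq_len(cfg$n_replicates)) {
        base <- drop(tpow %*% rnorm(deg + 1L, 0, cfg$baseline_coeff_sd))
        gain <- rnorm(1L, 1, cfg$scatter_gain_sd)
        offs <- rnorm(1L, 0, cfg$scatter_offset_sd)
        spec <- gain * (clean + base) + offs
        if (cfg$noise_sd > 0)
          spec <- spec + rnorm(cfg$n_points, 0, cfg$noise_sd)
        reps[r, ] <- spec
      }
      if (cfg$replicate_mode == "average") {
        row <- row + 1L
        X[row, ] <- colMeans(reps)
        labels[row] <- paste0("class", cl)
        ids[row] <- sprintf("s%04d", sample_no)
      } else {
        for (r in seq_len(cfg$n_replicates)) {
          row <- row + 1L
          X[row, ] <- reps[r, ]
          labels[row] <- paste0("class", cl)
          ids[row] <- sprintf("s%04d_r%d", sample_no, r)
        }
      }
    }
  }
  spectra_dataset(X, grid, labels, ids)
}

#' Between- to within-class distance ratio
#'
#' Generator diagnostic: the mean pairwise Euclidean distance between
#' class centroids divided by the mean distance of samples to their own
#' class centroid. Values well above 1 indicate a separable dataset.
#'
#' @param ds A [spectra_dataset()].
#' @return A single non-negative ratio.
#' @export
class_separation <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  labs <- droplevels(ds$labels)
  if (nlevels(labs) < 2L)
    stop("class_separation requires at least 2 classes present")
  cents <- do.call(rbind, lapply(levels(labs), function(l)
    colMeans(ds$X[labs == l, , drop = FALSE])))
  between <- mean(dist(cents))
  within_d <- vapply(seq_len(nrow(ds$X)), function(i) {
    sqrt(sum((ds$X[i, ] - cents[as.integer(labs)[i], ])^2))
  }, numeric(1))
  within <- mean(within_d)
  if (within == 0) return(Inf)
  between / within
}
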