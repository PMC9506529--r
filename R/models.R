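# Classifiers: the two-branch Double-Net (elementwise-sum merge of two
# independently parameterised feed-forward branches, softmax head), a
# plain back-propagation network, and wrappers giving the three
# classical baselines (decision tree, Gaussian naive Bayes, RBF SVM)
# the same train/predict contract. Networks are trained by mini-batch
# Adam on the multiclass cross-entropy; all matrix work goes through
# BLAS.

.act <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0),
                da = function(a) (a > 0) * 1),
    tanh = list(f = base::tanh,
                da = function(a) 1 - a^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   da = function(a) a * (1 - a)),
    identity = list(f = identity, da = function(a) 1),
    stop("unknown activation '", name, "'")
  )
}

#' Single-neuron forward pass
#'
#' Computes `activation(sum(weights * x) + bias)`: the weighted-sum
#' perceptron with bias, passed through an activation function.
#'
#' @param weights,x Numeric vectors of equal length.
#' @param bias Scalar bias.
#' @param activation One of `"identity"`, `"relu"`, `"tanh"`, `"sigmoid"`.
#' @return The scalar neuron output.
#' @export
neuron_forward <- function(weights, bias, x, activation = "identity") {
  if (length(weights) != length(x))
    stop("weights and x must have equal length (", length(weights),
         " vs ", length(x), ")")
  .act(activation)$f(sum(weights * x) + bias)
}

#' Hidden-layer description
#'
#' @param width Number of neurons (>= 1).
#' @param activation Activation function name.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(width, activation = "relu") {
  width <- as.integer(width)
  if (width < 1L) stop("layer width must be >= 1")
  .act(activation)  # validates the name
  structure(list(width = width, activation = activation), class = "layer_spec")
}

#' Back-propagation network architecture
#'
#' A plain multilayer perceptron: input, hidden layers, and a softmax
#' output over the classes.
#'
#' @param input_dim Number of input features.
#' @param hidden List of [layer_spec()] hidden layers.
#' @param n_classes Number of output classes (>= 2).
#' @return A `bp_net_spec`.
#' @export
bp_net_spec <- function(input_dim = 7468L, hidden = list(layer_spec(64L, "relu")),
                        n_classes = 7L) {
  input_dim <- as.integer(input_dim); n_classes <- as.integer(n_classes)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (!length(hidden) || !all(vapply(hidden, inherits, logical(1), "layer_spec")))
    stop("hidden must be a non-empty list of layer_spec objects")
  structure(list(input_dim = input_dim, hidden = hidden, n_classes = n_classes),
            class = "bp_net_spec")
}

#' Double-Net architecture
#'
#' Two feed-forward branches of identical topology applied to the same
#' input; their output activations are merged by elementwise summation
#' and passed to an affine softmax head. Branches are independently
#' initialised unless `share_weights = TRUE`, in which case a single
#' parameter set is used for both (so the merge output is exactly twice
#' one branch's output).
#'
#' @param input_dim Number of input features.
#' @param branch_hidden List of [layer_spec()] layers per branch.
#' @param n_classes Number of output classes (>= 2).
#' @param share_weights Share one parameter set between the branches.
#' @return A `double_net_spec`.
#' @export
double_net_spec <- function(input_dim = 7468L,
                            branch_hidden = list(layer_spec(64L, "relu"),
                                                 layer_spec(32L, "relu")),
                            n_classes = 7L, share_weights = FALSE) {
  input_dim <- as.integer(input_dim); n_classes <- as.integer(n_classes)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (!length(branch_hidden) ||
      !all(vapply(branch_hidden, inherits, logical(1), "layer_spec")))
    stop("branch_hidden must be a non-empty list of layer_spec objects")
  structure(list(input_dim = input_dim, branch_hidden = branch_hidden,
                 n_classes = n_classes, share_weights = isTRUE(share_weights)),
            class = "double_net_spec")
}

#' Training configuration for the networks
#'
#' @param epochs Number of passes over the training data (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling mini-batch shuffling.
#' @param early_stop_patience Optional: stop when the epoch loss has not
#'   improved for this many epochs.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 3e-3, batch_size = 32L,
                         seed = 1L, early_stop_patience = NULL) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

# ---- parameter construction -------------------------------------------

.init_stack_params <- function(widths, activations, prefix) {
  params <- list()
  for (i in seq_len(length(widths) - 1L)) {
    fan_in <- widths[i]
    scale <- if (activations[i] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    params[[paste0(prefix, "W", i)]] <-
      matrix(rnorm(fan_in * widths[i + 1L], 0, scale), fan_in, widths[i + 1L])
    params[[paste0(prefix, "b", i)]] <- numeric(widths[i + 1L])
  }
  params
}

.bp_widths <- function(spec)
  c(spec$input_dim, vapply(spec$hidden, `[[`, integer(1), "width"), spec$n_classes)
.bp_acts <- function(spec)
  c(vapply(spec$hidden, `[[`, character(1), "activation"), "identity")
.branch_widths <- function(spec)
  c(spec$input_dim, vapply(spec$branch_hidden, `[[`, integer(1), "width"))
.branch_acts <- function(spec)
  vapply(spec$branch_hidden, `[[`, character(1), "activation")

#' Build a back-propagation network
#'
#' @param spec A [bp_net_spec()].
#' @param seed Seed for the weight initialisation.
#' @return An untrained `bp_net` model (class `ftir_net`).
#' @export
build_bp_net <- function(spec = bp_net_spec(), seed = 1L) {
  stopifnot(inherits(spec, "bp_net_spec"))
  params <- withr::with_seed(as.integer(seed),
    .init_stack_params(.bp_widths(spec), .bp_acts(spec), ""))
  structure(list(type = "bp_net", spec = spec, params = params,
                 seed = as.integer(seed), classes = NULL, trained = FALSE),
            class = c("bp_net", "ftir_net"))
}

#' Build a Double-Net
#'
#' @param spec A [double_net_spec()].
#' @param seed Seed for the weight initialisation (the two branches draw
#'   independent weights from it unless `spec$share_weights`).
#' @return An untrained `double_net` model (class `ftir_net`).
#' @export
build_double_net <- function(spec = double_net_spec(), seed = 1L) {
  stopifnot(inherits(spec, "double_net_spec"))
  bw <- .branch_widths(spec); ba <- .branch_acts(spec)
  head_in <- bw[length(bw)]
  params <- withr::with_seed(as.integer(seed), {
    p <- .init_stack_params(bw, ba, "B1.")
    if (!spec$share_weights)
      p <- c(p, .init_stack_params(bw, ba, "B2."))
    p[["head.W"]] <- matrix(rnorm(head_in * spec$n_classes, 0, sqrt(1 / head_in)),
                            head_in, spec$n_classes)
    p[["head.b"]] <- numeric(spec$n_classes)
    p
  })
  structure(list(type = "double_net", spec = spec, params = params,
                 seed = as.integer(seed), classes = NULL, trained = FALSE),
            class = c("double_net", "ftir_net"))
}

#' Number of trainable parameters
#'
#' @param model A built network.
#' @return Integer parameter count (weights + biases).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "ftir_net"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward / backward -----------------------------------------------

.stack_layers <- function(params, prefix, n_layers, activations) {
  lapply(seq_len(n_layers), function(i)
    list(W = params[[paste0(prefix, "W", i)]],
         b = params[[paste0(prefix, "b", i)]],
         activation = activations[i]))
}

.stack_forward <- function(layers, X) {
  A <- X
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    Z <- sweep(A %*% L$W, 2L, L$b, `+`)
    A_out <- .act(L$activation)$f(Z)
    caches[[i]] <- list(A_in = A, A_out = A_out)
    A <- A_out
  }
  list(out = A, caches = caches)
}

# dA: gradient w.r.t. the stack output activations.
.stack_backward <- function(layers, caches, dA, prefix) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]
    cc <- caches[[i]]
    dZ <- dA * .act(L$activation)$da(cc$A_out)
    grads[[paste0(prefix, "W", i)]] <- crossprod(cc$A_in, dZ)
    grads[[paste0(prefix, "b", i)]] <- colSums(dZ)
    if (i > 1L) dA <- tcrossprod(dZ, L$W)
  }
  grads
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass returning class probabilities and caches for backprop.
.net_forward <- function(model, X) {
  p <- model$params; spec <- model$spec
  if (model$type == "bp_net") {
    acts <- .bp_acts(spec)
    layers <- .stack_layers(p, "", length(acts), acts)
    fw <- .stack_forward(layers, X)
    list(probs = .softmax(fw$out), bp = list(layers = layers, fw = fw))
  } else {
    acts <- .branch_acts(spec)
    nl <- length(acts)
    l1 <- .stack_layers(p, "B1.", nl, acts)
    f1 <- .stack_forward(l1, X)
    if (spec$share_weights) {
      l2 <- l1; f2 <- f1
    } else {
      l2 <- .stack_layers(p, "B2.", nl, acts)
      f2 <- .stack_forward(l2, X)
    }
    S <- f1$out + f2$out
    logits <- sweep(S %*% p[["head.W"]], 2L, p[["head.b"]], `+`)
    list(probs = .softmax(logits),
         dn = list(l1 = l1, f1 = f1, l2 = l2, f2 = f2, S = S))
  }
}

# Mean cross-entropy loss and parameter gradients for a batch.
.net_grads <- function(model, X, Y) {
  fw <- .net_forward(model, X)
  P <- fw$probs
  n <- nrow(X)
  loss <- -mean(log(pmax(rowSums(P * Y), 1e-12)))
  n_correct <- sum(max.col(P, ties.method = "first") == max.col(Y))
  dlogits <- (P - Y) / n
  if (model$type == "bp_net") {
    grads <- .stack_backward(fw$bp$layers, fw$bp$fw$caches, dlogits, "")
  } else {
    p <- model$params
    grads <- list()
    grads[["head.W"]] <- crossprod(fw$dn$S, dlogits)
    grads[["head.b"]] <- colSums(dlogits)
    dS <- tcrossprod(dlogits, p[["head.W"]])
    g1 <- .stack_backward(fw$dn$l1, fw$dn$f1$caches, dS, "B1.")
    if (model$spec$share_weights) {
      g2 <- .stack_backward(fw$dn$l2, fw$dn$f2$caches, dS, "B1.")
      for (nm in names(g1)) g1[[nm]] <- g1[[nm]] + g2[[nm]]
      grads <- c(grads, g1)
    } else {
      g2 <- .stack_backward(fw$dn$l2, fw$dn$f2$caches, dS, "B2.")
      grads <- c(grads, g1, g2)
    }
  }
  list(loss = loss, grads = grads, n_correct = n_correct)
}

# ---- training ----------------------------------------------------------

#' Train a model
#'
#' Networks (`ftir_net`) are trained by mini-batch Adam on the
#' multiclass cross-entropy; baselines delegate to their underlying
#' learner. Fully deterministic given the model's build seed and
#' `cfg$seed` (which controls shuffling).
#'
#' @param model A built network or [make_baseline()] model.
#' @param X Feature matrix, rows = samples.
#' @param y Class labels (factor or coercible).
#' @param cfg A [train_config()].
#' @param ... Passed to methods.
#' @return List with elements `model` (fitted) and `history` (per-epoch
#'   loss and training accuracy for networks; NULL for baselines).
#' @export
train_model <- function(model, X, y, cfg = train_config(), ...) {
  UseMethod("train_model")
}

#' @export
train_model.ftir_net <- function(model, X, y, cfg = train_config(), ...) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must match length of y")
  C <- model$spec$n_classes
  if (nlevels(y) > C)
    stop("model has ", C, " output classes but y has ", nlevels(y), " levels")
  if (ncol(X) != model$spec$input_dim)
    stop("model expects ", model$spec$input_dim, " features, got ", ncol(X))
  yi <- as.integer(y)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), yi)] <- 1

  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  # unshare parameter memory: the Adam kernel updates arrays in place
  model$params <- lapply(model$params, function(p) p + 0)
  zeros <- function(p) array(0, dim = dim(p) %||% length(p))
  m_st <- lapply(model$params, zeros)
  v_st <- lapply(model$params, zeros)  # distinct memory: updates are in place
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_accuracy = numeric(0))
  best_loss <- Inf; stall <- 0L

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      epoch_correct <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        gr <- .net_grads(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        if (!is.finite(gr$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               "; reduce the learning rate")
        epoch_loss <- epoch_loss + gr$loss * length(idx)
        epoch_correct <- epoch_correct + gr$n_correct
        t_step <- t_step + 1L
        corr <- lr * sqrt(1 - b2^t_step) / (1 - b1^t_step)
        for (nm in names(model$params))
          adam_update_(model$params[[nm]], m_st[[nm]], v_st[[nm]],
                       gr$grads[[nm]], corr, b1, b2, eps)
      }
      epoch_loss <- epoch_loss / n
      # training accuracy accumulated over the epoch's batch forwards
      history[epoch, ] <- list(epoch, epoch_loss, epoch_correct / n)
      if (!is.null(cfg$early_stop_patience)) {
        if (epoch_loss < best_loss - 1e-6) {
          best_loss <- epoch_loss; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$early_stop_patience) break
        }
      }
    }
  })
  model$classes <- levels(y)
  model$trained <- TRUE
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class-probability predictions
#'
#' @param model A fitted model.
#' @param X Feature matrix.
#' @param ... Passed to methods.
#' @return Matrix of per-class probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.ftir_net <- function(model, X, ...) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != model$spec$input_dim)
    stop("model expects ", model$spec$input_dim, " features, got ", ncol(X))
  P <- .net_forward(model, X)$probs
  colnames(P) <- model$classes %||% paste0("class", seq_len(ncol(P)))
  P
}

#' Class-label predictions
#'
#' The predicted label is the probability argmax; ties break to the
#' lowest class index.
#'
#' @param model A fitted model.
#' @param X Feature matrix.
#' @param ... Passed to methods.
#' @return Factor of predicted labels.
#' @export
predict_classes <- function(model, X, ...) UseMethod("predict_classes")

#' @export
predict_classes.ftir_net <- function(model, X, ...) {
  P <- predict_proba(model, X)
  cls <- model$classes %||% as.character(seq_len(ncol(P)))
  factor(cls[max.col(P, ties.method = "first")], levels = cls)
}

#' @export
predict.ftir_net <- function(object, newdata, ...) predict_classes(object, newdata)

#' @export
print.ftir_net <- function(x, ...) {
  cat("<", x$type, "> ", format(n_params(x), big.mark = ","),
      " parameters; input ", x$spec$input_dim, " -> ", x$spec$n_classes,
      " classes; ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# ---- classical baselines ----------------------------------------------

#' Construct a classical baseline classifier
#'
#' Returns an untrained model honouring the same
#' [train_model()]/[predict_classes()] contract as the networks:
#' `decision_tree` (impurity-based axis-aligned splits, via rpart),
#' `naive_bayes` (per-class independent Gaussian likelihoods, via
#' e1071), or `svm` (RBF kernel, one-vs-one pairwise multiclass, via
#' e1071).
#'
#' @param kind One of `"decision_tree"`, `"naive_bayes"`, `"svm"`.
#' @param params Named list of extra arguments for the learner.
#' @return An untrained `baseline_model`.
#' @export
make_baseline <- function(kind = c("decision_tree", "naive_bayes", "svm"),
                          params = list()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = params, trained = FALSE),
            class = c(kind, "baseline_model"))
}

.feat_names <- function(p) paste0("V", seq_len(p))

#' @export
train_model.baseline_model <- function(model, X, y, cfg = train_config(), ...) {
  X <- as.matrix(X)
  colnames(X) <- .feat_names(ncol(X))
  y <- factor(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  fit <- withr::with_seed(cfg$seed, switch(model$kind,
    decision_tree = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      do.call(rpart::rpart,
              c(list(formula = .y ~ ., data = df, method = "class"),
                model$params))
    },
    # extra args spliced via ... so x/y stay symbols (naiveBayes deparses them)
    naive_bayes = do.call(function(...) e1071::naiveBayes(x = X, y = y, ...),
                          model$params),
    svm = do.call(function(...) e1071::svm(x = X, y = y, kernel = "radial", ...),
                  model$params)
  ))
  model$fit <- fit
  model$classes <- levels(y)
  model$trained <- TRUE
  list(model = model, history = NULL)
}

#' @export
predict_classes.baseline_model <- function(model, X, ...) {
  if (!model$trained) stop("model has not been trained")
  X <- as.matrix(X)
  colnames(X) <- .feat_names(ncol(X))
  pred <- switch(model$kind,
    decision_tree = predict(model$fit, data.frame(X, check.names = FALSE),
                            type = "class"),
    naive_bayes = predict(model$fit, X),
    svm = predict(model$fit, X))
  factor(as.character(pred), levels = model$classes)
}

#' @export
predict_proba.baseline_model <- function(model, X, ...) {
  if (!model$trained) stop("model has not been trained")
  X <- as.matrix(X)
  colnames(X) <- .feat_names(ncol(X))
  switch(model$kind,
    decision_tree = predict(model$fit, data.frame(X, check.names = FALSE),
                            type = "prob"),
    naive_bayes = predict(model$fit, X, type = "raw"),
    svm = stop("probability predictions are not enabled for the SVM baseline; ",
               "pass params = list(probability = TRUE) and use predict() directly"))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("<baseline:", x$kind, "> ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}
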