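test_that("the neuron computes activation(sum(w*x) + b)", {
  expect_identical(neuron_forward(c(1, 1), 0, c(2, 3), "identity"), 5)
  expect_identical(neuron_forward(c(1, 1), -7, c(2, 3), "relu"), 0)
  expect_identical(neuron_forward(c(0.5, -1), 1, c(2, 1), "identity"), 1)
  expect_equal(neuron_forward(c(1, 0), 0, c(0, 0), "sigmoid"), 0.5)
  expect_error(neuron_forward(c(1, 2, 3), 0, c(1, 2)), "equal length")
})

test_that("parameter counts match the closed-form sums over layers", {
  # two branches of one identity layer 4 -> 3, head 3 -> 2:
  # 2*(4*3 + 3) + (3*2 + 2) = 38
  dn <- build_double_net(double_net_spec(
    input_dim = 4L, branch_hidden = list(layer_spec(3L, "identity")),
    n_classes = 2L), seed = 1L)
  expect_identical(n_params(dn), 38L)
  # shared weights halve the branch parameters: (4*3 + 3) + 8 = 23
  dn_sh <- build_double_net(double_net_spec(
    input_dim = 4L, branch_hidden = list(layer_spec(3L, "identity")),
    n_classes = 2L, share_weights = TRUE), seed = 1L)
  expect_identical(n_params(dn_sh), 23L)
  # single trunk: (5*4 + 4) + (4*3 + 3) = 39
  bp <- build_bp_net(bp_net_spec(input_dim = 5L,
                                 hidden = list(layer_spec(4L, "relu")),
                                 n_classes = 3L), seed = 1L)
  expect_identical(n_params(bp), 39L)
})

test_that("builds are seed-reproducible and outputs are proper probabilities", {
  spec <- double_net_spec(input_dim = 6L,
                          branch_hidden = list(layer_spec(5L, "relu")),
                          n_classes = 3L)
  m1 <- build_double_net(spec, seed = 11L)
  m2 <- build_double_net(spec, seed = 11L)
  expect_identical(m1$params, m2$params)
  X <- withr::with_seed(1L, matrix(rnorm(24), 4L, 6L))
  P <- predict_proba(m1, X)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("the sum merge is symmetric in the two branches", {
  spec <- double_net_spec(input_dim = 5L,
                          branch_hidden = list(layer_spec(4L, "tanh"),
                                               layer_spec(3L, "tanh")),
                          n_classes = 3L)
  m <- build_double_net(spec, seed = 2L)
  swapped <- m
  for (i in 1:2) {
    for (what in c("W", "b")) {
      k1 <- paste0("B1.", what, i); k2 <- paste0("B2.", what, i)
      tmp <- swapped$params[[k1]]
      swapped$params[[k1]] <- swapped$params[[k2]]
      swapped$params[[k2]] <- tmp
    }
  }
  X <- withr::with_seed(3L, matrix(rnorm(40), 8L, 5L))
  expect_equal(predict_proba(m, X), predict_proba(swapped, X), tolerance = 1e-12)
})

test_that("weight sharing degenerates to softmax(head(2 * branch(x)))", {
  spec <- double_net_spec(input_dim = 5L,
                          branch_hidden = list(layer_spec(4L, "tanh")),
                          n_classes = 3L, share_weights = TRUE)
  m <- build_double_net(spec, seed = 4L)
  X <- withr::with_seed(5L, matrix(rnorm(30), 6L, 5L))
  # manual forward through the single shared branch
  H <- tanh(sweep(X %*% m$params[["B1.W1"]], 2L, m$params[["B1.b1"]], `+`))
  logits <- sweep((2 * H) %*% m$params[["head.W"]], 2L, m$params[["head.b"]], `+`)
  P_manual <- exp(logits - apply(logits, 1L, max))
  P_manual <- P_manual / rowSums(P_manual)
  expect_equal(unname(predict_proba(m, X)), unname(P_manual), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences through the sum merge", {
  spec <- double_net_spec(input_dim = 5L,
                          branch_hidden = list(layer_spec(4L, "tanh"),
                                               layer_spec(3L, "sigmoid")),
                          n_classes = 3L)
  m <- build_double_net(spec, seed = 6L)
  X <- withr::with_seed(7L, matrix(rnorm(4 * 5), 4L, 5L))
  Y <- diag(3)[c(1, 2, 3, 1), ]
  an <- ftirnet:::.net_grads(m, X, Y)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (j in seq_len(min(length(p), 6L))) {
      mp <- m; mp$params[[nm]][j] <- p[j] + eps
      mm <- m; mm$params[[nm]][j] <- p[j] - eps
      num <- (ftirnet:::.net_grads(mp, X, Y)$loss -
              ftirnet:::.net_grads(mm, X, Y)$loss) / (2 * eps)
      expect_lt(abs(num - an$grads[[nm]][j]), 1e-4)
    }
  }
  # same check on the single-trunk network
  bp <- build_bp_net(bp_net_spec(input_dim = 5L,
                                 hidden = list(layer_spec(4L, "tanh")),
                                 n_classes = 3L), seed = 8L)
  an_bp <- ftirnet:::.net_grads(bp, X, Y)
  for (nm in names(bp$params)) {
    p <- bp$params[[nm]]
    for (j in seq_len(min(length(p), 6L))) {
      mp <- bp; mp$params[[nm]][j] <- p[j] + eps
      mm <- bp; mm$params[[nm]][j] <- p[j] - eps
      num <- (ftirnet:::.net_grads(mp, X, Y)$loss -
              ftirnet:::.net_grads(mm, X, Y)$loss) / (2 * eps)
      expect_lt(abs(num - an_bp$grads[[nm]][j]), 1e-4)
    }
  }
})

test_that("training solves a linearly separable toy and is seed-deterministic", {
  X <- withr::with_seed(9L, rbind(matrix(rnorm(50, mean = 2), 10L, 5L),
                                  matrix(rnorm(50, mean = -2), 10L, 5L)))
  y <- rep(c("pos", "neg"), each = 10L)
  spec <- double_net_spec(input_dim = 5L,
                          branch_hidden = list(layer_spec(8L, "relu")),
                          n_classes = 2L)
  cfg <- train_config(epochs = 100L, seed = 3L)
  fit1 <- train_model(build_double_net(spec, seed = 10L), X, y, cfg)
  expect_identical(tail(fit1$history$train_accuracy, 1L), 1)
  expect_identical(nrow(fit1$history), 100L)
  fit2 <- train_model(build_double_net(spec, seed = 10L), X, y, cfg)
  expect_identical(tail(fit1$history$loss, 1L), tail(fit2$history$loss, 1L))
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(as.character(predict_classes(fit1$model, X)),
                   as.character(predict_classes(fit2$model, X)))
})

test_that("prediction is the argmax with lowest-index tie-break", {
  bp <- build_bp_net(bp_net_spec(input_dim = 3L,
                                 hidden = list(layer_spec(2L, "identity")),
                                 n_classes = 4L), seed = 1L)
  # zero all parameters: every class equally probable, ties everywhere
  bp$params <- lapply(bp$params, function(p) p * 0)
  bp$classes <- c("w", "x", "y", "z")
  P <- predict_proba(bp, matrix(rnorm(9), 3L))
  expect_equal(unname(P), matrix(0.25, 3L, 4L))
  expect_identical(as.character(predict_classes(bp, matrix(rnorm(9), 3L))),
                   rep("w", 3L))
})

test_that("training aborts with a diagnostic when the loss diverges", {
  X <- matrix(Inf, 4L, 3L)  # non-finite activations poison the loss
  y <- c("a", "b", "a", "b")
  bp <- build_bp_net(bp_net_spec(input_dim = 3L,
                                 hidden = list(layer_spec(2L, "relu")),
                                 n_classes = 2L), seed = 1L)
  expect_error(train_model(bp, X, y, train_config(epochs = 5L)), "non-finite")
})

test_that("baselines honour the shared fit/predict contract", {
  # naive Bayes separates two well-separated Gaussian classes
  Xtr <- withr::with_seed(11L, rbind(matrix(rnorm(100, 0), 20L, 5L),
                                     matrix(rnorm(100, 4), 20L, 5L)))
  ytr <- rep(c("a", "b"), each = 20L)
  Xte <- withr::with_seed(12L, rbind(matrix(rnorm(100, 0), 20L, 5L),
                                     matrix(rnorm(100, 4), 20L, 5L)))
  yte <- rep(c("a", "b"), each = 20L)
  nb <- train_model(make_baseline("naive_bayes"), Xtr, ytr)$model
  expect_gt(mean(predict_classes(nb, Xte) == yte), 0.95)
  pr <- predict_proba(nb, Xte)
  expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-6)

  # decision tree nails a 1-feature threshold problem on train
  X1 <- matrix(c(1:20, rnorm(20)), 20L, 2L)
  y1 <- rep(c("lo", "hi"), each = 10L)
  dt <- train_model(make_baseline("decision_tree"),
                    X1, y1, cfg = train_config(seed = 1L))$model
  expect_identical(as.character(predict_classes(dt, X1)), y1)

  # one-vs-one SVM trains choose(3, 2) pairwise machines
  X3 <- withr::with_seed(13L, rbind(matrix(rnorm(40, 0), 10L, 4L),
                                    matrix(rnorm(40, 3), 10L, 4L),
                                    matrix(rnorm(40, -3), 10L, 4L)))
  y3 <- rep(c("a", "b", "c"), each = 10L)
  sv <- train_model(make_baseline("svm"), X3, y3)$model
  expect_length(sv$fit$rho, 3L)
  expect_s3_class(predict_classes(sv, X3), "factor")

  expect_error(make_baseline("boosting"), "arg")
  expect_error(predict_classes(make_baseline("svm"), X3), "not been trained")
})
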