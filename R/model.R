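#' Feed-forward network configuration
#'
#' Defaults follow the tuned architecture for the 430-feature hybrid input:
#' five hidden layers of 413-318-251-182-96 tanh units, a 2-unit softmax
#' output (class 0 = hotspot, 1 = coldspot), Xavier initialization, and
#' full-batch gradient descent whose per-parameter step is Adagrad-scaled
#' with momentum 0.9 at learning rate 0.1 for 1000 iterations, seed 6.
#'
#' @param input_width number of input features (set from the data).
#' @param hidden_widths ordered hidden-layer sizes.
#' @param output_width number of classes (2).
#' @param activation hidden activation: `"tanh"`, `"relu"` or `"sigmoid"`.
#' @param learning_rate step-size factor in `(0, 1]`.
#' @param iterations training epochs over the batch.
#' @param momentum momentum coefficient of the updater.
#' @param seed integer seed for initialization and any batch shuffling.
#' @param updater `"adagrad"` (Adagrad-scaled momentum) or `"sgd-momentum"`.
#' @param l2 L2 penalty on weights.
#' @param dropout hidden-unit dropout probability in `[0, 1)` (training only).
#' @param batch_size minibatch size; `NULL` = full batch.
#' @return a `dnn_config` list.
#' @export
dnn_config <- function(input_width,
                       hidden_widths = c(413, 318, 251, 182, 96),
                       output_width = 2,
                       activation = c("tanh", "relu", "sigmoid"),
                       learning_rate = 0.1, iterations = 1000,
                       momentum = 0.9, seed = 6,
                       updater = c("adagrad", "sgd-momentum"),
                       l2 = 1e-4, dropout = 0, batch_size = NULL) {
  activation <- match.arg(activation)
  updater <- match.arg(updater)
  widths <- c(input_width, hidden_widths, output_width)
  if (any(widths < 1)) stop("layer widths must be positive", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must be in (0, 1]", call. = FALSE)
  if (output_width != 2) stop("`output_width` must be 2", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 output_width = 2L, activation = activation,
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 momentum = momentum, seed = as.integer(seed),
                 updater = updater, l2 = l2, dropout = dropout,
                 batch_size = batch_size),
            class = "dnn_config")
}

.act <- function(z, kind) switch(kind,
  tanh = tanh(z), relu = pmax(z, 0), sigmoid = 1 / (1 + exp(-z)))

.act_grad <- function(a, kind) switch(kind,
  tanh = 1 - a^2, relu = (a > 0) * 1, sigmoid = a * (1 - a))

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Initialize a network with Xavier weights
#'
#' Weights of each layer are drawn from a zero-mean normal with variance
#' `2 / (fan_in + fan_out)`; biases start at exactly 0. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config a [dnn_config()].
#' @return a `trained_dnn` (untrained: empty loss trace).
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "dnn_config"))
  widths <- c(config$input_width, config$hidden_widths, config$output_width)
  .with_seed(config$seed, {
    weights <- lapply(seq_len(length(widths) - 1L), function(l) {
      fi <- widths[l]; fo <- widths[l + 1L]
      matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo)
    })
  })
  biases <- lapply(seq_len(length(widths) - 1L),
                   function(l) numeric(widths[l + 1L]))
  structure(list(weights = weights, biases = biases, config = config,
                 loss_trace = numeric(0)),
            class = "trained_dnn")
}

# Forward pass returning all layer activations (input first, softmax last).
.forward_pass <- function(net, X, masks = NULL) {
  nlay <- length(net$weights)
  A <- vector("list", nlay + 1L)
  A[[1L]] <- X
  for (l in seq_len(nlay)) {
    Z <- sweep(A[[l]] %*% net$weights[[l]], 2, net$biases[[l]], "+")
    if (l < nlay) {
      A[[l + 1L]] <- .act(Z, net$config$activation)
      if (!is.null(masks)) A[[l + 1L]] <- A[[l + 1L]] * masks[[l]]
    } else {
      A[[l + 1L]] <- .softmax(Z)
    }
  }
  A
}

#' Forward pass: class probabilities
#'
#' Hidden layers apply the configured activation; the output layer is
#' softmax, so each row is a probability pair summing to 1
#' (`hotspot`, `coldspot`).
#'
#' @param net a `trained_dnn`.
#' @param X numeric matrix, samples x `input_width`.
#' @return samples x 2 probability matrix.
#' @export
forward <- function(net, X) {
  stopifnot(inherits(net, "trained_dnn"))
  X <- as.matrix(X)
  if (ncol(X) != net$config$input_width)
    stop(sprintf("input width %d does not match network input %d",
                 ncol(X), net$config$input_width), call. = FALSE)
  P <- .forward_pass(net, X)[[length(net$weights) + 1L]]
  colnames(P) <- c("hotspot", "coldspot")
  P
}

# Cross-entropy loss and backprop gradients for one batch (Y one-hot).
.dnn_gradients <- function(net, X, Y, masks = NULL) {
  nlay <- length(net$weights)
  A <- .forward_pass(net, X, masks)
  P <- A[[nlay + 1L]]
  n <- nrow(X)
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-300)))) +
    0.5 * net$config$l2 * sum(vapply(net$weights,
                                     function(w) sum(w^2), numeric(1)))
  gW <- vector("list", nlay)
  gb <- vector("list", nlay)
  delta <- (P - Y) / n
  for (l in rev(seq_len(nlay))) {
    gW[[l]] <- crossprod(A[[l]], delta) + net$config$l2 * net$weights[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$weights[[l]])) *
        .act_grad(A[[l]], net$config$activation)
      if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

.as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (all(y %in% c("hotspot", "coldspot")))
      return(ifelse(y == "hotspot", 0L, 1L))
    if (all(y %in% c("0", "1"))) return(as.integer(y))
    stop("labels must be hotspot/coldspot or 0/1", call. = FALSE)
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  y
}

#' Train the feed-forward classifier
#'
#' Minimizes softmax cross-entropy (plus L2) by backpropagation with the
#' configured updater. Full-batch by default; with a `batch_size` the batch
#' order is reshuffled each epoch under the seed. Deterministic for fixed
#' data, config and seed. `loss_trace` records the full-data loss at each
#' of the `iterations` epochs.
#'
#' @param X numeric matrix, samples x features.
#' @param y labels: 0/1 (0 = hotspot) or `"hotspot"`/`"coldspot"`.
#' @param config a [dnn_config()]; its `input_width` must match `ncol(X)`.
#' @return a `trained_dnn` with `loss_trace` of length `iterations`.
#' @export
train_dnn <- function(X, y, config) {
  stopifnot(inherits(config, "dnn_config"))
  X <- as.matrix(X)
  if (ncol(X) != config$input_width)
    stop("`config$input_width` must equal ncol(X)", call. = FALSE)
  y01 <- .as_binary_labels(y)
  if (length(y01) != nrow(X)) stop("label/row mismatch", call. = FALSE)
  if (min(table(factor(y01, levels = 0:1))) < 2)
    stop("need >= 2 samples per class", call. = FALSE)
  Y <- cbind(y01 == 0L, y01 == 1L) * 1
  net <- init_network(config)
  nlay <- length(net$weights)
  accW <- lapply(net$weights, function(w) w * 0)
  accb <- lapply(net$biases, function(b) b * 0)
  velW <- lapply(net$weights, function(w) w * 0)
  velb <- lapply(net$biases, function(b) b * 0)
  eps <- 1e-8
  n <- nrow(X)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  loss_trace <- numeric(config$iterations)
  .with_seed(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      idx_order <- if (bs < n) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = bs)
      for (s in starts) {
        rows <- idx_order[s:min(s + bs - 1L, n)]
        masks <- if (config$dropout > 0) {
          lapply(net$config$hidden_widths, function(wd)
            matrix(stats::rbinom(length(rows) * wd, 1, 1 - config$dropout) /
                     (1 - config$dropout), length(rows), wd))
        } else NULL
        g <- .dnn_gradients(net, X[rows, , drop = FALSE],
                            Y[rows, , drop = FALSE], masks)
        for (l in seq_len(nlay)) {
          if (config$updater == "adagrad") {
            accW[[l]] <- accW[[l]] + g$gW[[l]]^2
            accb[[l]] <- accb[[l]] + g$gb[[l]]^2
            stepW <- config$learning_rate * g$gW[[l]] / (sqrt(accW[[l]]) + eps)
            stepb <- config$learning_rate * g$gb[[l]] / (sqrt(accb[[l]]) + eps)
          } else {
            stepW <- config$learning_rate * g$gW[[l]]
            stepb <- config$learning_rate * g$gb[[l]]
          }
          velW[[l]] <- config$momentum * velW[[l]] + stepW
          velb[[l]] <- config$momentum * velb[[l]] + stepb
          net$weights[[l]] <- net$weights[[l]] - velW[[l]]
          net$biases[[l]] <- net$biases[[l]] - velb[[l]]
        }
      }
      full <- .dnn_gradients(net, X, Y)
      if (!is.finite(full$loss))
        stop(sprintf("training diverged (non-finite loss at iteration %d)", it),
             call. = FALSE)
      loss_trace[it] <- full$loss
    }
  })
  net$loss_trace <- loss_trace
  net
}

#' @export
print.trained_dnn <- function(x, ...) {
  widths <- c(x$config$input_width, x$config$hidden_widths,
              x$config$output_width)
  cat(sprintf("<trained_dnn> %s, %s hidden activation, %s\n",
              paste(widths, collapse = "-"), x$config$activation,
              if (length(x$loss_trace))
                sprintf("final loss %.4g after %d iterations",
                        x$loss_trace[length(x$loss_trace)],
                        length(x$loss_trace))
              else "untrained"))
  invisible(x)
}

#' Predict class labels
#'
#' Argmax of the softmax probabilities under the 0 = hotspot /
#' 1 = coldspot convention; an exact tie goes to class 0.
#'
#' @param object a `trained_dnn`.
#' @param newdata feature matrix.
#' @param type `"class"` for 0/1 labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return integer labels or probability matrix.
#' @export
predict.trained_dnn <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  P <- forward(object, newdata)
  if (type == "prob") return(P)
  as.integer(P[, 1] < P[, 2])  # tie (equal probs) -> 0 = hotspot
}

#' Cross-validated baseline classifiers
#'
#' Evaluates an RBF-kernel SVM, k-nearest neighbours or random forest with
#' the same stratified-fold protocol and metric definitions as the network,
#' delegating the fits to `e1071::svm`, `class::knn` and
#' `randomForest::randomForest`.
#'
#' @param kind `"svm"`, `"knn"` or `"rf"`.
#' @param params named list: svm `cost`, `gamma`; knn `k`; rf `ntree`,
#'   `mtry`.
#' @param X feature matrix with rownames.
#' @param y labels (0/1 or hotspot/coldspot).
#' @param folds number of CV folds; `NULL` evaluates resubstitution
#'   (train = test).
#' @param seed fold-shuffle seed.
#' @return a `recspot_metrics` object (pooled over held-out folds) with the
#'   pooled `confusion` attached as an attribute.
#' @export
run_baseline <- function(kind = c("svm", "knn", "rf"), params = list(),
                         X, y, folds = 10, seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y01 <- .as_binary_labels(y)
  yf <- factor(y01, levels = c(0, 1))
  fit_predict <- function(tr, te) {
    switch(kind,
      svm = {
        m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(X)))
        as.integer(as.character(stats::predict(m, X[te, , drop = FALSE])))
      },
      knn = as.integer(as.character(
        class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE], yf[tr],
                   k = params$k %||% 5))),
      rf = {
        m <- randomForest::randomForest(
          X[tr, , drop = FALSE], yf[tr],
          ntree = params$ntree %||% 500,
          mtry = params$mtry %||% max(1, floor(sqrt(ncol(X)))))
        as.integer(as.character(stats::predict(m, X[te, , drop = FALSE])))
      })
  }
  if (is.null(folds)) {
    pred <- .with_seed(seed, fit_predict(seq_along(y01), seq_along(y01)))
    return(compute_metrics(confusion(y01, pred)))
  }
  fold_id <- make_folds(y01, folds, seed)
  pred <- integer(length(y01))
  .with_seed(seed, for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    pred[te] <- fit_predict(which(fold_id != f), te)
  })
  compute_metrics(confusion(y01, pred))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
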