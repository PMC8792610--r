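# Minimal dense neural-network machinery: Glorot init, ReLU MLP with
# inverted dropout, softmax cross-entropy, and Adam with decoupled-from-
# nothing L2 weight decay (added to the gradient, as in the common Adam
# implementation). All parameters live in nested lists of plain matrices so
# the same optimiser drives both the fully-connected heads and the
# graph-convolution weights.

glorot <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

#' Initialise a fully-connected network
#' @param widths Integer vector of layer widths, input first, class count
#'   last (e.g. `c(128, 128, 32, 16, 2)`).
#' @param seed Integer seed for Glorot-uniform initialisation.
#' @return List of layers, each `list(W, b)`.
#' @keywords internal
mlp_init <- function(widths, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      list(W = glorot(widths[l], widths[l + 1L]),
           b = matrix(0, 1L, widths[l + 1L]))
    })
  })
}

# Forward pass. Hidden layers: ReLU then (in training) inverted dropout.
# Output layer: linear + row softmax. Returns probabilities plus the caches
# needed for backprop.
mlp_forward <- function(X, layers, dropout = 0, training = FALSE) {
  L <- length(layers)
  cache <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(A), ncol(layers[[l]]$b), byrow = TRUE)
    if (l < L) {
      H <- relu(Z)
      if (training && dropout > 0) {
        mask <- matrix(runif(length(H)) >= dropout, nrow(H), ncol(H)) / (1 - dropout)
        cache[[l]] <- list(A_in = A, Z = Z, mask = mask)
        A <- H * mask
      } else {
        cache[[l]] <- list(A_in = A, Z = Z, mask = NULL)
        A <- H
      }
    } else {
      cache[[l]] <- list(A_in = A, Z = Z, mask = NULL)
      A <- softmax_rows(Z)
    }
  }
  list(probs = A, cache = cache)
}

# Backward pass from softmax cross-entropy. y is 0/1 integer labels.
# Returns list(grads = per-layer list(W, b), dX = gradient wrt input rows).
mlp_backward <- function(fw, layers, y) {
  L <- length(layers)
  B <- nrow(fw$probs)
  dZ <- fw$probs
  dZ[cbind(seq_len(B), y + 1L)] <- dZ[cbind(seq_len(B), y + 1L)] - 1
  dZ <- dZ / B
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A_in <- fw$cache[[l]]$A_in
    grads[[l]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[l]]$W)
    if (l > 1L) {
      mask <- fw$cache[[l - 1L]]$mask
      if (!is.null(mask)) dA <- dA * mask
      dZ <- dA * (fw$cache[[l - 1L]]$Z > 0)
    } else {
      dX <- dA
    }
  }
  list(grads = grads, dX = dX)
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))
}

# --- Adam over an arbitrary nested list of numeric arrays -----------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else list(m = p * 0, v = p * 0)
  }
  list(s = lapply(params, walk), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, s) {
    if (is.list(p) && is.null(s$m)) {
      out <- Map(walk, p, g, s)
      return(list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s")))
    }
    g <- g + weight_decay * p
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  out <- Map(walk, params, grads, state$s)
  list(params = lapply(out, `[[`, "p"),
       state = list(s = lapply(out, `[[`, "s"), t = t))
}

# Shuffled mini-batch index list for one epoch; batch_size NULL = full batch.
epoch_batches <- function(n, batch_size) {
  perm <- sample.int(n)
  if (is.null(batch_size) || batch_size >= n) return(list(perm))
  split(perm, ceiling(seq_along(perm) / batch_size))
}

#' Train a fully-connected softmax classifier
#'
#' The handcrafted-feature baseline head: an MLP whose first hidden layer
#' matches the input width (e.g. 316 -> 316 -> 32 -> 16 -> 2 for fused
#' degree/clustering/closeness features of a 116+200 scale pair), ReLU
#' activations, dropout after each hidden layer, softmax output, trained
#' with Adam on cross-entropy. When a validation set is supplied, the
#' parameters from the epoch with the best validation accuracy are kept
#' (ties resolved toward the later epoch).
#'
#' @param X Numeric feature matrix, one subject per row.
#' @param y Integer labels in `{0, 1}`.
#' @param config A [train_config()].
#' @param X_val,y_val Optional validation set for checkpoint selection.
#' @param widths Optional layer-width override (input first, 2 last).
#' @param standardize Z-score every feature using training-set statistics
#'   (stored in the fit and re-applied at prediction). Network statistics
#'   such as node strength live on arbitrary scales that saturate a softmax
#'   head, so the handcrafted baselines switch this on.
#' @return An `mlp_fit` with `layers`, `best_epoch`, `loss` trace, and
#'   `val_accuracy` trace; use [predict.mlp_fit()] for class probabilities.
#' @export
train_mlp <- function(X, y, config = train_config(), X_val = NULL, y_val = NULL,
                      widths = NULL, standardize = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  center <- NULL
  scl <- NULL
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scl, "/")
    if (!is.null(X_val))
      X_val <- sweep(sweep(as.matrix(X_val), 2L, center), 2L, scl, "/")
  }
  widths <- widths %||% c(ncol(X), ncol(X), 32L, 16L, 2L)
  if (widths[1] != ncol(X)) abort("first layer width must match feature length")
  layers <- mlp_init(widths, substream_seed(config$seed, "mlp-init"))
  opt <- adam_init(layers)
  loss_trace <- numeric(config$epochs)
  val_trace <- rep(NA_real_, config$epochs)
  best <- list(layers = layers, acc = -Inf, epoch = 0L)
  withr::with_seed(substream_seed(config$seed, "mlp-train"), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (idx in epoch_batches(nrow(X), config$batch_size)) {
        fw <- mlp_forward(X[idx, , drop = FALSE], layers,
                          dropout = config$dropout, training = TRUE)
        ep_loss <- ep_loss + cross_entropy(fw$probs, y[idx]) * length(idx)
        bw <- mlp_backward(fw, layers, y[idx])
        if (config$lr > 0) {
          step <- adam_step(layers, bw$grads, opt, lr = config$lr,
                            weight_decay = config$weight_decay)
          layers <- step$params
          opt <- step$state
        }
      }
      loss_trace[ep] <- ep_loss / nrow(X)
      if (!is.finite(loss_trace[ep])) abort("non-finite training loss")
      if (!is.null(X_val)) {
        pv <- mlp_forward(as.matrix(X_val), layers)$probs
        acc <- mean((pv[, 2] > 0.5) == (y_val == 1))
        val_trace[ep] <- acc
        if (acc >= best$acc) best <- list(layers = layers, acc = acc, epoch = ep)
      }
    }
  })
  if (is.null(X_val)) best <- list(layers = layers, acc = NA_real_, epoch = config$epochs)
  structure(
    list(layers = best$layers, widths = widths, best_epoch = best$epoch,
         loss = loss_trace, val_accuracy = val_trace, config = config,
         center = center, scale = scl),
    class = "mlp_fit"
  )
}

#' Predict class probabilities from an `mlp_fit`
#' @param object An `mlp_fit`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns: class 0, class 1); rows
#'   sum to one.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  mlp_forward(X, object$layers)$probs
}

#' Training hyperparameters
#'
#' Defaults follow the shared optimisation recipe used across all model
#' variants: Adam, learning rate 0.01, L2 regularisation 1e-5, 50 epochs,
#' cross-entropy loss.
#'
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param weight_decay L2 regularisation strength.
#' @param dropout Dropout rate for hidden fully-connected layers (0.5 for
#'   the graph-model head, 0.2 for the handcrafted baselines).
#' @param batch_size Mini-batch size (`NULL` = full batch).
#' @param seed Integer seed driving initialisation, batching, and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, lr = 0.01, weight_decay = 1e-5,
                         dropout = 0.5, batch_size = 16L, seed = 1L) {
  if (epochs < 1) abort("epochs must be at least 1")
  if (lr < 0) abort("learning rate must be non-negative")
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  structure(
    list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
         dropout = dropout,
         batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Baseline classifier on handcrafted network features
#'
#' @param features Subjects x features matrix (fused across scales).
#' @param labels Integer labels in `{0, 1}`.
#' @param config A [train_config()] (dropout defaults to 0.2 here).
#' @param ... Passed to [train_mlp()].
#' @return An `mlp_fit`.
#' @export
baseline_classifier <- function(features, labels, config = train_config(dropout = 0.2), ...) {
  train_mlp(features, labels, config = config, standardize = TRUE, ...)
}
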