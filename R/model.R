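# Per-scale two-layer spectral graph convolution with mean-and-max readout,
# ratio-weighted multi-scale fusion, and a fully-connected softmax head.
# The propagation rule is the first-order Chebyshev approximation
#   H^(l+1) = sigma( D~^(-1/2) (A + I) D~^(-1/2) H^(l) W^(l) ),
# so the spectral decomposition itself is never computed.

#' Symmetric self-looped adjacency normalisation
#'
#' Computes `Ahat = D~^(-1/2) (A + I) D~^(-1/2)` with `D~` the degree matrix
#' of the self-looped adjacency. Self-loops guarantee every degree is at
#' least one, so the operation is defined for any symmetric non-negative A;
#' `A = 0` yields the identity.
#'
#' @param A Symmetric non-negative adjacency matrix.
#' @return The normalised matrix (symmetric, non-negative).
#' @export
normalize_adjacency <- function(A) {
  check_symmetric(A, what = "adjacency")
  check_nonnegative(A, what = "adjacency")
  At <- unclass(A)
  diag(At) <- diag(At) + 1
  dis <- 1 / sqrt(rowSums(At))
  At * outer(dis, dis)
}

#' Two-layer graph-convolution forward pass
#'
#' `f(X, A) = ReLU( Ahat ReLU( Ahat X W0 ) W1 )`, one embedding row per
#' node. With `Ahat = I` this reduces to a per-node two-layer MLP.
#'
#' @param X Node-feature matrix (n x p; here the signed connectivity
#'   profile, p = n).
#' @param Ahat Normalised adjacency from [normalize_adjacency()].
#' @param params List with `W0` (p x d1) and `W1` (d1 x d2) weight matrices.
#' @return n x d2 node-embedding matrix.
#' @export
gcn_forward <- function(X, Ahat, params) {
  if (ncol(X) != nrow(params$W0))
    abort(sprintf("layer 1 shape mismatch: %d features vs %d rows of W0",
                  ncol(X), nrow(params$W0)))
  if (ncol(params$W0) != nrow(params$W1))
    abort("layer 2 shape mismatch between W0 and W1")
  relu(Ahat %*% relu((Ahat %*% X) %*% params$W0) %*% params$W1)
}

#' Mean-and-max graph readout
#'
#' Aggregates node embeddings into one graph-level vector: the column means
#' concatenated with the column maxima (in that order), giving a vector of
#' length `2 d` (64 for the default d = 32). Invariant to node ordering.
#'
#' @param H n x d node-embedding matrix.
#' @return Numeric vector of length `2 * ncol(H)`.
#' @export
readout <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) < 1 || ncol(H) < 1) abort("empty embedding matrix")
  c(colMeans(H), apply(H, 2L, max))
}

#' Multi-scale fusion configuration
#'
#' @param alpha Non-negative per-scale fusion weights summing to 1 (`NULL`
#'   = equal). With K scales each readout block is rescaled by `K * alpha_k`
#'   before concatenation, so equal weights leave the blocks unchanged.
#' @param hidden Widths of the three fully-connected head layers (`NULL`
#'   picks the architecture rule: fused width then 32, 16 for multi-scale;
#'   64, 16, 8 for a single scale).
#' @param dropout Dropout after each hidden head layer at training time.
#' @param n_classes Number of output classes.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(alpha = NULL, hidden = NULL, dropout = 0.5,
                          n_classes = 2L) {
  if (!is.null(alpha)) {
    if (any(alpha < 0)) abort("fusion weights must be non-negative")
    if (abs(sum(alpha) - 1) > 1e-8) abort("fusion weights must sum to 1")
  }
  structure(list(alpha = alpha, hidden = hidden, dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "fusion_config")
}

head_widths <- function(fused_len, n_scales, fusion) {
  hidden <- fusion$hidden %||%
    if (n_scales == 1L) c(64L, 16L, 8L) else c(fused_len, 32L, 16L)
  c(fused_len, hidden, fusion$n_classes)
}

fusion_alpha <- function(fusion, n_scales) {
  fusion$alpha %||% rep(1 / n_scales, n_scales)
}

#' Fuse per-scale graph representations and classify
#'
#' Scales each readout vector by `K * alpha_k`, concatenates the blocks in
#' the given scale order, and applies the fully-connected softmax head.
#'
#' @param reps Named list of per-scale readout vectors, in fusion order.
#' @param fusion A [fusion_config()].
#' @param head Head layers as produced by [mlp_init()].
#' @param training Apply dropout (training mode) or not.
#' @return Class-probability vector summing to 1.
#' @export
fuse_and_classify <- function(reps, fusion, head, training = FALSE) {
  K <- length(reps)
  alpha <- fusion_alpha(fusion, K)
  if (length(alpha) != K) abort("one fusion weight per scale is required")
  fused <- unlist(Map(function(f, a) K * a * f, reps, alpha), use.names = FALSE)
  drop(mlp_forward(matrix(fused, 1L), head, dropout = fusion$dropout,
                   training = training)$probs)
}

#' Initialise multi-scale model parameters
#'
#' Glorot-uniform per-scale convolution weights (independent across scales)
#' plus the fully-connected head.
#'
#' @param n_rois Named integer vector of ROI counts per scale, fusion order.
#' @param conv_widths Output channels of the two convolution layers.
#' @param fusion A [fusion_config()].
#' @param seed Integer seed.
#' @return An `mgrl_params` list with `gcn` (per scale `W0`, `W1`) and
#'   `head`.
#' @export
mgrl_init <- function(n_rois, conv_widths = c(32L, 32L),
                      fusion = fusion_config(), seed = 1L) {
  gcn <- withr::with_seed(substream_seed(seed, "gcn-init"), {
    lapply(n_rois, function(n) list(W0 = glorot(n, conv_widths[1]),
                                    W1 = glorot(conv_widths[1], conv_widths[2])))
  })
  fused_len <- 2L * conv_widths[2] * length(n_rois)
  head <- mlp_init(head_widths(fused_len, length(n_rois), fusion),
                   substream_seed(seed, "head-init"))
  structure(list(gcn = gcn, head = head, conv_widths = conv_widths,
                 fusion = fusion, scales = names(n_rois)),
            class = "mgrl_params")
}

#' Full multi-scale forward pass for one subject
#'
#' Composition normalise -> convolve -> readout per scale, then fusion and
#' the softmax head. Deterministic in evaluation mode (dropout off).
#'
#' @param sample A `multiscale_sample` (see [assemble_multiscale()]).
#' @param params An `mgrl_params`.
#' @param training Training mode (dropout on the head).
#' @return Named class-probability vector.
#' @export
mgrl_forward <- function(sample, params, training = FALSE) {
  stopifnot(inherits(sample, "multiscale_sample"))
  missing <- setdiff(params$scales, names(sample$graphs))
  if (length(missing) > 0)
    abort(sprintf("sample lacks scale(s): %s", paste(missing, collapse = ", ")))
  reps <- lapply(params$scales, function(sc) {
    g <- sample$graphs[[sc]]
    readout(gcn_forward(g$X, normalize_adjacency(g$A), params$gcn[[sc]]))
  })
  names(reps) <- params$scales
  p <- fuse_and_classify(reps, params$fusion, params$head, training = training)
  setNames(p, c("class0", "class1"))
}

# --- batched training over a precomputed cohort ---------------------------

# Precompute, once per graphs table, everything that never changes during
# training: the normalised adjacency Ahat and the first propagation
# product M = Ahat X for every subject at every requested scale.
precompute_gcn_inputs <- function(graphs, scales = scale_names(graphs)) {
  data <- lapply(scales, function(sc) {
    Ahat <- lapply(graphs[[sc]], function(g) normalize_adjacency(g$A))
    M <- Map(function(g, Ah) Ah %*% g$X, graphs[[sc]], Ahat)
    list(Ahat = Ahat, M = M, n_roi = nrow(Ahat[[1]]))
  })
  names(data) <- scales
  list(scales = scales, data = data, labels = graphs$label, n = nrow(graphs))
}

# Forward pass over a set of subjects. Returns per-scale caches plus the
# head forward cache; used for both training (with dropout) and scoring.
mgrl_batch_forward <- function(pre, idx, params, training = FALSE) {
  K <- length(pre$scales)
  alpha <- fusion_alpha(params$fusion, K)
  scale_cache <- vector("list", K)
  names(scale_cache) <- pre$scales
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    sc <- pre$scales[k]
    W0 <- params$gcn[[sc]]$W0
    W1 <- params$gcn[[sc]]$W1
    d2 <- ncol(W1)
    sub <- vector("list", length(idx))
    Fmat <- matrix(0, length(idx), 2L * d2)
    for (b in seq_along(idx)) {
      s <- idx[b]
      Z0 <- pre$data[[sc]]$M[[s]] %*% W0
      H1 <- relu(Z0)
      P <- pre$data[[sc]]$Ahat[[s]] %*% H1
      Z1 <- P %*% W1
      H2 <- relu(Z1)
      amax <- max.col(t(H2), ties.method = "first")
      Fmat[b, ] <- c(colMeans(H2), H2[cbind(amax, seq_len(d2))])
      sub[[b]] <- list(Z0 = Z0, P = P, Z1 = Z1, amax = amax, n = nrow(Z0))
    }
    scale_cache[[k]] <- list(sub = sub, Fmat = Fmat)
    blocks[[k]] <- K * alpha[k] * Fmat
  }
  fused <- do.call(cbind, blocks)
  fw <- mlp_forward(fused, params$head, dropout = params$fusion$dropout,
                    training = training)
  list(scale_cache = scale_cache, fused = fused, head_fw = fw, alpha = alpha)
}

# Backward pass matching mgrl_batch_forward; returns gradients with the
# same shape as params[c("gcn", "head")].
mgrl_batch_backward <- function(pre, idx, params, fw, y) {
  K <- length(pre$scales)
  head_bw <- mlp_backward(fw$head_fw, params$head, y)
  d2 <- ncol(params$gcn[[1]]$W1)
  block_w <- 2L * d2
  ggrads <- vector("list", K)
  names(ggrads) <- pre$scales
  for (k in seq_len(K)) {
    sc <- pre$scales[k]
    W1 <- params$gcn[[sc]]$W1
    dF <- fw$dX_override %||% head_bw$dX
    dF <- dF[, (k - 1L) * block_w + seq_len(block_w), drop = FALSE] *
      (K * fw$alpha[k])
    dW0 <- params$gcn[[sc]]$W0 * 0
    dW1 <- W1 * 0
    for (b in seq_along(idx)) {
      s <- idx[b]
      cachb <- fw$scale_cache[[k]]$sub[[b]]
      dmu <- dF[b, seq_len(d2)]
      dmx <- dF[b, d2 + seq_len(d2)]
      dH2 <- matrix(dmu / cachb$n, cachb$n, d2, byrow = TRUE)
      dH2[cbind(cachb$amax, seq_len(d2))] <-
        dH2[cbind(cachb$amax, seq_len(d2))] + dmx
      dZ1 <- dH2 * (cachb$Z1 > 0)
      dW1 <- dW1 + crossprod(cachb$P, dZ1)
      dH1 <- pre$data[[sc]]$Ahat[[s]] %*% (dZ1 %*% t(W1))
      dZ0 <- dH1 * (cachb$Z0 > 0)
      dW0 <- dW0 + crossprod(pre$data[[sc]]$M[[s]], dZ0)
    }
    ggrads[[k]] <- list(W0 = dW0, W1 = dW1)
  }
  list(gcn = ggrads, head = head_bw$grads)
}

#' Train the multi-scale graph model
#'
#' Adam on softmax cross-entropy over the per-scale convolution weights and
#' the fused head, mini-batched with a fresh shuffle each epoch. The
#' parameter snapshot from the epoch with the highest validation accuracy
#' is retained (ties resolved toward the later epoch); without a validation
#' set the final epoch is kept.
#'
#' @param graphs An `fc_graphs` tibble (or a precomputed input list from
#'   the internal precompute step).
#' @param train_idx,val_idx Integer row indices into `graphs`.
#' @param config A [train_config()].
#' @param fusion A [fusion_config()].
#' @param scales Scales to use, in fusion order (default: all; a single
#'   scale gives the single-atlas variant with head widths 64, 16, 8).
#' @return An `mgrl_fit` with `params`, `best_epoch`, `loss` and
#'   `val_accuracy` traces.
#' @export
train_mgrl <- function(graphs, train_idx, val_idx = NULL,
                       config = train_config(), fusion = fusion_config(),
                       scales = NULL) {
  pre <- if (inherits(graphs, "fc_graphs")) {
    precompute_gcn_inputs(graphs, scales %||% scale_names(graphs))
  } else graphs
  y <- pre$labels
  if (length(unique(y[train_idx])) < 2)
    abort("training labels contain a single class")
  n_rois <- vapply(pre$data, `[[`, numeric(1), "n_roi")
  params <- mgrl_init(setNames(as.integer(n_rois), pre$scales),
                      fusion = fusion, seed = substream_seed(config$seed, "mgrl"))
  opt <- adam_init(params[c("gcn", "head")])
  loss_trace <- numeric(config$epochs)
  val_trace <- rep(NA_real_, config$epochs)
  best <- list(params = params, acc = -Inf, epoch = 0L)
  withr::with_seed(substream_seed(config$seed, "mgrl-train"), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (idx in epoch_batches(length(train_idx), config$batch_size)) {
        bidx <- train_idx[idx]
        fw <- mgrl_batch_forward(pre, bidx, params, training = TRUE)
        ep_loss <- ep_loss + cross_entropy(fw$head_fw$probs, y[bidx]) * length(bidx)
        gr <- mgrl_batch_backward(pre, bidx, params, fw, y[bidx])
        if (config$lr > 0) {
          step <- adam_step(params[c("gcn", "head")], gr, opt,
                            lr = config$lr, weight_decay = config$weight_decay)
          params$gcn <- step$params$gcn
          params$head <- step$params$head
          opt <- step$state
        }
      }
      loss_trace[ep] <- ep_loss / length(train_idx)
      if (!is.finite(loss_trace[ep])) abort("non-finite training loss")
      if (!is.null(val_idx) && length(val_idx) > 0) {
        pv <- mgrl_batch_forward(pre, val_idx, params)$head_fw$probs
        acc <- mean((pv[, 2] > 0.5) == (y[val_idx] == 1))
        val_trace[ep] <- acc
        if (acc >= best$acc) best <- list(params = params, acc = acc, epoch = ep)
      }
    }
  })
  if (is.null(val_idx) || length(val_idx) == 0)
    best <- list(params = params, acc = NA_real_, epoch = config$epochs)
  structure(
    list(params = best$params, best_epoch = best$epoch, loss = loss_trace,
         val_accuracy = val_trace, config = config, scales = pre$scales),
    class = "mgrl_fit"
  )
}

#' Predict class probabilities for rows of an `fc_graphs` table
#' @param object An `mgrl_fit`.
#' @param newdata An `fc_graphs` tibble or precomputed input list.
#' @param idx Row indices to score (default: all).
#' @param ... Unused.
#' @return Matrix of class probabilities (columns class 0, class 1).
#' @export
predict.mgrl_fit <- function(object, newdata, idx = NULL, ...) {
  pre <- if (inherits(newdata, "fc_graphs")) {
    precompute_gcn_inputs(newdata, object$scales)
  } else newdata
  idx <- idx %||% seq_len(pre$n)
  mgrl_batch_forward(pre, idx, object$params)$head_fw$probs
}
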