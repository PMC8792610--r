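# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# Pearson edge weights by explicit double loop over ROI pairs.
naive_pearson <- function(ts) {
  n <- ncol(ts)
  C <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      si <- ts[, i] - mean(ts[, i])
      sj <- ts[, j] - mean(ts[, j])
      C[i, j] <- sum(si * sj) / sqrt(sum(si^2) * sum(sj^2))
    }
  }
  C
}

# Onnela weighted clustering by explicit triple loop.
naive_onnela <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  mx <- max(A)
  if (mx == 0) return(rep(0, n))
  W <- (A / mx)^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        s <- s + W[i, j] * W[j, h] * W[h, i]
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# All-pairs shortest-path distances (Floyd-Warshall) with length 1/weight.
naive_distances <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1 / A[A > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# Wasserman-Faust closeness from brute-force distances.
naive_closeness <- function(A) {
  d <- naive_distances(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ])
    ni <- sum(reach)
    if (ni < 2) return(0)
    ((ni - 1) / (n - 1)) * ((ni - 1) / sum(d[i, reach]))
  }, numeric(1))
}

# AUC as the explicit probability of correct ranking over all
# positive-negative pairs, ties counted one half.
naive_auc <- function(prob1, truth) {
  pos <- prob1[truth == 1]
  neg <- prob1[truth == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Proximal-gradient (ISTA) solver for 1/(2t) ||y - X w||^2 + lambda ||w||_1.
ista_lasso <- function(X, y, lambda, iters = 20000L) {
  t_n <- nrow(X)
  L <- max(eigen(crossprod(X) / t_n, symmetric = TRUE, only.values = TRUE)$values)
  w <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    g <- -crossprod(X, y - X %*% w) / t_n
    u <- w - g / L
    w_new <- sign(u) * pmax(abs(u) - lambda / L, 0)
    if (max(abs(w_new - w)) < 1e-12) { w <- as.numeric(w_new); break }
    w <- as.numeric(w_new)
  }
  w
}

# Random symmetric matrix with unit diagonal and distinct off-diagonal
# magnitudes (connectivity-like).
rand_connectivity <- function(n, seed) {
  withr::with_seed(seed, {
    C <- matrix(runif(n * n, -1, 1), n, n)
    C <- (C + t(C)) / 2
    diag(C) <- 1
    C
  })
}

# Random non-negative weighted adjacency (dense => connected).
rand_adjacency <- function(n, seed, density = 1) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n), n, n)
    if (density < 1) A[A > density] <- 0
    A <- (A + t(A)) / 2
    diag(A) <- 0
    A
  })
}

# Small, fast synthetic cohort for unit tests.
tiny_cohort <- function(n_subjects = 20, seed = 1, effect_size = 0.6,
                        fine = 24, coarse = 12, t_n = 50, frac = 0.2) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, n_timepoints = t_n, fine_rois = fine,
    coarse_rois = coarse, effect_edge_fraction = frac,
    effect_size = effect_size, seed = seed
  ))
}
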