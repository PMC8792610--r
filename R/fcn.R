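#' Pearson functional connectivity network
#'
#' Estimates the n x n connectivity matrix whose edge weight between ROIs i
#' and j is the Pearson correlation of their centred time series,
#' e_ij = (s_i - mean)' (s_j - mean) / (||s_i - mean|| ||s_j - mean||).
#'
#' @param ts A t x n numeric matrix, one column per ROI mean time series.
#' @return A symmetric n x n matrix with unit diagonal and entries in
#'   `[-1, 1]`, with attributes `method = "pearson"` and `retain = 1`.
#' @export
pearson_fcn <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) abort("need at least two time points")
  if (any(!is.finite(ts))) abort("time-series matrix contains non-finite values")
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    abort(sprintf("zero-variance ROI column(s): %s",
                  paste(colnames(ts)[bad] %||% bad, collapse = ", ")))
  }
  C <- cor(ts)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- NULL
  structure(C, method = "pearson", retain = 1)
}

#' Sparse-representation functional connectivity network
#'
#' Estimates connectivity by L1-penalised regression: each ROI's
#' (z-scored) series is regressed on all other ROIs' series, minimising
#' `1/(2t) ||s_i - S w||^2 + lambda ||w||_1` with the self-coefficient fixed
#' to zero (cyclic coordinate descent via glmnet). The coefficient matrix W
#' is symmetrised as `(|W| + |W'|) / 2`, so SR edge weights are
#' non-negative. Larger `lambda` gives sparser networks.
#'
#' @param ts A t x n numeric matrix.
#' @param lambda Positive L1 penalty (on the per-timepoint least-squares
#'   scale).
#' @return A symmetric non-negative n x n matrix with zero diagonal and
#'   attributes `method = "sparse_representation"`, `lambda`, `retain = 1`.
#' @export
sparse_representation_fcn <- function(ts, lambda) {
  ts <- as.matrix(ts)
  if (lambda <= 0) abort("lambda must be positive")
  if (nrow(ts) < 3) abort("need at least three time points")
  n <- ncol(ts)
  if (n < 3) abort("need at least three ROIs")
  S <- scale(ts)
  if (any(!is.finite(S))) abort("z-scoring failed: constant or non-finite column")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      glmnet::glmnet(S[, -i, drop = FALSE], S[, i],
                     lambda = lambda, standardize = FALSE, intercept = FALSE,
                     thresh = 1e-10, maxit = 100000L),
      error = function(e)
        abort(sprintf("sparse-representation solver failed for ROI %d: %s",
                      i, conditionMessage(e)))
    )
    W[i, -i] <- as.numeric(fit$beta)
  }
  A <- (abs(W) + abs(t(W))) / 2
  diag(A) <- 0
  structure(A, method = "sparse_representation", lambda = lambda, retain = 1)
}

#' Proportional edge thresholding
#'
#' Keeps the top `ceiling(retain_fraction * m)` upper-triangle edges by
#' absolute weight (m = n(n-1)/2), zeroes the rest, and mirrors to preserve
#' symmetry; the diagonal is untouched. Ties at the retention boundary are
#' broken by (|weight| descending, row index, column index), so the result
#' is deterministic. `retain_fraction = 1` returns the input unchanged.
#'
#' @param C Symmetric connectivity matrix.
#' @param retain_fraction Fraction of edges to retain, in `(0, 1]`.
#' @return The thresholded matrix, with attribute `retain` updated.
#' @export
proportional_threshold <- function(C, retain_fraction) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    abort("retain_fraction must lie in (0, 1]")
  check_symmetric(C, what = "connectivity matrix")
  if (retain_fraction == 1) {
    attr(C, "retain") <- 1
    return(C)
  }
  n <- nrow(C)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  w <- abs(C[ut])
  keep_k <- ceiling(retain_fraction * nrow(ut))
  ord <- order(-w, ut[, 1L], ut[, 2L])
  drop_idx <- ord[-seq_len(keep_k)]
  out <- C
  out[ut[drop_idx, , drop = FALSE]] <- 0
  out[ut[drop_idx, c(2L, 1L), drop = FALSE]] <- 0
  attr(out, "retain") <- retain_fraction
  out
}

#' Build a subject graph from a connectivity matrix
#'
#' Node features keep the signed connectivity profile (row i of X is
#' `(e_i1, ..., e_in)`) while the adjacency takes elementwise absolute
#' values, reading the magnitude of each correlation as connection strength.
#'
#' @param C Symmetric connectivity matrix (possibly thresholded).
#' @param label Class label in `{0, 1}`.
#' @param scale Scale name.
#' @return A `subject_graph` list with elements `X`, `A`, `label`, `scale`.
#' @export
build_graph <- function(C, label, scale = "scale1") {
  check_symmetric(C, what = "connectivity matrix")
  if (any(!is.finite(C))) abort("connectivity matrix contains non-finite values")
  X <- unclass(C)
  attributes(X) <- list(dim = dim(C))
  structure(
    list(X = X, A = abs(X), label = as.integer(label), scale = scale),
    class = "subject_graph"
  )
}

#' Bundle one subject's graphs across scales
#'
#' @param graphs Named list of `subject_graph` objects, one per scale; names
#'   fix the fusion/concatenation order.
#' @param subject Subject identifier.
#' @return A `multiscale_sample` with consistent label across scales.
#' @export
assemble_multiscale <- function(graphs, subject = NA_character_) {
  if (length(graphs) < 1) abort("need at least one scale")
  if (is.null(names(graphs)) || any(names(graphs) == ""))
    abort("graphs must be a named list (names are scale names)")
  labels <- vapply(graphs, `[[`, integer(1), "label")
  if (length(unique(labels)) != 1)
    abort(sprintf("label mismatch across scales for subject %s", subject))
  structure(
    list(subject = subject, label = labels[[1]], graphs = graphs),
    class = "multiscale_sample"
  )
}

#' Build per-subject graphs for a whole cohort
#'
#' Pipeline convenience: estimates one connectivity matrix per subject per
#' scale, optionally sparsifies by proportional thresholding, and assembles
#' signed-feature / absolute-adjacency graphs.
#'
#' @param cohort An `fc_cohort` (or any tibble with `subject`, `label`, and
#'   one time-series list-column per scale).
#' @param method `"pearson"` or `"sparse_representation"`.
#' @param retain_fraction Proportional threshold applied per subject before
#'   graph assembly (1 = dense).
#' @param lambda L1 penalty for the sparse-representation estimator.
#' @return A tibble of class `fc_graphs` with columns `subject`, `label`,
#'   and one `subject_graph` list-column per scale.
#' @export
cohort_graphs <- function(cohort, method = c("pearson", "sparse_representation"),
                          retain_fraction = 1, lambda = 0.1) {
  method <- match.arg(method)
  scales <- scale_names(cohort)
  out <- tibble(subject = cohort$subject, label = cohort$label)
  for (sc in scales) {
    out[[sc]] <- purrr::map2(cohort[[sc]], cohort$label, function(ts, lab) {
      C <- switch(method,
        pearson = pearson_fcn(ts),
        sparse_representation = sparse_representation_fcn(ts, lambda)
      )
      C <- proportional_threshold(C, retain_fraction)
      build_graph(C, lab, sc)
    })
  }
  structure(
    out,
    class = c("fc_graphs", class(out)),
    scales = attr(cohort, "scales"),
    method = method,
    retain = retain_fraction
  )
}

#' Extract one subject's multi-scale sample from an `fc_graphs` table
#' @param graphs An `fc_graphs` tibble.
#' @param i Row index.
#' @return A `multiscale_sample`.
#' @export
multiscale_sample <- function(graphs, i) {
  scales <- scale_names(graphs)
  assemble_multiscale(
    setNames(lapply(scales, function(sc) graphs[[sc]][[i]]), scales),
    subject = graphs$subject[i]
  )
}
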