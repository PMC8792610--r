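prep_adjacency <- function(A, what = "adjacency") {
  check_symmetric(A, what = what)
  check_nonnegative(A, what = what)
  A <- unclass(A)
  diag(A) <- 0
  A
}

#' Weighted degree centrality (node strength)
#'
#' @param A Symmetric non-negative adjacency matrix (diagonal ignored).
#' @return Length-n vector of node strengths, attribute `stat = "DC"`.
#' @export
degree_centrality <- function(A) {
  A <- prep_adjacency(A)
  structure(rowSums(A), stat = "DC")
}

#' Weighted local clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity: with weights rescaled by the maximum,
#' `c_i = sum_{j,k} (a_ij a_jk a_ki)^{1/3} / (k_i (k_i - 1))` where `k_i`
#' counts non-zero neighbours; `c_i = 0` when `k_i < 2`. Values lie in
#' `[0, 1]`.
#'
#' @inheritParams degree_centrality
#' @return Length-n vector, attribute `stat = "LCC"`.
#' @export
local_clustering <- function(A) {
  A <- prep_adjacency(A)
  mx <- max(A)
  if (mx == 0) return(structure(rep(0, nrow(A)), stat = "LCC"))
  W <- (A / mx)^(1 / 3)
  num <- diag(W %*% W %*% W)
  k <- rowSums(A > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  structure(as.numeric(cc), stat = "LCC")
}

#' Weighted closeness centrality
#'
#' Edge lengths are reciprocal weights (stronger connection = shorter
#' path); distances are shortest paths. For a node whose component has
#' `n_i` nodes, closeness is the Wasserman-Faust component-scaled form
#' `((n_i - 1) / (n - 1)) * ((n_i - 1) / sum of distances)`; isolated nodes
#' get 0, so aggressive thresholding never produces infinities.
#'
#' @inheritParams degree_centrality
#' @return Length-n vector, attribute `stat = "CC"`.
#' @export
closeness_centrality <- function(A) {
  A <- prep_adjacency(A)
  n <- nrow(A)
  if (n == 1) return(structure(0, stat = "CC"))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  } else {
    matrix(Inf, n, n)
  }
  diag(d) <- 0
  vals <- vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ])
    ni <- sum(reach)
    if (ni < 2) return(0)
    ((ni - 1) / (n - 1)) * ((ni - 1) / sum(d[i, reach]))
  }, numeric(1))
  structure(vals, stat = "CC")
}

#' Concatenate per-scale node-statistic vectors
#'
#' @param stats List of statistic vectors (as returned by the centrality
#'   functions), one per scale, in the configured scale order; all must
#'   share the same statistic tag.
#' @return Single fused numeric vector (e.g. 116 + 200 = 316 entries for an
#'   AAL-plus-CC200 style pair of scales).
#' @export
fuse_handcrafted <- function(stats) {
  if (length(stats) < 1) abort("need at least one statistic vector")
  tags <- vapply(stats, function(s) attr(s, "stat") %||% NA_character_, character(1))
  if (length(unique(tags)) != 1 || anyNA(tags))
    abort("all fused vectors must carry the same statistic tag")
  structure(unlist(lapply(stats, as.numeric), use.names = FALSE), stat = tags[[1]])
}

#' Handcrafted feature table for a cohort
#'
#' Computes one network statistic per node on every subject's adjacency at
#' every scale and concatenates across scales in fusion order.
#'
#' @param graphs An `fc_graphs` tibble.
#' @param stat `"dc"`, `"lcc"`, or `"cc"`.
#' @return List with `features` (subjects x fused-length matrix) and
#'   `labels`.
#' @export
handcrafted_features <- function(graphs, stat = c("dc", "lcc", "cc")) {
  stat <- match.arg(stat)
  fn <- switch(stat, dc = degree_centrality, lcc = local_clustering,
               cc = closeness_centrality)
  scales <- scale_names(graphs)
  feats <- t(vapply(seq_len(nrow(graphs)), function(i) {
    fuse_handcrafted(lapply(scales, function(sc) fn(graphs[[sc]][[i]]$A)))
  }, numeric(sum(attr(graphs, "scales")$n_roi))))
  list(features = feats, labels = graphs$label)
}
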