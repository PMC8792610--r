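#' Repeated random train/validation/test splits
#'
#' Draws `reps` independent shuffled partitions with sizes
#' `floor(0.8 n)` / `floor(0.1 n)` / remainder by default. Splits are
#' unstratified; a repetition whose train, validation, or test set lacks one
#' of the two classes is redrawn (the redraw count is recorded in the
#' `redraws` attribute). Deterministic given `seed`, and intended to be
#' computed once and shared verbatim by every method under comparison.
#'
#' @param labels Integer vector of subject labels in `{0, 1}`.
#' @param reps Number of repetitions (default 100).
#' @param fractions Train/validation/test fractions.
#' @param seed Integer seed.
#' @return List of `reps` lists with integer `train`, `val`, `test`.
#' @export
make_splits <- function(labels, reps = 100L, fractions = c(0.8, 0.1, 0.1),
                        seed = 1L) {
  n <- length(labels)
  if (n < 10) abort("need at least 10 subjects to split")
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  if (n_train < 2 || n - n_train - n_val < 1)
    abort("fractions leave an empty partition")
  redraws <- 0L
  splits <- withr::with_seed(substream_seed(seed, "splits"), {
    lapply(seq_len(reps), function(r) {
      repeat {
        perm <- sample.int(n)
        s <- list(train = sort(perm[seq_len(n_train)]),
                  val = sort(perm[n_train + seq_len(n_val)]),
                  test = sort(perm[(n_train + n_val + 1L):n]))
        ok <- all(vapply(s, function(i)
          length(i) == 0 || length(unique(labels[i])) == 2L, logical(1)))
        if (ok) return(s)
        redraws <<- redraws + 1L
        if (redraws > 1000L)
          abort(paste("could not draw splits with both classes in every",
                      "partition; labels too imbalanced or partitions too small"))
      }
    })
  })
  structure(splits, redraws = redraws, fractions = fractions, seed = seed)
}

# Midrank AUC: probability that a random positive outranks a random
# negative by predicted class-1 probability, ties counted half.
auc_rank <- function(prob1, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob1, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC polyline from predicted probabilities (thresholds descending).
roc_points <- function(prob1, truth) {
  ord <- order(prob1, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1)
  fp <- cumsum(truth[ord] == 0)
  keep <- c(diff(prob1[ord]) != 0, TRUE)
  tibble(
    fpr = c(0, fp[keep] / max(sum(truth == 0), 1)),
    tpr = c(0, tp[keep] / max(sum(truth == 1), 1))
  )
}

#' Classification metrics for one test set
#'
#' Confusion-count metrics with the case class (label 1) as positive:
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 the harmonic mean of precision and recall, and midrank AUC over the
#' predicted class-1 probability. Predicted class is `prob1 > 0.5`. AUC is
#' `NA` for a single-class test set; precision and F1 are `NA` when no
#' positive predictions exist.
#'
#' @param truth Integer labels in `{0, 1}`.
#' @param prob1 Predicted probability of class 1.
#' @return One-row tibble with counts, the five metrics, and an `roc`
#'   list-column of (FPR, TPR) points.
#' @export
classification_metrics <- function(truth, prob1) {
  if (length(truth) == 0) abort("empty test set")
  pred <- as.integer(prob1 > 0.5)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth),
    recall = recall, precision = precision, f1 = f1,
    auc = auc_rank(prob1, truth),
    roc = list(roc_points(prob1, truth))
  )
}

protocol_methods <- function(graphs) {
  c("mgrl", paste0("gcn_", scale_names(graphs)), "dcf", "lccf", "ccf")
}

fit_one_method <- function(method, pre_all, pre_scale, feats, labels, split,
                           config, fusion) {
  cfg <- config
  if (startsWith(method, "gcn_") || method == "mgrl") {
    pre <- if (method == "mgrl") pre_all else pre_scale[[sub("^gcn_", "", method)]]
    fus <- if (method == "mgrl") fusion else fusion_config(dropout = fusion$dropout)
    fit <- train_mgrl(pre, split$train, split$val, config = cfg, fusion = fus)
    prob <- predict(fit, pre, idx = split$test)[, 2]
  } else {
    stat <- c(dcf = "dc", lccf = "lcc", ccf = "cc")[[method]]
    X <- feats[[stat]]
    cfg$dropout <- 0.2
    fit <- train_mlp(X[split$train, , drop = FALSE], labels[split$train],
                     config = cfg, standardize = TRUE,
                     X_val = X[split$val, , drop = FALSE], y_val = labels[split$val])
    prob <- predict(fit, X[split$test, , drop = FALSE])[, 2]
  }
  classification_metrics(labels[split$test], prob)
}

#' Run the repeated-split comparison protocol
#'
#' Evaluates one or more methods over identical repeated random splits:
#' the multi-scale graph model (`"mgrl"`), its single-scale variants
#' (`"gcn_<scale>"`), and the handcrafted baselines (`"dcf"`, `"lccf"`,
#' `"ccf"`: fused degree, local-clustering, and closeness features into a
#' fully-connected head). Every method consumes the same split index sets;
#' per-repetition training seeds are derived from the protocol seed and the
#' repetition id only, so they are also shared across methods.
#'
#' @param graphs An `fc_graphs` tibble.
#' @param methods Character vector of method names (default: all six for a
#'   two-scale table).
#' @param splits Splits from [make_splits()] (computed from `seed` if
#'   omitted).
#' @param reps Repetitions when `splits` is omitted.
#' @param config A [train_config()]; its `seed` is re-derived per
#'   repetition.
#' @param fusion A [fusion_config()] for the multi-scale model.
#' @param seed Root seed for splits and per-repetition training.
#' @return An `mgrl_protocol` object: tibble of per-repetition metrics with
#'   columns `method`, `rep`, the five metrics, confusion counts, and an
#'   `roc` list-column. Use [glance()] for mean +/- SD summaries.
#' @export
run_protocol <- function(graphs, methods = NULL, splits = NULL, reps = 100L,
                         config = train_config(), fusion = fusion_config(),
                         seed = 1L) {
  methods <- methods %||% protocol_methods(graphs)
  bad <- setdiff(methods, protocol_methods(graphs))
  if (length(bad) > 0)
    abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  splits <- splits %||% make_splits(graphs$label, reps = reps, seed = seed)
  labels <- graphs$label

  need_gcn <- any(methods == "mgrl" | startsWith(methods, "gcn_"))
  pre_all <- if (need_gcn) precompute_gcn_inputs(graphs) else NULL
  pre_scale <- list()
  for (m in methods[startsWith(methods, "gcn_")]) {
    sc <- sub("^gcn_", "", m)
    pre_scale[[sc]] <- list(scales = sc, data = pre_all$data[sc],
                            labels = pre_all$labels, n = pre_all$n)
  }
  feats <- list()
  for (stat in unique(c(dcf = "dc", lccf = "lcc", ccf = "cc")[intersect(
    methods, c("dcf", "lccf", "ccf"))])) {
    feats[[stat]] <- handcrafted_features(graphs, stat)$features
  }

  rows <- purrr::map_dfr(seq_along(splits), function(r) {
    cfg <- config
    cfg$seed <- substream_seed(seed, paste0("rep", r))
    purrr::map_dfr(methods, function(m) {
      dplyr::bind_cols(
        tibble(method = m, rep = r),
        fit_one_method(m, pre_all, pre_scale, feats, labels, splits[[r]],
                       cfg, fusion)
      )
    })
  })
  structure(rows, class = c("mgrl_protocol", class(rows)),
            splits = splits, config = config, fusion = fusion, seed = seed)
}

#' Edge-retention (sparsity) sweep
#'
#' Rebuilds per-subject graphs at each proportional-threshold retention
#' level and re-runs the protocol, reusing one set of splits throughout.
#' Performance need not be monotone in retention.
#'
#' @param cohort An `fc_cohort`.
#' @param retain Retention fractions (default `c(1, 0.9, 0.8, 0.7, 0.6)`).
#' @param methods,reps,config,fusion,seed As in [run_protocol()].
#' @param method Connectivity estimator passed to [cohort_graphs()].
#' @return Tibble of per-repetition metrics with a `retain` column, class
#'   `mgrl_sweep`.
#' @export
sparsity_sweep <- function(cohort, retain = c(1, 0.9, 0.8, 0.7, 0.6),
                           methods = "mgrl", reps = 20L,
                           config = train_config(), fusion = fusion_config(),
                           method = "pearson", seed = 1L) {
  splits <- make_splits(cohort$label, reps = reps, seed = seed)
  rows <- purrr::map_dfr(retain, function(rf) {
    g <- cohort_graphs(cohort, method = method, retain_fraction = rf)
    res <- run_protocol(g, methods = methods, splits = splits,
                        config = config, fusion = fusion, seed = seed)
    dplyr::bind_cols(tibble(retain = rf), as_tibble(res))
  })
  structure(rows, class = c("mgrl_sweep", class(rows)), sweep = "retain")
}

#' Fusion-ratio sweep
#'
#' Re-runs the two-scale protocol with fusion weights `(alpha, 1 - alpha)`
#' over a grid of ratios (first scale in fusion order gets `alpha`),
#' reusing one set of splits.
#'
#' @param graphs A two-scale `fc_graphs` tibble.
#' @param ratios Weights for the first scale (default `0.1 ... 0.9`).
#' @param reps,config,seed As in [run_protocol()].
#' @return Tibble of per-repetition metrics with an `alpha` column, class
#'   `mgrl_sweep`.
#' @export
fusion_ratio_sweep <- function(graphs, ratios = seq(0.1, 0.9, by = 0.1),
                               reps = 20L, config = train_config(), seed = 1L) {
  if (length(scale_names(graphs)) != 2L)
    abort("the fusion-ratio sweep needs exactly two scales")
  splits <- make_splits(graphs$label, reps = reps, seed = seed)
  rows <- purrr::map_dfr(ratios, function(a) {
    res <- run_protocol(graphs, methods = "mgrl", splits = splits,
                        config = config,
                        fusion = fusion_config(alpha = c(a, 1 - a)), seed = seed)
    dplyr::bind_cols(tibble(alpha = a), as_tibble(res))
  })
  structure(rows, class = c("mgrl_sweep", class(rows)), sweep = "alpha")
}
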