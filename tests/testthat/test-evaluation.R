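test_that("split sizes follow the floor/floor/remainder rule", {
  labels <- rep(c(0L, 1L), length.out = 184)
  sp <- make_splits(labels, reps = 5, seed = 1)
  for (s in sp) {
    expect_length(s$train, 147)
    expect_length(s$val, 18)
    expect_length(s$test, 19)
    all_idx <- c(s$train, s$val, s$test)
    expect_equal(sort(all_idx), 1:184)        # union and disjointness
    expect_equal(anyDuplicated(all_idx), 0)
    for (part in s) expect_equal(length(unique(labels[part])), 2)
  }
  expect_identical(make_splits(labels, reps = 5, seed = 1), sp)
  expect_false(identical(make_splits(labels, reps = 5, seed = 2), sp))
})

test_that("metrics match the confusion-count formulas", {
  truth <- rep(c(1L, 0L), each = 10)
  perfect <- classification_metrics(truth, c(rep(0.9, 10), rep(0.1, 10)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  # TP=8, FN=2, FP=3, TN=7
  truth <- c(rep(1L, 10), rep(0L, 10))
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7))
  m <- classification_metrics(truth, prob)
  expect_equal(m[, c("tp", "fn", "fp", "tn")],
               tibble::tibble(tp = 8L, fn = 2L, fp = 3L, tn = 7L))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$f1, 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8))

  tied <- classification_metrics(truth, rep(0.5, 20))
  expect_equal(tied$auc, 0.5)
})

test_that("rank-based AUC agrees with the all-pairs oracle and pROC", {
  for (k in 1:20) {
    withr::with_seed(500 + k, {
      n <- sample(8:20, 1)
      truth <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
      prob <- round(runif(n), 2)   # rounding forces ties
    })
    m <- classification_metrics(truth, prob)
    expect_equal(m$auc, naive_auc(prob, truth), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                                  direction = "<")))
      expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
    }
  }
})

test_that("single-class test sets yield missing AUC excluded from summaries", {
  m <- classification_metrics(rep(1L, 5), runif(5))
  expect_true(is.na(m$auc))
  x <- structure(
    dplyr::bind_rows(
      dplyr::mutate(classification_metrics(c(1L, 0L), c(0.8, 0.2)), method = "m", rep = 1L),
      dplyr::mutate(classification_metrics(rep(1L, 2), c(0.8, 0.9)), method = "m", rep = 2L)
    ),
    class = c("mgrl_protocol", class(tibble::tibble()))
  )
  g <- glance(x)
  expect_equal(g$n_missing_auc, 1L)
  expect_equal(g$auc_mean, 1)
})

test_that("the comparison protocol shares splits and keeps metric identities", {
  co <- tiny_cohort(n_subjects = 24, seed = 31, fine = 12, coarse = 6, t_n = 30)
  g <- cohort_graphs(co)
  sp <- make_splits(co$label, reps = 3, seed = 5)
  res <- run_protocol(g, splits = sp, config = train_config(epochs = 3, seed = 2))
  expect_identical(attr(res, "splits"), sp)
  td <- tidy(res)
  expect_setequal(unique(td$method),
                  c("mgrl", "gcn_coarse", "gcn_fine", "dcf", "lccf", "ccf"))
  expect_equal(nrow(td), 6 * 3)
  n_test <- length(sp[[1]]$test)
  for (r in seq_len(nrow(td))) {
    row <- td[r, ]
    expect_equal(row$tp + row$tn + row$fp + row$fn, n_test)
    expect_equal(row$accuracy, (row$tp + row$tn) / n_test)
    if (!is.na(row$f1)) {
      expect_equal(row$f1,
                   2 * row$precision * row$recall / (row$precision + row$recall))
    }
  }
  # rerunning with the same seed reproduces every number bit-identically
  res2 <- run_protocol(g, splits = sp, config = train_config(epochs = 3, seed = 2))
  expect_identical(tidy(res), tidy(res2))
})

test_that("a single repetition reports zero spread", {
  co <- tiny_cohort(n_subjects = 20, seed = 37, fine = 10, coarse = 5, t_n = 25)
  g <- cohort_graphs(co)
  res <- run_protocol(g, methods = "dcf", reps = 1,
                      config = train_config(epochs = 2, seed = 1), seed = 3)
  gl <- glance(res)
  expect_equal(gl$n_reps, 1L)
  expect_equal(gl$accuracy_sd, 0)
})

test_that("the retention sweep reproduces the dense run at 100%", {
  co <- tiny_cohort(n_subjects = 20, seed = 41, fine = 10, coarse = 5, t_n = 25)
  cfg <- train_config(epochs = 3, seed = 4)
  sw <- sparsity_sweep(co, retain = c(1, 0.8), methods = "mgrl", reps = 2,
                       config = cfg, seed = 6)
  expect_setequal(unique(sw$retain), c(1, 0.8))
  expect_true(all(c("accuracy", "recall", "precision", "f1", "auc") %in% names(sw)))
  base <- run_protocol(cohort_graphs(co), methods = "mgrl",
                       splits = make_splits(co$label, reps = 2, seed = 6),
                       config = cfg, seed = 6)
  expect_equal(dplyr::filter(tidy(sw), retain == 1)$accuracy, tidy(base)$accuracy)
})

test_that("the fusion-ratio sweep matches the equal-weight run at one half", {
  co <- tiny_cohort(n_subjects = 20, seed = 43, fine = 10, coarse = 5, t_n = 25)
  g <- cohort_graphs(co)
  cfg <- train_config(epochs = 3, seed = 4)
  sw <- fusion_ratio_sweep(g, ratios = c(0.3, 0.5), reps = 2, config = cfg, seed = 8)
  expect_setequal(unique(sw$alpha), c(0.3, 0.5))
  base <- run_protocol(g, methods = "mgrl",
                       splits = make_splits(co$label, reps = 2, seed = 8),
                       config = cfg, fusion = fusion_config(alpha = c(0.5, 0.5)),
                       seed = 8)
  expect_equal(dplyr::filter(tidy(sw), alpha == 0.5)$accuracy, tidy(base)$accuracy)
  full <- fusion_ratio_sweep(g, ratios = seq(0.1, 0.9, 0.1), reps = 1,
                             config = train_config(epochs = 1, seed = 1), seed = 2)
  expect_equal(length(unique(full$alpha)), 9)
})

test_that("tidiers and plots expose the protocol results", {
  co <- tiny_cohort(n_subjects = 20, seed = 47, fine = 10, coarse = 5, t_n = 25)
  g <- cohort_graphs(co)
  res <- run_protocol(g, methods = c("mgrl", "dcf"), reps = 2,
                      config = train_config(epochs = 2, seed = 1), seed = 3)
  gl <- glance(res)
  expect_equal(nrow(gl), 2)
  expect_true(all(gl$accuracy_mean >= 0 & gl$accuracy_mean <= 1))
  p1 <- ggplot2::autoplot(res)
  expect_s3_class(p1, "ggplot")
  sw <- sparsity_sweep(co, retain = c(1, 0.6), methods = "mgrl", reps = 2,
                       config = train_config(epochs = 2, seed = 1), seed = 3)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})
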