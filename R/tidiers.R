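#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-repetition metrics of a protocol run
#' @param x An `mgrl_protocol`.
#' @param ... Unused.
#' @return Tibble with one row per method x repetition (ROC points
#'   dropped).
#' @export
tidy.mgrl_protocol <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("roc"))
}

#' Mean +/- SD metric summary of a protocol run
#'
#' Averages the five metrics over repetitions per method; repetitions with
#' an undefined metric (single-class test set for AUC, no positive
#' predictions for precision/F1) are excluded from that metric's mean and
#' counted in `n_missing_auc`. A single repetition reports SD 0.
#'
#' @param x An `mgrl_protocol` (or `mgrl_sweep`).
#' @param ... Unused.
#' @return Tibble with one row per method (and sweep key if present).
#' @export
glance.mgrl_protocol <- function(x, ...) {
  keys <- intersect(c("retain", "alpha", "method"), names(x))
  sd0 <- function(v) if (sum(!is.na(v)) <= 1) 0 else sd(v, na.rm = TRUE)
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), dplyr::across(dplyr::all_of(keys))),
    dplyr::across(dplyr::all_of(c("accuracy", "recall", "precision", "f1", "auc")),
                  list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd0(.x))),
    n_reps = dplyr::n(),
    n_missing_auc = sum(is.na(.data$auc)),
    .groups = "drop"
  )
}

#' @export
glance.mgrl_sweep <- glance.mgrl_protocol

#' @export
tidy.mgrl_sweep <- tidy.mgrl_protocol

#' Loss and validation traces of a model fit
#' @param x An `mgrl_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_accuracy`.
#' @export
tidy.mgrl_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), loss = x$loss, val_accuracy = x$val_accuracy)
}

#' @export
tidy.mlp_fit <- tidy.mgrl_fit

#' @export
glance.mgrl_fit <- function(x, ...) {
  tibble(best_epoch = x$best_epoch, final_loss = x$loss[length(x$loss)],
         best_val_accuracy = if (all(is.na(x$val_accuracy))) NA_real_
                             else max(x$val_accuracy, na.rm = TRUE))
}

#' @export
glance.mlp_fit <- glance.mgrl_fit

#' @export
print.mgrl_fit <- function(x, ...) {
  cat(sprintf("<mgrl_fit> scales: %s | best epoch %d | final loss %.4f\n",
              paste(x$scales, collapse = "+"), x$best_epoch,
              x$loss[length(x$loss)]))
  invisible(x)
}

#' ROC curves from a protocol run
#'
#' Pools each method's per-repetition test predictions into one ROC
#' polyline per method.
#'
#' @param object An `mgrl_protocol`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgrl_protocol <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::select(as_tibble(object), "method", "rep", "roc"), "roc"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$method,
                                   group = interaction(.data$method, .data$rep))) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Sweep summary plot
#'
#' Mean accuracy (with +/- 1 SD ribbon) against the swept quantity: edge
#' retention for a sparsity sweep, first-scale fusion weight for a ratio
#' sweep.
#'
#' @param object An `mgrl_sweep`.
#' @param metric Metric to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgrl_sweep <- function(object, metric = "accuracy", ...) {
  key <- attr(object, "sweep")
  g <- glance.mgrl_protocol(object)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(g, ggplot2::aes(x = .data[[key]], y = .data[[mcol]],
                                  colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                      ymax = .data[[mcol]] + .data[[scol]],
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (key == "retain") "Edge retention fraction"
                      else "Fusion weight of first scale",
                  y = paste("Mean", metric)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
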