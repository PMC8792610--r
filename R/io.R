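#' Read a ROI time-series matrix from delimited text
#'
#' Expects a rectangular numeric table, rows = time points, columns = ROIs,
#' with a header row.
#'
#' @param path File path (tab- or whitespace-delimited).
#' @return Numeric t x n matrix.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE),
    error = function(e) abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0 || ncol(df) == 0) abort(sprintf("empty matrix file: %s", path))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0)
    abort(sprintf("non-numeric column(s) %s in %s", paste(bad, collapse = ", "), path))
  m <- as.matrix(df)
  if (any(!is.finite(m))) abort(sprintf("non-finite entries in %s", path))
  if (nrow(m) < 2) abort(sprintf("need at least 2 time points in %s", path))
  m
}

#' Read a subject-label table
#'
#' Two tab-separated columns `subject` and `label` (0/1) with a header.
#'
#' @param path File path.
#' @return Tibble with `subject` (character) and `label` (integer).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  if (!identical(names(df), c("subject", "label")))
    abort("labels table must have columns: subject, label")
  if (anyDuplicated(df$subject)) {
    dup <- df$subject[duplicated(df$subject)][1]
    abort(sprintf("duplicate subject id in labels: %s (line %d)",
                  dup, which(df$subject == dup)[2] + 1L))
  }
  if (!all(df$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  as_tibble(df)
}

#' Write a connectivity matrix as delimited text
#' @param C Square matrix.
#' @param path Output path.
#' @export
write_connectivity <- function(C, path) {
  m <- as.matrix(C)
  colnames(m) <- paste0("ROI", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a protocol metrics table
#'
#' Emits one row per method x repetition as TSV (machine-readable raw
#' table; the `roc` list-column is dropped).
#'
#' @param report An `mgrl_protocol` or `mgrl_sweep` tibble.
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  df <- as.data.frame(dplyr::select(as_tibble(report), -dplyr::any_of("roc")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_defaults <- list(
  method = "mgrl",
  fcn = list(method = "pearson", lambda = 0.1, retain_fraction = 1.0),
  model = list(conv_widths = c(32L, 32L), dropout = 0.5, alpha = NULL),
  train = list(epochs = 50L, lr = 0.01, weight_decay = 1e-5, batch_size = 16L),
  eval = list(reps = 100L, fractions = c(0.8, 0.1, 0.1)),
  seed = 1L
)

#' Load a run configuration from YAML
#'
#' Unknown keys are an error; missing keys fall back to the package
#' defaults (learning rate 0.01, weight decay 1e-5, 50 epochs, dropout 0.5,
#' 100 repetitions of an 80/10/10 split). Range violations are collected
#' and reported in a single message.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path) %||% list()
  merge_section <- function(def, got, prefix) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown) > 0)
      abort(sprintf("unknown config key(s): %s",
                    paste0(prefix, unknown, collapse = ", ")))
    utils::modifyList(def, got)
  }
  unknown <- setdiff(names(raw), names(config_defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- config_defaults
  for (k in names(raw)) {
    cfg[[k]] <- if (is.list(config_defaults[[k]])) {
      merge_section(config_defaults[[k]], raw[[k]], paste0(k, "."))
    } else raw[[k]]
  }
  if (!"alpha" %in% names(cfg$model)) cfg$model["alpha"] <- list(NULL)
  problems <- character(0)
  if (cfg$fcn$retain_fraction <= 0 || cfg$fcn$retain_fraction > 1)
    problems <- c(problems, "fcn.retain_fraction must lie in (0, 1]")
  if (cfg$fcn$lambda <= 0) problems <- c(problems, "fcn.lambda must be positive")
  if (cfg$train$lr < 0) problems <- c(problems, "train.lr must be non-negative")
  if (cfg$train$epochs < 1) problems <- c(problems, "train.epochs must be >= 1")
  if (cfg$model$dropout < 0 || cfg$model$dropout >= 1)
    problems <- c(problems, "model.dropout must lie in [0, 1)")
  if (!is.null(cfg$model$alpha) && abs(sum(cfg$model$alpha) - 1) > 1e-8)
    problems <- c(problems, "model.alpha must sum to 1")
  if (cfg$eval$reps < 1) problems <- c(problems, "eval.reps must be >= 1")
  if (length(problems) > 0)
    abort(paste0("invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
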