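#' Specify a synthetic multi-scale cohort
#'
#' Defines the generating conditions for a synthetic rs-fMRI-like cohort:
#' per-subject ROI time series at a fine and a coarse parcellation scale,
#' with a class-dependent perturbation planted on a subset of inter-ROI
#' covariances at the fine scale. The coarse scale is derived from the fine
#' one by averaging disjoint contiguous blocks of fine ROIs, so the two
#' scales view the same underlying activity (the redundancy-plus-
#' complementarity structure that multi-atlas fusion relies on).
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_timepoints Time points per series (default 175, the length of a
#'   typical preprocessed resting-state scan).
#' @param fine_rois Number of fine-scale ROIs (default 200).
#' @param coarse_rois Number of coarse-scale ROIs (default 116); must not
#'   exceed `fine_rois`.
#' @param effect_edge_fraction Fraction of fine-scale off-diagonal covariance
#'   entries perturbed in the case class, in `[0, 1]`.
#' @param effect_size Magnitude of the covariance perturbation added (with
#'   random sign) to each affected entry.
#' @param noise_sd Standard deviation of i.i.d. observation noise added to
#'   every fine-scale series.
#' @param class_balance Fraction of subjects assigned the positive class
#'   (label 1), in `(0, 1)`.
#' @param seed Integer root seed; every random stage draws from a named
#'   substream derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects,
                        n_timepoints = 175L,
                        fine_rois = 200L,
                        coarse_rois = 116L,
                        effect_edge_fraction = 0.1,
                        effect_size = 0.6,
                        noise_sd = 0.5,
                        class_balance = 0.5,
                        seed = 1L) {
  if (n_subjects < 2) abort("n_subjects must be at least 2")
  if (n_timepoints < 2) abort("n_timepoints must be at least 2")
  if (coarse_rois > fine_rois) abort("coarse_rois must not exceed fine_rois")
  if (coarse_rois < 1) abort("coarse_rois must be positive")
  if (effect_edge_fraction < 0 || effect_edge_fraction > 1)
    abort("effect_edge_fraction must lie in [0, 1]")
  if (effect_size < 0) abort("effect_size must be non-negative")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (class_balance <= 0 || class_balance >= 1)
    abort("class_balance must lie strictly in (0, 1)")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_timepoints = as.integer(n_timepoints),
      fine_rois = as.integer(fine_rois),
      coarse_rois = as.integer(coarse_rois),
      effect_edge_fraction = effect_edge_fraction,
      effect_size = effect_size,
      noise_sd = noise_sd,
      class_balance = class_balance,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Project a symmetric matrix to the nearest (Frobenius) symmetric
# positive-definite matrix by clipping eigenvalues at a small floor.
project_spd <- function(S, floor = 1e-4) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  ok <- tryCatch({ chol(out); TRUE }, error = function(e) FALSE)
  if (!ok) abort("covariance projection failed to produce a positive-definite matrix")
  out
}

# Contiguous partition of 1..n_fine into n_coarse non-empty blocks, with
# seeded random cut points. Returns a list of index vectors.
coarse_grouping <- function(n_fine, n_coarse, seed) {
  if (n_coarse == n_fine) return(as.list(seq_len(n_fine)))
  cuts <- withr::with_seed(seed, sort(sample(seq_len(n_fine - 1L), n_coarse - 1L)))
  bounds <- c(0L, cuts, n_fine)
  lapply(seq_len(n_coarse), function(k) seq.int(bounds[k] + 1L, bounds[k + 1L]))
}

#' Generate a synthetic two-scale cohort
#'
#' Draws per-subject fine-scale time series from a zero-mean multivariate
#' normal whose covariance depends on class: controls (label 0) use a
#' block-modular base covariance, cases (label 1) use the base covariance
#' plus a signed perturbation of magnitude `effect_size` on a seeded random
#' `effect_edge_fraction` of off-diagonal entries (projected back to the
#' nearest positive-definite matrix). Independent Gaussian observation noise
#' (`noise_sd`) is added, and coarse-scale series are exact means of
#' contiguous blocks of the observed fine series. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `fc_cohort` with columns `subject`, `label`,
#'   and one list-column of time-series matrices per scale (`coarse`,
#'   `fine`). Attributes carry the spec, the scale table, the fine-to-coarse
#'   grouping, and the perturbed edge list.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$fine_rois
  m <- p * (p - 1L) / 2L
  n_eff <- round(spec$effect_edge_fraction * m)
  if (spec$effect_size > 0 && n_eff == 0)
    warn("effect_edge_fraction selects no edges: generating a null cohort")

  # Modular base covariance shared by both classes: unit variances, within-
  # module covariance 0.3, ~20 ROIs per module.
  n_mod <- max(1L, round(p / 20))
  module <- withr::with_seed(
    substream_seed(spec$seed, "modules"),
    sample(rep_len(seq_len(n_mod), p))
  )
  sigma0 <- outer(module, module, `==`) * 0.3
  diag(sigma0) <- 1
  sigma0 <- project_spd(sigma0)

  sigma1 <- sigma0
  eff <- NULL
  if (n_eff > 0 && spec$effect_size > 0) {
    ut <- which(upper.tri(sigma0), arr.ind = TRUE)
    pick <- withr::with_seed(
      substream_seed(spec$seed, "effect"),
      list(idx = sample(nrow(ut), n_eff), sign = sample(c(-1, 1), n_eff, replace = TRUE))
    )
    eff <- tibble(
      i = ut[pick$idx, 1L], j = ut[pick$idx, 2L],
      delta = pick$sign * spec$effect_size
    )
    for (r in seq_len(nrow(eff))) {
      sigma1[eff$i[r], eff$j[r]] <- sigma1[eff$i[r], eff$j[r]] + eff$delta[r]
      sigma1[eff$j[r], eff$i[r]] <- sigma1[eff$i[r], eff$j[r]]
    }
    sigma1 <- project_spd(sigma1)
  }

  n1 <- round(spec$n_subjects * spec$class_balance)
  labels <- withr::with_seed(
    substream_seed(spec$seed, "labels"),
    sample(c(rep(1L, n1), rep(0L, spec$n_subjects - n1)))
  )

  groups <- coarse_grouping(p, spec$coarse_rois, substream_seed(spec$seed, "grouping"))
  chol0 <- chol(sigma0)
  chol1 <- chol(sigma1)
  t_n <- spec$n_timepoints

  draws <- withr::with_seed(substream_seed(spec$seed, "subjects"), {
    lapply(seq_len(spec$n_subjects), function(s) {
      z <- matrix(rnorm(t_n * p), t_n, p)
      x <- z %*% (if (labels[s] == 1L) chol1 else chol0)
      x <- x + matrix(rnorm(t_n * p, sd = spec$noise_sd), t_n, p)
      colnames(x) <- paste0("ROI", seq_len(p))
      x
    })
  })
  coarse <- lapply(draws, function(x) {
    cm <- vapply(groups, function(g) rowMeans(x[, g, drop = FALSE]), numeric(t_n))
    colnames(cm) <- paste0("ROI", seq_len(spec$coarse_rois))
    cm
  })

  out <- tibble(
    subject = sprintf("S%04d", seq_len(spec$n_subjects)),
    label = labels,
    coarse = coarse,
    fine = draws
  )
  structure(
    out,
    class = c("fc_cohort", class(out)),
    spec = spec,
    scales = tibble(scale = c("coarse", "fine"),
                    n_roi = c(spec$coarse_rois, spec$fine_rois)),
    grouping = groups,
    effect_edges = eff
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  sc <- attr(x, "scales")
  cat(sprintf(
    "<fc_cohort> %d subjects (%d positive), %d time points, scales: %s\n",
    nrow(x), sum(x$label), attr(x, "spec")$n_timepoints,
    paste(sprintf("%s[%d]", sc$scale, sc$n_roi), collapse = ", ")
  ))
  NextMethod()
}

#' Cohort scale names in fusion order
#' @param cohort An `fc_cohort` or `fc_graphs` object.
#' @return Character vector of scale names, coarse first.
#' @export
scale_names <- function(cohort) attr(cohort, "scales")$scale

#' Write a cohort to delimited-text files
#'
#' Writes one TSV matrix per subject per scale (rows = time points, columns
#' = ROIs), named `<subject>_<scale>.tsv`, plus `labels.tsv` and a YAML
#' `manifest.yaml` listing scales and dimensions.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if missing).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (nrow(cohort) == 0) abort("cannot write an empty cohort")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.yaml")
  if (file.exists(manifest_path) && !overwrite)
    abort("manifest already exists in this directory; use overwrite = TRUE")

  scales <- attr(cohort, "scales")
  files <- character(0)
  for (sc in scales$scale) {
    for (r in seq_len(nrow(cohort))) {
      f <- sprintf("%s_%s.tsv", cohort$subject[r], sc)
      utils::write.table(cohort[[sc]][[r]], file.path(dir, f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
  }
  utils::write.table(
    data.frame(subject = cohort$subject, label = cohort$label),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- list(
    n_subjects = nrow(cohort),
    n_timepoints = nrow(cohort[[scales$scale[1]]][[1]]),
    scales = lapply(seq_len(nrow(scales)), function(k)
      list(name = scales$scale[k], n_roi = as.integer(scales$n_roi[k]))),
    labels = "labels.tsv",
    files = files
  )
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory holding `manifest.yaml`.
#' @return An `fc_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) abort("no manifest.yaml found in directory")
  manifest <- yaml::read_yaml(manifest_path)
  labels <- read_labels(file.path(dir, manifest$labels))
  scales <- tibble(
    scale = vapply(manifest$scales, `[[`, character(1), "name"),
    n_roi = vapply(manifest$scales, `[[`, integer(1), "n_roi")
  )
  out <- tibble(subject = labels$subject, label = labels$label)
  for (sc in scales$scale) {
    out[[sc]] <- lapply(out$subject, function(s)
      read_timeseries(file.path(dir, sprintf("%s_%s.tsv", s, sc))))
  }
  structure(out, class = c("fc_cohort", class(out)), scales = scales)
}
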