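#' @title Accuracy evaluation, window tuning and ablations
#' @name evaluation
#' @description
#' Confusion-matrix metrics, grid search over the two evidence time windows
#' (BI and HF/FO) maximizing F1 against labeled admissions, and component
#' ablations that re-run the detector with individual criteria disabled.
NULL

#' Build a confusion matrix from predicted and true flags
#'
#' @param pred Logical vector of predicted ARDS flags.
#' @param truth Logical vector of true labels (same length).
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Compute accuracy metrics from a confusion matrix
#'
#' Accuracy, specificity, recall (sensitivity), precision and F1, each as a
#' percentage. Ratios with a zero denominator are reported as 0 and listed
#' in the `undefined` field. Values are kept at full precision; the print
#' method rounds to one decimal.
#'
#' @param cm List with `tp`, `fp`, `fn`, `tn` (see [confusion_matrix()]).
#' @return Object of class `metrics_report` with fields `accuracy`,
#'   `specificity`, `recall`, `precision`, `f1` (percent) and `undefined`
#'   (character vector).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("confusion matrix is all zero", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  accuracy <- (tp + tn) / total
  specificity <- ratio(tn, tn + fp, "specificity")
  recall <- ratio(tp, tp + fn, "recall")
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = 100 * accuracy, specificity = 100 * specificity,
                 recall = 100 * recall, precision = 100 * precision,
                 f1 = 100 * f1, undefined = unique(undefined),
                 cm = list(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  specificity %.1f%%  recall %.1f%%  precision %.1f%%  F1 %.1f%%\n",
              x$accuracy, x$specificity, x$recall, x$precision, x$f1))
  if (length(x$undefined) > 0L) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, specificity = m$specificity,
             recall = m$recall, precision = m$precision, f1 = m$f1)
}

#' Default candidate durations for window tuning (minutes)
#'
#' The tuning grid: 4 h, 8 h, 12 h, 1 d, 2 d, 5 d and 7 d.
#'
#' @return Named numeric vector of durations in minutes.
#' @export
default_window_grid <- function() {
  c("4h" = 4 * 60, "8h" = 8 * 60, "12h" = 12 * 60, "1d" = 1440,
    "2d" = 2 * 1440, "5d" = 5 * 1440, "7d" = 7 * 1440)
}

#' Grid-search the BI and HF/FO time windows
#'
#' Runs the detector at every (delta_bi, delta_hffo) pair of the candidate
#' set (49 pairs at the default grid), scores each against the ground-truth
#' labels, and returns the pair maximizing F1. Ties are broken toward the
#' smaller delta_bi, then the smaller delta_hffo (the more conservative
#' phenotype). Selection uses full-precision F1; rounding is display-only.
#'
#' @param admissions List of `admission_record` objects.
#' @param labels Data frame with `admission_id` and logical `ards_label`.
#' @param evidence Injected evidence table for the whole cohort (columns
#'   `admission_id`, `time`, `kind`), or `NULL` to classify notes with
#'   `models`.
#' @param candidates Candidate durations in minutes (used for both windows);
#'   default [default_window_grid()].
#' @param config Base [berlin_config()]; its two windows are overridden.
#' @param models Optional trained classifiers when `evidence` is `NULL`.
#' @return List with `best_delta_bi`, `best_delta_hffo` (minutes), `grid`
#'   (one row per pair with the confusion counts and metrics) and `summary`
#'   (across-grid min/max/mean with Student-t 95% half-width per metric).
#' @export
tune_windows <- function(admissions, labels, evidence = NULL,
                         candidates = default_window_grid(),
                         config = berlin_config(), models = NULL) {
  lab <- labels$ards_label[match(vapply(admissions, `[[`, "", "admission_id"),
                                 labels$admission_id)]
  if (anyNA(lab)) stop("labels missing for some admissions", call. = FALSE)
  if (length(unique(lab)) < 2L) {
    stop("single class: labels must contain positive and negative admissions",
         call. = FALSE)
  }
  pairs <- expand.grid(delta_bi = candidates, delta_hffo = candidates)
  grid <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cfg <- config
    cfg$delta_bi <- pairs$delta_bi[i]
    cfg$delta_hffo <- pairs$delta_hffo[i]
    verdicts <- detect_cohort(admissions, models = models,
                              evidence = evidence, config = cfg)
    pred <- vapply(verdicts, `[[`, logical(1), "ards")
    m <- compute_metrics(confusion_matrix(pred, lab))
    cbind(data.frame(delta_bi = pairs$delta_bi[i],
                     delta_hffo = pairs$delta_hffo[i],
                     tp = m$cm$tp, fp = m$cm$fp, fn = m$cm$fn, tn = m$cm$tn),
          metrics_row(m))
  }))
  ord <- order(-grid$f1, grid$delta_bi, grid$delta_hffo)
  best <- grid[ord[1], ]
  summary <- do.call(rbind, lapply(c("accuracy", "precision", "recall", "f1"),
                                   function(m) {
    v <- grid[[m]]
    n <- length(v)
    half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
            else NA_real_
    data.frame(metric = m, min = min(v), max = max(v), mean = mean(v),
               ci95_halfwidth = half, stringsAsFactors = FALSE)
  }))
  list(best_delta_bi = best$delta_bi, best_delta_hffo = best$delta_hffo,
       grid = grid, summary = summary, n_pairs = nrow(grid))
}

.ABLATION_VARIANTS <- c("no_hffo", "no_trach_acuteness", "no_onset_horizon",
                        "no_vent_minimum", "oracle_bi")

variant_config <- function(variant, config) {
  config$disabled_checks <- switch(
    variant,
    no_hffo = union(config$disabled_checks, "hffo"),
    no_trach_acuteness = union(config$disabled_checks, "trach"),
    no_onset_horizon = union(config$disabled_checks, "horizon"),
    no_vent_minimum = union(config$disabled_checks, "vent"),
    config$disabled_checks)
  config
}

#' Component ablations of the detector
#'
#' Re-runs the detector with one component disabled per variant and reports
#' each metric next to its signed delta against the baseline. The
#' `oracle_bi` variant replaces the (possibly noisy) BI evidence with the
#' true BI evidence while keeping everything else fixed.
#'
#' @param admissions List of `admission_record` objects.
#' @param labels Data frame with `admission_id`, logical `ards_label`.
#' @param evidence True injected evidence table.
#' @param variants Subset of `no_hffo`, `no_trach_acuteness`,
#'   `no_onset_horizon`, `no_vent_minimum`, `oracle_bi` (empty for baseline
#'   only).
#' @param config A [berlin_config()].
#' @param noisy_evidence Optional evidence table with classifier noise; when
#'   given it is used for the baseline and all variants except the BI rows
#'   under `oracle_bi`.
#' @return Data frame: one baseline row plus one row per variant with
#'   metrics, `n_positive` and `delta_*` columns.
#' @export
ablation_run <- function(admissions, labels, evidence, variants = character(0),
                         config = berlin_config(), noisy_evidence = NULL) {
  bad <- setdiff(variants, .ABLATION_VARIANTS)
  if (length(bad) > 0L) {
    stop("unknown variant name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lab <- labels$ards_label[match(vapply(admissions, `[[`, "", "admission_id"),
                                 labels$admission_id)]
  base_ev <- if (is.null(noisy_evidence)) evidence else noisy_evidence

  run <- function(ev, cfg) {
    verdicts <- detect_cohort(admissions, evidence = ev, config = cfg)
    pred <- vapply(verdicts, `[[`, logical(1), "ards")
    m <- compute_metrics(confusion_matrix(pred, lab))
    cbind(metrics_row(m), data.frame(n_positive = sum(pred)))
  }

  baseline <- run(base_ev, config)
  rows <- cbind(data.frame(variant = "baseline"), baseline,
                delta_accuracy = 0, delta_specificity = 0, delta_recall = 0,
                delta_precision = 0, delta_f1 = 0, delta_n_positive = 0)
  for (v in variants) {
    ev <- base_ev
    if (v == "oracle_bi") {
      ev <- rbind(evidence[evidence$kind %in% c("bi_pos", "bi_neg"), ,
                           drop = FALSE],
                  base_ev[base_ev$kind == "hffo", , drop = FALSE])
    }
    res <- run(ev, variant_config(v, config))
    rows <- rbind(rows, cbind(
      data.frame(variant = v), res,
      delta_accuracy = res$accuracy - baseline$accuracy,
      delta_specificity = res$specificity - baseline$specificity,
      delta_recall = res$recall - baseline$recall,
      delta_precision = res$precision - baseline$precision,
      delta_f1 = res$f1 - baseline$f1,
      delta_n_positive = res$n_positive - baseline$n_positive))
  }
  rownames(rows) <- NULL
  rows
}

#' Overlap counts among multiple flag columns
#'
#' Counts admissions in every combination of the given logical flag columns
#' (the input to a Venn-style comparison of detection methods).
#'
#' @param flags Data frame of logical columns (one per method), one row per
#'   admission.
#' @return Data frame with one row per observed combination and its `n`.
#' @export
overlap_counts <- function(flags) {
  stopifnot(is.data.frame(flags), all(vapply(flags, is.logical, logical(1))))
  key <- apply(flags, 1, function(r) paste(names(flags)[r], collapse = "+"))
  key[key == ""] <- "(none)"
  tab <- table(key)
  data.frame(combination = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
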