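# Evaluation of predictions against reference interfaces.

#' Confusion counts of a prediction against a reference interface
#'
#' Standard 2x2 counts over an evaluation universe (by default the surface
#' residues of the evaluated structure; binding is a surface phenomenon and
#' the expected-size model is surface-based, but any universe - e.g. all
#' residues - can be passed).
#'
#' @param prediction predicted residue keys (subset of \code{universe}).
#' @param reference reference interface residue keys (subset of
#'   \code{universe}).
#' @param universe all evaluated residue keys.
#' @return list with TP, FP, TN, FN.
#' @export
confusion <- function(prediction, reference, universe) {
  if (length(universe) == 0) stop("empty evaluation universe")
  prediction <- intersect(prediction, universe)
  reference <- intersect(reference, universe)
  tp <- length(intersect(prediction, reference))
  fp <- length(setdiff(prediction, reference))
  fn <- length(setdiff(reference, prediction))
  tn <- length(universe) - tp - fp - fn
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Six performance measures from confusion counts
#'
#' Sens = TP/(TP+FN), PPV = TP/(TP+FP), Spe = TN/(TN+FP),
#' Acc = (TP+TN)/total, F1 = harmonic mean of Sens and PPV, and MCC =
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). All values are
#' reported multiplied by 100, i.e. in [0, 100] ([-100, 100] for MCC). A
#' zero denominator makes the affected measure undefined (\code{NA}), never
#' silently zero; MCC is undefined whenever any marginal is zero.
#'
#' @param counts list with TP, FP, TN, FN.
#' @return list with Sens, PPV, Spe, Acc, F1, MCC (x100).
#' @export
#' @examples
#' eval_metrics(list(TP = 5, FP = 5, TN = 85, FN = 5))$MCC  # ~44.4
eval_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  total <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  ppv <- safe_div(tp, tp + fp)
  spe <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, total)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * sens * ppv / (sens + ppv)
  } else NA_real_
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  } else NA_real_
  lapply(list(Sens = sens, PPV = ppv, Spe = spe, Acc = acc, F1 = f1,
              MCC = mcc), function(v) 100 * v)
}

#' Evaluate a prediction against a reference interface
#'
#' @param pred a \code{pdna_prediction} (or a character vector of predicted
#'   residue keys).
#' @param reference reference residue keys (e.g. from
#'   \code{\link{interface_residues}}).
#' @param universe evaluation universe; defaults to the prediction's
#'   surface residues.
#' @return list with \code{counts} and \code{metrics}.
#' @export
evaluate_prediction <- function(pred, reference, universe = NULL) {
  keys <- if (inherits(pred, "pdna_prediction")) {
    universe <- universe %||% pred$surface
    predicted_residues(pred)
  } else {
    pred
  }
  if (is.null(universe)) stop("an evaluation universe is required")
  cts <- confusion(keys, reference, universe)
  list(counts = cts, metrics = eval_metrics(cts))
}

#' Best-scheme evaluation
#'
#' Per-protein evaluation rule: scores every supplied prediction (one per
#' scoring scheme, or any combination of patches) and reports the one with
#' the highest F1.
#'
#' @param preds named list of \code{pdna_prediction} objects or residue-key
#'   vectors.
#' @param reference reference residue keys.
#' @param universe evaluation universe.
#' @return list with \code{best} (name of the winner), \code{evaluation}
#'   (its metrics) and \code{all} (metrics for every entry).
#' @export
evaluate_best_scheme <- function(preds, reference, universe = NULL) {
  evals <- lapply(preds, evaluate_prediction, reference = reference,
                  universe = universe)
  f1 <- vapply(evals, function(e) {
    v <- e$metrics$F1
    if (is.na(v)) -Inf else v
  }, numeric(1))
  best <- names(evals)[which.max(f1)]
  list(best = best, evaluation = evals[[best]], all = evals)
}

#' Paired comparison of per-protein performance values
#'
#' Implements the significance protocol for comparing two methods over the
#' same proteins: normality of the paired differences is assessed with the
#' Anderson-Darling test; if normal (p >= 0.05) a paired t-test is used,
#' otherwise the Wilcoxon signed-rank test. The difference is significant
#' when the final p-value is below 0.05. The Anderson-Darling test needs at
#' least 8 observations; for 5-7 pairs the Wilcoxon branch is used
#' directly.
#'
#' @param values_a,values_b equal-length paired numeric vectors (n >= 5).
#' @return list with \code{test} ("paired t-test", "wilcoxon signed-rank"
#'   or "no difference"), \code{statistic}, \code{p_value} and
#'   \code{significant}.
#' @export
paired_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length")
  }
  if (length(values_a) < 5) stop("need at least 5 pairs")
  diffs <- values_a - values_b
  if (all(diffs == 0)) {
    return(list(test = "no difference", statistic = NA_real_,
                p_value = NA_real_, significant = FALSE))
  }
  normal <- if (length(diffs) >= 8) {
    nortest::ad.test(diffs)$p.value >= 0.05
  } else {
    FALSE
  }
  if (normal) {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    list(test = "paired t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, significant = tt$p.value < 0.05)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              paired = TRUE, exact = FALSE))
    list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, significant = wt$p.value < 0.05)
  }
}
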