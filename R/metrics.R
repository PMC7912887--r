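# Confusion counts, the seven evaluation metrics, and percentile CIs over
# repeated runs.

#' Tally confusion counts from probabilities and labels
#'
#' A call is positive when the predicted probability is >= `threshold`
#' (default 0.5).
#'
#' @param y_true Integer/numeric vector of 0/1 labels.
#' @param y_prob Numeric vector of probabilities in `[0,1]`, same length.
#' @param threshold Decision threshold.
#' @return A `confusion_counts` list with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("y_true and y_prob differ in length", call. = FALSE)
  }
  stopifnot(all(y_true %in% c(0, 1)))
  if (any(y_prob < 0 | y_prob > 1)) {
    stop("probabilities outside [0,1]", call. = FALSE)
  }
  call_pos <- y_prob >= threshold
  pos <- y_true == 1
  structure(list(tp = sum(call_pos & pos), tn = sum(!call_pos & !pos),
                 fp = sum(call_pos & !pos), fn = sum(!call_pos & pos)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Compute the six ratio metrics from confusion counts
#'
#' accuracy = (TP+TN)/total; sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP); PPV = TP/(TP+FP); NPV = TN/(TN+FN);
#' F-score = harmonic mean of PPV and sensitivity. A ratio whose
#' denominator is zero (e.g. PPV with no positive calls, or specificity on
#' an all-positive evaluation set) is reported as `NA` rather than forced
#' to 0 or 1.
#'
#' @param counts A `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   f_score, ppv, npv.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  sens <- safe_ratio(tp, tp + fn)
  ppv <- safe_ratio(tp, tp + fp)
  f <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sens,
    specificity = safe_ratio(tn, tn + fp),
    f_score = f,
    ppv = ppv,
    npv = safe_ratio(tn, tn + fn))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and 0/1 labels.
#' 0 for perfectly confident correct predictions; 0.25 for a constant 0.5.
#'
#' @inheritParams confusion
#' @return Numeric scalar in `[0,1]`.
#' @export
brier <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) {
    stop("y_true and y_prob differ in length", call. = FALSE)
  }
  if (any(y_prob < 0 | y_prob > 1)) {
    stop("probabilities outside [0,1]", call. = FALSE)
  }
  mean((y_prob - y_true)^2)
}

#' Full metrics report for one evaluation
#'
#' Convenience wrapper: confusion at the threshold, the six ratio metrics,
#' and the Brier score.
#'
#' @inheritParams confusion
#' @return Named numeric vector with the seven metrics.
#' @export
metrics_report <- function(y_true, y_prob, threshold = 0.5) {
  c(compute_metrics(confusion(y_true, y_prob, threshold)),
    brier = brier(y_true, y_prob))
}

#' Percentile confidence interval over repeated-run metric values
#'
#' Empirical 2.5% / 97.5% percentiles (by default) with linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector of per-run metric values (length >= 2).
#' @param lo,hi Percentile bounds, in percent.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
percentile_ci <- function(values, lo = 2.5, hi = 97.5) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  q <- stats::quantile(values, probs = c(lo, hi) / 100, names = FALSE, type = 7)
  c(ci_low = q[1L], ci_high = q[2L])
}

#' Aggregate repeated-run metric reports
#'
#' Takes a list of per-run metric vectors (as returned by
#' [metrics_report()]) and reports, per metric, the mean and the 2.5/97.5
#' percentile interval — the repeated-resplit summary layout.
#'
#' @param reports List of named numeric vectors sharing the same names.
#' @return Data frame with columns metric, mean, ci_low, ci_high.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 2L)
  m <- do.call(rbind, reports)
  safe_ci <- function(v) {
    if (sum(!is.na(v)) < 2L) return(c(ci_low = NA_real_, ci_high = NA_real_))
    percentile_ci(v)
  }
  cis <- apply(m, 2L, safe_ci)
  data.frame(metric = colnames(m),
             mean = colMeans(m, na.rm = TRUE),
             ci_low = cis["ci_low", ],
             ci_high = cis["ci_high", ],
             row.names = NULL)
}
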