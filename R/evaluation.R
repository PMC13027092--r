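# Patient-level evaluation: confusion-matrix metrics, ROC/AUC (Mann-Whitney
# with half-credit ties), Hanley-McNeil AUC standard error, and the one-sided
# power of the AUC test against a null of 0.5.

#' Patient-level confusion matrix
#'
#' Positive means inflamed; negative means healthy.
#' @param tp,fn,tn,fp nonnegative counts.
#' @return a `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  cm <- list(tp = assert_count(tp, "tp", 0L), fn = assert_count(fn, "fn", 0L),
             tn = assert_count(tn, "tn", 0L), fp = assert_count(fp, "fp", 0L))
  if (cm$tp + cm$fn + cm$tn + cm$fp == 0L) stopf("confusion matrix has no subjects")
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d TN=%d FP=%d (n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

#' Confusion matrix from a predictions table
#'
#' @param predictions data.frame with columns `label` and `pred` (values
#'   positive/negative); every row must be labeled.
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(predictions) {
  if (!all(c("label", "pred") %in% names(predictions)))
    stopf("predictions need `label` and `pred` columns")
  if (any(is.na(predictions$label))) stopf("unlabeled rows cannot enter a confusion matrix")
  truth <- normalize_label(predictions$label)
  pred <- normalize_label(predictions$pred)
  confusion_matrix(tp = sum(pred == "positive" & truth == "positive"),
                   fn = sum(pred == "negative" & truth == "positive"),
                   tn = sum(pred == "negative" & truth == "negative"),
                   fp = sum(pred == "positive" & truth == "negative"))
}

#' Confusion-matrix metrics
#'
#' accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP),
#' F1 = harmonic mean of sensitivity and precision. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with accuracy, sensitivity, specificity, precision, f1
#'   (proportions in \[0, 1\]).
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$tn + cm$fp
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(cm$tp, cm$tp + cm$fn)
  prec <- div(cm$tp, cm$tp + cm$fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(accuracy = div(cm$tp + cm$tn, total),
       sensitivity = sens,
       specificity = div(cm$tn, cm$tn + cm$fp),
       precision = prec,
       f1 = f1)
}

#' Empirical ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted 1/2; ROC points are computed at every
#' distinct threshold and always include (0,0) and (1,1).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels (positive/negative), same length.
#' @return list with `auc` and `roc`, a data.frame of (fpr, tpr, threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_label(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  pos <- labels == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be present to compute an ROC")
  r <- rank(scores, ties.method = "average")            # mid-ranks give half-credit ties
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(thr, function(t) sum(scores[!pos] >= t), numeric(1)) / n_neg),
    tpr = c(0, vapply(thr, function(t) sum(scores[pos] >= t), numeric(1)) / n_pos),
    threshold = c(Inf, thr)
  )
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  list(auc = auc, roc = roc)
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)] /
#' (n_pos * n_neg)` with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC in (0, 1).
#' @param n_pos,n_neg class sizes (each at least 2).
#' @return standard error.
#' @export
auc_standard_error <- function(auc, n_pos, n_neg) {
  auc <- assert_number(auc, "auc", 0, 1, strict_min = TRUE)
  if (auc >= 1) stopf("`auc` must lie strictly inside (0, 1)")
  n_pos <- assert_count(n_pos, "n_pos", 2L)
  n_neg <- assert_count(n_neg, "n_neg", 2L)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) + (n_neg - 1) * (q2 - auc^2)) /
    (n_pos * n_neg)
  sqrt(se2)
}

#' Z statistic and statistical power of the AUC test
#'
#' Tests the observed AUC against a null AUC (0.5 by default):
#' `Z = (AUC - null) / SE(AUC)` with the Hanley-McNeil standard error, and
#' one-sided normal power `Phi(Z - z_{1-alpha})` (two-sided uses
#' `z_{1-alpha/2}` and adds the lower tail).
#'
#' @param auc observed AUC.
#' @param n_pos,n_neg class sizes.
#' @param alpha significance level.
#' @param null_auc AUC under the null hypothesis.
#' @param two_sided if `TRUE`, two-sided power.
#' @return list with `z`, `se`, and `power`.
#' @export
auc_power <- function(auc, n_pos, n_neg, alpha = 0.05, null_auc = 0.5,
                      two_sided = FALSE) {
  alpha <- assert_number(alpha, "alpha", 0, 1, strict_min = TRUE)
  if (alpha >= 1) stopf("alpha must lie in (0, 1)")
  se <- auc_standard_error(auc, n_pos, n_neg)
  z <- (auc - null_auc) / se
  power <- if (two_sided) {
    crit <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(z - crit) + stats::pnorm(-z - crit)
  } else {
    stats::pnorm(z - stats::qnorm(1 - alpha))
  }
  list(z = z, se = se, power = power)
}

#' Full metrics report for a predictions table
#'
#' Confusion-matrix metrics at the decision threshold plus AUC, its
#' Hanley-McNeil standard error, Z statistic and one-sided power.
#'
#' @param predictions data.frame with `label`, `p_positive`, `pred` columns
#'   (as emitted by [predict_cohort()]).
#' @param alpha significance level for the power computation.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(predictions, alpha = 0.05) {
  cm <- confusion_from_predictions(predictions)
  m <- metrics_from_cm(cm)
  ra <- roc_auc(predictions$p_positive, predictions$label)
  n_pos <- cm$tp + cm$fn; n_neg <- cm$tn + cm$fp
  pw <- auc_power(min(max(ra$auc, 1e-6), 1 - 1e-6), n_pos, n_neg, alpha = alpha)
  structure(c(m, list(auc = ra$auc, auc_se = pw$se, z_stat = pw$z,
                      power = pw$power, confusion = cm, roc = ra$roc)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.2f%%, sensitivity %.2f%%, ",
                     "specificity %.2f%%, F1 %.4f, AUC %.4f (SE %.4f)\n"),
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$f1, x$auc, x$auc_se))
  invisible(x)
}

#' Percentage-point improvement between two metric reports
#'
#' Differences `b - a` per metric in percentage points (proportion metrics are
#' scaled by 100). Display values are rounded to 2 decimals; the unrounded
#' delta is retained.
#'
#' @param metrics_a,metrics_b lists as returned by [metrics_from_cm()] or
#'   [metrics_report()] (reference first).
#' @return data.frame with metric, value_a, value_b, delta_pp, delta_display.
#' @export
improvement_report <- function(metrics_a, metrics_b) {
  keys <- intersect(c("accuracy", "sensitivity", "specificity", "precision", "f1", "auc"),
                    intersect(names(metrics_a), names(metrics_b)))
  out <- do.call(rbind, lapply(keys, function(k) {
    a <- metrics_a[[k]]; b <- metrics_b[[k]]
    delta <- 100 * (b - a)
    data.frame(metric = k, value_a = a, value_b = b,
               delta_pp = delta, delta_display = round(delta, 2))
  }))
  out
}
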