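# Classification performance: confusion matrices, one-vs-rest metrics with
# exact Clopper-Pearson binomial confidence intervals, Pearson correlation,
# and the two-sample t-test.

#' Confusion matrix over the three tissue classes
#'
#' @param true_classes,predicted_classes Equal-length character vectors over
#'   `{malignant, benign, fat}` (or `classes`).
#' @param classes Class levels, fixing row/column order.
#' @return 3x3 integer matrix of counts, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(true_classes, predicted_classes,
                             classes = CLASS_LEVELS) {
  if (length(true_classes) != length(predicted_classes))
    stop("label vectors differ in length")
  bad <- setdiff(unique(c(true_classes, predicted_classes)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tt <- table(factor(true_classes, levels = classes),
              factor(predicted_classes, levels = classes))
  m <- matrix(as.integer(tt), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' One-vs-rest metrics for one class
#'
#' Collapses the confusion matrix to class-vs-rest and reports sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, and accuracy
#' `(TP + TN) / total`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param confusion Square count matrix with matching dimnames.
#' @param class Class of interest (a row/column name).
#' @return List with `sensitivity`, `specificity`, `accuracy`, and the
#'   underlying counts `tp`, `fn`, `fp`, `tn`.
#' @export
class_metrics <- function(confusion, class) {
  if (!class %in% rownames(confusion)) stop("unknown class: ", class)
  tot <- sum(confusion)
  if (tot == 0) stop("empty confusion matrix")
  i <- match(class, rownames(confusion))
  tp <- confusion[i, i]
  fn <- sum(confusion[i, -i])
  fp <- sum(confusion[-i, i])
  tn <- tot - tp - fn - fp
  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = ratio_or_na(tp, tp + fn),
       specificity = ratio_or_na(tn, tn + fp),
       accuracy = (tp + tn) / tot,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,trials Counts with `0 <= successes <= trials`, `trials > 0`.
#' @param level Coverage; default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  x <- successes; n <- trials
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n <= 0 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("invalid counts for Clopper-Pearson interval")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Pearson correlation with a t-based p-value
#'
#' Sample correlation `r = S_xy / sqrt(S_xx S_yy)` with a two-sided p-value
#' from `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, each with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("zero variance")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (`t = (mean_a - mean_b) / (s_p
#' sqrt(1/n_a + 1/n_b))` on `n_a + n_b - 2` df), two-sided. Welch's unequal
#' variance form available by flag. Two groups with zero pooled variance and
#' equal means give `t = 0, p = 1`; with unequal means the statistic is
#' undefined and an error is raised.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) form; default `FALSE`.
#' @return List with `t`, `p_value`, `df`.
#' @export
two_sample_ttest <- function(group_a, group_b, welch = FALSE) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  dmean <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (dmean == 0) return(list(t = 0, p_value = 1, df = na + nb - 2))
      stop("zero variance with unequal means: t undefined")
    }
    tstat <- dmean / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    if (sp2 == 0) {
      if (dmean == 0) return(list(t = 0, p_value = 1, df = df))
      stop("zero pooled variance with unequal means: t undefined")
    }
    tstat <- dmean / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = tstat, p_value = 2 * stats::pt(-abs(tstat), df = df), df = df)
}

#' Full classification performance report
#'
#' Confusion matrix plus per-class one-vs-rest sensitivity, specificity, and
#' accuracy, each with an exact Clopper-Pearson interval, and the overall
#' accuracy (`trace / total`). Undefined metrics (empty class) stay `NA`.
#'
#' @param true_classes,predicted_classes Label vectors.
#' @param level CI coverage; default 0.95.
#' @param unit `"specimen"` or `"pixel"` (annotation only).
#' @return A `performance_report`: `confusion`, `metrics` data.frame
#'   (class, metric, estimate, ci_lower, ci_upper, n), `overall_accuracy`
#'   with its CI, `unit`, `level`.
#' @export
performance_report <- function(true_classes, predicted_classes, level = 0.95,
                               unit = c("specimen", "pixel")) {
  unit <- match.arg(unit)
  conf <- confusion_matrix(true_classes, predicted_classes)
  rows <- list()
  for (cl in rownames(conf)) {
    m <- class_metrics(conf, cl)
    spec_pairs <- list(
      sensitivity = c(m$tp, m$tp + m$fn),
      specificity = c(m$tn, m$tn + m$fp),
      accuracy = c(m$tp + m$tn, sum(conf)))
    for (metric in names(spec_pairs)) {
      cnt <- spec_pairs[[metric]]
      est <- m[[metric]]
      ci <- if (is.na(est)) c(NA_real_, NA_real_) else
        clopper_pearson(cnt[1], cnt[2], level)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, metric = metric, estimate = est,
        ci_lower = ci[1], ci_upper = ci[2], n = cnt[2],
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  tot <- sum(conf)
  acc_ci <- clopper_pearson(sum(diag(conf)), tot, level)
  structure(
    list(confusion = conf, metrics = metrics,
         overall_accuracy = sum(diag(conf)) / tot,
         overall_accuracy_ci = acc_ci, unit = unit, level = level,
         n = tot),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report (%s level, unit = %s, n = %d)\n",
              format(x$level), x$unit, x$n))
  print(x$confusion)
  cat(sprintf("overall accuracy %.2f (%.2f-%.2f)\n", x$overall_accuracy,
              x$overall_accuracy_ci[1], x$overall_accuracy_ci[2]))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %-12s %s (%s-%s)\n", m$class[i], m$metric[i],
                ifelse(is.na(m$estimate[i]), "NA", sprintf("%.2f", m$estimate[i])),
                ifelse(is.na(m$ci_lower[i]), "NA", sprintf("%.2f", m$ci_lower[i])),
                ifelse(is.na(m$ci_upper[i]), "NA", sprintf("%.2f", m$ci_upper[i]))))
  invisible(x)
}
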