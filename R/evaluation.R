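#' Confusion matrix for quality classification
#'
#' Convention: positive = sufficient quality. `tp` and `fn` count
#' sufficient-quality images classified correctly and wrongly; `tn` and
#' `fp` count insufficient-quality images classified correctly and
#' wrongly.
#'
#' @param tp,fp,tn,fn non-negative integer counts, total > 0.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Classification rates from a confusion matrix
#'
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`, `precision = TP/(TP+FP)`,
#' `recall = TPR`. A rate with a zero denominator is `NaN`.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `tpr`, `fpr`, `precision`, `recall`, `fnr`
#'   (`1 - tpr`).
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  div <- function(a, b) if (b == 0) NaN else a / b
  tpr <- div(cm$tp, cm$tp + cm$fn)
  list(tpr = tpr,
       fpr = div(cm$fp, cm$fp + cm$tn),
       precision = div(cm$tp, cm$tp + cm$fp),
       recall = tpr,
       fnr = 1 - tpr)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return `(tp + tn) / total`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$tn + cm$fn)
}

check_scored_labels <- function(scores, labels, require_both = TRUE) {
  stopifnot(length(scores) == length(labels), length(scores) >= 2)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (require_both && length(unique(labels)) < 2L)
    stop("both classes must be present")
  if (!any(labels == 1L)) stop("at least one positive is required")
  labels
}

curve_points <- function(scores, labels, require_both = TRUE) {
  # one operating point per distinct score, rule: score >= t -> positive
  labels <- check_scored_labels(scores, labels, require_both)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  data.frame(threshold = thr, tp = tp, fp = fp,
             fn = np - tp, tn = nn - fp,
             tpr = tp / np, fpr = fp / nn,
             precision = ifelse(tp + fp == 0, NaN, tp / (tp + fp)),
             recall = tp / np)
}

#' ROC curve and area under it
#'
#' Operating points are taken at every distinct score with the
#' classification rule `score >= threshold -> positive`; the curve is
#' anchored at (0,0) and ends at (1,1), and the AUC is the trapezoidal
#' area, which equals the Mann-Whitney probability that a random positive
#' outscores a random negative (ties counted 1/2).
#'
#' @param scores numeric scores (here: FD values); higher = more likely
#'   positive.
#' @param labels binary labels aligned with `scores` (1 = positive =
#'   sufficient quality).
#' @return an object of class `roc_curve`: data.frame `points`
#'   (threshold, fpr, tpr, ...) and scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pts <- curve_points(scores, labels)
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Precision-recall curve and area under it
#'
#' Same operating points as [roc_curve()]; the AUC-PR is the trapezoidal
#' area in recall order, anchored at recall 0 with the precision of the
#' strictest threshold.
#'
#' @inheritParams roc_curve
#' @return an object of class `pr_curve`: data.frame `points` and scalar
#'   `auc`.
#' @export
pr_curve <- function(scores, labels) {
  pts <- curve_points(scores, labels, require_both = FALSE)
  rec <- c(0, pts$recall)
  prec <- c(pts$precision[1], pts$precision)
  auc <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "pr_curve")
}

#' Optimal operating threshold of a classification curve
#'
#' For a ROC curve the cutoff maximizes Youden's J (`TPR - FPR`); for a
#' PR curve it maximizes F1 (`2PR/(P+R)`). Ties are broken toward the
#' larger threshold (the stricter rule).
#'
#' @param curve a `roc_curve` or `pr_curve`.
#' @return the optimal threshold (a score value).
#' @export
optimal_cutoff <- function(curve) {
  pts <- curve$points
  crit <- if (inherits(curve, "roc_curve")) {
    pts$tpr - pts$fpr
  } else if (inherits(curve, "pr_curve")) {
    p <- pts$precision; r <- pts$recall
    ifelse(is.nan(p) | p + r == 0, 0, 2 * p * r / (p + r))
  } else stop("curve must be a roc_curve or pr_curve")
  best <- which(crit == max(crit))
  max(pts$threshold[best])
}

#' Group summary and two-group comparison of FD values
#'
#' Reports each group's mean with a t-based 95% confidence interval
#' (`mean +/- t(0.975, n-1) * SE`), and for two groups a Welch
#' independent-sample t-test with significance declared at p < 0.001.
#'
#' @param x numeric vector, first group (n >= 2).
#' @param y optional numeric vector, second group (n >= 2).
#' @param conf confidence level, default 0.95.
#' @return list with per-group `mean`, `ci` (lower, upper), `n`; and for
#'   two groups `p_value`, `t_statistic`, `significant` (p < 0.001).
#' @export
group_stats <- function(x, y = NULL, conf = 0.95) {
  one <- function(v) {
    if (length(v) < 2) stop("each group needs n >= 2")
    n <- length(v); m <- mean(v)
    half <- qt(1 - (1 - conf) / 2, n - 1) * sd(v) / sqrt(n)
    list(mean = m, ci = c(m - half, m + half), n = n)
  }
  out <- list(group1 = one(x))
  if (!is.null(y)) {
    out$group2 <- one(y)
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      out$t_statistic <- 0; out$p_value <- 1   # degenerate: no variance
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    }
    out$significant <- out$p_value < 0.001
  }
  out
}

#' Evaluate a table of scored, labeled images
#'
#' Convenience wrapper computing both curves, AUCs and optimal cutoffs
#' from a data.frame with `fd` and binary `label` columns (1 =
#' sufficient quality).
#'
#' @param df data.frame with numeric `fd` and 0/1 `label`.
#' @return list with `roc`, `pr`, `auc_roc`, `auc_pr`, `cutoff_roc`,
#'   `cutoff_pr`, and `group_stats` comparing positive vs negative FDs.
#' @export
evaluate_scores <- function(df) {
  stopifnot(all(c("fd", "label") %in% names(df)))
  roc <- roc_curve(df$fd, df$label)
  pr <- pr_curve(df$fd, df$label)
  gs <- if (sum(df$label == 1) >= 2 && sum(df$label == 0) >= 2)
    group_stats(df$fd[df$label == 1], df$fd[df$label == 0]) else NULL
  list(roc = roc, pr = pr, auc_roc = roc$auc, auc_pr = pr$auc,
       cutoff_roc = optimal_cutoff(roc), cutoff_pr = optimal_cutoff(pr),
       group_stats = gs)
}
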