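#' Leave-one-out cross-validation scores
#'
#' For each case the entire pipeline — PCA, root gate threshold, feature
#' selection, SVM training and calibration — is refitted on the other
#' n - 1 cases and the held-out case is scored.  Nothing fitted ever
#' sees its own test case.
#'
#' @param x n x 26 feature matrix or feature-table data frame.
#' @param y class labels (taken from the `label` column if missing).
#' @param trainer `"cascade"`, `"baseline"`, or a function
#'   `function(x, y, config)` returning an object with a `predict`
#'   method.
#' @param config a [cascade_config()].
#' @param case_ids optional case identifiers.
#' @return data frame of class `loocv_result` with columns `case_id`,
#'   `label`, `P`, `P1`, `P2` (`P1`/`P2` are `NA` for models without a
#'   gate decomposition).
#' @export
loocv_scores <- function(x, y = NULL, trainer = c("cascade", "baseline"),
                         config = cascade_config(), case_ids = NULL) {
  d <- as_feature_matrix(x, y)
  if (is.null(d$y)) stop("labels are required")
  n <- nrow(d$x)
  if (n < 8) stop("need at least 8 cases for LOOCV")
  if (is.null(case_ids)) {
    case_ids <- if (is.data.frame(x) && "case_id" %in% names(x))
      as.character(x$case_id) else sprintf("case_%03d", seq_len(n))
  }
  fit_fun <- if (is.function(trainer)) trainer else
    switch(match.arg(trainer), cascade = fit_cascade, baseline = fit_baseline)
  P <- P1 <- P2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ytr <- d$y[-i]
    if (length(unique(ytr)) != 2)
      stop("fold ", i, " loses one class entirely")
    m <- fit_fun(d$x[-i, , drop = FALSE], ytr, config)
    if (inherits(m, "cascade_model")) {
      pr <- predict(m, d$x[i, , drop = FALSE], type = "parts")
      P[i] <- pr$P; P1[i] <- pr$P1; P2[i] <- pr$P2
    } else {
      P[i] <- predict(m, d$x[i, , drop = FALSE])
    }
  }
  structure(data.frame(case_id = case_ids, label = d$y, P = P, P1 = P1,
                       P2 = P2, stringsAsFactors = FALSE),
            class = c("loocv_result", "data.frame"))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC with ties counted one half; the positive class is
#' SPCH by default.
#'
#' @param scores numeric scores (larger favours the positive class).
#' @param labels class labels.
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "SPCH") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes required")
  r <- rank(scores)
  npos <- sum(pos)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * sum(!pos))
}

#' Empirical ROC curve points
#'
#' All distinct score values serve as thresholds (prediction rule:
#' score > threshold); the curve includes the (0,0) and (1,1)
#' endpoints.
#'
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels, positive = "SPCH") {
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(t) {
    pred <- scores > t
    c(sensitivity = mean(pred[pos]), specificity = mean(!pred[!pos]))
  }, numeric(2)))
  data.frame(threshold = thr, sensitivity = pts[, 1],
             specificity = pts[, 2])
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predicted positive iff `score > threshold` (strict, so gate-rejected
#' cases with score exactly 0 are always negative at threshold 0.5).
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @return named vector: `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, plus raw counts `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5,
                              positive = "SPCH") {
  pos <- labels == positive
  pred <- scores > threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(pos),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param A area under the curve.
#' @param n_pos,n_neg class sizes.
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(A, n_pos, n_neg) {
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
          (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg))
}

#' Compare two correlated AUCs (Hanley-McNeil z-test)
#'
#' Both score sets must be measured on the same cases.  The correlation
#' term `r` between the two AUC estimates is looked up from the
#' tabulated binormal-model values ([hm_r_lookup()]) indexed by the mean
#' AUC and the average of the within-class Spearman correlations between
#' the two score sets; `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 -
#' 2 r SE1 SE2)` with a two-sided normal p-value.  The degenerate 0/0
#' case (identical AUCs and fully correlated scores) is reported as no
#' difference (`z = 0`, `p = 1`).
#'
#' @param scores1,scores2 two score sets over the same cases.
#' @param labels class labels.
#' @param positive positive class label.
#' @return list of class `auc_comparison`: `A1`, `A2`, `SE1`, `SE2`,
#'   `Q1`, `Q2` per model, `r_within`, `r`, `z`, `p`.
#' @export
compare_auc <- function(scores1, scores2, labels, positive = "SPCH") {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels))
    stop("score sets and labels must cover the same cases")
  pos <- labels == positive
  A1 <- roc_auc(scores1, labels, positive)
  A2 <- roc_auc(scores2, labels, positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  SE1 <- hanley_mcneil_se(A1, n_pos, n_neg)
  SE2 <- hanley_mcneil_se(A2, n_pos, n_neg)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b, method = "spearman")
  }
  r_within <- (safe_cor(scores1[pos], scores2[pos]) +
                 safe_cor(scores1[!pos], scores2[!pos])) / 2
  r <- hm_r_lookup((A1 + A2) / 2, r_within)
  denom2 <- SE1^2 + SE2^2 - 2 * r * SE1 * SE2
  if (denom2 <= 0 || (A1 == A2 && denom2 == 0)) {
    z <- 0; p <- 1
  } else {
    z <- (A1 - A2) / sqrt(denom2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(A1 = A1, A2 = A2, SE1 = SE1, SE2 = SE2,
                 Q1 = c(A1 / (2 - A1), A2 / (2 - A2)),
                 Q2 = c(2 * A1^2 / (1 + A1), 2 * A2^2 / (1 + A2)),
                 r_within = r_within, r = r, z = z, p = p,
                 n_pos = n_pos, n_neg = n_neg),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("Correlated AUC comparison (Hanley-McNeil)\n")
  cat(sprintf("  A1 = %.4f (SE %.4f)   A2 = %.4f (SE %.4f)\n",
              x$A1, x$SE1, x$A2, x$SE2))
  cat(sprintf("  within-class rank correlation = %.3f -> r = %.3f\n",
              x$r_within, x$r))
  cat(sprintf("  z = %.3f, two-sided p = %.4f\n", x$z, x$p))
  invisible(x)
}

#' ROC summary of a score set
#'
#' @inheritParams confusion_metrics
#' @return list of class `roc_summary`: `auc`, `curve`, `threshold`,
#'   and the confusion metrics at that threshold.
#' @export
roc_summary <- function(scores, labels, threshold = 0.5,
                        positive = "SPCH") {
  m <- confusion_metrics(scores, labels, threshold, positive)
  structure(list(auc = roc_auc(scores, labels, positive),
                 curve = roc_curve(scores, labels, positive),
                 threshold = threshold, metrics = m),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC = %.4f\n", x$auc))
  cat(sprintf("At threshold %.3g: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$threshold, 100 * x$metrics["sensitivity"],
              100 * x$metrics["specificity"], 100 * x$metrics["accuracy"]))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a [roc_summary()] object.
#' @param ... passed to [plot()].
#' @export
plot.roc_summary <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
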