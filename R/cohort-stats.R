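#' Levene's test for homogeneity of variance (two samples)
#'
#' Classic mean-centred Levene test: a one-way ANOVA F statistic on the
#' absolute deviations from the group means, referred to
#' `F(1, n1 + n2 - 2)`.  Two degenerate all-constant samples give
#' `W = 0, p = 1` by convention.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list with `W` and `p`.
#' @export
levene_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  if (stats::sd(z) == 0) return(list(W = 0, p = 1))
  fit <- stats::anova(stats::lm(z ~ g))
  list(W = unname(fit[["F value"]][1]), p = unname(fit[["Pr(>F)"]][1]))
}

#' Two-sample group summary
#'
#' @param n sample size (>= 2).
#' @param mean group mean.
#' @param sd sample standard deviation (divide-by-(n-1)).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled variant: `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2)/(n1+n2-2)`,
#' `df = n1+n2-2`.  Welch variant: `SE^2 = s1^2/n1 + s2^2/n2` with
#' Welch-Satterthwaite degrees of freedom.  Two-sided p from the t
#' distribution.  Two groups with zero spread and equal means give
#' `t = 0, p = 1`; zero spread with unequal means is an error.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`,
#'   `sd`).
#' @param variant `"pooled"` or `"welch"`.
#' @return list of class `test_result`: `t`, `df`, `p`, `variant`.
#' @export
ttest_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- g1$n; n2 <- g2$n; s1 <- g1$sd; s2 <- g2$sd
  delta <- g1$mean - g2$mean
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0)
      (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    if (delta != 0) stop("zero standard error with unequal means")
    return(structure(list(t = 0, df = df, p = 1, variant = variant),
                     class = "test_result"))
  }
  t <- delta / se
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 variant = variant),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4f, df = %.2f, p = %.4g",
              x$variant, x$t, x$df, x$p))
  if (!is.null(x$levene_p)) cat(sprintf(" (Levene p = %.3g)", x$levene_p))
  cat("\n")
  invisible(x)
}

#' Per-feature univariate comparison report
#'
#' For each of the 26 features: group mean and sample SD, Levene's test
#' on the raw data, then the pooled t-test when Levene's p >= 0.05 and
#' the Welch t-test otherwise; two-sided p with significance flags at
#' alpha = 0.05 (uncorrected, matching the reporting convention of the
#' reference cohort).
#'
#' @param x feature table (data frame with the 26 canonical feature
#'   columns) or numeric matrix.
#' @param y class labels (taken from the `label` column if missing).
#' @param positive group reported first (default `"SPCH"`).
#' @param alpha significance level for the flags.
#' @return data frame of class `feature_report`, 26 rows in canonical
#'   order: `feature`, `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`,
#'   `levene_p`, `variant`, `t`, `df`, `p`, `significant`.
#' @export
feature_table_report <- function(x, y = NULL, positive = "SPCH",
                                 alpha = 0.05) {
  d <- as_feature_matrix(x, y)
  if (is.null(d$y)) stop("labels are required")
  pos <- d$y == positive
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("both groups need n >= 2")
  feats <- intersect(feature_names(), colnames(d$x))
  if (length(feats) == 0) feats <- colnames(d$x)
  rows <- lapply(feats, function(f) {
    a <- d$x[pos, f]; b <- d$x[!pos, f]
    lev <- levene_test(a, b)
    variant <- if (lev$p < alpha) "welch" else "pooled"
    tt <- ttest_from_summary(group_summary(length(a), mean(a), stats::sd(a)),
                             group_summary(length(b), mean(b), stats::sd(b)),
                             variant = variant)
    data.frame(feature = f, mean_pos = mean(a), sd_pos = stats::sd(a),
               mean_neg = mean(b), sd_neg = stats::sd(b),
               levene_p = lev$p, variant = variant, t = tt$t, df = tt$df,
               p = tt$p, significant = tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("feature_report", "data.frame"))
}

#' Published reference cohort feature summaries
#'
#' The per-feature group summaries (n, mean, sample SD) and reported
#' p-values of the 13-SPCH / 49-LPA clinical reference cohort this
#' package is modelled on, shipped as a plain-text table.  Useful for
#' reproducing the reported univariate p-values from summary statistics
#' via [ttest_from_summary()].
#'
#' @return data frame: `feature`, `n_spch`, `mean_spch`, `sd_spch`,
#'   `n_lpa`, `mean_lpa`, `sd_lpa`, `p_reported`.
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "reference_cohort_summaries.csv",
                      package = "radiocascade")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
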