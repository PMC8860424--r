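#' Weighted linear support-vector classifier
#'
#' The margin classifier used at every node of the cascade and in the
#' baseline model: a linear-kernel soft-margin SVM solved by
#' deterministic dual coordinate descent (fixed pseudo-random visiting
#' order, warm-startable), with per-class misclassification costs.  Features are standardised
#' internally (training mean/sd); constant columns are left unscaled.
#'
#' Class weights default to `"balanced"`, i.e. inversely proportional to
#' class frequencies (`n / (2 * n_k)`), which keeps the minority class
#' from being swamped at 13:49 imbalance.
#'
#' @param x numeric matrix (rows = cases).
#' @param y vector of class labels with exactly two distinct values.
#' @param positive label of the positive class; decision values are
#'   oriented so larger values favour this class.
#' @param cost soft-margin cost parameter C.
#' @param class_weights `"balanced"`, `"none"`, or a named numeric
#'   vector of per-class multipliers of `cost`.
#' @return object of class `linear_svm` with elements `w`, `b` (on the
#'   standardised scale), `center`, `scale`, `levels`, `positive`.
#' @seealso [predict.linear_svm()]
#' @export
linear_svm <- function(x, y, positive, cost = 1, class_weights = "balanced") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2L)
    stop("linear_svm requires exactly two classes, got ", length(lev))
  if (!positive %in% lev)
    stop("positive class '", positive, "' not present in y")
  yy <- ifelse(y == positive, 1, -1)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")

  Cvec <- svm_case_costs(yy, cost, class_weights, lev, positive)
  fit <- .svm_dcd_fit(xs, yy, Cvec)
  structure(list(w = as.numeric(fit$w), b = fit$b, alpha = fit$alpha,
                 center = ctr, scale = scl, levels = lev,
                 positive = positive, cost = cost,
                 class_weights = class_weights),
            class = "linear_svm")
}

svm_case_costs <- function(yy, cost, class_weights, lev, positive) {
  n <- length(yy)
  npos <- sum(yy > 0)
  nneg <- n - npos
  if (identical(class_weights, "balanced")) {
    wpos <- n / (2 * npos)
    wneg <- n / (2 * nneg)
  } else if (identical(class_weights, "none")) {
    wpos <- wneg <- 1
  } else {
    if (is.null(names(class_weights)))
      stop("class_weights must be 'balanced', 'none' or a named vector")
    wpos <- class_weights[[positive]]
    wneg <- class_weights[[setdiff(lev, positive)]]
  }
  ifelse(yy > 0, cost * wpos, cost * wneg)
}

#' Decision values or class predictions from a linear SVM
#'
#' @param object a [linear_svm()] fit.
#' @param newdata numeric matrix with the training column layout.
#' @param type `"decision"` (default) for signed decision values
#'   oriented toward the positive class, or `"class"`.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, type = c("decision", "class"),
                               ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$w))
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  d <- drop(xs %*% object$w) + object$b
  if (type == "decision") return(d)
  ifelse(d > 0, object$positive, setdiff(object$levels, object$positive))
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM (dual coordinate descent)\n")
  cat("  features:", length(x$w), " cost:", x$cost,
      " positive class:", x$positive, "\n")
  invisible(x)
}

# Leave-one-out balanced accuracy of the linear SVM on (x, y): the SFS
# wrapper criterion.  Standardisation is computed once on the full
# provided set; each LOO refit is warm-started in C++.
loo_balanced_accuracy <- function(x, y, positive, cost = 1,
                                  class_weights = "balanced") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  lev <- unique(y)
  yy <- ifelse(y == positive, 1, -1)
  xs <- standardize_columns(x)
  Cvec <- svm_case_costs(yy, cost, class_weights, lev, positive)
  loo_balacc_raw(xs, yy, Cvec)
}

standardize_columns <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
}

# criterion on a pre-standardised matrix (no per-call scaling); the
# selection criterion tolerates a looser dual solve than the final fits
loo_balacc_raw <- function(xs, yy, Cvec) {
  dec <- .svm_dcd_loo(xs, yy, Cvec, max_pass = 100, tol = 2e-2)
  pred_pos <- dec > 0
  (mean(pred_pos[yy > 0]) + mean(!pred_pos[yy < 0])) / 2
}
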