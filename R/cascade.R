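#' Cascade model configuration
#'
#' Settings for [fit_cascade()] and [fit_baseline()].  The margin
#' classifier at every node is a linear-kernel SVM with cost 1 and class
#' weights inversely proportional to class frequencies; all of this is
#' adjustable here.
#'
#' @param cost SVM soft-margin cost.
#' @param class_weights `"balanced"`, `"none"`, or named numeric.
#' @param positive positive (minority) class label, default `"SPCH"`.
#' @param standardized_pca if `TRUE`, the root PCA standardises features
#'   first; the default operates on raw (unstandardised) features, so
#'   large-scale features dominate the leading components.
#' @param soft_gate if `TRUE`, `P1` is the calibrated root probability
#'   instead of the hard 0/1 gate.
#' @param leaf_all_cases if `TRUE`, the leaf is trained on all cases,
#'   not only those the root forwards.
#' @param k_leaf number of leaf features (default 2).
#' @param k_baseline `c(min, max)` features for the baseline (default
#'   3 to 6).
#' @param seed recorded for provenance; all fits are deterministic.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(cost = 1, class_weights = "balanced",
                           positive = "SPCH", standardized_pca = FALSE,
                           soft_gate = FALSE, leaf_all_cases = FALSE,
                           k_leaf = 2, k_baseline = c(3, 6), seed = 1) {
  structure(list(cost = cost, class_weights = class_weights,
                 positive = positive,
                 standardized_pca = isTRUE(standardized_pca),
                 soft_gate = isTRUE(soft_gate),
                 leaf_all_cases = isTRUE(leaf_all_cases),
                 k_leaf = as.integer(k_leaf),
                 k_baseline = as.integer(k_baseline),
                 seed = as.integer(seed)),
            class = "cascade_config")
}

#' Two-component principal component analysis
#'
#' PCA of the training feature matrix retaining the two components with
#' the largest eigenvalues.  By default the features are centred but not
#' standardised, so the leading components follow the large-scale
#' features that dominate raw variance.
#'
#' @param x numeric matrix, n >= 3 rows.
#' @param standardize scale columns to unit variance first.
#' @return list with `mean`, `scale`, `loadings` (2 x p, orthonormal
#'   rows) and `explained_fraction`.
#' @export
fit_pca2 <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 cases")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("rank-0 input: all features constant")
  scl <- if (standardize) ifelse(sds > 0, sds, 1) else rep(1, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = if (standardize) scl else FALSE)
  ev <- pc$sdev^2
  list(mean = pc$center, scale = scl,
       loadings = t(pc$rotation[, 1:2, drop = FALSE]),
       explained_fraction = sum(ev[1:2]) / sum(ev))
}

pca2_scores <- function(pca, x) {
  x <- matrix(as.numeric(as.matrix(x)), ncol = length(pca$mean))
  xs <- sweep(sweep(x, 2, pca$mean, "-"), 2, pca$scale, "/")
  xs %*% t(pca$loadings)
}

#' Root-gate threshold sweep
#'
#' Given decision values oriented toward the positive class, sweeps the
#' threshold over all candidate cuts for which every positive training
#' case stays strictly on the forward side, and picks the cut that
#' removes ("picks out") the most negatives — equivalently maximises the
#' positive predictive value of the forwarded set under the 100%
#' training-sensitivity constraint.  A negative that ties the positive
#' extremum is forwarded, never picked out.
#'
#' @param dec numeric decision values.
#' @param labels class labels.
#' @param positive positive class label.
#' @return list with `tau` (cases with `dec < tau` are picked out),
#'   `n_picked`, `forwarded_ppv`.
#' @export
root_threshold <- function(dec, labels, positive) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes required")
  tau <- min(dec[pos])
  picked <- dec < tau
  fwd <- !picked
  list(tau = tau, n_picked = sum(picked),
       forwarded_ppv = sum(pos[fwd]) / sum(fwd))
}

#' Fit the PCA-gated root node
#'
#' Trains the margin classifier on the 2 PC scores and sets the gate
#' threshold by [root_threshold()].
#'
#' @param pc_scores n x 2 score matrix.
#' @param labels class labels (both classes present).
#' @param config a [cascade_config()].
#' @return list of class `root_model` with the SVM, `tau`, and gate
#'   statistics.
#' @export
fit_root <- function(pc_scores, labels, config = cascade_config()) {
  if (length(unique(labels)) != 2) stop("both classes required at the root")
  svm <- linear_svm(pc_scores, labels, positive = config$positive,
                    cost = config$cost, class_weights = config$class_weights)
  dec <- predict(svm, pc_scores)
  thr <- root_threshold(dec, labels, config$positive)
  calib <- platt_calibration(dec, labels == config$positive)
  structure(list(svm = svm, tau = thr$tau, n_picked = thr$n_picked,
                 forwarded_ppv = thr$forwarded_ppv, calibration = calib),
            class = "root_model")
}

# Platt-type sigmoid calibration of decision values: fits
# p(positive | f) = 1 / (1 + exp(A f + B)) by regularised maximum
# likelihood (smoothed targets), deterministic BFGS from a fixed start.
# A is clamped to <= 0 so the map is monotone non-decreasing in f.
platt_calibration <- function(dec, is_pos) {
  npos <- sum(is_pos)
  nneg <- sum(!is_pos)
  t_pos <- (npos + 1) / (npos + 2)
  t_neg <- 1 / (nneg + 2)
  tt <- ifelse(is_pos, t_pos, t_neg)
  obj <- function(par) {
    z <- par[1] * dec + par[2]
    lp1 <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))   # -log p
    lp0 <- ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))  # -log(1-p)
    sum(tt * lp1 + (1 - tt) * lp0)
  }
  start <- c(A = 0, B = log((nneg + 1) / (npos + 1)))
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  A <- min(fit$par[1], 0)
  B <- if (A == fit$par[1]) fit$par[2] else
    stats::optim(c(B = start[2]), function(b) obj(c(0, b)),
                 method = "BFGS")$par[1]
  list(A = unname(A), B = unname(B))
}

platt_apply <- function(calib, dec) {
  1 / (1 + exp(calib$A * dec + calib$B))
}

# gate comparison with a relative tie guard: a case whose decision value
# equals the threshold (the training SPCH minimum) is always forwarded,
# and serialisation round-off cannot flip it
gate_forward <- function(dec, tau) {
  dec >= tau - 1e-8 * max(1, abs(tau))
}

#' Sequential forward feature selection
#'
#' Plain greedy forward selection with a wrapper criterion: the
#' leave-one-out balanced accuracy of the margin classifier within the
#' provided training set.  Selection grows until `k_max` features, or —
#' once at least `k_min` are selected — until no candidate strictly
#' improves the criterion.  Ties are broken in favour of the earlier
#' feature in canonical column order.
#'
#' @param x feature matrix with named columns.
#' @param labels class labels (both classes present).
#' @param k_min,k_max selection size bounds.
#' @param config a [cascade_config()].
#' @return character vector of selected feature names, in selection
#'   order.
#' @export
sfs_select <- function(x, labels, k_min = 2, k_max = 2,
                       config = cascade_config()) {
  x <- as.matrix(x)
  if (length(unique(labels)) != 2) stop("both classes required")
  if (k_min < 1 || k_max > ncol(x) || k_min > k_max)
    stop("invalid k_min/k_max")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("f", seq_len(ncol(x)))
  yy <- ifelse(as.character(labels) == config$positive, 1, -1)
  Cvec <- svm_case_costs(yy, config$cost, config$class_weights,
                         unique(as.character(labels)), config$positive)
  xs <- standardize_columns(x)   # scaling is per-column, subset-free
  selected <- integer(0)
  best_crit <- -Inf
  repeat {
    cand <- setdiff(seq_len(ncol(x)), selected)
    if (length(cand) == 0 || length(selected) >= k_max) break
    crit <- vapply(cand, function(j) {
      loo_balacc_raw(xs[, c(selected, j), drop = FALSE], yy, Cvec)
    }, numeric(1))
    j_best <- cand[which.max(crit)]   # which.max keeps the first tie
    c_best <- max(crit)
    if (length(selected) >= k_min && c_best <= best_crit) break
    selected <- c(selected, j_best)
    best_crit <- max(best_crit, c_best)
  }
  nms[selected]
}

#' Fit the two-level cascade classifier
#'
#' The divide-and-conquer SPCH--LPA model: a root gate (two-component
#' PCA of all 26 features plus a margin classifier whose threshold is
#' set to pick out as many negatives as possible while forwarding every
#' training positive), followed by a leaf node (two features chosen by
#' [sfs_select()], a margin classifier, and Platt calibration) trained
#' on the forwarded cases only.  The predicted score is
#' `P = P1 * P2` with the hard gate `P1` in `{0, 1}` and the calibrated
#' leaf probability `P2` in `[0, 1]`.
#'
#' @param x n x 26 feature matrix or a feature-table data frame (the
#'   `label` column is then used when `y` is missing).
#' @param y class labels.
#' @param config a [cascade_config()].
#' @return object of class `cascade_model`.
#' @seealso [predict.cascade_model()], [fit_baseline()]
#' @export
fit_cascade <- function(x, y = NULL, config = cascade_config()) {
  d <- as_feature_matrix(x, y)
  if (nrow(d$x) < 8) stop("need at least 8 training cases")
  if (length(unique(d$y)) != 2) stop("both classes required")
  pca <- fit_pca2(d$x, standardize = config$standardized_pca)
  scores <- pca2_scores(pca, d$x)
  root <- fit_root(scores, d$y, config)
  dec <- predict(root$svm, scores)
  fwd <- gate_forward(dec, root$tau)
  leaf_x <- if (config$leaf_all_cases) d$x else d$x[fwd, , drop = FALSE]
  leaf_y <- if (config$leaf_all_cases) d$y else d$y[fwd]
  if (length(unique(leaf_y)) != 2)
    stop("all training negatives picked out at the root: ",
         "leaf node has a single class")
  feats <- sfs_select(leaf_x, leaf_y, k_min = config$k_leaf,
                      k_max = config$k_leaf, config = config)
  leaf_svm <- linear_svm(leaf_x[, feats, drop = FALSE], leaf_y,
                         positive = config$positive, cost = config$cost,
                         class_weights = config$class_weights)
  leaf_dec <- predict(leaf_svm, leaf_x[, feats, drop = FALSE])
  calib <- platt_calibration(leaf_dec, leaf_y == config$positive)
  structure(list(pca = pca, root = root,
                 leaf = list(selected_features = feats, svm = leaf_svm,
                             calibration = calib),
                 feature_names = colnames(d$x), config = config,
                 n_train = nrow(d$x), n_forwarded = sum(fwd)),
            class = "cascade_model")
}

#' Predict SPCH probabilities from a cascade model
#'
#' @param object a [fit_cascade()] model.
#' @param newdata feature matrix / data frame with the training columns.
#' @param type `"prob"` for the final score `P`, `"parts"` for a data
#'   frame with `P`, `P1`, `P2`.
#' @param ... unused.
#' @export
predict.cascade_model <- function(object, newdata, type = c("prob", "parts"),
                                  ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)$x[, object$feature_names, drop = FALSE]
  scores <- pca2_scores(object$pca, x)
  dec <- predict(object$root$svm, scores)
  p1 <- if (object$config$soft_gate)
    platt_apply(object$root$calibration, dec)
  else as.numeric(gate_forward(dec, object$root$tau))
  leaf_dec <- predict(object$leaf$svm,
                      x[, object$leaf$selected_features, drop = FALSE])
  p2 <- platt_apply(object$leaf$calibration, leaf_dec)
  p <- p1 * p2
  if (type == "prob") p else data.frame(P = p, P1 = p1, P2 = p2)
}

#' Fit the single-stage baseline classifier
#'
#' Sequential forward selection of 3--6 features on all training cases,
#' one margin classifier, Platt calibration.  `predict` returns the
#' calibrated probability of the positive class.
#'
#' @inheritParams fit_cascade
#' @return object of class `baseline_model`.
#' @export
fit_baseline <- function(x, y = NULL, config = cascade_config()) {
  d <- as_feature_matrix(x, y)
  if (nrow(d$x) < 8) stop("need at least 8 training cases")
  if (length(unique(d$y)) != 2) stop("both classes required")
  feats <- sfs_select(d$x, d$y, k_min = config$k_baseline[1],
                      k_max = config$k_baseline[2], config = config)
  svm <- linear_svm(d$x[, feats, drop = FALSE], d$y,
                    positive = config$positive, cost = config$cost,
                    class_weights = config$class_weights)
  dec <- predict(svm, d$x[, feats, drop = FALSE])
  calib <- platt_calibration(dec, d$y == config$positive)
  structure(list(selected_features = feats, svm = svm, calibration = calib,
                 feature_names = colnames(d$x), config = config,
                 n_train = nrow(d$x)),
            class = "baseline_model")
}

#' @rdname fit_baseline
#' @param object a `baseline_model`.
#' @param newdata feature matrix / data frame.
#' @param ... unused.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)$x[, object$feature_names, drop = FALSE]
  dec <- predict(object$svm, x[, object$selected_features, drop = FALSE])
  platt_apply(object$calibration, dec)
}

# Accept a plain matrix, a matrix-like data frame, or a feature table
# with case_id/label columns.
as_feature_matrix <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (is.null(y) && "label" %in% names(x)) y <- x$label
    x <- x[, setdiff(names(x), c("case_id", "label")), drop = FALSE]
    x <- as.matrix(x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = if (is.null(y)) NULL else as.character(y))
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("Two-level cascade classifier (positive class:",
      x$config$positive, ")\n")
  cat("  root: PCA-2 gate, explained fraction",
      sprintf("%.4f", x$pca$explained_fraction),
      "| picked out", x$root$n_picked, "of", x$n_train, "training cases\n")
  cat("  leaf:", paste(x$leaf$selected_features, collapse = " + "),
      "on", x$n_forwarded, "forwarded cases\n")
  invisible(x)
}

#' @export
summary.cascade_model <- function(object, ...) {
  out <- list(explained_fraction = object$pca$explained_fraction,
              tau = object$root$tau, n_picked = object$root$n_picked,
              forwarded_ppv = object$root$forwarded_ppv,
              leaf_features = object$leaf$selected_features,
              n_train = object$n_train, n_forwarded = object$n_forwarded)
  class(out) <- "summary.cascade_model"
  out
}

#' @export
print.summary.cascade_model <- function(x, ...) {
  cat("Cascade model summary\n")
  cat("  PCA-2 explained variance fraction:",
      sprintf("%.4f", x$explained_fraction), "\n")
  cat("  root gate: tau =", signif(x$tau, 5), "| picked out", x$n_picked,
      "cases | forwarded-set PPV =", sprintf("%.3f", x$forwarded_ppv), "\n")
  cat("  leaf features:", paste(x$leaf_features, collapse = ", "), "\n")
  cat("  training cases:", x$n_train, "(", x$n_forwarded, "forwarded )\n")
  invisible(x)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Baseline SVM classifier (positive class:", x$config$positive, ")\n")
  cat("  selected features:", paste(x$selected_features, collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.cascade_model <- function(object, ...) {
  list(root = c(object$root$svm$w, intercept = object$root$svm$b),
       leaf = stats::setNames(c(object$leaf$svm$w,
                                intercept = object$leaf$svm$b),
                              c(object$leaf$selected_features, "intercept")))
}

#' Serialise a fitted model to plain-text JSON
#'
#' Writes all numeric parameters (PCA mean and loadings, SVM weights,
#' gate threshold, calibration, selected features, config echo) so the
#' model can be re-read and used for prediction without refitting.
#'
#' @param model a `cascade_model` or `baseline_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser <- rapply(unclass(model), identity, how = "list")
  ser$.class <- class(model)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- ser$.class
  ser$.class <- NULL
  fix_svm <- function(s) {
    s$w <- as.numeric(s$w); s$b <- as.numeric(s$b)
    s$center <- as.numeric(s$center); s$scale <- as.numeric(s$scale)
    class(s) <- "linear_svm"
    s
  }
  if ("cascade_model" %in% cls) {
    if (!is.matrix(ser$pca$loadings))
      ser$pca$loadings <- do.call(rbind, lapply(ser$pca$loadings, as.numeric))
    ser$pca$loadings <- matrix(as.numeric(ser$pca$loadings), nrow = 2)
    ser$pca$mean <- as.numeric(ser$pca$mean)
    ser$pca$scale <- as.numeric(ser$pca$scale)
    ser$root$svm <- fix_svm(ser$root$svm)
    class(ser$root) <- "root_model"
    ser$leaf$svm <- fix_svm(ser$leaf$svm)
  } else {
    ser$svm <- fix_svm(ser$svm)
  }
  class(ser$config) <- "cascade_config"
  structure(ser, class = cls)
}
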