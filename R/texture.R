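#' Feature-extraction settings
#'
#' Quantization and convention settings for [extract_features()].  The
#' histogram and GLCM channels are quantized independently: histogram
#' features use a fine 256-level scale (so percentiles land on a
#' familiar 8-bit-like range), GLCM features a coarser 32-level scale
#' that keeps the co-occurrence matrix well populated at lesion sizes of
#' a few hundred to a few thousand voxels.
#'
#' @param window HU window `c(lo, hi)`; intensities are clipped to it
#'   before level mapping.
#' @param hist_levels grey levels for the histogram channel.
#' @param glcm_levels grey levels for the GLCM channel.
#' @param log_base logarithm base for all entropy-type features
#'   (default natural log).
#' @param percentile_type quantile interpolation type passed to
#'   [stats::quantile()] (default 7: linear interpolation between order
#'   statistics).
#' @param glcm_fallback if `TRUE`, a lesion with no horizontally
#'   adjacent in-mask voxel pair gets a degenerate diagonal GLCM built
#'   from its level histogram instead of an error.
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(window = c(-1000, 400), hist_levels = 256,
                              glcm_levels = 32, log_base = exp(1),
                              percentile_type = 7, glcm_fallback = FALSE) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("degenerate window: need lo < hi")
  if (hist_levels < 2 || glcm_levels < 2)
    stop("need at least 2 grey levels")
  structure(list(window = as.numeric(window), hist_levels = as.integer(hist_levels),
                 glcm_levels = as.integer(glcm_levels), log_base = log_base,
                 percentile_type = as.integer(percentile_type),
                 glcm_fallback = isTRUE(glcm_fallback)),
            class = "extraction_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Quantize in-mask HU values to discrete grey levels
#'
#' Clips intensities to the HU window and maps them linearly onto
#' `1..n_levels` with round-half-up, a fully deterministic scheme.
#'
#' @param volume a [ct_volume()].
#' @param mask the aligned [lesion_mask()].
#' @param window HU window `c(lo, hi)`, `lo < hi`.
#' @param n_levels number of grey levels (>= 2).
#' @return list of class `quantized_lesion`: `levels` (integer array,
#'   defined everywhere but meaningful in-mask), `n_levels`, `mask`.
#' @export
rescale_to_levels <- function(volume, mask, window = c(-1000, 400),
                              n_levels = 32) {
  if (window[1] >= window[2]) stop("degenerate window: need lo < hi")
  if (n_levels < 2) stop("n_levels must be >= 2")
  x <- pmin(pmax(volume$voxels, window[1]), window[2])
  lev <- 1L + as.integer(round_half_up((x - window[1]) / (window[2] - window[1]) *
                                         (n_levels - 1)))
  structure(list(levels = array(lev, dim = dim(volume$voxels)),
                 n_levels = as.integer(n_levels), mask = mask),
            class = "quantized_lesion")
}

#' Histogram features of a quantized lesion
#'
#' Five first-order features of the in-mask grey-level distribution:
#' skewness `m3 / m2^(3/2)` and kurtosis `m4 / m2^2` (population central
#' moments, Pearson non-excess convention), the 75th and 97.5th
#' percentiles (linear interpolation between order statistics), and
#' uniformity, the sum of squared bin probabilities of the level
#' histogram.  A constant lesion yields skewness 0 and kurtosis 0 by
#' convention (the 0/0 limit is replaced by 0).
#'
#' @param quantized a [rescale_to_levels()] result.
#' @param percentile_type [stats::quantile()] type (default 7).
#' @return named numeric vector of the 5 histogram features.
#' @export
histogram_features <- function(quantized, percentile_type = 7) {
  v <- as.numeric(quantized$levels[quantized$mask$flags])
  if (length(v) == 0L) stop("empty sample")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  q <- stats::quantile(v, c(0.75, 0.975), type = percentile_type,
                       names = FALSE)
  counts <- tabulate(quantized$levels[quantized$mask$flags],
                     nbins = quantized$n_levels)
  p <- counts / sum(counts)
  c(skewness = skew, kurtosis = kurt, p75 = q[1], p975 = q[2],
    uniformity = sum(p^2))
}

#' Build the grey-level co-occurrence matrix of a lesion
#'
#' Co-occurrences are counted over all horizontally adjacent voxel pairs
#' (unit offset along the in-plane left-right axis, the first array
#' dimension) whose two voxels are both inside the lesion mask.
#' Accumulation is symmetric: each ordered pair contributes to both
#' `(i,j)` and `(j,i)`.  The matrix is normalised to joint probabilities
#' and returned with its marginals and the derived sum/difference
#' distributions.
#'
#' @param quantized a [rescale_to_levels()] result.
#' @param fallback if `TRUE`, a lesion with no valid pair gets a
#'   diagonal GLCM proportional to its level histogram (a single-cell
#'   matrix for a single-voxel or constant degenerate lesion) instead of
#'   an error.
#' @return list of class `glcm`: `p` (Ng x Ng), `Ng`, marginals `px`,
#'   `py`, moments `mux`, `muy`, `sigx`, `sigy`, distributions
#'   `p_sum` (k = 2..2Ng) and `p_diff` (k = 0..Ng-1), and `n_pairs`.
#' @export
build_glcm <- function(quantized, fallback = FALSE) {
  lev <- quantized$levels
  flg <- quantized$mask$flags
  ng <- quantized$n_levels
  n1 <- dim(lev)[1]
  counts <- matrix(0, ng, ng)
  if (n1 >= 2) {
    a <- lev[-n1, , , drop = FALSE]
    b <- lev[-1, , , drop = FALSE]
    ok <- flg[-n1, , , drop = FALSE] & flg[-1, , , drop = FALSE]
    ai <- a[ok]; bi <- b[ok]
    if (length(ai) > 0) {
      tab <- tabulate((ai - 1L) * ng + bi, nbins = ng * ng)
      counts <- matrix(tab, ng, ng, byrow = TRUE)
      counts <- counts + t(counts)     # symmetric accumulation
    }
  }
  n_pairs <- sum(counts) / 2
  if (n_pairs == 0) {
    if (!fallback)
      stop("no co-occurring pairs: lesion has no horizontally adjacent ",
           "in-mask voxels")
    h <- tabulate(lev[flg], nbins = ng)
    counts <- diag(h, nrow = ng)
  }
  glcm_from_counts(counts)
}

#' Build a GLCM object from a raw co-occurrence count matrix
#'
#' Normalises a square count matrix to joint probabilities and computes
#' marginals and the sum/difference distributions.  Used internally by
#' [build_glcm()]; exported for constructing small matrices directly.
#'
#' @param counts square non-negative matrix of pair counts.
#' @return a `glcm` object (see [build_glcm()]).
#' @export
glcm_from_counts <- function(counts) {
  ng <- nrow(counts)
  p <- counts / sum(counts)
  px <- rowSums(p)
  py <- colSums(p)
  i <- seq_len(ng)
  mux <- sum(i * px)
  muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px))
  sigy <- sqrt(sum((i - muy)^2 * py))
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  p_sum <- vapply(2:(2 * ng), function(k) sum(p[ii + jj == k]), numeric(1))
  names(p_sum) <- 2:(2 * ng)
  p_diff <- vapply(0:(ng - 1), function(k) sum(p[abs(ii - jj) == k]),
                   numeric(1))
  names(p_diff) <- 0:(ng - 1)
  structure(list(p = p, Ng = ng, px = px, py = py, mux = mux, muy = muy,
                 sigx = sigx, sigy = sigy, p_sum = p_sum, p_diff = p_diff,
                 n_pairs = sum(counts) / 2),
            class = "glcm")
}

xlogx_sum <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' The 21 GLCM texture features
#'
#' Haralick-family features with fixed conventions: correlation is 0
#' when either marginal is degenerate; difference variance is the
#' `sum((i-j)^2 p)` variant (identical to contrast); sum variance is
#' centred on sum average; information measures of correlation use
#' `imc1 = (HXY - HXY1)/max(HX, HY)` (0 when both marginal entropies
#' vanish) and `imc2 = sqrt(1 - exp(-2 (HXY2 - HXY)))` clipped to
#' `[0, 1]`; entropies default to natural log.
#'
#' @param glcm a [build_glcm()] result.
#' @param log_base base for entropy-type features.
#' @return named numeric vector of the 21 GLCM features.
#' @export
glcm_features <- function(glcm, log_base = exp(1)) {
  p <- glcm$p
  ng <- glcm$Ng
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM is not normalized")
  i <- seq_len(ng)
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  mux <- glcm$mux; muy <- glcm$muy
  sigx <- glcm$sigx; sigy <- glcm$sigy

  autocorrelation <- sum(ii * jj * p)
  contrast <- sum((ii - jj)^2 * p)
  correlation <- if (sigx * sigy > 0)
    (autocorrelation - mux * muy) / (sigx * sigy) else 0
  cluster_prominence <- sum((ii + jj - mux - muy)^4 * p)
  cluster_shade <- sum((ii + jj - mux - muy)^3 * p)
  dissimilarity <- sum(abs(ii - jj) * p)
  energy <- sum(p^2)
  entropy <- xlogx_sum(p, log_base)
  inverse_difference <- sum(p / (1 + abs(ii - jj)))
  inverse_difference_moment <- sum(p / (1 + (ii - jj)^2))
  maximum_probability <- max(p)
  mu <- sum(i * glcm$px)
  sum_of_squares_variance <- sum((i - mu)^2 * glcm$px)
  k_sum <- as.numeric(names(glcm$p_sum))
  sum_average <- sum(k_sum * glcm$p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * glcm$p_sum)
  sum_entropy <- xlogx_sum(glcm$p_sum, log_base)
  difference_variance <- contrast
  difference_entropy <- xlogx_sum(glcm$p_diff, log_base)

  HX <- xlogx_sum(glcm$px, log_base)
  HY <- xlogx_sum(glcm$py, log_base)
  pxpy <- outer(glcm$px, glcm$py)
  ok <- pxpy > 0
  HXY1 <- -sum(p[ok] * log(pxpy[ok], base = log_base))
  HXY2 <- xlogx_sum(pxpy, log_base)
  imc1 <- if (max(HX, HY) > 0) (entropy - HXY1) / max(HX, HY) else 0
  arg <- 1 - exp(-2 * (HXY2 - entropy))
  imc2 <- sqrt(min(max(arg, 0), 1))
  inverse_difference_normalized <- sum(p / (1 + abs(ii - jj) / ng))
  inverse_difference_moment_normalized <- sum(p / (1 + ((ii - jj) / ng)^2))

  c(autocorrelation = autocorrelation, contrast = contrast,
    correlation = correlation, cluster_prominence = cluster_prominence,
    cluster_shade = cluster_shade, dissimilarity = dissimilarity,
    energy = energy, entropy = entropy,
    inverse_difference = inverse_difference,
    inverse_difference_moment = inverse_difference_moment,
    maximum_probability = maximum_probability,
    sum_of_squares_variance = sum_of_squares_variance,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    inverse_difference_normalized = inverse_difference_normalized,
    inverse_difference_moment_normalized = inverse_difference_moment_normalized)
}

#' Extract the 26 radiomic features of one lesion
#'
#' Crops the volume of interest, quantizes the lesion twice (fine scale
#' for histogram features, coarse scale for the GLCM), and returns the
#' full named feature vector in canonical order ([feature_names()]).
#'
#' @param volume a [ct_volume()].
#' @param mask the aligned [lesion_mask()].
#' @param config an [extraction_config()].
#' @return named numeric vector of 26 features.
#' @export
extract_features <- function(volume, mask, config = extraction_config()) {
  voi <- extract_voi(volume, mask, margin = 2)
  qh <- rescale_to_levels(voi$volume, voi$mask, window = config$window,
                          n_levels = config$hist_levels)
  hf <- histogram_features(qh, percentile_type = config$percentile_type)
  qg <- rescale_to_levels(voi$volume, voi$mask, window = config$window,
                          n_levels = config$glcm_levels)
  g <- build_glcm(qg, fallback = config$glcm_fallback)
  gf <- glcm_features(g, log_base = config$log_base)
  out <- c(hf, gf)[feature_names()]
  stopifnot(all(is.finite(out)))
  out
}

#' Write / read a feature table
#'
#' Plain CSV with fixed header: `case_id`, `label`, then the 26
#' canonical feature names.
#'
#' @param x data frame with those columns.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_feature_table <- function(x, path) {
  cols <- c("case_id", "label", feature_names())
  if (!all(cols %in% names(x)))
    stop("feature table is missing columns: ",
         paste(setdiff(cols, names(x)), collapse = ", "))
  utils::write.csv(x[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("case_id", "label", feature_names())
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0)
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  x[, cols]
}
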