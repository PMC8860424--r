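#' Canonical radiomic feature names
#'
#' The 26 feature names computed by [extract_features()], in canonical
#' reporting order: 5 histogram features followed by 21 grey-level
#' co-occurrence matrix (GLCM) features.  All feature tables, model
#' serialisations and reports use this order.
#'
#' @param which `"all"`, `"histogram"` or `"glcm"`.
#' @return character vector of feature names.
#' @export
feature_names <- function(which = c("all", "histogram", "glcm")) {
  which <- match.arg(which)
  hist <- c("skewness", "kurtosis", "p75", "p975", "uniformity")
  glcm <- c("autocorrelation", "contrast", "correlation",
            "cluster_prominence", "cluster_shade", "dissimilarity",
            "energy", "entropy", "inverse_difference",
            "inverse_difference_moment", "maximum_probability",
            "sum_of_squares_variance", "sum_average", "sum_variance",
            "sum_entropy", "difference_variance", "difference_entropy",
            "imc1", "imc2", "inverse_difference_normalized",
            "inverse_difference_moment_normalized")
  switch(which, all = c(hist, glcm), histogram = hist, glcm = glcm)
}
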