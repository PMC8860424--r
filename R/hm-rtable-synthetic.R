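# Correlation term r for the Hanley-McNeil correlated-AUC z-test.
#
# The published lookup table is not redistributable here, so this is a
# SYNTHETIC reconstruction computed once by Monte-Carlo simulation under
# the binormal model the original table was derived from: two scores
# per case, bivariate normal within each class, both tests at the same
# true AUC.  Each cell is the simulated correlation between the two
# empirical (rank-based) AUC estimates; rows are indexed by the average
# within-class Spearman correlation of the two score sets, columns by
# the mean AUC.  4000 replicates of 50 + 50 cases per cell; rows were
# made monotone along the correlation axis (within simulation noise)
# and the zero-correlation row clamped to exactly 0.

.hm_srow <- c(0.000, 0.095, 0.187, 0.281, 0.378, 0.473, 0.572, 0.672,
              0.774, 0.881)
.hm_agrid <- c(0.5, 0.6, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 0.975)
.hm_rtab <- rbind(
  c(0.000, 0.000, 0.000, 0.000, 0.000, 0.000, 0.000, 0.000, 0.000),
  c(0.124, 0.082, 0.088, 0.079, 0.088, 0.081, 0.048, 0.039, 0.038),
  c(0.178, 0.176, 0.175, 0.181, 0.176, 0.161, 0.125, 0.127, 0.093),
  c(0.283, 0.284, 0.269, 0.265, 0.271, 0.270, 0.229, 0.182, 0.186),
  c(0.394, 0.358, 0.373, 0.355, 0.353, 0.339, 0.330, 0.272, 0.256),
  c(0.463, 0.471, 0.448, 0.436, 0.438, 0.429, 0.392, 0.372, 0.334),
  c(0.594, 0.595, 0.564, 0.559, 0.549, 0.549, 0.492, 0.442, 0.405),
  c(0.679, 0.676, 0.669, 0.642, 0.646, 0.646, 0.619, 0.554, 0.537),
  c(0.785, 0.769, 0.788, 0.770, 0.748, 0.754, 0.736, 0.693, 0.670),
  c(0.886, 0.883, 0.886, 0.884, 0.883, 0.869, 0.870, 0.846, 0.820))

#' Correlation term for correlated AUC estimates
#'
#' Bilinear interpolation in the tabulated binormal-model correlation
#' surface (see the source file for how the synthetic table was built):
#' given the mean AUC of the two tests and the average within-class
#' Spearman correlation of their scores, returns the correlation `r`
#' between the two empirical AUC estimates.  Out-of-range inputs clamp
#' to the table edges; a mean AUC below 0.5 is mapped to `1 - AUC`
#' (the surface is symmetric in the orientation of the test).
#'
#' @param a_mean mean of the two AUCs.
#' @param r_avg average within-class Spearman correlation of the two
#'   score sets.
#' @return interpolated correlation term in `[0, 1]`.
#' @export
hm_r_lookup <- function(a_mean, r_avg) {
  a <- max(a_mean, 1 - a_mean)
  a <- min(max(a, min(.hm_agrid)), max(.hm_agrid))
  s <- min(max(r_avg, min(.hm_srow)), max(.hm_srow))
  ai <- findInterval(a, .hm_agrid, rightmost.closed = TRUE)
  si <- findInterval(s, .hm_srow, rightmost.closed = TRUE)
  ai <- min(ai, length(.hm_agrid) - 1L)
  si <- min(si, length(.hm_srow) - 1L)
  wa <- (a - .hm_agrid[ai]) / (.hm_agrid[ai + 1] - .hm_agrid[ai])
  ws <- (s - .hm_srow[si]) / (.hm_srow[si + 1] - .hm_srow[si])
  v00 <- .hm_rtab[si, ai];     v01 <- .hm_rtab[si, ai + 1]
  v10 <- .hm_rtab[si + 1, ai]; v11 <- .hm_rtab[si + 1, ai + 1]
  (1 - ws) * ((1 - wa) * v00 + wa * v01) +
    ws * ((1 - wa) * v10 + wa * v11)
}
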