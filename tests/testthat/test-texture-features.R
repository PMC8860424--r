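test_that("quantization maps the HU window onto grey levels deterministically", {
  vol <- fx_volume(array(c(-1000, 400, -300, -1200, 150, 0, -800, -654),
                         dim = c(2, 2, 2)))
  q <- rescale_to_levels(vol, fx_mask(c(2, 2, 2)), window = c(-1000, 400),
                         n_levels = 256)
  lv <- q$levels
  expect_equal(lv[1, 1, 1], 1L)      # window floor
  expect_equal(lv[2, 1, 1], 256L)    # window ceiling
  expect_equal(lv[1, 2, 1], 129L)    # 1 + round(255 * 700/1400)
  expect_equal(lv[2, 2, 1], 1L)      # clipped below
  expect_error(rescale_to_levels(vol, fx_mask(c(2, 2, 2)),
                                 window = c(10, 10)), "degenerate")
})

test_that("histogram features match hand-computed values", {
  # constant input: degenerate conventions
  qc <- fx_quantized(array(7L, c(2, 2, 1)), n_levels = 16)
  hf <- histogram_features(qc)
  expect_equal(unname(hf[c("skewness", "kurtosis")]), c(0, 0))
  expect_equal(unname(hf["uniformity"]), 1)
  expect_equal(unname(hf[c("p75", "p975")]), c(7, 7))

  # {1,2,3,4} at Ng = 4: uniformity sum((1/4)^2) = 0.25, p75 = 3.25
  q4 <- fx_quantized(array(1:4, c(4, 1, 1)), n_levels = 4)
  h4 <- histogram_features(q4)
  expect_equal(unname(h4["uniformity"]), 0.25)
  expect_equal(unname(h4["p75"]), 3.25)

  # {0,0,1}-shaped sample (levels {1,1,2}): m3/m2^1.5 = sqrt(1/2)
  q3 <- fx_quantized(array(c(1L, 1L, 2L), c(3, 1, 1)), n_levels = 2)
  expect_equal(unname(histogram_features(q3)["skewness"]),
               (2 / 27) / (2 / 9)^1.5, tolerance = 1e-12)
})

test_that("build_glcm counts horizontally adjacent in-mask pairs symmetrically", {
  # 1x1x4 row is not horizontal; place the run along the first axis
  row <- fx_quantized(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), n_levels = 2)
  g <- build_glcm(row)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(g$n_pairs, 3)

  # constant 2x2x2 block at level k: single diagonal cell
  const <- fx_quantized(array(2L, c(2, 2, 2)), n_levels = 3)
  gc <- build_glcm(const)
  expect_equal(gc$p[2, 2], 1)
  expect_equal(sum(gc$p), 1)

  # masking out the 2nd voxel leaves only the pair at positions 3-4
  m <- fx_mask(c(4, 1, 1))
  m$flags[2, 1, 1] <- FALSE
  masked <- fx_quantized(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)),
                         n_levels = 2, mask = m)
  gm <- build_glcm(masked)
  expect_equal(gm$p[1, 2], 0.5)
  expect_equal(gm$p[2, 1], 0.5)
  expect_equal(gm$n_pairs, 1)

  # single voxel: no pairs
  single <- fx_quantized(array(1L, c(1, 1, 1)), n_levels = 2)
  expect_error(build_glcm(single), "no co-occurring pairs")
  gf <- build_glcm(single, fallback = TRUE)
  expect_equal(gf$p[1, 1], 1)
})

test_that("GLCM features match closed-form values on small matrices", {
  # single-cell GLCM
  f1 <- glcm_features(glcm_from_counts(matrix(4, 1, 1)))
  expect_equal(unname(f1[c("energy", "entropy", "contrast",
                           "maximum_probability", "dissimilarity")]),
               c(1, 0, 0, 1, 0))

  # diagonal 2x2: perfect correlation
  f2 <- glcm_features(glcm_from_counts(diag(c(1, 1))))
  expect_equal(unname(f2["contrast"]), 0)
  expect_equal(unname(f2["correlation"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["entropy"]), log(2))
  expect_equal(unname(f2["sum_average"]), 3)

  # the [1,2,1,2] row: anti-diagonal, perfect anticorrelation
  row <- fx_quantized(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), n_levels = 2)
  f3 <- glcm_features(build_glcm(row))
  expect_equal(unname(f3["contrast"]), 1)
  expect_equal(unname(f3["correlation"]), -1)
  expect_equal(unname(f3["dissimilarity"]), 1)
  expect_equal(unname(f3["difference_variance"]), 1)
})

test_that("GLCM and all 21 features match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:200) {
    ng <- 4L
    levels <- array(sample.int(ng, 64, replace = TRUE), c(4, 4, 4))
    repeat {
      flags <- array(runif(64) < 0.6, c(4, 4, 4))
      if (sum(flags) >= 8) break
    }
    counts <- oracle_glcm(levels, flags, ng)
    q <- fx_quantized(levels, ng, mask = local({
      m <- fx_mask(c(4, 4, 4)); m$flags <- flags; m
    }))
    if (sum(counts) == 0) {
      expect_error(build_glcm(q), "no co-occurring pairs")
      next
    }
    g <- build_glcm(q)
    expect_equal(g$p, counts / sum(counts), tolerance = 1e-14)
    got <- glcm_features(g)
    want <- oracle_glcm_features(counts / sum(counts))
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("GLCM probabilities and derived distributions are normalized", {
  set.seed(5)
  for (rep in 1:25) {
    levels <- array(sample.int(6, 125, replace = TRUE), c(5, 5, 5))
    q <- fx_quantized(levels, 6)
    g <- build_glcm(q)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(sum(g$p_sum), 1, tolerance = 1e-12)
    expect_equal(sum(g$p_diff), 1, tolerance = 1e-12)
    expect_true(all(g$p >= 0))
    expect_equal(g$p, t(g$p))
  }
})

test_that("extract_features returns 26 finite named values with conventions", {
  vol <- fx_volume(array(-800, dim = c(3, 3, 3)))
  mask <- fx_mask(c(3, 3, 3))
  fv <- extract_features(vol, mask)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["uniformity"]), 1)
  expect_equal(unname(fv["energy"]), 1)
  expect_equal(unname(fv["contrast"]), 0)
  expect_equal(unname(fv["correlation"]), 0)

  set.seed(3)
  arr <- array(rnorm(5^3, -600, 150), dim = c(5, 5, 5))
  v2 <- fx_volume(arr)
  fv2 <- extract_features(v2, fx_mask(c(5, 5, 5)))
  expect_length(fv2, 26)
  expect_true(all(is.finite(fv2)))
  expect_identical(fv2, extract_features(v2, fx_mask(c(5, 5, 5))))
  expect_true(fv2["energy"] > 0 && fv2["energy"] <= 1)
  expect_true(fv2["imc2"] >= 0 && fv2["imc2"] <= 1)
})

test_that("whole-level HU shifts move percentiles and preserve GLCM features", {
  set.seed(9)
  arr <- array(rnorm(6^3, -600, 80), dim = c(6, 6, 6))
  arr <- pmin(pmax(arr, -900), -300)
  cfg <- extraction_config()
  lw_glcm <- 1400 / (cfg$glcm_levels - 1)     # HU per GLCM level
  shift <- 4 * lw_glcm                        # whole number of level widths
  f0 <- extract_features(fx_volume(arr), fx_mask(c(6, 6, 6)), cfg)
  f1 <- extract_features(fx_volume(arr + shift), fx_mask(c(6, 6, 6)), cfg)
  expect_equal(unname(f1[c("contrast", "correlation", "energy")]),
               unname(f0[c("contrast", "correlation", "energy")]),
               tolerance = 1e-12)
  lw_hist <- 1400 / (cfg$hist_levels - 1)
  # exact only up to one fine-channel level (integer rounding per voxel)
  expect_lt(abs(unname(f1["p75"] - f0["p75"]) - shift / lw_hist), 1)
})

test_that("smoother lesions have higher GLCM correlation and lower contrast", {
  smooth_corr <- rough_corr <- smooth_con <- rough_con <- numeric(50)
  for (s in 1:50) {
    rough <- generate_lesion(class_params(noise_sd = 100, smooth_len = 0.3),
                             seed = s, grid_size = 24)
    smooth <- generate_lesion(class_params(noise_sd = 100, smooth_len = 2),
                              seed = s, grid_size = 24)
    fr <- extract_features(rough$volume, rough$mask)
    fs <- extract_features(smooth$volume, smooth$mask)
    rough_corr[s] <- fr["correlation"]; smooth_corr[s] <- fs["correlation"]
    rough_con[s] <- fr["contrast"]; smooth_con[s] <- fs["contrast"]
  }
  expect_gt(mean(smooth_corr), mean(rough_corr))
  expect_lt(mean(smooth_con), mean(rough_con))
})

test_that("feature tables round-trip through CSV", {
  tab <- fx_toy_table(3, 5)
  df <- cbind(data.frame(case_id = sprintf("c%d", 1:8), label = tab$y,
                         stringsAsFactors = FALSE), as.data.frame(tab$x))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(df, f)
  back <- read_feature_table(f)
  expect_equal(back$case_id, df$case_id)
  expect_equal(as.matrix(back[, feature_names()]),
               as.matrix(df[, feature_names()]), tolerance = 1e-12)
  expect_error(read_feature_table({
    f2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing columns")
})
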