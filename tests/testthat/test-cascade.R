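test_that("two-component PCA captures the dominant plane", {
  # rank-1 data: points on a line in 26-space
  set.seed(2)
  dir26 <- rnorm(26)
  x <- outer(rnorm(10), dir26)
  p <- fit_pca2(x)
  expect_equal(p$explained_fraction, 1, tolerance = 1e-12)

  # axis-aligned variances (4, 1, 0): two components explain all
  x3 <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1), rep(0, 200))
  p3 <- fit_pca2(x3)
  expect_equal(p3$explained_fraction, 1, tolerance = 1e-12)
  expect_gt(abs(p3$loadings[1, 1]), 0.99)   # PC1 along the sd-2 axis

  # orthonormal loadings
  expect_equal(unname(p3$loadings %*% t(p3$loadings)), diag(2),
               tolerance = 1e-10)
  expect_error(fit_pca2(matrix(1, 5, 3)), "rank-0")
})

test_that("root threshold maximizes picked-out negatives under the constraint", {
  dec <- c(2, 3, -3, -2, -1, 2.5)
  lab <- c("SPCH", "SPCH", "LPA", "LPA", "LPA", "LPA")
  r <- root_threshold(dec, lab, "SPCH")
  expect_equal(r$n_picked, 3)
  expect_equal(r$forwarded_ppv, 2 / 3)
  expect_true(all(dec[lab == "SPCH"] >= r$tau))

  # exhaustive sweep oracle on random decision values
  set.seed(4)
  for (rep in 1:50) {
    d <- round(rnorm(20), 2)
    l <- sample(rep(c("SPCH", "LPA"), c(6, 14)))
    r <- root_threshold(d, l, "SPCH")
    best <- max(vapply(c(d, Inf), function(tau) {
      if (any(d[l == "SPCH"] < tau)) -1L else sum(d[l == "LPA"] < tau)
    }, integer(1)))
    expect_equal(r$n_picked, best)
    expect_equal(sum(d[l == "SPCH"] < r$tau), 0)  # never picks a positive
  }

  # perfectly separated: all negatives picked out
  rs <- root_threshold(c(5, 6, -1, -2), c("SPCH", "SPCH", "LPA", "LPA"),
                       "SPCH")
  expect_equal(rs$n_picked, 2)
  expect_equal(rs$forwarded_ppv, 1)

  # a negative tying the positive extremum is forwarded, never picked
  rt <- root_threshold(c(1, 2, 1, -5), c("SPCH", "SPCH", "LPA", "LPA"),
                       "SPCH")
  expect_equal(rt$n_picked, 1)
})

test_that("forward selection finds the separating feature and obeys bounds", {
  tab <- fx_toy_table(6, 10, sep_feature = "correlation", gap = 8)
  sel <- sfs_select(tab$x, tab$y, k_min = 2, k_max = 2)
  expect_length(sel, 2)
  expect_equal(sel[1], "correlation")

  # tie-break: an identical copy earlier in column order wins
  x2 <- tab$x
  x2[, "skewness"] <- x2[, "correlation"]   # col 1 duplicates col 8
  sel2 <- sfs_select(x2, tab$y, k_min = 1, k_max = 1)
  expect_equal(sel2, "skewness")

  expect_error(sfs_select(tab$x, rep("LPA", 16)), "both classes")
  expect_error(sfs_select(tab$x, tab$y, k_min = 0, k_max = 2), "k_min")
})

test_that("the fitted cascade forwards every training positive", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  m <- fit_cascade(ft)
  pr <- predict(m, ft, type = "parts")
  expect_true(all(pr$P1[ft$label == "SPCH"] == 1))
  expect_gte(min(pr$P[ft$label == "SPCH"]),
             stats::median(pr$P[ft$label == "LPA"]))
  expect_equal(length(m$leaf$selected_features), 2)
  expect_error(fit_cascade(ft, rep("LPA", nrow(ft))), "both classes")
})

test_that("cascade predictions factor as P = P1 * P2 with a hard gate", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  m <- fit_cascade(ft)
  pr <- predict(m, ft, type = "parts")
  expect_true(all(pr$P1 %in% c(0, 1)))
  expect_true(all(pr$P2 >= 0 & pr$P2 <= 1))
  expect_equal(pr$P, pr$P1 * pr$P2)
  expect_true(all(pr$P[pr$P1 == 0] == 0))
  expect_equal(predict(m, ft), pr$P)
})

test_that("leaf calibration is monotone in the decision value", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  m <- fit_cascade(ft)
  calib <- m$leaf$calibration
  expect_lte(calib$A, 0)
  grid <- seq(-5, 5, length.out = 41)
  p2 <- radiocascade:::platt_apply(calib, grid)
  expect_true(all(diff(p2) >= 0))
})

test_that("baseline selects 3-6 features deterministically", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  b1 <- fit_baseline(ft)
  b2 <- fit_baseline(ft)
  expect_gte(length(b1$selected_features), 3)
  expect_lte(length(b1$selected_features), 6)
  expect_identical(b1$selected_features, b2$selected_features)
  expect_identical(predict(b1, ft), predict(b2, ft))

  tab <- fx_toy_table(6, 12, gap = 8)
  bt <- fit_baseline(tab$x, tab$y)
  expect_equal(roc_auc(predict(bt, tab$x), tab$y), 1)
})

test_that("models serialise to JSON and back without changing predictions", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  m <- fit_cascade(ft)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_s3_class(m2, "cascade_model")
  expect_equal(predict(m2, ft, type = "parts"), predict(m, ft, type = "parts"),
               tolerance = 1e-12)

  b <- fit_baseline(ft)
  fb <- withr::local_tempfile(fileext = ".json")
  write_model(b, fb)
  expect_equal(predict(read_model(fb), ft), predict(b, ft),
               tolerance = 1e-12)
})

test_that("cascade model prints and summarises its structure", {
  ft <- cohort_features(cohort_spec(n_spch = 6, n_lpa = 18, grid_size = 32,
                                    seed = 7))
  m <- fit_cascade(ft)
  expect_output(print(m), "Two-level cascade")
  s <- summary(m)
  expect_output(print(s), "explained variance")
  expect_true(s$explained_fraction > 0 && s$explained_fraction <= 1)
  expect_named(coef(m)$leaf,
               c(m$leaf$selected_features, "intercept"))
})
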