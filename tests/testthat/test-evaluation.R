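test_that("LOOCV refits the whole pipeline and scores each case once", {
  tab <- fx_toy_table(5, 7, gap = 8)
  df <- cbind(data.frame(case_id = sprintf("c%02d", 1:12), label = tab$y,
                         stringsAsFactors = FALSE), as.data.frame(tab$x))
  res <- loocv_scores(df, trainer = "baseline")
  expect_equal(nrow(res), 12)
  expect_equal(sort(res$case_id), sort(df$case_id))
  expect_equal(anyDuplicated(res$case_id), 0)
  expect_equal(roc_auc(res$P, res$label), 1)   # separable by construction

  res2 <- loocv_scores(df, trainer = "baseline")
  expect_identical(res$P, res2$P)              # deterministic

  # custom trainer function route
  res3 <- loocv_scores(df, trainer = function(x, y, config)
    fit_baseline(x, y, config))
  expect_equal(res3$P, res$P)
})

test_that("rank-based AUC handles ties and matches pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.1), c("SPCH", "LPA")), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c("SPCH", "LPA"), 5)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.6, 0.7, 0.1),
                       c("SPCH", "SPCH", "LPA", "LPA")), 0.75)

  brute_auc <- function(s, l) {
    pos <- s[l == "SPCH"]; neg <- s[l != "SPCH"]
    cnt <- 0
    for (a in pos) for (b in neg)
      cnt <- cnt + (a > b) + 0.5 * (a == b)
    cnt / (length(pos) * length(neg))
  }
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    npos <- sample(1:(n - 1), 1)
    l <- sample(rep(c("SPCH", "LPA"), c(npos, n - npos)))
    s <- sample(round(runif(n), 1))   # coarse grid forces ties
    expect_equal(roc_auc(s, l), brute_auc(s, l))
  }
  expect_error(roc_auc(1:3, rep("LPA", 3)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(8)
  s <- runif(30); l <- sample(rep(c("SPCH", "LPA"), c(10, 20)))
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("LPA", "SPCH"),
                                              direction = "<", quiet = TRUE))))
})

test_that("confusion metrics use a strict threshold and consistent counts", {
  # 13 positives with 12 above 0.5, 49 negatives with 45 at or below
  scores <- c(rep(0.9, 12), 0.2, rep(0.1, 45), rep(0.8, 4))
  labels <- rep(c("SPCH", "LPA"), c(13, 49))
  m <- confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(m["sensitivity"]), 12 / 13)
  expect_equal(unname(m["specificity"]), 45 / 49)
  expect_equal(unname(m["accuracy"]), 57 / 62)
  expect_equal(unname(m["tp"] + m["fn"]), 13)
  expect_equal(unname(m["tn"] + m["fp"]), 49)

  perfect <- confusion_metrics(c(1, 1, 0, 0),
                               c("SPCH", "SPCH", "LPA", "LPA"), 0.5)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv")]), rep(1, 4))

  high <- confusion_metrics(c(0.9, 0.8, 0.1), c("SPCH", "SPCH", "LPA"), 1)
  expect_equal(unname(high["sensitivity"]), 0)
  expect_equal(unname(high["specificity"]), 1)

  # gate-rejected cases (score exactly 0) are negative at any threshold >= 0
  z <- confusion_metrics(c(0, 0.7), c("SPCH", "SPCH"), 0)
  expect_equal(unname(z["sensitivity"]), 0.5)
})

test_that("ROC curve spans (0,0) to (1,1)", {
  s <- c(0.9, 0.7, 0.7, 0.2, 0.1)
  l <- c("SPCH", "SPCH", "LPA", "LPA", "LPA")
  cur <- roc_curve(s, l)
  expect_equal(cur$sensitivity[1], 0)
  expect_equal(cur$specificity[1], 1)
  expect_equal(cur$sensitivity[nrow(cur)], 1)
  expect_equal(cur$specificity[nrow(cur)], 0)
})

test_that("Hanley-McNeil SE matches the closed form", {
  expect_equal(hanley_mcneil_se(1, 13, 49), 0)
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  expect_equal(hanley_mcneil_se(0.954, 13, 49), 0.0414696, tolerance = 1e-6)
})

test_that("correlated AUC comparison composes its pieces correctly", {
  set.seed(12)
  labels <- rep(c("SPCH", "LPA"), c(13, 49))
  s1 <- runif(62) + (labels == "SPCH") * 2
  s2 <- runif(62) + (labels == "SPCH") * 0.8

  cmp <- compare_auc(s1, s2, labels)
  expect_equal(cmp$A1, roc_auc(s1, labels))
  expect_equal(cmp$A2, roc_auc(s2, labels))
  expect_equal(cmp$SE1, hanley_mcneil_se(cmp$A1, 13, 49))
  denom <- sqrt(cmp$SE1^2 + cmp$SE2^2 - 2 * cmp$r * cmp$SE1 * cmp$SE2)
  expect_equal(cmp$z, (cmp$A1 - cmp$A2) / denom, tolerance = 1e-12)
  expect_equal(cmp$p, 2 * pnorm(-abs(cmp$z)), tolerance = 1e-12)
  expect_true(cmp$r >= -1 && cmp$r <= 1)

  # identical score sets: no difference by convention
  same <- compare_auc(s1, s1, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  expect_error(compare_auc(s1[-1], s2, labels), "same cases")
})

test_that("the tabulated r term increases with within-class correlation", {
  for (a in c(0.55, 0.7, 0.85, 0.95)) {
    r_along <- vapply(seq(0, 0.85, by = 0.05), function(s)
      hm_r_lookup(a, s), numeric(1))
    expect_true(all(diff(r_along) >= 0))
  }
  expect_equal(hm_r_lookup(0.8, 0), 0, tolerance = 1e-12)
  # clamping at the table edges
  expect_equal(hm_r_lookup(0.99, 0.95), hm_r_lookup(0.975, 0.881))
  # symmetric in test orientation
  expect_equal(hm_r_lookup(0.3, 0.5), hm_r_lookup(0.7, 0.5))
})

test_that("roc_summary bundles AUC and threshold metrics", {
  s <- c(0.9, 0.8, 0.3, 0.2, 0.1)
  l <- c("SPCH", "SPCH", "LPA", "LPA", "LPA")
  rs <- roc_summary(s, l, threshold = 0.5)
  expect_equal(rs$auc, 1)
  expect_equal(unname(rs$metrics["accuracy"]), 1)
  expect_output(print(rs), "AUC")
})
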