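# Performance statistics and their independent oracles.

test_that("confusion matrix counts true-by-predicted labels", {
  cm <- confusion_matrix(c("malignant", "malignant", "benign", "fat"),
                         c("malignant", "benign", "benign", "fat"))
  expect_equal(cm["malignant", "malignant"], 1L)
  expect_equal(cm["malignant", "benign"], 1L)
  expect_equal(cm["benign", "benign"], 1L)
  expect_equal(cm["fat", "fat"], 1L)
  expect_equal(sum(cm), 4L)
  expect_equal(unname(rowSums(cm)), c(2L, 1L, 1L))

  pred <- c("benign", "fat", "malignant")
  expect_equal(diag(confusion_matrix(pred, pred)), c(malignant = 1L,
                                                     benign = 1L, fat = 1L))
  expect_error(confusion_matrix("malignant", "weird"), "unknown label")
})

test_that("one-vs-rest metrics match hand arithmetic", {
  cm <- confusion_matrix(rep("benign", 2), rep("benign", 2))
  m <- class_metrics(cm, "benign")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$specificity))  # no non-benign cases: undefined, not 0

  # the 90% / 81% operating point: 10 malignant (9 correct),
  # 21 non-malignant (17 correct)
  cm <- matrix(c(9, 1, 0,
                 3, 13, 0,
                 1, 0, 4), 3, 3, byrow = TRUE,
               dimnames = list(true = c("malignant", "benign", "fat"),
                               predicted = c("malignant", "benign", "fat")))
  m <- class_metrics(cm, "malignant")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 17 / 21)
  expect_equal(m$accuracy, 26 / 31)

  # invariant to permuting the two "rest" classes together
  p <- c(1, 3, 2)
  m2 <- class_metrics(cm[p, p], "malignant")
  expect_equal(m, m2)
})

test_that("Clopper-Pearson equals exact binomial tail inversion", {
  # independent oracle: solve the binomial tail equations by uniroot
  oracle <- function(x, n, level = 0.95) {
    a <- 1 - level
    lo <- if (x == 0) 0 else
      stats::uniroot(function(p) stats::pbinom(x - 1, n, p) - (1 - a / 2),
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    hi <- if (x == n) 1 else
      stats::uniroot(function(p) stats::pbinom(x, n, p) - a / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(lo, hi)
  }
  for (n in c(1, 5, 10, 25)) for (x in 0:n) {
    expect_equal(unname(clopper_pearson(x, n)), oracle(x, n),
                 tolerance = 1e-7)
  }
  # frozen example: x = 9, n = 10
  ci <- clopper_pearson(9, 10)
  expect_equal(unname(ci), c(0.5549839, 0.9974714), tolerance = 1e-4)
  expect_equal(unname(clopper_pearson(0, 10))[1], 0)
  expect_equal(unname(clopper_pearson(10, 10))[2], 1)

  # monotone in x; always contains x/n
  for (n in c(8, 17)) {
    cis <- t(sapply(0:n, function(x) clopper_pearson(x, n)))
    expect_true(all(diff(cis[, 1]) >= 0) && all(diff(cis[, 2]) >= 0))
    expect_true(all(cis[, 1] <= (0:n) / n & (0:n) / n <= cis[, 2]))
  }
  expect_error(clopper_pearson(5, 4), "invalid counts")
  expect_error(clopper_pearson(-1, 4), "invalid counts")
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(314)
  x <- stats::rbinom(2000, 30, 0.8)
  covered <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, 30)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("Pearson correlation matches formula and stats::cor.test", {
  pc <- pearson_correlation(1:3, c(1, 2, 2))
  expect_equal(pc$r, sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  set.seed(6)
  x <- rnorm(20); y <- 0.3 * x + rnorm(20)
  pc <- pearson_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(pc$r, pearson_correlation(y, x)$r)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("pooled t-test matches hand arithmetic and stats::t.test", {
  tt <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -sqrt(3 / 2), tolerance = 1e-9)  # = -1.2247
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.2878641, tolerance = 1e-6)

  set.seed(8)
  a <- rnorm(12); b <- rnorm(15, mean = 0.4)
  tt <- two_sample_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
  tw <- two_sample_ttest(a, b, welch = TRUE)
  refw <- stats::t.test(a, b)
  expect_equal(tw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-9)

  same <- two_sample_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(two_sample_ttest(c(2, 2), c(3, 3)), "undefined")
  # antisymmetric in group order
  expect_equal(two_sample_ttest(a, b)$t, -two_sample_ttest(b, a)$t)
})

test_that("null-distribution checks: p-values are uniform", {
  set.seed(99)
  p_t <- replicate(2000, two_sample_ttest(rnorm(8), rnorm(8))$p_value)
  expect_true(all(p_t >= 0 & p_t <= 1))
  ks <- stats::ks.test(p_t, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("performance report assembles metrics with CIs", {
  set.seed(4)
  truth <- sample(c("malignant", "benign", "fat"), 40, replace = TRUE)
  pred <- truth
  flip <- sample(40, 8)
  pred[flip] <- sample(c("malignant", "benign", "fat"), 8, replace = TRUE)
  rep_ <- performance_report(truth, pred)
  expect_equal(rep_$overall_accuracy,
               sum(diag(rep_$confusion)) / sum(rep_$confusion))
  expect_equal(unname(rowSums(rep_$confusion)),
               unname(as.vector(table(factor(truth,
                 levels = c("malignant", "benign", "fat"))))))
  m <- rep_$metrics
  expect_true(all(m$ci_lower <= m$estimate & m$estimate <= m$ci_upper,
                  na.rm = TRUE))
  # CI columns reproduce clopper_pearson on the underlying counts
  sens_m <- m[m$class == "malignant" & m$metric == "sensitivity", ]
  cmx <- class_metrics(rep_$confusion, "malignant")
  ci <- clopper_pearson(cmx$tp, cmx$tp + cmx$fn)
  expect_equal(c(sens_m$ci_lower, sens_m$ci_upper), unname(ci))
})
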