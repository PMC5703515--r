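test_that("ICC equals 1 on identity and tracks the variance-components closed form", {
  a <- c(5, 17, 33, 48, 12, 29)
  expect_equal(icc(a, a)$icc, 1)
  expect_error(icc(rep(3, 5), rep(3, 5)), "undefined")
  # b = a + e, var(a)=100: two-way components give sa2/(sa2 + se2/2)
  set.seed(50)
  a <- rnorm(1000, 40, 10)
  for (se2 in c(25, 100)) {
    b <- a + rnorm(1000, 0, sqrt(se2))
    expect_equal(icc(a, b)$icc, 100 / (100 + se2 / 2), tolerance = 0.05)
  }
  # a systematic offset lowers absolute agreement but not consistency
  b_off <- a + 8
  expect_lt(icc(a, b_off)$icc, icc(a, b_off, variant = "consistency")$icc)
  expect_equal(icc(a, b_off, variant = "consistency")$icc, 1, tolerance = 1e-9)
  # CI brackets the point estimate
  r <- icc(a, a + rnorm(1000, 0, 5))
  expect_true(r$ci[1] < r$icc && r$icc < r$ci[2])
})

test_that("Bland-Altman bias, limits and swap antisymmetry", {
  a <- c(10, 20, 30, 40)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_width, 0)
  r <- bland_altman(a, a + 5)
  expect_equal(r$bias, 5)
  expect_equal(r$loa_width, 0)
  set.seed(51)
  b <- a * 1.1 + rnorm(4)
  r1 <- bland_altman(a, b); r2 <- bland_altman(b, a)
  expect_equal(r1$bias, -r2$bias)
  expect_equal(r1$loa_width, r2$loa_width)
  expect_equal(r1$loa_width, 2 * 1.96 * sd(b - a))
  expect_true(r1$loa_low <= r1$bias && r1$bias <= r1$loa_high)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("mountain plot folds the empirical CDF and peaks at the median", {
  set.seed(52)
  d <- rnorm(20, 0, 4)
  mp <- mountain_plot(d)
  expect_equal(mp$folded, brute_mountain(d))
  expect_true(all(mp$folded <= 50))
  expect_equal(mp$difference[which.max(mp$folded)], stats::median(d),
               tolerance = max(abs(diff(sort(d)))))
  # symmetric differences give a symmetric curve
  ds <- c(-3, -2, -1, 1, 2, 3)
  mps <- mountain_plot(ds)
  expect_equal(mps$folded, rev(mps$folded))
  # identical differences: single spike location
  mc <- mountain_plot(rep(2.5, 5))
  expect_true(all(mc$difference == 2.5))
})

test_that("confusion metrics reproduce hand arithmetic and the Sp=100% rule", {
  # TP=79 FN=2 TN=17 FP=12 (cutoff dichotomy built directly)
  true <- c(rep(20, 79), rep(20, 2), rep(5, 17), rep(5, 12))
  pred <- c(rep(20, 79), rep(5, 2), rep(5, 17), rep(20, 12))
  m <- confusion_metrics(pred, true, cutoff = 15)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(79L, 2L, 17L, 12L))
  expect_equal(m$se, 97.5, tolerance = 0.05)
  expect_equal(m$sp, 58.6, tolerance = 0.05)
  expect_equal(m$acc, 87.3, tolerance = 0.05)
  expect_equal(m$lr_pos, (79 / 81) / (1 - 17 / 29), tolerance = 1e-9)
  # accuracy identity Acc = (Se*n_pos + Sp*n_neg)/n
  expect_equal(m$acc, (m$se * 81 + m$sp * 29) / 110, tolerance = 1e-9)

  perfect <- confusion_metrics(c(40, 40, 5, 5), c(35, 50, 2, 9), 15)
  expect_equal(c(perfect$se, perfect$sp, perfect$ppv, perfect$npv, perfect$acc),
               rep(100, 5))
  expect_false(perfect$lr_pos_defined)
  expect_true(is.na(perfect$lr_pos))
  expect_error(confusion_metrics(1:3, 1:3, 0), "positive")
})

test_that("AUC equals the Mann-Whitney oracle and is rank-invariant", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  set.seed(53)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  if (sum(lb) %in% c(0, 60)) lb[1:2] <- c(0, 1)
  expect_equal(roc_auc(sc, lb)$auc, brute_auc(sc, lb))
  # ties
  sct <- sample(1:5, 60, TRUE)
  expect_equal(roc_auc(sct, lb)$auc, brute_auc(sct, lb))
  # strictly monotone transform of the scores leaves AUC unchanged
  expect_equal(roc_auc(exp(sc), lb)$auc, roc_auc(sc, lb)$auc)
  # uninformative scores give AUC near 1/2
  set.seed(54)
  big <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(big$auc - 0.5), 0.05)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  sc <- rnorm(120); lb <- as.integer(sc + rnorm(120) > 0.3)
  own <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(own, ref, tolerance = 1e-12)
})

test_that("severity classes use the 5/15/30 cutoffs with inclusive lower bounds", {
  expect_identical(as.character(severity_class(c(4.2, 5, 14.9, 15, 29.9, 30, 80))),
                   c("normal", "mild", "mild", "moderate", "moderate",
                     "severe", "severe"))
  expect_error(severity_class(-1), "nonnegative")
})

test_that("the full evaluation report is internally consistent", {
  set.seed(56)
  true <- runif(90, 0, 60)
  est <- pmax(0, true + rnorm(90, 1, 8))
  rep <- evaluate_agreement(true, est)
  expect_equal(rep$bland_altman$bias, mean(est - true))
  m30 <- rep$diagnostic$cutoff30$metrics
  expect_equal(m30$acc, 100 * (m30$tp + m30$tn) / 90, tolerance = 1e-9)
  expect_true(rep$diagnostic$cutoff15$auc$auc > 0.8)
  expect_true(rep$icc$icc > 0.8)
})
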