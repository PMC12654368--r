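test_that("classification report matches hand-computed confusion metrics", {
  # TP=2, FP=1, FN=1, TN=6: F1+ = 2/3, F1- = 6/7
  y <- c(rep("positive", 3), rep("negative", 7))
  p <- c(0.9, 0.8, 0.1, 0.7, rep(0.2, 6))
  r <- classification_report(y, p)
  expect_equal(r$macro_f1, (2 / 3 + 6 / 7) / 2, tolerance = 1e-12)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$confusion["positive", "positive"], 2)
  expect_equal(r$confusion["negative", "positive"], 1)
  expect_true(all(abs(rowSums(r$confusion_normalized) - 1) < 1e-12))
  # weighted-F1 bracketed by the class F1s
  expect_gte(r$weighted_f1, min(r$per_class$f1))
  expect_lte(r$weighted_f1, max(r$per_class$f1))
})

test_that("perfect predictions yield perfect scores", {
  y <- rep(c("positive", "negative"), each = 10)
  p <- rep(c(1, 0), each = 10)
  r <- classification_report(y, p)
  expect_equal(r$macro_f1, 1.0)
  expect_equal(r$brier, 0.0)
  expect_equal(r$auc, 1.0)
})

test_that("constant predictor recovers the prevalence baseline AP", {
  set.seed(42)
  y <- ifelse(runif(200) < 0.93, "positive", "negative")
  r <- classification_report(y, rep(0.5, 200))
  expect_equal(r$average_precision, mean(y == "positive"), tolerance = 1e-12)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rep(c(1, 0), each = 50)
  p <- plogis(rnorm(100, mean = rep(c(0.8, -0.3), each = 50))) # overlapping
  r <- classification_report(y, p)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("single-class truth flags probability metrics as unavailable", {
  r <- classification_report(rep("positive", 5), c(0.9, 0.8, 0.9, 0.7, 0.6))
  expect_true(is.na(r$auc))
  expect_true(is.na(r$average_precision))
})

test_that("macro metrics are invariant to class renaming", {
  y <- c(rep("positive", 3), rep("negative", 7))
  p <- c(0.9, 0.8, 0.1, 0.7, rep(0.2, 6))
  a <- classification_report(y, p)
  renamed <- ifelse(y == "positive", "caseA", "caseB")
  b <- classification_report(renamed, p, positive = "caseA")
  expect_equal(a$macro_f1, b$macro_f1)
  expect_equal(a$macro_precision, b$macro_precision)
  expect_equal(a$auc, b$auc)
})

test_that("regression report implements the R2 and RMSE definitions", {
  expect_equal(regression_report(c(0, 1, 2), c(0, 1, 2))$r2, 1)
  expect_equal(regression_report(c(0, 1, 2), c(0, 1, 2))$rmse, 0)
  expect_equal(regression_report(c(0, 1, 2), c(0, 1, 3))$rmse, sqrt(1 / 3))
  y <- c(1, 4, 2, 8, 5)
  expect_equal(regression_report(y, rep(mean(y), 5))$r2, 0)
  const <- regression_report(rep(2, 5), 1:5)
  expect_true(is.na(const$r2))
  expect_false(const$r2_defined)
})

test_that("tertile RMSE localizes error to the right stratum", {
  y <- as.numeric(1:9)
  expect_equal(unname(tertile_rmse(y, y)), c(0, 0, 0))
  yh <- y; yh[y > 6] <- yh[y > 6] + 2
  tr <- tertile_rmse(y, yh)
  expect_equal(unname(tr[c("low", "mid")]), c(0, 0))
  expect_gt(tr[["high"]], 0)
  expect_equal(unname(tertile_rmse(y, y + 1)), c(1, 1, 1))
})

test_that("conformal band uses the conservative order statistic", {
  expect_equal(conformal_band(rep(0, 30))$q, 0)
  expect_equal(conformal_coverage(1:5, 1:5, 0), 1)
  b <- conformal_band(1:100)        # |residuals| = 1..100
  expect_equal(b$q, 95)
  expect_warning(conformal_band(1:10), "unstable")
  # coverage of the calibration residuals is at least level - 1/n
  set.seed(1)
  r <- rnorm(200)
  b2 <- conformal_band(r)
  expect_gte(conformal_coverage(r, 0, b2$q), 0.95 - 1 / 200)
  # coverage non-decreasing in q
  y <- rnorm(50); yh <- y + rnorm(50)
  qs <- seq(0, 3, by = 0.5)
  cov <- vapply(qs, function(q) conformal_coverage(y, yh, q), 0)
  expect_true(all(diff(cov) >= 0))
})

test_that("metrics are invariant to simultaneous permutation", {
  set.seed(5)
  y <- ifelse(runif(60) < 0.7, "positive", "negative")
  p <- runif(60)
  perm <- sample(60)
  a <- classification_report(y, p)
  b <- classification_report(y[perm], p[perm])
  expect_equal(a$macro_f1, b$macro_f1)
  expect_equal(a$auc, b$auc)
  yn <- rnorm(60); yhn <- yn + rnorm(60)
  expect_equal(regression_report(yn, yhn)$rmse,
               regression_report(yn[perm], yhn[perm])$rmse)
})

test_that("multi-class reports average one-vs-rest over categories", {
  y <- c("A", "A", "B", "B", "C", "C")
  p <- rbind(c(.8, .1, .1), c(.7, .2, .1), c(.1, .8, .1),
             c(.2, .7, .1), c(.1, .1, .8), c(.6, .2, .2))
  colnames(p) <- c("A", "B", "C")
  r <- classification_report(y, p)
  expect_equal(r$accuracy, 5 / 6)
  expect_true(is.na(r$auc))
  expect_equal(dim(r$confusion), c(3L, 3L))
})
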