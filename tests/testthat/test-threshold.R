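test_that("confusion statistics match hand-computed confusion matrices", {
  # perfect sensitivity with 6 false positives on a 49/51 split
  fx <- confusion_fixture(tp = 49, fn = 0, tn = 45, fp = 6)
  op <- confusion_at(fx$similarities, fx$labels, 0.5)
  expect_equal(op$tp, 49); expect_equal(op$fn, 0)
  expect_equal(op$tn, 45); expect_equal(op$fp, 6)
  expect_equal(op$sensitivity, 1.0)
  expect_equal(op$specificity, 45 / 51)
  expect_equal(op$f_index, 98 / 104)
  expect_equal(op$mcc, (49 * 45) / sqrt(55 * 49 * 51 * 45))

  # near-symmetric errors: MCC is exactly rational
  fx <- confusion_fixture(tp = 48, fn = 1, tn = 48, fp = 3)
  op <- confusion_at(fx$similarities, fx$labels, 0.5)
  expect_equal(op$accuracy, 0.960)
  expect_equal(op$mcc, 2301 / 2499)
  expect_equal(op$youden, op$sensitivity + op$specificity - 1)
})

test_that("degenerate thresholds and empty denominators behave", {
  fx <- confusion_fixture(tp = 10, fn = 0, tn = 10, fp = 0)
  op0 <- confusion_at(fx$similarities, fx$labels, 0)
  expect_equal(op0$sensitivity, 1)
  expect_equal(op0$specificity, 0)
  op_hi <- confusion_at(fx$similarities, fx$labels, 2)
  expect_true(is.na(op_hi$precision))   # nothing predicted similar
  expect_error(confusion_at(numeric(0), character(0), 0.5), "empty")
})

test_that("threshold comparison is inclusive at the boundary", {
  op <- confusion_at(c(0.5, 0.49), c("similar", "non-similar"), 0.5)
  expect_equal(op$tp, 1)  # exactly-at-threshold counts as similar
  expect_equal(op$tn, 1)
})

test_that("ROC curves contain the corners and respect sweep cardinality", {
  set.seed(51)
  s <- runif(40)
  y <- ifelse(rbinom(40, 1, plogis(-4 + 8 * s)) == 1, "similar",
              "non-similar")
  if (length(unique(y)) < 2) skip("degenerate draw")
  roc <- roc_curve(s, y)
  # n distinct similarities admit at most n + 1 distinct operating points
  expect_lte(nrow(unique(roc[, c("fpr", "sensitivity")])),
             length(unique(s)) + 1)
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 0))
  expect_true(any(roc$fpr == 1 & roc$sensitivity == 1))
  # monotone along the curve
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
})

test_that("perfectly separated classes pass through (0, 1)", {
  s <- c(rep(0.2, 5), rep(0.8, 5))
  y <- rep(c("non-similar", "similar"), each = 5)
  roc <- roc_curve(s, y)
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 1))
  expect_equal(auc(roc), 1.0)
  expect_error(roc_curve(s, rep("similar", 10)), "both")
})

test_that("identical similarities collapse the curve to three points", {
  roc <- roc_curve(rep(0.5, 10), rep(c("similar", "non-similar"), 5))
  expect_equal(nrow(roc), 3)
  expect_equal(auc(roc), 0.5)
})

test_that("trapezoidal AUC equals the concordance oracle", {
  set.seed(52)
  for (rep in 1:30) {
    n <- sample(c(20, 50, 100), 1)
    s <- round(runif(n), 2)          # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    roc <- roc_curve(s, y)
    expect_equal(auc(roc), auc_concordance_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(53)
  s <- runif(60)
  y <- rbinom(60, 1, plogis(-3 + 6 * s))
  a1 <- auc(roc_curve(s, y))
  a2 <- auc(roc_curve(s^3, y))
  a3 <- auc(roc_curve(plogis(5 * s), y))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  s <- runif(80)
  y <- rbinom(80, 1, plogis(-4 + 8 * s))
  ours <- auc(roc_curve(s, y))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("t_ROC selection maximizes Youden under the floors", {
  s <- c(rep(0.2, 10), rep(0.8, 10))
  y <- rep(c("non-similar", "similar"), each = 10)
  op <- select_t_roc(s, y)
  expect_equal(op$youden, 1)
  expect_gt(op$threshold, 0.2); expect_lt(op$threshold, 0.8)

  set.seed(55)
  s <- runif(200)
  y <- rbinom(200, 1, plogis(-5 + 10 * s))
  op <- select_t_roc(s, y, min_sens = 0, min_spec = 0)
  roc <- roc_curve(s, y)
  expect_equal(op$youden, max(roc$youden, na.rm = TRUE))
})

test_that("unreachable floors are relaxed with a warning", {
  set.seed(56)
  s <- runif(50)
  y <- rbinom(50, 1, 0.5)   # labels carry no signal
  expect_warning(op <- select_t_roc(s, y, min_sens = 0.99, min_spec = 0.99),
                 "floors")
  expect_s3_class(op, "operating_point")
})

test_that("label complement with inverted predictions preserves Youden", {
  set.seed(57)
  s <- runif(60)
  y <- rbinom(60, 1, plogis(-4 + 8 * s))
  if (length(unique(y)) < 2) skip("degenerate draw")
  op <- select_t_roc(s, y, min_sens = 0, min_spec = 0)
  flipped <- select_t_roc(-s, 1 - y, min_sens = 0, min_spec = 0)
  expect_equal(flipped$youden, op$youden, tolerance = 1e-12)
})

test_that("simulated panels put t_ROC near the logistic threshold t_LR", {
  # balanced prevalence: the ROC optimum and the probability-0.5 threshold
  # agree to within the inter-pair spacing
  hits <- vapply(1:40, function(seed) {
    cfg <- panel_sim_config(beta0_true = -12.754, beta1_true = 2.524,
                            seed = seed)
    tr <- simulate_training_set(cfg)
    op <- suppressWarnings(select_t_roc(tr$similarity, tr$label))
    abs(op$threshold - 0.505) <= 0.08
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
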