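test_that("majority labeling requires a strict majority", {
  expect_equal(label_majority(c(0.51, 0.50, 0.00, 1.00)),
               c("similar", "non-similar", "non-similar", "similar"))
  expect_error(label_majority(1.2), "\\[0, 1\\]")
  expect_error(label_majority(-0.1), "\\[0, 1\\]")
})

test_that("logistic fit recovers known coefficients from simulated data", {
  set.seed(41)
  n <- 10000
  s <- runif(n)
  p <- plogis(-12.754 + 2.524 * 10 * s)
  y <- rbinom(n, 1, p)
  fit <- fit_logistic(s, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta0 - (-12.754)) / fit$se_beta0, 3)
  expect_lt(abs(fit$beta1 - 2.524) / fit$se_beta1, 3)
})

test_that("slope is not significant when labels ignore similarity", {
  set.seed(42)
  covered <- replicate(200, {
    s <- runif(100)
    y <- rbinom(100, 1, 0.5)
    fit <- suppressWarnings(fit_logistic(s, y))
    abs(fit$beta1 / fit$se_beta1) < 2
  })
  expect_gte(mean(covered), 0.9)
})

test_that("t_lr is exactly the 0.5-crossing of the fitted curve", {
  set.seed(43)
  for (rep in 1:5) {
    s <- runif(200)
    y <- rbinom(200, 1, plogis(-6 + 1.2 * 10 * s))
    if (length(unique(y)) < 2) next
    fit <- suppressWarnings(fit_logistic(s, y))
    expect_equal(fit$t_lr, -fit$beta0 / (10 * fit$beta1), tolerance = 1e-12)
    expect_equal(predict_probability(fit, fit$t_lr)$probability, 0.5,
                 tolerance = 1e-10)
    # monotone increasing for positive slope
    grid <- predict_probability(fit, seq(0, 1, 0.1))$probability
    expect_true(all(diff(grid) > 0))
  }
})

test_that("the x10 internal scale is a pure reparameterization", {
  set.seed(44)
  s <- runif(150)
  y <- rbinom(150, 1, plogis(-5 + 10 * s))
  fit <- fit_logistic(s, y)
  raw <- glm(y ~ s, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  expect_equal(fit$beta1, coef(raw)[["s"]] / 10, tolerance = 1e-6)
  expect_equal(predict_probability(fit, s)$probability,
               unname(fitted(raw)), tolerance = 1e-6)
})

test_that("one-class input is rejected", {
  expect_error(fit_logistic(runif(10), rep("similar", 10)), "one-class")
  expect_error(fit_logistic(runif(10), rep(1, 10), n_trials = 100),
               "one-class")
})

test_that("complete separation is detected, capped, and firth-estimable", {
  s <- c(seq(0.1, 0.4, length.out = 10), seq(0.6, 0.9, length.out = 10))
  y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- fit_logistic(s, y), "separation")
  expect_true(fit$separation)
  expect_true(is.finite(fit$beta1))
  expect_gt(fit$t_lr, 0.4); expect_lt(fit$t_lr, 0.6)
  firth <- fit_logistic(s, y, method = "firth")
  expect_false(firth$separation)
  expect_lt(firth$beta1, fit$beta1)  # penalization shrinks the slope
  expect_true(is.finite(firth$se_beta1))
})

test_that("nagelkerke R2 matches its closed form and limits", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  # perfectly predicted balanced data: loglik -> 0
  ll0 <- 100 * log(0.5)
  expect_equal(nagelkerke_r2(ll0, 0, 100), 1)
  # frozen value computed from the closed form at ll1 = ll0 / 2:
  # (1 - exp(-0.6931472)) / (1 - exp(-1.3862944)) = 0.5 / 0.75
  expect_equal(nagelkerke_r2(ll0, ll0 / 2, 100), 2 / 3, tolerance = 1e-7)
  expect_error(nagelkerke_r2(-10, -5, 0), "positive")
})

test_that("Hosmer-Lemeshow is null at a perfect aggregate fit and powered
           against a mis-specified link", {
  y <- rep(c(0, 1), 50)
  hl <- hosmer_lemeshow(rep(0.5, 100), y, n_groups = 10)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)

  set.seed(45)
  rejected <- replicate(20, {
    x <- runif(1000)
    # probability steps at x = 0.5: no logistic in x fits this link
    y <- rbinom(1000, 1, ifelse(x > 0.5, 0.9, 0.1))
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(fitted(fit), y, 10)$p_value < 0.05
  })
  expect_gte(mean(rejected), 0.9)
})

test_that("predicted probabilities from published-style coefficients", {
  mdl <- calibration_model(-9.022, 1.380, scheme = "structural-keys-166")
  expect_equal(predict_probability(mdl, 0.650)$probability, 0.487,
               tolerance = 1e-3)
  expect_equal(predict_probability(mdl, mdl$t_lr)$probability, 0.5,
               tolerance = 1e-12)
  expect_true(is.na(predict_probability(mdl, 0.5)$ci_low))
})

test_that("confidence limits bracket the fitted curve", {
  set.seed(46)
  s <- runif(120)
  y <- rbinom(120, 1, plogis(-5 + 10 * s))
  fit <- fit_logistic(s, y)
  pr <- predict_probability(fit, seq(0.05, 0.95, 0.1))
  expect_true(all(pr$ci_low < pr$probability))
  expect_true(all(pr$probability < pr$ci_high))
})

test_that("outlier flagging finds a contrarian pair and refits stably", {
  set.seed(47)
  s <- runif(99, 0.1, 1)
  y <- as.integer(s >= 0.5)
  noise <- sample(which(abs(s - 0.5) < 0.15), 6)
  y[noise] <- 1 - y[noise]                     # keep the fit finite
  s <- c(s, 0.217); y <- c(y, 1)               # similar verdict at low s
  fit <- suppressWarnings(fit_logistic(s, y))
  flagged <- flag_outliers(fit)
  expect_true(100 %in% flagged)

  refit <- suppressWarnings(fit_logistic(s, y, exclude = flagged,
                                         pair_ids = sprintf("p%d", 1:100)))
  expect_true("p100" %in% refit$excluded_pairs)
  if (!fit$separation && !refit$separation) {
    expect_lt(abs(refit$beta1 - fit$beta1), 3 * fit$se_beta1)
  }
})

test_that("well-calibrated data yields no outlier flags", {
  # probabilities kept in [0.15, 0.85]: a Pearson residual cannot reach 3
  # unless the model is misfit
  set.seed(48)
  s <- runif(100)
  y <- rbinom(100, 1, plogis(-1.7 + 3.4 * s))
  fit <- fit_logistic(s, y)
  expect_length(flag_outliers(fit), 0)
})

test_that("grouped binomial fitting uses the vote fractions directly", {
  set.seed(49)
  s <- runif(80)
  m <- 143
  yf <- rbinom(80, m, plogis(-8 + 1.6 * 10 * s)) / m
  fit <- fit_logistic(s, yf, n_trials = m)
  expect_lt(abs(fit$beta1 - 1.6) / fit$se_beta1, 3)
  expect_lt(fit$se_beta1, 0.5)
})
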