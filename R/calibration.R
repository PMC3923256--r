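#' Majority label from an expert vote fraction
#'
#' A molecule pair is labeled `"similar"` when strictly more than 50% of the
#' panel answered Yes, mirroring majority voting in a committee: a 50/50
#' split is not a majority and yields `"non-similar"`.
#'
#' @param yes_fraction Numeric vector of Yes-vote fractions in \[0, 1\].
#' @return Character vector, `"similar"` or `"non-similar"`.
#' @export
label_majority <- function(yes_fraction) {
  stopifnot(is.numeric(yes_fraction))
  if (any(is.na(yes_fraction)) || any(yes_fraction < 0 | yes_fraction > 1)) {
    stop("yes_fraction must lie in [0, 1]", call. = FALSE)
  }
  ifelse(yes_fraction > 0.5, "similar", "non-similar")
}

# normalize label input to 0/1
to_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("similar", "non-similar")
    if (any(bad)) {
      stop("labels must be 'similar' or 'non-similar'; got: ",
           paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
    }
    as.integer(labels == "similar")
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    as.integer(labels)
  } else {
    stop("labels must be binary (similar/non-similar, logical, or 0/1)",
         call. = FALSE)
  }
}

# linear-predictor coefficient cap used when complete separation is detected
SEPARATION_CAP <- 30

#' Fit the logistic similarity calibration
#'
#' Models the probability that the expert majority calls a molecule pair
#' similar as a logistic function of its computed Tanimoto similarity:
#' \deqn{\mathrm{logit}\, p = \beta_0 + \beta_1 (10 s)}
#' Coefficients are reported on the 0.1-similarity scale, so that
#' \eqn{\exp(\beta_1)} is the odds multiplier per 0.1 increment in
#' similarity. The similarity at which the fitted probability crosses 0.5,
#' \eqn{t_{LR} = -\beta_0 / (10 \beta_1)}, is the calibrated decision
#' threshold.
#'
#' @param similarities Numeric vector of Tanimoto similarities in \[0, 1\].
#' @param labels Either binary majority labels (`"similar"`/`"non-similar"`,
#'   logical, or 0/1), or — when `n_trials` is supplied — per-pair Yes-vote
#'   fractions, fitted as grouped binomial counts out of `n_trials` votes.
#' @param n_trials Number of panel votes behind each fraction (scalar or
#'   vector), for the grouped-binomial fit. `NULL` (default) for binary
#'   labels.
#' @param method `"mle"` (iteratively reweighted least squares, the default)
#'   or `"firth"` (Jeffreys-prior penalized fit, binary labels only), useful
#'   when the classes are separable.
#' @param exclude Integer indices of observations to drop from the fit
#'   (recorded in the model as `excluded_pairs`); see [flag_outliers()].
#'   Exclusion is never automatic.
#' @param pair_ids Optional ids used to report exclusions.
#' @param hl_groups Number of Hosmer--Lemeshow groups (default 10).
#' @param scheme Optional fingerprint scheme name stored with the model.
#' @return A `calibration_model`: coefficients `beta0`, `beta1` (per 0.1
#'   similarity), standard errors, covariance, `r2_nagelkerke`,
#'   `hl_statistic`/`hl_pvalue`, threshold `t_lr`, `n_obs`, convergence and
#'   separation status. When complete separation is detected the returned
#'   coefficients are rescaled so the largest fitted linear predictor is
#'   `30` in absolute value (the 0.5-crossing is invariant to this
#'   rescaling) and `separation` is `TRUE`.
#' @export
fit_logistic <- function(similarities, labels, n_trials = NULL,
                         method = c("mle", "firth"), exclude = integer(),
                         pair_ids = NULL, hl_groups = 10, scheme = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.numeric(similarities), all(is.finite(similarities)))
  n_all <- length(similarities)
  stopifnot(length(labels) == n_all)
  if (is.null(pair_ids)) pair_ids <- as.character(seq_len(n_all))
  keep <- setdiff(seq_len(n_all), exclude)
  excluded_pairs <- pair_ids[setdiff(seq_len(n_all), keep)]
  s <- similarities[keep]
  x10 <- 10 * s
  n <- length(s)

  grouped <- !is.null(n_trials)
  if (grouped) {
    if (method == "firth") {
      stop("firth fitting is only supported for binary labels", call. = FALSE)
    }
    stopifnot(is.numeric(labels), all(labels >= 0 & labels <= 1))
    m <- rep_len(n_trials, n_all)[keep]
    yes <- round(labels[keep] * m)
    if (sum(yes) == 0 || sum(m - yes) == 0) {
      stop("one-class input: every vote fraction is on the same side",
           call. = FALSE)
    }
    fit_data <- data.frame(yes = yes, no = m - yes, x10 = x10)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(cbind(yes, no) ~ x10, family = stats::binomial(),
                 data = fit_data,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    y_bin <- NULL
    ll1 <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(
      stats::glm(cbind(yes, no) ~ 1, family = stats::binomial(),
                 data = fit_data)))
    hl <- hl_or_na(stats::fitted(fit), yes, hl_groups, n_trials = m)
  } else {
    y_bin <- to_binary_labels(labels)[keep]
    if (length(unique(y_bin)) < 2L) {
      stop("one-class input: need both similar and non-similar pairs",
           call. = FALSE)
    }
    if (min(tabulate(y_bin + 1L, 2L)) < 2L) {
      warning("fewer than 2 observations in one class; ",
              "estimates may be unstable")
    }
    if (method == "firth") {
      fit <- firth_logistic(x10, y_bin)
    } else {
      sep_warn <- FALSE
      fit <- withCallingHandlers(
        stats::glm(y_bin ~ x10, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w)))
            sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        })
    }
    ll1 <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(
      stats::glm(y_bin ~ 1, family = stats::binomial())))
    hl <- hl_or_na(stats::fitted(fit), y_bin, hl_groups)
  }

  beta <- stats::coef(fit)
  vc <- stats::vcov(fit)
  converged <- if (!is.null(fit$converged)) fit$converged else TRUE

  separation <- FALSE
  if (method != "firth") {
    lp <- beta[1] + beta[2] * x10
    separation <- sep_warn && max(abs(lp)) > SEPARATION_CAP * 2
    if (separation) {
      # rescale so the model stays finite; the 0.5-crossing is unchanged
      fac <- SEPARATION_CAP * 2 / max(abs(lp))
      beta <- beta * fac
      warning("complete or quasi-complete separation detected; ",
              "coefficients capped (consider method = 'firth')")
    }
  }

  model <- structure(list(
    scheme = scheme,
    beta0 = unname(beta[1]), beta1 = unname(beta[2]),
    se_beta0 = sqrt(vc[1, 1]), se_beta1 = sqrt(vc[2, 2]),
    vcov = vc,
    r2_nagelkerke = nagelkerke_r2(ll0, ll1, n),
    hl_statistic = hl$statistic, hl_pvalue = hl$p_value,
    loglik = ll1, loglik_null = ll0,
    n_obs = n, converged = converged, separation = separation,
    excluded_pairs = excluded_pairs,
    grouped = grouped,
    data = list(similarities = s, y = if (grouped) NULL else y_bin)
  ), class = "calibration_model")
  model$t_lr <- t_lr_from(model)
  model
}

# shrink the group count on small samples; below 6 observations the test
# is uninformative and reported as NA
hl_or_na <- function(p, y, n_groups, n_trials = NULL) {
  g <- min(n_groups, max(3, floor(length(p) / 2)))
  if (length(p) < g || length(p) < 6) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_integer_,
                n_groups_used = 0L, merged = FALSE))
  }
  hosmer_lemeshow(p, y, n_groups = g, n_trials = n_trials)
}

t_lr_from <- function(model) {
  if (is.na(model$beta1) || model$beta1 <= 0) {
    warning("non-positive slope; t_lr undefined")
    return(NA_real_)
  }
  -model$beta0 / (10 * model$beta1)
}

#' Construct a calibration model from known coefficients
#'
#' Builds a `calibration_model` directly from intercept and slope values
#' (on the 0.1-similarity scale), e.g. coefficients published for a
#' reference fingerprint, so that [predict_probability()] and threshold
#' arithmetic can be applied without refitting. No covariance is available,
#' so confidence limits are `NA`.
#'
#' @param beta0,beta1 Logit intercept and slope per 0.1 similarity.
#' @param scheme Optional scheme name.
#' @return A `calibration_model`.
#' @export
calibration_model <- function(beta0, beta1, scheme = NA_character_) {
  stopifnot(is.numeric(beta0), is.numeric(beta1),
            length(beta0) == 1L, length(beta1) == 1L)
  model <- structure(list(
    scheme = scheme, beta0 = beta0, beta1 = beta1,
    se_beta0 = NA_real_, se_beta1 = NA_real_, vcov = NULL,
    r2_nagelkerke = NA_real_, hl_statistic = NA_real_, hl_pvalue = NA_real_,
    loglik = NA_real_, loglik_null = NA_real_,
    n_obs = NA_integer_, converged = NA, separation = FALSE,
    excluded_pairs = character(0), grouped = NA, data = NULL
  ), class = "calibration_model")
  model$t_lr <- t_lr_from(model)
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>",
      if (!is.na(x$scheme)) paste0(" scheme: ", x$scheme), "\n",
      sprintf("  logit p = %.3f + %.3f * (10 s)   [per 0.1 similarity]\n",
              x$beta0, x$beta1), sep = "")
  if (!is.na(x$se_beta1)) {
    cat(sprintf("  SE(beta0) %.3f  SE(beta1) %.3f\n", x$se_beta0, x$se_beta1))
  }
  if (!is.na(x$r2_nagelkerke)) {
    cat(sprintf("  Nagelkerke R2 %.3f | HL X2 %.2f (p %.3f) | n %d\n",
                x$r2_nagelkerke, x$hl_statistic, x$hl_pvalue, x$n_obs))
  }
  cat(sprintf("  t_LR = %.3f", x$t_lr))
  if (isTRUE(x$separation)) cat("  [separation detected]")
  if (length(x$excluded_pairs)) {
    cat("  excluded:", paste(x$excluded_pairs, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# Jeffreys-prior (Firth) penalized logistic fit, binary response.
firth_logistic <- function(x10, y, maxit = 100, tol = 1e-8) {
  X <- cbind(1, x10)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X, W * X)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((X %*% XtWX_inv) * X) * W
    score <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(XtWX_inv %*% score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  vc <- solve(crossprod(X, W * X))
  dimnames(vc) <- list(c("(Intercept)", "x10"), c("(Intercept)", "x10"))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  structure(list(coefficients = stats::setNames(beta, c("(Intercept)", "x10")),
                 fitted.values = p, vcov_ = vc, loglik_ = ll,
                 converged = it < maxit),
            class = "firth_logistic")
}

#' @export
vcov.firth_logistic <- function(object, ...) object$vcov_

#' @export
logLik.firth_logistic <- function(object, ...) {
  structure(object$loglik_, df = 2, class = "logLik")
}

#' Nagelkerke pseudo R-squared
#'
#' Cox--Snell likelihood-ratio R-squared rescaled to attain 1 for a
#' perfectly predicted binary outcome:
#' \deqn{R^2 = \frac{1 - \exp(2(\ell_0 - \ell_1)/n)}{1 - \exp(2 \ell_0 / n)}}
#'
#' @param loglik_null,loglik_model Log-likelihoods of the intercept-only and
#'   fitted models (`loglik_model >= loglik_null`).
#' @param n_obs Number of observations.
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive", call. = FALSE)
  stopifnot(loglik_model >= loglik_null - 1e-8)
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n_obs)
  max_cs <- 1 - exp(2 * loglik_null / n_obs)
  if (max_cs <= 0) return(0)
  min(1, r2_cs / max_cs)
}

#' Hosmer--Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk test: observations are sorted by predicted probability
#' and split into `n_groups` near-equal groups (tied probabilities are kept
#' in the same group); the statistic compares observed and expected event
#' counts per group,
#' \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))},
#' referred to a chi-squared distribution with `n_groups - 2` degrees of
#' freedom. Groups whose expected count makes the denominator vanish are
#' merged with their neighbor (reported via `merged`).
#'
#' @param predicted_probs Fitted probabilities.
#' @param labels Binary outcomes (0/1 or similar/non-similar), or — when
#'   `n_trials` is given — per-observation success counts.
#' @param n_groups Number of risk groups (default 10, minimum 3).
#' @param n_trials Optional per-observation trial counts for grouped
#'   binomial data.
#' @return List with `statistic`, `p_value`, `df`, `n_groups_used`, and
#'   `merged` (whether any groups were merged).
#' @export
hosmer_lemeshow <- function(predicted_probs, labels, n_groups = 10,
                            n_trials = NULL) {
  stopifnot(n_groups >= 3, length(predicted_probs) >= n_groups)
  p <- predicted_probs
  n <- length(p)
  if (is.null(n_trials)) {
    y <- to_binary_labels(labels)
    m <- rep(1, n)
  } else {
    y <- as.numeric(labels)
    m <- rep_len(as.numeric(n_trials), n)
  }
  ord <- order(p)
  p <- p[ord]; y <- y[ord]; m <- m[ord]
  grp <- ceiling(seq_len(n) * n_groups / n)
  # keep ties together: every run of equal p goes to the group of its head
  grp <- stats::ave(grp, match(p, unique(p)), FUN = function(g) g[1])
  grp <- match(grp, sort(unique(grp)))

  O <- tapply(y, grp, sum)
  E <- tapply(p * m, grp, sum)
  Ng <- tapply(m, grp, sum)

  # merge groups with degenerate expected counts into their neighbor
  merged <- FALSE
  k <- 1
  while (k <= length(O)) {
    denom <- E[k] * (1 - E[k] / Ng[k])
    if (denom <= .Machine$double.eps * Ng[k] && length(O) > 1) {
      j <- if (k == length(O)) k - 1 else k + 1
      O[j] <- O[j] + O[k]; E[j] <- E[j] + E[k]; Ng[j] <- Ng[j] + Ng[k]
      O <- O[-k]; E <- E[-k]; Ng <- Ng[-k]
      merged <- TRUE
    } else {
      k <- k + 1
    }
  }
  denom <- E * (1 - E / Ng)
  stat <- sum((O - E)^2 / denom)
  df <- length(O) - 2
  p_value <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE)
             else NA_real_
  list(statistic = unname(stat), p_value = unname(p_value), df = df,
       n_groups_used = length(O), merged = merged)
}

#' Predicted probability of an expert-majority similar verdict
#'
#' Evaluates the calibration curve \eqn{p(s) = \mathrm{logistic}(\beta_0 +
#' \beta_1 \cdot 10 s)} with pointwise 95% confidence limits obtained on the
#' linear-predictor scale (\eqn{\pm 1.96} standard errors from the
#' coefficient covariance) and transformed through the logistic.
#'
#' @param model A `calibration_model`.
#' @param similarity Numeric vector of similarities.
#' @return Tibble with columns `similarity`, `probability`, `ci_low`,
#'   `ci_high` (limits are `NA` when the model carries no covariance).
#' @export
predict_probability <- function(model, similarity) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(similarity))
  x10 <- 10 * similarity
  eta <- model$beta0 + model$beta1 * x10
  prob <- stats::plogis(eta)
  if (!is.null(model$vcov)) {
    X <- cbind(1, x10)
    se_eta <- sqrt(rowSums((X %*% model$vcov) * X))
    ci_low <- stats::plogis(eta - 1.96 * se_eta)
    ci_high <- stats::plogis(eta + 1.96 * se_eta)
  } else {
    ci_low <- ci_high <- rep(NA_real_, length(eta))
  }
  tibble::tibble(similarity = similarity, probability = prob,
                 ci_low = ci_low, ci_high = ci_high)
}

#' Flag outlying pairs under a fitted calibration
#'
#' Flags observations whose standardized Pearson residual exceeds 3 in
#' absolute value — e.g. a pair the experts call similar despite a very low
#' computed similarity. Flagging never removes anything automatically; pass
#' the returned indices to `fit_logistic(exclude = ...)` to obtain a
#' second fit and report both.
#'
#' @param model A fitted `calibration_model`.
#' @param similarities,labels The data to assess (defaults to the data the
#'   model was fitted on, when stored).
#' @param threshold Absolute standardized-residual cutoff (default 3).
#' @return Integer indices of flagged observations (possibly empty).
#' @export
flag_outliers <- function(model, similarities = NULL, labels = NULL,
                          threshold = 3) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.null(similarities)) {
    if (is.null(model$data) || is.null(model$data$y)) {
      stop("model carries no binary data; supply similarities and labels",
           call. = FALSE)
    }
    similarities <- model$data$similarities
    y <- model$data$y
  } else {
    y <- to_binary_labels(labels)
  }
  x10 <- 10 * similarities
  p <- stats::plogis(model$beta0 + model$beta1 * x10)
  W <- p * (1 - p)
  X <- cbind(1, x10)
  XtWX_inv <- solve(crossprod(X, W * X))
  h <- rowSums((X %*% XtWX_inv) * X) * W
  r <- (y - p) / sqrt(pmax(W, .Machine$double.eps))
  r_std <- r / sqrt(pmax(1 - h, .Machine$double.eps))
  which(abs(r_std) > threshold)
}
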