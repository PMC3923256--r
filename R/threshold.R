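# the seven operating-point statistics, from exact integer counts
op_stats <- function(tp, tn, fp, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sens,
    specificity = spec,
    precision = ratio(tp, tp + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    f_index = ratio(2 * tp, 2 * tp + fp + fn),
    youden = sens + spec - 1,
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
}

#' Confusion-matrix statistics at a similarity threshold
#'
#' Classifies every pair as similar when its computed similarity is greater
#' than or equal to `t` (inclusive), tabulates the confusion matrix against
#' the expert majority labels, and derives sensitivity, specificity,
#' precision, accuracy, the F index, the Youden index (sensitivity +
#' specificity - 1) and the Matthews correlation coefficient. Ratios with a
#' zero denominator are reported as `NA`, never as 0.
#'
#' @param similarities Numeric vector in \[0, 1\].
#' @param labels Binary majority labels.
#' @param t Threshold.
#' @param model Optional `calibration_model`; when given, the calibrated
#'   probability at `t` is attached as `predicted_probability`.
#' @return An `operating_point`: threshold, the four counts, the seven
#'   statistics, and optionally the calibrated probability.
#' @export
confusion_at <- function(similarities, labels, t, model = NULL) {
  stopifnot(is.numeric(similarities), is.finite(t))
  if (length(similarities) == 0L) stop("empty input", call. = FALSE)
  y <- to_binary_labels(labels)
  stopifnot(length(y) == length(similarities))
  pred <- similarities >= t
  st <- op_stats(tp = sum(pred & y == 1), tn = sum(!pred & y == 0),
                 fp = sum(pred & y == 0), fn = sum(!pred & y == 1))
  st <- c(list(threshold = t), st)
  st$predicted_probability <- if (!is.null(model)) {
    predict_probability(model, t)$probability
  } else {
    NA_real_
  }
  structure(st, class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> t = %.3f\n", x$threshold))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf(
    "  sens %.3f spec %.3f prec %.3f acc %.3f F %.3f Youden %.3f MCC %.4f\n",
    x$sensitivity, x$specificity, x$precision, x$accuracy, x$f_index,
    x$youden, x$mcc))
  if (!is.na(x$predicted_probability)) {
    cat(sprintf("  calibrated probability at t: %.3f\n",
                x$predicted_probability))
  }
  invisible(x)
}

#' @export
as.data.frame.operating_point <- function(x, ...) {
  as.data.frame(x[c("threshold", "tp", "tn", "fp", "fn", "sensitivity",
                    "specificity", "precision", "accuracy", "f_index",
                    "youden", "mcc", "predicted_probability")])
}

# candidate thresholds: midpoints between consecutive distinct similarities
# plus sentinels below the minimum and above the maximum, so knife-edge
# equality with an observed value never decides a classification
candidate_thresholds <- function(similarities) {
  u <- sort(unique(similarities))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  sort(unique(c(u[1] - 0.5, mids, u, u[length(u)] + 0.5)))
}

#' ROC curve over all distinct operating thresholds
#'
#' Sweeps the classification threshold over the midpoints between
#' consecutive distinct similarity values (plus sentinels beyond the
#' observed range, which contribute the (0,0) and (1,1) corners) and
#' returns the full set of operating points ordered along the curve.
#'
#' @inheritParams confusion_at
#' @return Tibble with one row per threshold, ordered by (1 - specificity,
#'   sensitivity), containing the threshold, counts, and all statistics.
#' @export
roc_curve <- function(similarities, labels, model = NULL) {
  y <- to_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("ROC requires both similar and non-similar pairs", call. = FALSE)
  }
  ts <- candidate_thresholds(similarities)
  rows <- lapply(ts, function(t)
    as.data.frame(confusion_at(similarities, labels, t, model = model)))
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$fpr <- 1 - out$specificity
  out[order(out$fpr, out$sensitivity), , drop = FALSE]
}

#' Area under the ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). For a threshold
#' sweep over distinct-value midpoints this equals the Mann--Whitney
#' concordance probability with tied similarity values credited 1/2.
#'
#' @param roc A tibble from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  stopifnot(is.data.frame(roc),
            all(c("fpr", "sensitivity") %in% names(roc)))
  x <- roc$fpr; y <- roc$sensitivity
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Select the ROC-optimal operating threshold
#'
#' Among candidate thresholds whose sensitivity and specificity meet the
#' configured floors, returns the operating point maximizing the Youden
#' index; ties are broken by higher MCC, then higher accuracy, then smaller
#' threshold. If no candidate meets the floors they are relaxed with a
#' warning and the unconstrained Youden maximum is returned.
#'
#' @inheritParams confusion_at
#' @param min_sens,min_spec Sensitivity and specificity floors
#'   (defaults 0.90 and 0.85).
#' @return The selected `operating_point`.
#' @export
select_t_roc <- function(similarities, labels, min_sens = 0.9,
                         min_spec = 0.85, model = NULL) {
  y <- to_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("threshold selection requires both classes", call. = FALSE)
  }
  ts <- candidate_thresholds(similarities)
  pts <- lapply(ts, function(t) confusion_at(similarities, labels, t,
                                             model = model))
  ok <- vapply(pts, function(p) {
    !is.na(p$sensitivity) && !is.na(p$specificity) &&
      p$sensitivity >= min_sens && p$specificity >= min_spec
  }, logical(1))
  if (!any(ok)) {
    warning("no threshold satisfies the sensitivity/specificity floors (",
            min_sens, "/", min_spec, "); returning unconstrained optimum")
    ok <- rep(TRUE, length(pts))
  }
  cand <- pts[ok]
  key <- vapply(cand, function(p) p$youden, numeric(1))
  mccs <- vapply(cand, function(p) ifelse(is.na(p$mcc), -Inf, p$mcc),
                 numeric(1))
  accs <- vapply(cand, function(p) ifelse(is.na(p$accuracy), -Inf, p$accuracy),
                 numeric(1))
  tvals <- vapply(cand, function(p) p$threshold, numeric(1))
  ord <- order(-key, -mccs, -accs, tvals)
  cand[[ord[1]]]
}
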