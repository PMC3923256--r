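#' Classify similarity values against a threshold
#'
#' A pair is predicted `"similar"` when its computed similarity is greater
#' than or equal to the threshold (inclusive), `"non-similar"` otherwise.
#'
#' @param similarity Numeric vector.
#' @param threshold Scalar threshold.
#' @return Character vector of labels.
#' @export
classify_similarity <- function(similarity, threshold) {
  stopifnot(is.numeric(similarity), is.numeric(threshold),
            length(threshold) == 1L, is.finite(threshold))
  ifelse(similarity >= threshold, "similar", "non-similar")
}

#' Classify one profile row under one fingerprint scheme
#'
#' @param profile A one-row data frame (or list) carrying a similarity
#'   column named after `scheme`.
#' @param scheme Scheme name.
#' @param threshold Decision threshold for that scheme.
#' @return `"similar"` or `"non-similar"`.
#' @export
classify_pair <- function(profile, scheme, threshold) {
  if (!scheme %in% names(profile) || is.na(profile[[scheme]][1])) {
    stop("profile carries no similarity for scheme '", scheme, "'",
         call. = FALSE)
  }
  classify_similarity(profile[[scheme]][1], threshold)
}

#' Consensus vote over per-scheme classifications
#'
#' The consensus verdict is `"similar"` when at least `min_votes` of the
#' individual per-fingerprint classifications are similar (with the default
#' panel of fingerprints and `min_votes = 3`, "three or more" votes carry
#' the decision).
#'
#' @param labels Character vector of per-scheme labels.
#' @param min_votes Minimum number of similar votes (default 3).
#' @return `"similar"` or `"non-similar"`.
#' @export
consensus_vote <- function(labels, min_votes = 3) {
  stopifnot(length(labels) >= 1L, min_votes >= 1L,
            min_votes <= length(labels))
  n_sim <- sum(to_binary_labels(labels))
  if (n_sim >= min_votes) "similar" else "non-similar"
}

#' Correct-prediction counts per scheme and for the consensus
#'
#' Applies each scheme's thresholds to a labeled similarity table, counts
#' correct predictions under the calibration threshold (`t_lr`) and the
#' ROC-optimal threshold (`t_roc`), and appends the consensus row (at least
#' `min_votes` schemes voting similar). Pairs missing a similarity for any
#' scheme are excluded from the consensus row with a warning rather than
#' imputed.
#'
#' @param profiles Labeled similarity table: one column per scheme plus a
#'   `label` column of reference labels.
#' @param thresholds Data frame with columns `scheme`, `t_lr`, `t_roc`.
#' @param min_votes Consensus vote minimum (default 3).
#' @return Tibble with columns `scheme`, `correct_t_lr`, `correct_t_roc`;
#'   the final row is the consensus.
#' @export
count_correct <- function(profiles, thresholds, min_votes = 3) {
  stopifnot(is.data.frame(profiles), is.data.frame(thresholds),
            all(c("scheme", "t_lr", "t_roc") %in% names(thresholds)))
  if (!"label" %in% names(profiles)) {
    stop("profiles must carry a 'label' column", call. = FALSE)
  }
  if (any(is.na(profiles$label))) {
    stop("every profile must be labeled", call. = FALSE)
  }
  y <- to_binary_labels(profiles$label)
  schemes <- thresholds$scheme
  missing_cols <- setdiff(schemes, names(profiles))
  if (length(missing_cols)) {
    stop("profiles lack similarity columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(min_votes >= 1, min_votes <= length(schemes))

  pred <- function(kind) {
    vapply(seq_along(schemes), function(k) {
      t <- thresholds[[kind]][k]
      as.integer(profiles[[schemes[k]]] >= t)
    }, integer(nrow(profiles)))
  }
  sim_mat <- as.matrix(profiles[, schemes, drop = FALSE])
  complete <- !apply(is.na(sim_mat), 1, any)
  if (!all(complete)) {
    warning(sum(!complete), " pair(s) lack a similarity for some scheme; ",
            "excluded from the consensus count")
  }
  res <- lapply(c(t_lr = "t_lr", t_roc = "t_roc"), function(kind) {
    p <- pred(kind)  # n_pairs x n_schemes matrix of 0/1 votes
    if (nrow(profiles) == 1L) p <- matrix(p, nrow = 1L)
    per_scheme <- colSums(p == y, na.rm = TRUE)
    cons_vote <- as.integer(rowSums(p, na.rm = FALSE) >= min_votes)
    consensus <- sum(cons_vote[complete] == y[complete])
    c(per_scheme, consensus)
  })
  tibble::tibble(
    scheme = c(schemes, "consensus"),
    correct_t_lr = as.integer(res$t_lr),
    correct_t_roc = as.integer(res$t_roc)
  )
}
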