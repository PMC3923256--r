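#' Drug-likeness filter rule
#'
#' Bounds in the spirit of Lipinski's rule of five, as used to assemble a
#' drug-like training set: at most 10 hydrogen-bond acceptors, 5 donors,
#' molecular mass of at most 500 Daltons, logP of at most 5, and at least
#' one carbon atom.
#'
#' @param max_hba,max_hbd,max_mw,max_logp Inclusive upper bounds.
#' @param min_carbon Minimum carbon count (inclusive).
#' @return A `filter_rule` object.
#' @export
filter_rule <- function(max_hba = 10, max_hbd = 5, max_mw = 500,
                        max_logp = 5, min_carbon = 1) {
  stopifnot(is.finite(max_hba), is.finite(max_hbd), is.finite(max_mw),
            is.finite(max_logp), is.finite(min_carbon))
  structure(list(max_hba = max_hba, max_hbd = max_hbd, max_mw = max_mw,
                 max_logp = max_logp, min_carbon = min_carbon),
            class = "filter_rule")
}

#' Filter molecules by drug-likeness bounds
#'
#' @param mols List of `molecule_record` objects.
#' @param rule A [filter_rule()]; all comparisons against upper bounds are
#'   inclusive (a molecule exactly at every bound is retained).
#' @return The subset of `mols` satisfying every bound, in input order.
#' @export
filter_druglike <- function(mols, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  keep <- vapply(mols, function(m) {
    stopifnot(is_molecule_record(m))
    m$n_hba <= rule$max_hba && m$n_hbd <= rule$max_hbd &&
      m$mol_weight <= rule$max_mw && m$logp <= rule$max_logp &&
      m$n_carbon >= rule$min_carbon
  }, logical(1))
  mols[keep]
}

#' Select molecule pairs stratified over the similarity range
#'
#' Partitions the observed similarity range on a reference fingerprint
#' scheme into equal-width bins and samples pairs from each bin without
#' replacement, so that the selected set covers as wide and as even a spread
#' of Tanimoto values as possible. Shortfalls in sparse bins are
#' redistributed to the nearest bins that still hold candidates.
#'
#' @param profiles A similarity table (as from [pair_similarity_table()])
#'   containing the reference scheme column.
#' @param n_pairs Number of pairs to select.
#' @param n_bins Number of equal-width similarity bins (default 10).
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @param scheme Reference scheme column (default `circular-binary-r2`).
#' @return The selected rows of `profiles`, ordered by similarity.
#' @export
select_stratified_pairs <- function(profiles, n_pairs, n_bins = 10, seed = 1,
                                    scheme = "circular-binary-r2") {
  stopifnot(is.data.frame(profiles), n_pairs >= n_bins, n_bins >= 1)
  if (!scheme %in% names(profiles)) {
    stop("profiles lack a similarity column for scheme '", scheme, "'",
         call. = FALSE)
  }
  sims <- profiles[[scheme]]
  n_cand <- length(sims)
  if (n_cand == 0L) stop("no candidate pairs", call. = FALSE)
  if (n_cand < n_pairs) {
    stop("insufficient candidate pairs: need ", n_pairs, ", have ", n_cand,
         " (deficit ", n_pairs - n_cand, ")", call. = FALSE)
  }
  lo <- min(sims); hi <- max(sims)
  if (hi > lo) {
    breaks <- seq(lo, hi, length.out = n_bins + 1)
    bin <- findInterval(sims, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  } else {
    bin <- rep(1L, n_cand)
  }
  occupied <- sort(unique(bin))
  if (length(occupied) < n_bins && n_bins > 1L) {
    warning("only ", length(occupied), " of ", n_bins,
            " similarity bins contain candidate pairs")
  }

  withr::with_seed(seed, {
    quota <- integer(n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    # base allocation, then redistribute shortfall to nearest bins w/ spare
    quota[occupied] <- ceiling(n_pairs / n_bins)
    quota <- pmin(quota, counts)
    while (sum(quota) > n_pairs) {
      over <- which(quota == max(quota[quota > 0]))
      quota[over[length(over)]] <- quota[over[length(over)]] - 1L
    }
    while (sum(quota) < n_pairs) {
      spare <- counts - quota
      cand_bins <- which(spare > 0)
      # nearest bin (by index) to an under-full one; preserves spread
      under <- which(quota < ceiling(n_pairs / n_bins))
      if (length(under) == 0L) under <- seq_len(n_bins)
      gaps <- vapply(cand_bins, function(b) min(abs(b - under)), numeric(1))
      pick <- cand_bins[which.min(gaps)]
      quota[pick] <- quota[pick] + 1L
    }
    sel <- integer(0)
    for (b in seq_len(n_bins)) {
      if (quota[b] == 0L) next
      members <- which(bin == b)
      sel <- c(sel, if (length(members) == 1L) members else
        sample(members, quota[b]))
    }
  })
  out <- profiles[sel[order(sims[sel])], , drop = FALSE]
  rownames(out) <- NULL
  out
}
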