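# Independent oracles used to cross-check the implementation.

# set-based Tanimoto for binary vectors: |A n B| / |A u B|
tanimoto_set_oracle <- function(a, b) {
  A <- which(a > 0)
  B <- which(b > 0)
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

# Mann-Whitney concordance probability with ties credited 1/2 (O(n^2))
auc_concordance_oracle <- function(similarities, labels) {
  y <- as.integer(labels == "similar" | labels == 1 | labels == TRUE)
  pos <- similarities[y == 1]
  neg <- similarities[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# build a fingerprint object directly (for arithmetic tests)
make_fp <- function(values, scheme = "circular-count-r2",
                    length = base::length(values)) {
  structure(list(scheme = scheme, length = length,
                 values = as.integer(values)),
            class = "fingerprint")
}

# a molecule record with chosen descriptors (for filter tests)
make_record <- function(id, mw = 300, hba = 2, hbd = 1, logp = 2,
                        n_carbon = 10) {
  structure(list(id = id, smiles = "", mol_weight = mw, n_hba = hba,
                 n_hbd = hbd, logp = logp, n_carbon = n_carbon),
            class = "molecule_record")
}

# similarity/label vectors realizing a given confusion matrix at t = 0.5
confusion_fixture <- function(tp, fn, tn, fp) {
  list(
    similarities = c(rep(0.75, tp), rep(0.25, fn), rep(0.25, tn),
                     rep(0.75, fp)),
    labels = c(rep("similar", tp + fn), rep("non-similar", tn + fp))
  )
}
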