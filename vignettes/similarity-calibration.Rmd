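---
title: "Calibrating fingerprint similarity against expert judgment: methods"
author: "simcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating fingerprint similarity against expert judgment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcal)
```

## The problem

When a committee of experts must decide whether a candidate medicine is
structurally similar to an already-authorized drug — as happens in orphan-drug
market-exclusivity assessment — the decision is a majority vote over
subjective binary judgments. Computed 2D-fingerprint Tanimoto similarity is
objective and reproducible, but it lives on an arbitrary \[0, 1\] scale whose
meaning differs between fingerprint types: a Tanimoto of 0.5 under one scheme
may correspond to obvious structural kinship, under another to a marginal
resemblance. `simcal` calibrates that scale: it fits the probability that an
expert majority would call a molecule pair *similar* as a function of the
computed similarity, and derives the operating thresholds a decision-support
tool needs.

## The model

Let $s \in [0,1]$ be the Tanimoto similarity of a molecule pair under one
fingerprint scheme, and $p(s)$ the probability that strictly more than 50% of
a panel answers "Yes, similar". The calibration is an ordinary logistic
regression on the 0.1-similarity scale,

$$\operatorname{logit} p = \beta_0 + \beta_1 (10\,s),$$

so that $e^{\beta_1}$ is the odds multiplier per 0.1 increment of similarity
— the scale on which such calibrations are conventionally reported. Two
thresholds fall out of the analysis:

* $t_{LR} = -\beta_0 / (10\,\beta_1)$, the similarity at which the fitted
  probability crosses 0.5. This is an *identity* of the model, and
  `fit_logistic()` guarantees it to numerical precision
  (`predict_probability(model, model$t_lr)` is 0.5).
* $t_{ROC}$, chosen by sweeping a classification threshold over the data and
  maximizing the Youden index ($\text{sens} + \text{spec} - 1$) subject to
  sensitivity/specificity floors, with ties broken by MCC, then accuracy,
  then smaller threshold.

At near-balanced prevalence the two thresholds agree closely; they diverge as
prevalence moves away from one half, which is why both are reported and both
are applied to any external test set.

Fit quality is summarized by Nagelkerke's $R^2$ (a rescaled Cox–Snell
likelihood-ratio statistic in \[0, 1\]) and the Hosmer–Lemeshow
deciles-of-risk test (default 10 groups, $\chi^2$ with $g-2$ degrees of
freedom, groups with degenerate expected counts merged with a neighbor).
Classification of a pair is always *inclusive*: predicted similar when
$s \ge t$.

## Fingerprint schemes

Five open 2D fingerprint families are provided, spanning the main design axes
found in commercial fingerprints:

| scheme | construction | length (default) |
|---|---|---|
| `circular-binary-r2` | hashed circular atom environments, radius 2 (diameter 4), presence | 1024 |
| `circular-count-r2` | same environments, occurrence counts | 1024 |
| `path-hashed-binary` | all simple atom/bond paths up to 7 bonds, hashed | 2048 |
| `structural-keys-166` | the 166 MACCS structural keys (via Open Babel) | 166 (fixed) |
| `generic-keys` | hashed topological atom-pair keys | 1024 |

Circular environments use invariants (element, degree, bond-order sum, ring
membership) refined iteratively, in the ECFP manner; the count variant sums
occurrences into each folded position, and on 0/1 vectors count-Tanimoto
($\sum\min/\sum\max$) reduces *exactly* to the binary set form — a property
the test suite verifies against an exhaustive set-based oracle. Hashing uses
a fixed 32-bit FNV-1a over integer token streams, so fingerprints are
bit-reproducible across platforms; molecules are canonicalized (Open Babel)
before hashing, so any SMILES variant of a structure yields the same vector.
Commercial fingerprints (BCI, Daylight, Unity, Pipeline Pilot ECFP) cannot be
reproduced bit-exactly without the licensed software; the pipeline is
deliberately scheme-agnostic and every conclusion (coefficients, thresholds,
consensus behaviour) is re-derived per scheme rather than assumed to
transfer.

Two Tanimoto edge cases are fixed by policy: two all-zero fingerprints
compare as 0 with a warning (an empty representation carries no evidence of
similarity — the conservative choice for a dissimilarity-sensitive,
regulatory use), and salts are reduced to their largest covalent fragment
before fingerprinting, since expert assessments concern the active moiety.

## Dataset construction

`filter_druglike()` applies inclusive rule-of-five-style bounds (≤10
H-bond acceptors, ≤5 donors, ≤500 Da, logP ≤5, ≥1 carbon).
`select_stratified_pairs()` partitions the observed similarity range into
`n_bins` equal-width bins (default 10 — the source procedure says only "as
wide and as equal a spread as possible", so the bin count is a package
choice) and samples evenly from each without replacement, redistributing
shortfalls from sparse bins to their nearest neighbours to preserve spread.
Duplicate-structure pairs (similarity 1.0) are allowed; observed ranges in
real panel studies reach 1.0.

## The synthetic expert panel

No public dataset pairs molecule structures with per-pair expert vote
fractions, so the generator produces one with the statistical structure such
a study exhibits:

* **Similarities.** `abstract-grid` mode places $(1-\pi) n$ values evenly
  below and $\pi n$ above the population threshold, spanning
  $[0.116, 1.0]$ with uniform jitter, where $\pi$ is the target prevalence
  (0.49 for training, 0.11 for the external-test regime). Values keep a
  0.005 margin from the threshold itself: this pins the realized prevalence
  near its target while still populating the ambiguous zone around the
  threshold. `analog-series` mode instead computes *real* circular-fingerprint
  Tanimoto values over substituent-enumerated analogs of four packaged
  drug-like scaffolds (aryloxypropanolamine, benzodiazepinone,
  arylsulfonamide, phenothiazine cores — echoing common pharmacological
  classes), including exact self-pairs at similarity 1.
* **Votes.** Expert $j$ has a personal intercept offset
  $\delta_j \sim N(0, \sigma^2)$ (default $\sigma = 2$ on the log-odds
  scale); votes are independent Bernoulli with
  $p_{ij} = \operatorname{logistic}(\beta_0 + \delta_j + \beta_1\,10 s_i)$,
  with defaults $\beta_0 = -12.75$, $\beta_1 = 2.5$ near a strong circular-
  fingerprint calibration. Heterogeneity enters only through intercepts: a
  random-slope model is not identifiable from 100 pairs and intercept
  spread alone reproduces the qualitative signature of real panels — a
  bimodal agreement histogram with most pairs in clear consensus
  (vote fraction below 0.1 or at least 0.9) and a visible minority band of
  genuine disagreement.

What the generator does **not** emulate: depiction and alignment effects on
human perception (a real panel judges drawn structures, and unaligned
depictions demonstrably depress perceived similarity), correlations between
experts, pair-level idiosyncrasies (a real pair can strike experts as
similar for reasons no fingerprint captures), and instability of a single
expert across occasions. Consequently, passing the end-to-end tests shows
the *pipeline* is correct under its stated model, not that any particular
fingerprint would achieve the same accuracy on a new human panel.

One structural consequence deserves emphasis: with 143 experts the
panel-mean vote is nearly deterministic given similarity, so *majority
labels* derived from the generator are close to a step function and a
binary-label logistic fit on them is frequently separable. The package
detects separation, caps the coefficients (rescaling leaves $t_{LR}$
invariant) and flags the model, with an optional Jeffreys-prior (Firth)
penalized fit; parameter-recovery validation fits the vote *fractions* as
grouped binomial counts, which is the information-preserving route.

## Numerical choices

* Logistic fits use IRLS (`stats::glm`) with convergence tolerance $10^{-8}$
  and at most 100 iterations.
* All confusion-matrix statistics are computed from exact integer counts;
  ratios with zero denominators are `NA`, never silently 0. Reports round to
  3 decimals (4 for MCC); internal values keep full precision.
* ROC candidate thresholds are the midpoints between consecutive distinct
  similarities, the observed values themselves, and sentinels beyond the
  range — so knife-edge equality never decides a classification, and the
  (0,0)/(1,1) corners are always present. Trapezoidal AUC over this sweep
  equals the Mann–Whitney concordance probability with ties credited 1/2
  (verified to $10^{-12}$ against an $O(n^2)$ oracle).
* The Youden index is sensitivity + specificity − 1 throughout.
* Outlier flagging uses |standardized Pearson residual| > 3; removal is
  never automatic — the screened refit carries its predecessor and the
  excluded pair ids.
* Ties at vote fraction exactly 0.5 are *non-similar* (a 50/50 split is not
  a majority).
* Consensus over an even number of schemes: exactly `min_votes` similar
  votes suffice ("three or more" of six carries). Pairs missing a scheme's
  similarity are excluded from consensus with a warning rather than imputed.

## Problem sizes used in validation

The stochastic test suite uses sizes that keep the full run in well under a
minute of simulation time while leaving comfortable statistical margins:
parameter recovery over 200 simulated panels (100 pairs × 143 experts),
Hosmer–Lemeshow size over 500 well-specified replicates of $n = 500$,
AUC–concordance equivalence over 100 random datasets of $n = 100$, and
end-to-end train/test transfer over 10 seeds. The simulated full pipeline
(`run_full`) uses the analog-series source: 48 molecules, ~1100 candidate
pairs, 100 training and 100 test pairs across all five schemes.

## Known limitations

* Commercial fingerprint emulation is approximate by design; coefficients
  fitted here are not interchangeable with those published for BCI, Daylight
  or Unity fingerprints, and any regulatory use must recalibrate per scheme.
* Descriptor-based similarity (physicochemical property vectors) is out of
  scope, as are similarity coefficients other than Tanimoto, 3D/shape
  methods, multi-predictor calibrations and weighted fusion.
* Molecules with a single heavy atom are rejected (no 2D substructural
  information; the upstream SDF round-trip also cannot represent them).
* The rater-level vote model is unvalidatable against published studies,
  which report only aggregate fractions; it is a modelling choice, stated
  rather than guessed from data.
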