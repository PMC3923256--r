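#' Configuration for the synthetic expert-panel generator
#'
#' The generator emulates the statistical structure of an expert-panel
#' similarity study: a set of molecule pairs spanning the practical Tanimoto
#' range (roughly 0.12 to 1.00), a large heterogeneous panel whose members
#' differ in their personal leniency, and a vote model in which the log-odds
#' of a Yes vote rise linearly with computed similarity. Defaults mirror a
#' regulatory-style study: 100 pairs, 143 experts, logit coefficients near a
#' strong circular-fingerprint calibration (\eqn{\beta_0 = -12.75},
#' \eqn{\beta_1 = 2.5} per 0.1 similarity), expert heterogeneity
#' (`expert_sd = 2` on the log-odds scale) strong enough to produce the
#' characteristic bimodal agreement distribution, and a near-balanced
#' training prevalence of 0.49 (an imbalanced external test set is typically
#' drawn at 0.11).
#'
#' @param n_pairs Number of molecule pairs (default 100).
#' @param n_experts Panel size (default 143).
#' @param beta0_true,beta1_true Population logit coefficients, slope per 0.1
#'   similarity.
#' @param expert_sd Standard deviation of per-expert intercept offsets
#'   (log-odds scale, `>= 0`).
#' @param similarity_source `"abstract-grid"` (similarity values placed to
#'   span the range directly) or `"analog-series"` (real Tanimoto values
#'   computed over enumerated substituent analogs of packaged scaffolds).
#' @param prevalence_target Intended fraction of similar pairs, in (0, 1).
#' @param seed Integer seed; every generator operation is a pure function of
#'   the configuration including this seed.
#' @return A `panel_sim_config` object.
#' @export
panel_sim_config <- function(n_pairs = 100, n_experts = 143,
                             beta0_true = -12.75, beta1_true = 2.5,
                             expert_sd = 2.0,
                             similarity_source = c("abstract-grid",
                                                   "analog-series"),
                             prevalence_target = 0.49, seed = 1) {
  similarity_source <- match.arg(similarity_source)
  stopifnot(n_pairs >= 2, n_experts >= 1, expert_sd >= 0,
            prevalence_target > 0, prevalence_target < 1,
            beta1_true >= 0, is.finite(beta0_true))
  structure(list(
    n_pairs = as.integer(n_pairs), n_experts = as.integer(n_experts),
    beta0_true = beta0_true, beta1_true = beta1_true,
    expert_sd = expert_sd, similarity_source = similarity_source,
    prevalence_target = prevalence_target, seed = as.integer(seed)
  ), class = "panel_sim_config")
}

# similarity at which the population-average vote probability crosses 0.5
# (the expert offsets are symmetric, so this is -beta0 / (10 beta1))
true_threshold <- function(config) {
  -config$beta0_true / (10 * config$beta1_true)
}

#' Simulate per-pair similarity values
#'
#' In `"abstract-grid"` mode, places `floor((1 - prevalence) n)` values
#' evenly below the population threshold and the rest evenly above it,
#' spanning \[0.116, 1.0\] with uniform jitter — an idealization of a
#' training set assembled to cover the similarity range with a target
#' prevalence. In `"analog-series"` mode, returns real circular-fingerprint
#' Tanimoto values computed over substituent-enumerated analog series of
#' packaged drug-like scaffolds (including self-pairs at similarity 1).
#'
#' @param config A [panel_sim_config()].
#' @return Numeric vector of `n_pairs` similarities; deterministic per seed.
#' @export
simulate_similarities <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  if (config$similarity_source == "analog-series") {
    return(analog_profiles(config)$similarity)
  }
  n <- config$n_pairs
  lo_edge <- 0.116
  hi_edge <- 1.0
  if (config$beta1_true == 0) {
    # flat vote model: no threshold exists; cover the range evenly
    withr::with_seed(config$seed, {
      s <- seq(lo_edge, hi_edge, length.out = n)
      step <- diff(s[1:2])
      s <- pmin(pmax(s + stats::runif(n, -0.3, 0.3) * step, 0.02), 1)
    })
    return(s)
  }
  t_star <- true_threshold(config)
  # keep a sliver clear of the threshold so the target prevalence is met in
  # expectation, while still populating the ambiguous mid-agreement zone
  margin <- 0.005
  n_hi <- max(1L, round(n * config$prevalence_target))
  n_lo <- n - n_hi
  withr::with_seed(config$seed, {
    lo <- seq(lo_edge, t_star - margin, length.out = max(n_lo, 1L))
    hi <- seq(t_star + margin, hi_edge, length.out = n_hi)
    step_lo <- if (n_lo > 1) diff(lo[1:2]) else 0.01
    step_hi <- if (n_hi > 1) diff(hi[1:2]) else 0.01
    lo <- lo + stats::runif(length(lo), -0.3, 0.3) * step_lo
    hi <- hi + stats::runif(length(hi), -0.3, 0.3) * step_hi
    s <- c(if (n_lo > 0) pmin(pmax(lo, 0.02), t_star - 0.002),
           pmin(pmax(hi, t_star + 0.002), 1))
  })
  s
}

#' Simulate expert-panel Yes-vote fractions
#'
#' Each expert j carries a personal intercept offset
#' \eqn{\delta_j \sim N(0, \mathrm{expert\_sd}^2)}; their votes on pair i
#' are independent Bernoulli draws with
#' \eqn{p_{ij} = \mathrm{logistic}(\beta_0 + \delta_j + \beta_1 \cdot 10
#' s_i)}. The returned Yes fraction for a pair is the mean vote across the
#' panel. Heterogeneous panels (`expert_sd > 0`) spread intermediate
#' agreement values and reproduce the bimodal agreement histogram seen in
#' real panels.
#'
#' @param similarities Numeric vector in \[0, 1\].
#' @param config A [panel_sim_config()].
#' @return Numeric vector of Yes fractions, one per pair; deterministic per
#'   seed.
#' @export
simulate_votes <- function(similarities, config) {
  stopifnot(inherits(config, "panel_sim_config"),
            all(similarities >= 0 & similarities <= 1))
  n <- length(similarities)
  m <- config$n_experts
  withr::with_seed(config$seed + 1L, {
    delta <- stats::rnorm(m, 0, config$expert_sd)
    lp <- outer(delta, config$beta0_true + config$beta1_true * 10 *
                  similarities, "+")
    votes <- matrix(stats::rbinom(m * n, 1L, stats::plogis(lp)), nrow = m)
    yf <- colMeans(votes)
  })
  yf
}

#' Simulate a labeled training set
#'
#' Similarities, panel vote fractions and majority labels in one table,
#' ready for calibration.
#'
#' @param config A [panel_sim_config()].
#' @return Tibble with `pair_id`, `similarity`, `yes_fraction`, `label`.
#' @export
simulate_training_set <- function(config) {
  s <- simulate_similarities(config)
  yf <- simulate_votes(s, config)
  tibble::tibble(
    pair_id = sprintf("pair%03d", seq_along(s)),
    similarity = s,
    yes_fraction = yf,
    label = label_majority(yf)
  )
}

#' Simulate a labeled external test set
#'
#' Same generative model as [simulate_training_set()] but with an imbalanced
#' prevalence (default 0.11, typical of a regulatory submission stream where
#' applicants avoid obviously similar molecules) and an independent random
#' stream, so a training and a test set built from the same configuration do
#' not share draws.
#'
#' @param config A [panel_sim_config()].
#' @param prevalence Similar-pair prevalence for the test regime (default
#'   0.11); `NULL` keeps the configuration's value.
#' @return Tibble with `pair_id`, `similarity`, `yes_fraction`, `label`.
#' @export
simulate_testset <- function(config, prevalence = 0.11) {
  stopifnot(inherits(config, "panel_sim_config"))
  cfg <- config
  if (!is.null(prevalence)) cfg$prevalence_target <- prevalence
  cfg$seed <- config$seed + 7919L  # independent stream from the training set
  out <- simulate_training_set(cfg)
  out$pair_id <- sub("^pair", "test", out$pair_id)
  out
}

# ---- analog-series similarity source ------------------------------------

# Drug-like scaffold templates with one open substitution site. Synthetic
# series constructed for the generator; chosen to echo common pharmacological
# classes (aryloxypropanolamine beta-blocker cores, benzodiazepinone,
# arylsulfonamide, phenothiazine-like) without any external data dependency.
ANALOG_SCAFFOLDS <- list(
  beta_blocker = "CC(C)NCC(O)COc1ccc(%s)cc1",
  benzodiazepinone = "O=C1CN=C(c2ccccc2)c2cc(%s)ccc2N1",
  sulfonamide = "NS(=O)(=O)c1ccc(%s)cc1",
  phenothiazine = "CN(C)CCCN1c2ccccc2Sc2ccc(%s)cc21"
)

ANALOG_SUBSTITUENTS <- c("", "C", "CC", "CCC", "O", "OC", "N", "F", "Cl",
                         "C(=O)O", "C(=O)OC", "S(C)(=O)=O")

analog_smiles <- function() {
  out <- list()
  for (sc in names(ANALOG_SCAFFOLDS)) {
    tpl <- ANALOG_SCAFFOLDS[[sc]]
    for (k in seq_along(ANALOG_SUBSTITUENTS)) {
      sub <- ANALOG_SUBSTITUENTS[k]
      smi <- sprintf(tpl, sub)
      if (sub == "") smi <- gsub("()", "", smi, fixed = TRUE)
      out[[paste0(sc, "_", k)]] <- smi
    }
  }
  out
}

# pair table over the analog series: all within-series pairs, one self-pair
# per series, and a deterministic sample of cross-series pairs
analog_profiles <- function(config) {
  smi <- analog_smiles()
  ids <- names(smi)
  series <- sub("_[0-9]+$", "", ids)
  mols <- mapply(parse_molecule, unlist(smi), ids, SIMPLIFY = FALSE)
  pairs <- list()
  for (sc in unique(series)) {
    members <- which(series == sc)
    idx <- utils::combn(members, 2)
    for (c_i in seq_len(ncol(idx))) {
      a <- idx[1, c_i]; b <- idx[2, c_i]
      pairs[[paste0(ids[a], "|", ids[b])]] <- list(mols[[a]], mols[[b]])
    }
    pairs[[paste0(ids[members[1]], "|", ids[members[1]])]] <-
      list(mols[[members[1]]], mols[[members[1]]])
  }
  cross <- utils::combn(match(unique(series), series), 2)
  for (c_i in seq_len(ncol(cross))) {
    a <- cross[1, c_i]; b <- cross[2, c_i]
    pairs[[paste0(ids[a], "|", ids[b])]] <- list(mols[[a]], mols[[b]])
  }
  prof <- pair_similarity_table(pairs, schemes = "circular-binary-r2")
  names(prof)[names(prof) == "circular-binary-r2"] <- "similarity"
  n_avail <- nrow(prof)
  n <- min(config$n_pairs, n_avail)
  withr::with_seed(config$seed, {
    sel <- sort(sample.int(n_avail, n))
  })
  prof[sel, , drop = FALSE]
}
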