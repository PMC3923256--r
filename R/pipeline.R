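#' Configuration for a full calibration run
#'
#' @param mode `"simulate"` (synthetic analog-series study, no input files)
#'   or `"files"` (molecule pairs and expert votes read from CSV).
#' @param pairs_file,votes_file Training inputs for `"files"` mode: a pair
#'   CSV (`pair_id`, `smiles_a`, `smiles_b`) and a vote CSV (`pair_id`,
#'   `yes_fraction`).
#' @param test_pairs_file,test_votes_file Optional labeled test set in
#'   `"files"` mode.
#' @param schemes Fingerprint schemes to calibrate (default all five).
#' @param reference_scheme Scheme driving simulated expert votes and
#'   stratified selection.
#' @param min_sens,min_spec Floors for ROC threshold selection.
#' @param min_votes Consensus vote minimum.
#' @param drop_outliers If `TRUE`, pairs flagged by [flag_outliers()] are
#'   refitted without; both fits are reported.
#' @param sim A [panel_sim_config()] for `"simulate"` mode; its seed is
#'   taken from `seed`.
#' @param seed Integer seed recorded in every output.
#' @param digits Report rounding (3; MCC uses 4).
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("simulate", "files"),
                       pairs_file = NULL, votes_file = NULL,
                       test_pairs_file = NULL, test_votes_file = NULL,
                       schemes = fingerprint_schemes(),
                       reference_scheme = "circular-binary-r2",
                       min_sens = 0.9, min_spec = 0.85, min_votes = 3,
                       drop_outliers = FALSE,
                       sim = NULL, seed = 1, digits = 3) {
  mode <- match.arg(mode)
  if (length(schemes) == 0L) stop("empty scheme list", call. = FALSE)
  for (s in schemes) check_scheme(s)
  check_scheme(reference_scheme)
  if (mode == "files") {
    for (f in c(pairs_file, votes_file, test_pairs_file, test_votes_file)) {
      if (!is.null(f) && !file.exists(f)) {
        stop("input file not found: ", f, call. = FALSE)
      }
    }
    if (is.null(pairs_file) || is.null(votes_file)) {
      stop("files mode needs pairs_file and votes_file", call. = FALSE)
    }
  }
  if (is.null(sim)) {
    sim <- panel_sim_config(similarity_source = "analog-series", seed = seed)
  }
  sim$seed <- as.integer(seed)
  stopifnot(min_votes >= 1, min_votes <= length(schemes))
  structure(list(
    mode = mode, pairs_file = pairs_file, votes_file = votes_file,
    test_pairs_file = test_pairs_file, test_votes_file = test_votes_file,
    schemes = schemes, reference_scheme = reference_scheme,
    min_sens = min_sens, min_spec = min_spec, min_votes = min_votes,
    drop_outliers = drop_outliers, sim = sim, seed = as.integer(seed),
    digits = digits
  ), class = "run_config")
}

config_hash <- function(config) {
  hash_string(paste(deparse(unclass(config)), collapse = ""))
}

#' Calibrate one fingerprint scheme against expert votes
#'
#' Majority-labels the vote fractions, fits the logistic calibration, and
#' optionally refits without flagged outliers (both fits retained: the
#' outlier-screened fit carries the original as `$initial_fit`).
#'
#' @param similarities Tanimoto similarities for one scheme.
#' @param yes_fraction Expert Yes-vote fractions.
#' @param pair_ids Pair identifiers.
#' @param scheme Scheme name recorded in the model.
#' @param drop_outliers Refit without flagged pairs (never silently; the
#'   exclusions are listed in the model).
#' @return A `calibration_model`.
#' @export
calibrate_scheme <- function(similarities, yes_fraction,
                             pair_ids = NULL, scheme = NA_character_,
                             drop_outliers = FALSE) {
  labels <- label_majority(yes_fraction)
  fit <- fit_logistic(similarities, labels, pair_ids = pair_ids,
                      scheme = scheme)
  if (drop_outliers) {
    flagged <- flag_outliers(fit)
    if (length(flagged) > 0) {
      refit <- fit_logistic(similarities, labels, exclude = flagged,
                            pair_ids = pair_ids, scheme = scheme)
      refit$initial_fit <- fit
      return(refit)
    }
  }
  fit
}

# assemble the simulated study: an analog-series candidate pool, a
# stratified training selection, a low-prevalence test selection, and
# simulated panel votes for both
simulate_study <- function(config) {
  sim <- config$sim
  ref <- config$reference_scheme
  smi <- analog_smiles()
  ids <- names(smi)
  mols <- mapply(parse_molecule, unlist(smi), ids, SIMPLIFY = FALSE)
  idx <- utils::combn(length(mols), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(k) {
    list(mols[[idx[1, k]]], mols[[idx[2, k]]])
  })
  names(pairs) <- paste0(ids[idx[1, ]], "|", ids[idx[2, ]])
  # self-pairs: the observed similarity range reaches 1.0
  for (k in seq(1, length(mols), by = 12)) {
    pairs[[paste0(ids[k], "|", ids[k])]] <- list(mols[[k]], mols[[k]])
  }
  schemes <- union(config$schemes, ref)
  cand <- pair_similarity_table(pairs, schemes = schemes)

  train <- select_stratified_pairs(cand, n_pairs = sim$n_pairs,
                                   n_bins = 10, seed = sim$seed,
                                   scheme = ref)
  rest <- cand[!cand$pair_id %in% train$pair_id, , drop = FALSE]

  t_star <- true_threshold(sim)
  hi_pool <- which(rest[[ref]] >= t_star)
  lo_pool <- which(rest[[ref]] < t_star)
  n_test <- min(sim$n_pairs, nrow(rest))
  n_hi <- min(length(hi_pool), max(1L, round(0.11 * n_test)))
  n_lo <- min(length(lo_pool), n_test - n_hi)
  withr::with_seed(sim$seed + 17L, {
    test_idx <- c(sample(hi_pool, n_hi), sample(lo_pool, n_lo))
  })
  test <- rest[sort(test_idx), , drop = FALSE]

  train$yes_fraction <- simulate_votes(train[[ref]], sim)
  train$label <- label_majority(train$yes_fraction)
  test_cfg <- sim
  test_cfg$seed <- sim$seed + 7919L
  test$yes_fraction <- simulate_votes(test[[ref]], test_cfg)
  test$label <- label_majority(test$yes_fraction)
  list(train = train, test = test)
}

load_study <- function(config) {
  profiles <- pair_similarity_table(read_pairs_csv(config$pairs_file),
                                    schemes = config$schemes)
  votes <- read_votes_csv(config$votes_file)
  train <- merge(profiles, votes, by = "pair_id", sort = FALSE)
  if (nrow(train) == 0L) {
    stop("no pairs shared between pairs and votes files", call. = FALSE)
  }
  train$label <- label_majority(train$yes_fraction)
  test <- NULL
  if (!is.null(config$test_pairs_file)) {
    tp <- pair_similarity_table(read_pairs_csv(config$test_pairs_file),
                                schemes = config$schemes)
    if (!is.null(config$test_votes_file)) {
      tv <- read_votes_csv(config$test_votes_file)
      tp <- merge(tp, tv, by = "pair_id", sort = FALSE)
      tp$label <- label_majority(tp$yes_fraction)
    }
    test <- tibble::as_tibble(tp)
  }
  list(train = tibble::as_tibble(train), test = test)
}

#' Run the full calibration pipeline
#'
#' Assembles the labeled training data (simulated analog-series study or
#' user files), fits the logistic calibration per fingerprint scheme, sweeps
#' ROC curves and selects operating thresholds, and — when a labeled test
#' set is available — evaluates per-scheme and consensus correct-prediction
#' counts.
#'
#' @param config A [run_config()].
#' @return A `simcal_run` list: `calibration` (per-scheme coefficient and
#'   fit summary), `operating` (selected operating points), `thresholds`,
#'   `roc` (long table of all swept points), `correct_counts` (when a test
#'   set exists), `models`, the `train`/`test` tables, and a `manifest`
#'   recording seed and configuration hash.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- if (config$mode == "simulate") simulate_study(config)
           else load_study(config)
  train <- study$train

  models <- list()
  cal_rows <- list()
  op_rows <- list()
  roc_rows <- list()
  for (scheme in config$schemes) {
    s <- train[[scheme]]
    model <- calibrate_scheme(s, train$yes_fraction,
                              pair_ids = train$pair_id, scheme = scheme,
                              drop_outliers = config$drop_outliers)
    roc <- roc_curve(s, train$label, model = model)
    roc$scheme <- scheme
    op <- select_t_roc(s, train$label, min_sens = config$min_sens,
                       min_spec = config$min_spec, model = model)
    models[[scheme]] <- model
    cal_rows[[scheme]] <- tibble::tibble(
      scheme = scheme, beta0 = model$beta0, beta1 = model$beta1,
      se_beta0 = model$se_beta0, se_beta1 = model$se_beta1,
      r2_nagelkerke = model$r2_nagelkerke, hl_pvalue = model$hl_pvalue,
      t_lr = model$t_lr, auc = auc(roc), n_obs = model$n_obs,
      separation = model$separation,
      n_excluded = length(model$excluded_pairs)
    )
    op_rows[[scheme]] <- tibble::tibble(
      scheme = scheme, t_roc = op$threshold,
      probability = op$predicted_probability,
      sensitivity = op$sensitivity, specificity = op$specificity,
      precision = op$precision, accuracy = op$accuracy,
      f_index = op$f_index, youden = op$youden, mcc = op$mcc
    )
    roc_rows[[scheme]] <- roc
  }
  calibration <- do.call(rbind, cal_rows)
  operating <- do.call(rbind, op_rows)
  thresholds <- tibble::tibble(
    scheme = calibration$scheme, t_lr = calibration$t_lr,
    t_roc = operating$t_roc
  )

  correct_counts <- NULL
  test <- study$test
  if (!is.null(test) && "label" %in% names(test)) {
    correct_counts <- count_correct(test, thresholds,
                                    min_votes = config$min_votes)
  }

  structure(list(
    calibration = calibration, operating = operating,
    thresholds = thresholds, roc = do.call(rbind, roc_rows),
    correct_counts = correct_counts, models = models,
    train = train, test = test,
    manifest = list(
      seed = config$seed,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("simcal")),
      schemes = config$schemes,
      n_train = nrow(train),
      n_test = if (is.null(test)) 0L else nrow(test),
      excluded = lapply(models, function(m) m$excluded_pairs)
    )
  ), class = "simcal_run")
}

#' @export
print.simcal_run <- function(x, ...) {
  cat("<simcal_run> seed", x$manifest$seed, "| config",
      x$manifest$config_hash, "\n")
  cat("Calibration (coefficients per 0.1 similarity):\n")
  print(report_tables(x)$calibration)
  cat("\nSelected operating points:\n")
  print(report_tables(x)$operating)
  if (!is.null(x$correct_counts)) {
    cat("\nTest-set correct predictions (n =", x$manifest$n_test, "):\n")
    print(x$correct_counts)
  }
  invisible(x)
}

round_cols <- function(df, digits, mcc_digits = 4) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- round(df[[nm]], if (nm == "mcc") mcc_digits else digits)
    }
  }
  df
}

#' Rounded report tables from a pipeline run
#'
#' @param results A `simcal_run` from [run_full()].
#' @param digits Decimal places (default 3; MCC is reported at 4).
#' @return List of tibbles: `calibration`, `operating`, `thresholds`, and
#'   `correct_counts` when available.
#' @export
report_tables <- function(results, digits = 3) {
  stopifnot(inherits(results, "simcal_run"))
  if (nrow(results$calibration) == 0L) {
    stop("run contains no calibrated schemes", call. = FALSE)
  }
  out <- list(
    calibration = round_cols(results$calibration, digits),
    operating = round_cols(results$operating, digits),
    thresholds = round_cols(results$thresholds, digits)
  )
  if (!is.null(results$correct_counts)) {
    out$correct_counts <- results$correct_counts
  }
  out
}

#' Write a report bundle to a directory
#'
#' Emits `calibration_summary.csv`, `operating_points.csv`,
#' `thresholds.csv`, `roc_curves.csv`, `correct_counts.csv` (when a test
#' set was evaluated) and `manifest.json`. Every CSV carries the run seed
#' and configuration hash as columns, so any file can be traced to the run
#' that produced it.
#'
#' @param results A `simcal_run`.
#' @param dir Output directory (created if needed).
#' @param digits Rounding for report tables.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(results, dir, digits = 3) {
  stopifnot(inherits(results, "simcal_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(results, digits = digits)
  tabs$roc_curves <- round_cols(results$roc, digits)
  stamp <- function(df) {
    df$seed <- results$manifest$seed
    df$config_hash <- results$manifest$config_hash
    df
  }
  files <- c(calibration = "calibration_summary.csv",
             operating = "operating_points.csv",
             thresholds = "thresholds.csv",
             correct_counts = "correct_counts.csv",
             roc_curves = "roc_curves.csv")
  for (nm in names(files)) {
    if (!is.null(tabs[[nm]])) {
      utils::write.csv(stamp(tabs[[nm]]), file.path(dir, files[[nm]]),
                       row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
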