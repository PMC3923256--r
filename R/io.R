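#' Read a SMILES file
#'
#' One molecule per line, `SMILES<tab>id`; lines without an id get a
#' sequential one.
#'
#' @param path File path.
#' @return Tibble with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty SMILES file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[\t ]+")
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%04d", i)
    }, character(1))
  )
}

#' Read a molecule-pair CSV
#'
#' Expects columns `pair_id`, `smiles_a`, `smiles_b`.
#' @param path File path.
#' @return Tibble.
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  req <- c("pair_id", "smiles_a", "smiles_b")
  if (!all(req %in% names(df))) {
    stop("pairs CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read an expert vote CSV
#'
#' Expects columns `pair_id` and `yes_fraction` (fraction of Yes votes in
#' \[0, 1\]).
#' @param path File path.
#' @return Tibble.
#' @export
read_votes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("pair_id", "yes_fraction")
  if (!all(req %in% names(df))) {
    stop("votes CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$yes_fraction < 0 | df$yes_fraction > 1)) {
    stop("yes_fraction outside [0, 1] in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a similarity table as CSV
#'
#' Similarity columns are printed to 3 decimal places.
#'
#' @param profiles Similarity table from [pair_similarity_table()].
#' @param path Output path.
#' @param digits Decimal places for similarity columns (default 3).
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(profiles, path, digits = 3) {
  out <- profiles
  for (nm in intersect(names(out), fingerprint_schemes())) {
    out[[nm]] <- formatC(out[[nm]], digits = digits, format = "f")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  fields <- model[c("scheme", "beta0", "beta1", "se_beta0", "se_beta1",
                    "r2_nagelkerke", "hl_statistic", "hl_pvalue", "t_lr",
                    "n_obs", "converged", "separation", "excluded_pairs")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
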