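#' Supported 2D fingerprint schemes
#'
#' Five open fingerprint families spanning the main design axes of 2D
#' fingerprints used in similarity assessment:
#' \describe{
#'   \item{`circular-binary-r2`}{Hashed circular atom environments of radius
#'     2 (diameter 4), presence/absence. ECFP4-like.}
#'   \item{`circular-count-r2`}{The same environments with occurrence counts.
#'     ECFC4-like.}
#'   \item{`path-hashed-binary`}{Hashed linear atom/bond paths of up to 7
#'     bonds. Daylight-like.}
#'   \item{`structural-keys-166`}{The 166-bit MACCS structural key set
#'     (computed via Open Babel). MDL-like.}
#'   \item{`generic-keys`}{Hashed atom-pair keys (topological-distance atom
#'     pairs folded to a fixed length). A generic hashed-dictionary scheme in
#'     the spirit of BCI/Unity keys.}
#' }
#' @return Character vector of scheme names.
#' @export
fingerprint_schemes <- function() {
  c("circular-binary-r2", "circular-count-r2", "path-hashed-binary",
    "structural-keys-166", "generic-keys")
}

FP_DEFAULT_LENGTH <- c(
  "circular-binary-r2" = 1024L,
  "circular-count-r2" = 1024L,
  "path-hashed-binary" = 2048L,
  "structural-keys-166" = 166L,
  "generic-keys" = 1024L
)

#' Default fingerprint length for a scheme
#' @param scheme Scheme name, one of [fingerprint_schemes()].
#' @return Integer vector length.
#' @export
default_fp_length <- function(scheme) {
  check_scheme(scheme)
  unname(FP_DEFAULT_LENGTH[scheme])
}

check_scheme <- function(scheme) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% fingerprint_schemes()) {
    stop("unsupported fingerprint scheme: '", paste(scheme, collapse = ","),
         "'. Supported: ", paste(fingerprint_schemes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(scheme)
}

#' Compute a 2D fingerprint for a molecule
#'
#' @param mol A `molecule_record` from [parse_molecule()].
#' @param scheme One of [fingerprint_schemes()].
#' @param length Vector length; defaults per scheme
#'   (1024/1024/2048/166/1024). `structural-keys-166` is a fixed key
#'   dictionary and only supports length 166.
#' @return A `fingerprint` object: list with `scheme`, `length`, and `values`
#'   (non-negative integers; 0/1 for binary schemes). Deterministic for a
#'   given (canonical SMILES, scheme, length).
#' @export
compute_fingerprint <- function(mol, scheme, length = default_fp_length(scheme)) {
  stopifnot(is_molecule_record(mol))
  check_scheme(scheme)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (scheme == "structural-keys-166" && length != 166L) {
    stop("structural-keys-166 is a fixed 166-key dictionary; length must be 166",
         call. = FALSE)
  }
  values <- switch(scheme,
    "circular-binary-r2" = fold_features(morgan_features(mol, radius = 2L),
                                         length, counts = FALSE),
    "circular-count-r2" = fold_features(morgan_features(mol, radius = 2L),
                                        length, counts = TRUE),
    "path-hashed-binary" = fold_features(path_features(mol, max_bonds = 7L),
                                         length, counts = FALSE),
    "structural-keys-166" = maccs_values(mol),
    "generic-keys" = atom_pair_values(mol, length)
  )
  structure(list(scheme = scheme, length = length, values = values),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s, length %d, %d set positions\n",
              x$scheme, x$length, sum(x$values > 0)))
  invisible(x)
}

# ---- circular (Morgan-style) environments -------------------------------

# Iteratively refined atom-environment identifiers, radii 0..radius.
# Returns a named count: feature hash -> number of atoms carrying it.
morgan_features <- function(mol, radius = 2L) {
  n <- length(mol$elements)
  z <- atomic_numbers(mol$elements)
  bonds <- mol$bonds
  nbr <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      nbr[[i]] <- rbind(nbr[[i]], c(j, o))
      nbr[[j]] <- rbind(nbr[[j]], c(i, o))
    }
  }
  degree <- vapply(nbr, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  osum <- vapply(nbr, function(m) if (is.null(m)) 0L else sum(m[, 2]), integer(1))

  ids <- vapply(seq_len(n), function(i) {
    hash_tokens(c(z[i], degree[i], osum[i], as.integer(mol$ring_atom[i])))
  }, numeric(1))

  feats <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      m <- nbr[[i]]
      if (is.null(m)) return(hash_tokens(c(r, ids[i])))
      pairs <- cbind(m[, 2], ids[m[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_tokens(c(r, ids[i], as.vector(t(pairs[ord, , drop = FALSE]))))
    }, numeric(1))
    ids <- new_ids
    feats <- c(feats, ids)
  }
  tab <- table(feats)
  stats::setNames(as.integer(tab), names(tab))
}

# ---- linear paths (Daylight-style) --------------------------------------

# All simple atom/bond paths of 0..max_bonds bonds; each path is canonicalized
# against its reverse so that it is counted once regardless of direction.
path_features <- function(mol, max_bonds = 7L) {
  n <- length(mol$elements)
  z <- atomic_numbers(mol$elements)
  bonds <- mol$bonds
  nbr <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      nbr[[i]] <- rbind(nbr[[i]], c(j, o))
      nbr[[j]] <- rbind(nbr[[j]], c(i, o))
    }
  }
  seen <- new.env(parent = emptyenv())

  add_path <- function(tokens) {
    rev_tokens <- rev(tokens)
    for (k in seq_along(tokens)) {
      if (tokens[k] < rev_tokens[k]) break
      if (tokens[k] > rev_tokens[k]) { tokens <- rev_tokens; break }
    }
    key <- paste(tokens, collapse = ".")
    if (is.null(seen[[key]])) seen[[key]] <- hash_tokens(tokens)
  }

  walk <- function(atom, tokens, visited, depth) {
    add_path(tokens)
    if (depth == max_bonds) return(invisible())
    m <- nbr[[atom]]
    if (is.null(m)) return(invisible())
    for (r in seq_len(nrow(m))) {
      v <- m[r, 1]
      if (visited[v]) next
      visited[v] <- TRUE
      walk(v, c(tokens, m[r, 2], z[v]), visited, depth + 1L)
      visited[v] <- FALSE
    }
  }
  for (a in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[a] <- TRUE
    walk(a, z[a], visited, 0L)
  }
  ids <- unlist(as.list(seen), use.names = FALSE)
  if (length(ids) == 0) return(integer(0))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

# fold hashed feature ids into a fixed-length vector
fold_features <- function(feats, length, counts) {
  v <- integer(length)
  if (base::length(feats) == 0) return(v)
  pos <- as.numeric(names(feats)) %% length + 1
  for (k in seq_along(pos)) {
    v[pos[k]] <- v[pos[k]] + feats[k]
  }
  if (!counts) v <- as.integer(v > 0)
  v
}

# ---- MACCS 166 structural keys (via Open Babel) -------------------------

maccs_values <- function(mol) {
  fp <- quiet_ob(ChemmineR::fingerprintOB(mol$sdf, "MACCS"))
  # Open Babel pads the 166 MACCS keys to a 256-bit word; keep keys 1..166
  as.integer(fp@fpma[1, seq_len(166L)])
}

# ---- hashed atom-pair keys ----------------------------------------------

atom_pair_values <- function(mol, length) {
  ap <- quiet_ob(ChemmineR::sdf2ap(mol$sdf))
  codes <- unique(as.numeric(ap@AP[[1]]))
  # atom-pair codes pack typed endpoints and distance into fixed bit fields;
  # hash before folding so the modulus does not collapse onto the low field
  pos <- vapply(codes, function(cd) {
    hash_tokens(c(cd %/% TWO32, cd %% TWO32))
  }, numeric(1))
  v <- integer(length)
  v[unique(pos %% length) + 1] <- 1L
  v
}

# ---- Tanimoto -----------------------------------------------------------

#' Tanimoto similarity between two fingerprints
#'
#' For binary fingerprints this is the classic set overlap
#' \eqn{|A \cap B| / |A \cup B|}; for count fingerprints the min/max
#' generalization \eqn{\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)}, which
#' reduces exactly to the binary form on 0/1 vectors.
#'
#' @param a,b `fingerprint` objects with identical scheme and length.
#' @return Similarity in \[0, 1\]. Two all-zero fingerprints compare as 0
#'   with a warning: for a dissimilarity-sensitive application an empty
#'   representation carries no evidence of similarity.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$scheme != b$scheme || a$length != b$length) {
    stop("fingerprint scheme/length mismatch: ",
         a$scheme, "[", a$length, "] vs ", b$scheme, "[", b$length, "]",
         call. = FALSE)
  }
  denom <- sum(pmax(a$values, b$values))
  if (denom == 0) {
    warning("both fingerprints are empty; returning similarity 0")
    return(0)
  }
  sum(pmin(a$values, b$values)) / denom
}

# ---- pair similarity tables ---------------------------------------------

#' Compute Tanimoto similarities for molecule pairs under several schemes
#'
#' @param pairs Either a data frame with columns `pair_id`, `smiles_a`,
#'   `smiles_b`, or a list whose elements are length-2 lists of
#'   `molecule_record` objects (optionally named to provide pair ids).
#' @param schemes Character vector of scheme names
#'   (default all of [fingerprint_schemes()]).
#' @param lengths Optional named integer vector overriding per-scheme
#'   fingerprint lengths.
#' @return A tibble with one row per pair (input order preserved):
#'   `pair_id`, `molecule_a_id`, `molecule_b_id`, and one similarity column
#'   per scheme.
#' @export
pair_similarity_table <- function(pairs, schemes = fingerprint_schemes(),
                                  lengths = NULL) {
  stopifnot(length(schemes) >= 1L)
  for (s in schemes) check_scheme(s)
  if (is.data.frame(pairs)) {
    req <- c("pair_id", "smiles_a", "smiles_b")
    if (!all(req %in% names(pairs))) {
      stop("pairs data frame needs columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(pairs) == 0L) stop("no molecule pairs supplied", call. = FALSE)
    ids_a <- paste0(pairs$pair_id, "_a")
    ids_b <- paste0(pairs$pair_id, "_b")
    # parse each distinct SMILES once
    smi <- c(pairs$smiles_a, pairs$smiles_b)
    ids <- c(ids_a, ids_b)
    keep <- !duplicated(smi)
    mols <- mapply(parse_molecule, smi[keep], ids[keep], SIMPLIFY = FALSE)
    names(mols) <- smi[keep]
    pair_list <- lapply(seq_len(nrow(pairs)), function(i) {
      list(mols[[pairs$smiles_a[i]]], mols[[pairs$smiles_b[i]]])
    })
    pair_ids <- as.character(pairs$pair_id)
  } else if (is.list(pairs)) {
    if (length(pairs) == 0L) stop("no molecule pairs supplied", call. = FALSE)
    ok <- vapply(pairs, function(p) {
      is.list(p) && length(p) == 2L && is_molecule_record(p[[1]]) &&
        is_molecule_record(p[[2]])
    }, logical(1))
    if (!all(ok)) {
      stop("each pair must be a list of two molecule_record objects",
           call. = FALSE)
    }
    pair_list <- pairs
    pair_ids <- if (!is.null(names(pairs))) names(pairs) else
      as.character(seq_along(pairs))
  } else {
    stop("pairs must be a data frame or a list of record pairs", call. = FALSE)
  }

  fp_cache <- new.env(parent = emptyenv())
  get_fp <- function(mol, scheme) {
    len <- if (!is.null(lengths) && scheme %in% names(lengths))
      as.integer(lengths[[scheme]]) else default_fp_length(scheme)
    key <- paste0(scheme, "|", len, "|", mol$smiles)
    if (is.null(fp_cache[[key]])) {
      fp_cache[[key]] <- compute_fingerprint(mol, scheme, len)
    }
    fp_cache[[key]]
  }

  out <- tibble::tibble(
    pair_id = pair_ids,
    molecule_a_id = vapply(pair_list, function(p) p[[1]]$id, character(1)),
    molecule_b_id = vapply(pair_list, function(p) p[[2]]$id, character(1))
  )
  for (scheme in schemes) {
    out[[scheme]] <- vapply(pair_list, function(p) {
      tryCatch(
        tanimoto(get_fp(p[[1]], scheme), get_fp(p[[2]], scheme)),
        error = function(e) {
          stop("pair (", p[[1]]$id, ", ", p[[2]]$id, "): ",
               conditionMessage(e), call. = FALSE)
        }
      )
    }, numeric(1))
  }
  out
}
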