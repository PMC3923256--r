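#' Parse a SMILES string into a molecule record
#'
#' Parses a SMILES string (via Open Babel through \pkg{ChemmineR}), keeps the
#' largest covalent fragment when the input encodes a salt or mixture,
#' canonicalizes it, and computes the physicochemical descriptors used by the
#' drug-likeness filter: molecular weight, hydrogen-bond acceptor and donor
#' counts, an octanol--water logP estimate, and the carbon count.
#'
#' @param smiles A single SMILES string.
#' @param id Identifier carried through all downstream tables and error
#'   messages.
#' @return An object of class `molecule_record`: a list with elements `id`,
#'   `smiles` (canonical), `mol_weight` (Daltons), `n_hba`, `n_hbd`, `logp`,
#'   `n_carbon`, plus the internal connection table used by the fingerprint
#'   generators.
#' @details Molecules with a single heavy atom are rejected: they carry no
#'   2D substructural information and the similarity model is meaningless
#'   for them.
#' @examples
#' \donttest{
#' parse_molecule("CCO", "ethanol")
#' }
#' @export
parse_molecule <- function(smiles, id) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            is.character(id), length(id) == 1L)
  if (!nzchar(trimws(smiles))) {
    stop("empty SMILES for molecule '", id, "'", call. = FALSE)
  }
  smiles <- largest_fragment(smiles, id)
  sdf <- parse_smiles_sdf(smiles, id)
  props <- quiet_ob(ChemmineR::propOB(sdf))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  if (length(elements) < 2L) {
    stop("molecule '", id, "' has fewer than two heavy atoms; ",
         "2D fingerprints are undefined for it", call. = FALSE)
  }
  bonds <- matrix(as.integer(bb[, 1:3, drop = FALSE]), ncol = 3L)
  rec <- list(
    id = id,
    smiles = props$cansmi[1],
    mol_weight = as.numeric(props$MW[1]),
    n_hba = as.integer(props$HBA1[1]),
    n_hbd = as.integer(props$HBD[1]),
    logp = as.numeric(props$logP[1]),
    n_carbon = sum(elements == "C"),
    elements = elements,
    bonds = bonds,
    ring_atom = ring_atoms(length(elements), bonds),
    sdf = sdf
  )
  structure(rec, class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$id, "\n  SMILES: ", x$smiles,
      sprintf("\n  MW %.1f Da | HBA %d | HBD %d | logP %.2f | C atoms %d\n",
              x$mol_weight, x$n_hba, x$n_hbd, x$logp, x$n_carbon), sep = "")
  invisible(x)
}

is_molecule_record <- function(x) inherits(x, "molecule_record")

# Open Babel writes parse diagnostics to the console; capture them so a batch
# run is quiet, but keep real errors.
quiet_ob <- function(expr) {
  out <- utils::capture.output(res <- suppressWarnings(expr), type = "output")
  res
}

parse_smiles_sdf <- function(smiles, id) {
  sdf <- tryCatch(
    quiet_ob(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) {
      stop("cannot parse SMILES for molecule '", id, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(sdf) != 1L || !ChemmineR::validSDF(sdf)) {
    stop("cannot parse SMILES for molecule '", id, "'", call. = FALSE)
  }
  sdf
}

# Salt stripping: a dot in SMILES separates covalently disconnected
# components; keep the one with the most heavy atoms (ties: the first).
largest_fragment <- function(smiles, id) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) {
    stop("cannot parse SMILES for molecule '", id, "'", call. = FALSE)
  }
  if (length(parts) == 1L) return(parts)
  sizes <- vapply(parts, count_heavy_atoms, numeric(1))
  parts[[which.max(sizes)]]
}

# heavy-atom count straight from SMILES text (sufficient for fragment ranking)
count_heavy_atoms <- function(s) {
  n_bracket <- lengths(regmatches(s, gregexpr("\\[[^]]*\\]", s)))
  bare <- gsub("\\[[^]]*\\]", "", s)
  organic <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", bare)
  n_bracket + sum(attr(organic[[1]], "match.length") > 0)
}

# Ring membership via bridge detection: an atom is in a ring iff it has an
# incident edge that is not a bridge.
ring_atoms <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(rep(FALSE, n_atoms))
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, k))
    adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  disc <- rep(NA_integer_, n_atoms)
  low <- rep(NA_integer_, n_atoms)
  is_bridge <- rep(FALSE, nrow(bonds))
  timer <- 0L

  visit <- function(u, parent_edge) {
    timer <<- timer + 1L
    disc[u] <<- low[u] <<- timer
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; e <- nb[r, 2]
        if (e == parent_edge) next
        if (is.na(disc[v])) {
          visit(v, e)
          low[u] <<- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[e] <<- TRUE
        } else {
          low[u] <<- min(low[u], disc[v])
        }
      }
    }
  }
  for (u in seq_len(n_atoms)) if (is.na(disc[u])) visit(u, 0L)

  in_ring <- rep(FALSE, n_atoms)
  ring_edges <- which(!is_bridge)
  in_ring[unique(as.vector(bonds[ring_edges, 1:2]))] <- TRUE
  in_ring
}

# atomic numbers for fingerprint invariants
ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

atomic_numbers <- function(elements) {
  z <- ATOMIC_NUMBER[elements]
  # rare elements: stable fallback outside the common range
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- 200 + vapply(elements[miss],
                            function(e) hash_tokens(utf8ToInt(e)) %% 1000,
                            numeric(1))
  }
  unname(z)
}
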