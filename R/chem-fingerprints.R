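## Reaction fingerprints.
##
## Three constructions, all deterministic hashed enumerations over the
## heavy-atom graph:
##  * structural: per-molecule linear-path fingerprint (1638 bits), OR-combined
##    per side and concatenated to 3276 bits;
##  * difference: per-molecule atom-pair count fingerprint (2048 ints), summed
##    per side, products subtracted from substrates;
##  * drfp: circular-substructure environments of both sides; the symmetric
##    difference of the two substructure sets is hashed into 2048 bits.

FP_MOL_BITS <- 1638L
FP_DIFF_BITS <- 2048L
FP_DRFP_BITS <- 2048L
FP_PATH_MAX_BONDS <- 7L

bond_symbol <- function(order) {
  c("-", "=", "#", ":")[pmin(order, 4L)]
}

# Canonical strings for every simple linear path of 0..max_bonds bonds.
# Each path is read from both ends; the lexicographic minimum makes the
# string independent of traversal direction and atom numbering.
mol_path_strings <- function(graph, max_bonds = FP_PATH_MAX_BONDS) {
  n <- length(graph$elem)
  adj <- graph$adj
  out <- new.env(parent = emptyenv())
  walk <- function(path_atoms, fwd, rev, depth) {
    key <- if (fwd <= rev) fwd else rev
    assign(key, TRUE, envir = out)
    if (depth >= max_bonds) return(invisible())
    tail <- path_atoms[length(path_atoms)]
    nb <- adj[[tail]]
    if (nrow(nb) == 0) return(invisible())
    for (k in seq_len(nrow(nb))) {
      nxt <- nb[k, 1]
      if (nxt %in% path_atoms) next
      b <- bond_symbol(nb[k, 2])
      e <- graph$elem[nxt]
      walk(c(path_atoms, nxt),
           paste0(fwd, b, e),
           paste0(e, b, rev),
           depth + 1L)
    }
  }
  for (s in seq_len(n)) {
    walk(s, graph$elem[s], graph$elem[s], 0L)
  }
  ls(out)
}

#' Per-molecule structural fingerprint
#'
#' A 1638-bit binary fingerprint of a single molecule: all linear paths of up
#' to seven bonds are enumerated, serialised canonically, and hashed into the
#' bit vector. Deterministic for a given structure.
#'
#' @param molecule A `kcat_molecule`, SMILES or InChI string.
#' @return Integer vector of length 1638 with entries in \{0, 1\}.
#' @export
molecule_fingerprint <- function(molecule) {
  mol <- if (inherits(molecule, "kcat_molecule")) molecule else
    parse_molecule(molecule)
  key <- paste0("molfp:", mol$cansmi)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  paths <- mol_path_strings(mol$graph)
  fp <- integer(FP_MOL_BITS)
  fp[unique(hash_to_bucket(paths, FP_MOL_BITS)) + 1L] <- 1L
  cache_set(key, fp)
}

# Atom invariant: element, heavy degree, number of bonds of order > 1.
atom_invariants <- function(graph) {
  n <- length(graph$elem)
  vapply(seq_len(n), function(i) {
    nb <- graph$adj[[i]]
    paste0(graph$elem[i], nrow(nb), sum(nb[, 2] > 1L))
  }, character(1))
}

# Atom-pair count fingerprint: features (invariant_i, invariant_j, distance)
# hashed into 2048 counting buckets.
mol_atom_pair_counts <- function(mol) {
  key <- paste0("apfp:", mol$cansmi)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- mol$graph
  n <- length(g$elem)
  counts <- integer(FP_DIFF_BITS)
  if (n >= 2L) {
    inv <- atom_invariants(g)
    feats <- character(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- g$dist[i, j]
        if (is.infinite(d)) next
        lo <- min(inv[i], inv[j]); hi <- max(inv[i], inv[j])
        feats <- c(feats, paste(lo, hi, d, sep = "|"))
      }
    }
    if (length(feats) > 0) {
      tab <- table(hash_to_bucket(feats, FP_DIFF_BITS))
      counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
  }
  cache_set(key, counts)
}

# Circular-environment tokens for one molecule: iterated neighbourhood
# labels (Morgan-style) for radius 0..max_radius, compressed to short hash
# tokens per level so label length stays bounded. Tokens depend only on
# local structure, never on atom numbering.
mol_env_tokens <- function(mol, max_radius = 3L) {
  key <- paste0("env:", mol$cansmi, ":", max_radius)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- mol$graph
  n <- length(g$elem)
  lab <- g$elem
  tokens <- paste0("r0:", lab)
  if (max_radius > 0 && n > 1L) {
    for (r in seq_len(max_radius)) {
      newlab <- character(n)
      for (i in seq_len(n)) {
        nb <- g$adj[[i]]
        if (nrow(nb) == 0) {
          newlab[i] <- lab[i]
        } else {
          parts <- sort(paste0(bond_symbol(nb[, 2]), lab[nb[, 1]]))
          full <- paste0(g$elem[i], "(", paste(parts, collapse = ""), ")")
          newlab[i] <- digest::digest(full, algo = "murmur32",
                                      serialize = FALSE)
        }
      }
      lab <- newlab
      tokens <- c(tokens, paste0("r", r, ":", lab))
    }
  }
  cache_set(key, unique(tokens))
}

side_env_set <- function(mols, max_radius) {
  unique(unlist(lapply(mols, mol_env_tokens, max_radius = max_radius)))
}

#' Reaction fingerprints
#'
#' Computes one of the three reaction fingerprints:
#' \describe{
#'   \item{`structural`}{bitwise OR of the per-molecule structural
#'     fingerprints of each side, concatenated substrates-then-products
#'     (length 3276, binary).}
#'   \item{`difference`}{summed per-substrate atom-pair count fingerprints
#'     minus the summed per-product ones (length 2048, integer).}
#'   \item{`drfp`}{circular substructure environments (radius 0..`max_radius`)
#'     of both sides; environments present on exactly one side are hashed
#'     into an `n_bits`-long binary vector.}
#' }
#' All three are invariant to reactant order within each side.
#'
#' @param reaction A `kcat_reaction` or a reaction-SMILES string.
#' @param kind One of `"drfp"`, `"structural"`, `"difference"`.
#' @param n_bits DRFP width (default 2048).
#' @param max_radius DRFP maximal environment radius (default 3).
#' @return An integer vector of class `kcat_fingerprint` with attribute
#'   `kind`.
#' @export
reaction_fingerprint <- function(reaction,
                                 kind = c("drfp", "structural", "difference"),
                                 n_bits = FP_DRFP_BITS, max_radius = 3L) {
  kind <- match.arg(kind)
  r <- as_kcat_reaction(reaction)
  key <- paste0("rfp:", kind, ":", n_bits, ":", max_radius, ":", r$key)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)

  vec <- switch(kind,
    structural = {
      or_side <- function(mols) {
        fp <- integer(FP_MOL_BITS)
        for (m in mols) fp <- pmax(fp, molecule_fingerprint(m))
        fp
      }
      c(or_side(r$substrates), or_side(r$products))
    },
    difference = {
      sum_side <- function(mols) {
        v <- integer(FP_DIFF_BITS)
        for (m in mols) v <- v + mol_atom_pair_counts(m)
        v
      }
      sum_side(r$substrates) - sum_side(r$products)
    },
    drfp = {
      s_set <- side_env_set(r$substrates, max_radius)
      p_set <- side_env_set(r$products, max_radius)
      sym_diff <- c(setdiff(s_set, p_set), setdiff(p_set, s_set))
      fp <- integer(n_bits)
      if (length(sym_diff) > 0) {
        fp[unique(hash_to_bucket(sym_diff, n_bits)) + 1L] <- 1L
      }
      fp
    }
  )
  fp <- structure(as.integer(vec), kind = kind, class = "kcat_fingerprint")
  cache_set(key, fp)
}

#' Raw similarity of two structural reaction fingerprints
#'
#' One minus the Jaccard distance over the positions where at least one of
#' the two binary fingerprints is set: the fraction of agreeing entries among
#' the jointly non-zero ones. Symmetric, in \[0, 1\], and 1 on identical
#' fingerprints. Two all-zero fingerprints are defined to have similarity 1
#' (identical objects); a warning is raised in that degenerate case.
#'
#' @param a,b Binary fingerprints of equal length.
#' @return A similarity in \[0, 1\].
#' @export
reaction_similarity <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    abort(sprintf("fingerprint length mismatch: %d vs %d",
                  length(a), length(b)))
  }
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warn("both fingerprints are all-zero; similarity defined as 1")
    return(1)
  }
  sum(a & b) / union_n
}

#' Min-max normalisation of similarity scores
#'
#' Rescales a collection of raw similarity scores to span \[0, 1\]. The
#' rescaling is monotonic; if all scores are equal the span is degenerate and
#' every score maps to 1.
#'
#' @param raw_scores Numeric vector of raw similarities (length >= 1).
#' @return Numeric vector of normalised scores in \[0, 1\].
#' @export
normalize_similarities <- function(raw_scores) {
  stopifnot(length(raw_scores) >= 1L, is.numeric(raw_scores))
  lo <- min(raw_scores); hi <- max(raw_scores)
  if (hi - lo <= 0) {
    inform("all similarity scores equal; degenerate span, returning 1s")
    return(rep(1, length(raw_scores)))
  }
  (raw_scores - lo) / (hi - lo)
}
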