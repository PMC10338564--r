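## Molecule layer: parsing, canonical forms, molecular weights, graphs.
##
## SMILES/InChI handling, canonicalisation and molecular weights go through
## OpenBabel (ChemmineOB). The molecular graph (elements + bonds + topological
## distances) is recovered from the generated V2000 molblock and feeds the
## fingerprint constructions in chem-fingerprints.R.

.kcat_chem_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .kcat_chem_cache, inherits = FALSE)) {
    get(key, envir = .kcat_chem_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(key, value) {
  assign(key, value, envir = .kcat_chem_cache)
  value
}

#' Parse a molecule from SMILES or InChI
#'
#' Parses a single reactant into an internal molecule record holding its
#' canonical SMILES, molecular weight (g/mol), molecular formula and the
#' heavy-atom graph used by the fingerprint constructions.
#'
#' @param text A SMILES string or an InChI string (prefix `InChI=`).
#' @return A list of class `kcat_molecule` with elements `raw`, `cansmi`,
#'   `formula`, `mol_weight` and `graph`.
#' @examples
#' \dontrun{
#' m <- parse_molecule("CCO")
#' m$mol_weight  # 46.07
#' }
#' @export
parse_molecule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  key <- paste0("mol:", text)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)

  smi <- text
  if (startsWith(text, "InChI=")) {
    smi <- tryCatch(
      trimws(ChemmineOB::convertFormat("INCHI", "SMI", text)),
      error = function(e) {
        abort(paste0("cannot parse InChI reactant: '", text, "'"),
              class = "kcat_parse_error")
      }
    )
    if (!nzchar(smi)) {
      abort(paste0("cannot parse InChI reactant: '", text, "'"),
            class = "kcat_parse_error")
    }
  }

  props <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smi, ChemmineOB::prop_OB)[[1]],
    error = function(e) {
      abort(paste0("cannot parse reactant: '", text, "'"),
            class = "kcat_parse_error")
    }
  )
  if (!is.data.frame(props) || nrow(props) != 1L || !is.finite(props$MW) ||
      props$MW <= 0) {
    abort(paste0("cannot parse reactant: '", text, "'"),
          class = "kcat_parse_error")
  }

  mol <- structure(
    list(
      raw = text,
      cansmi = as.character(props$cansmi),
      formula = as.character(props$formula),
      mol_weight = as.numeric(props$MW),
      graph = mol_graph(as.character(props$cansmi))
    ),
    class = "kcat_molecule"
  )
  cache_set(key, mol)
}

# Heavy-atom graph: elements, bond table (a1, a2, order) and topological
# distances. ChemmineR's SDF container rejects zero-bond molecules (e.g.
# water), so those fall back to a trivial single-node graph read from the
# molblock atom lines.
mol_graph <- function(cansmi) {
  molblock <- ChemmineOB::convertFormat("SMILES", "MOL", cansmi)
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]

  graph <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))
    if (!ChemmineR::validSDF(sdf)[1]) stop("degenerate molecule")
    ab <- ChemmineR::atomblock(sdf[[1]])
    bb <- ChemmineR::bondblock(sdf[[1]])
    elem <- sub("_.*$", "", rownames(ab))
    bonds <- cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
    list(elem = elem, bonds = bonds)
  }, error = function(e) {
    counts <- lines[4]
    n_atoms <- as.integer(substr(counts, 1, 3))
    if (is.na(n_atoms) || n_atoms < 1L) {
      abort(paste0("cannot build molecular graph for '", cansmi, "'"),
            class = "kcat_parse_error")
    }
    atom_lines <- lines[5:(4 + n_atoms)]
    elem <- trimws(substr(atom_lines, 32, 34))
    list(elem = elem,
         bonds = matrix(integer(0), ncol = 3,
                        dimnames = list(NULL, c("a1", "a2", "order"))))
  })

  graph$dist <- graph_distances(length(graph$elem), graph$bonds)
  graph$adj <- graph_adjacency(length(graph$elem), graph$bonds)
  graph
}

# Neighbour list: for each atom, matrix of (neighbour index, bond order).
graph_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(integer(0), ncol = 2)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds[b, 1]; a2 <- bonds[b, 2]; o <- bonds[b, 3]
      adj[[a1]] <- rbind(adj[[a1]], c(a2, o))
      adj[[a2]] <- rbind(adj[[a2]], c(a1, o))
    }
  }
  adj
}

# All-pairs shortest paths by BFS (molecules are tiny, unweighted).
graph_distances <- function(n, bonds) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(bonds) == 0 || n == 1L) return(d)
  nbrs <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    nbrs[[bonds[b, 1]]] <- c(nbrs[[bonds[b, 1]]], bonds[b, 2])
    nbrs[[bonds[b, 2]]] <- c(nbrs[[bonds[b, 2]]], bonds[b, 1])
  }
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

#' Parse a reaction string
#'
#' Accepts the reaction-SMILES dialect `"A.B>>C.D"` (no agents segment) or,
#' alternatively, explicit per-side reactant lists which may mix SMILES and
#' InChI. The canonical reaction key sorts the canonical SMILES of each side,
#' so the key is invariant to reactant order within a side.
#'
#' @param text Reaction SMILES `"subs>>prods"`. Ignored when `substrates` and
#'   `products` are given.
#' @param substrates,products Optional character vectors of per-reactant
#'   SMILES or InChI strings.
#' @return A list of class `kcat_reaction` with `substrates`, `products`
#'   (lists of `kcat_molecule`) and the canonical `key`.
#' @examples
#' \dontrun{
#' r <- parse_reaction("CCO>>CC=O")
#' r$key
#' }
#' @export
parse_reaction <- function(text = NULL, substrates = NULL, products = NULL) {
  if (is.null(substrates) || is.null(products)) {
    stopifnot(is.character(text), length(text) == 1L)
    sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
    if (length(sides) != 2L || !nzchar(trimws(sides[1])) ||
        !nzchar(trimws(sides[2]))) {
      abort(paste0("reaction must have the form 'subs>>prods', got: '",
                   text, "'"), class = "kcat_parse_error")
    }
    substrates <- strsplit(trimws(sides[1]), ".", fixed = TRUE)[[1]]
    products <- strsplit(trimws(sides[2]), ".", fixed = TRUE)[[1]]
  }
  if (length(substrates) < 1L || length(products) < 1L) {
    abort("a reaction needs at least one substrate and one product",
          class = "kcat_parse_error")
  }
  subs <- lapply(substrates, parse_molecule)
  prods <- lapply(products, parse_molecule)
  key <- paste0(
    paste(sort(vapply(subs, `[[`, character(1), "cansmi")), collapse = "."),
    ">>",
    paste(sort(vapply(prods, `[[`, character(1), "cansmi")), collapse = ".")
  )
  structure(list(substrates = subs, products = prods, key = key),
            class = "kcat_reaction")
}

as_kcat_reaction <- function(x) {
  if (inherits(x, "kcat_reaction")) return(x)
  key <- paste0("rxn:", x)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  cache_set(key, parse_reaction(x))
}

#' @export
print.kcat_reaction <- function(x, ...) {
  cat("<kcat_reaction> ", x$key, "\n", sep = "")
  invisible(x)
}

#' Check the mass balance of a reaction
#'
#' Compares the summed molecular weights of the two reaction sides. The
#' tolerance is relative (`rel_tol` times the heavier side) with an absolute
#' floor of `abs_tol` g/mol so that proton-level bookkeeping differences do
#' not reject otherwise balanced reactions.
#'
#' @param reaction A `kcat_reaction` or a reaction-SMILES string.
#' @param rel_tol Relative tolerance (default 0.01).
#' @param abs_tol Absolute floor in g/mol (default 1.5).
#' @return `TRUE` if the side weights agree within tolerance.
#' @export
mass_balance_ok <- function(reaction, rel_tol = 0.01, abs_tol = 1.5) {
  r <- as_kcat_reaction(reaction)
  mw_s <- sum(vapply(r$substrates, `[[`, numeric(1), "mol_weight"))
  mw_p <- sum(vapply(r$products, `[[`, numeric(1), "mol_weight"))
  tol <- max(rel_tol * max(mw_s, mw_p), abs_tol)
  abs(mw_s - mw_p) <= tol
}
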