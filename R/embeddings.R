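## Enzyme representations: fixed-length 1280-dim vectors behind a pluggable
## backend. Externally computed protein-language-model vectors enter through
## load_embeddings(); the "stub" backend is a deterministic, fully offline
## stand-in: a seeded sparse random projection (count sketch) of the
## sequence's 3-mer counts. Each 3-mer maps to one fixed coordinate with a
## fixed sign, so coordinates are signed counts of small 3-mer groups. The
## stub has the locality property the evaluation relies on: sequences that
## are close in Hamming distance share most 3-mers and therefore map to
## cosine-close vectors. The sparse form also keeps the features learnable
## by axis-aligned tree splits, unlike a dense Gaussian projection which
## smears every 3-mer across all coordinates.

EMBED_DIM <- 1280L
EMBED_TRUNCATE <- 1024L

.kcat_embed_cache <- new.env(parent = emptyenv())

# Deterministic (coordinate, sign) slot for one k-mer under a given seed.
kmer_slot <- function(kmer, seed) {
  key <- paste0(seed, ":", kmer)
  hit <- if (exists(key, envir = .kcat_embed_cache, inherits = FALSE)) {
    get(key, envir = .kcat_embed_cache, inherits = FALSE)
  } else {
    NULL
  }
  if (!is.null(hit)) return(hit)
  h <- derive_seed(seed, paste0("kmer:", kmer))
  slot <- c(coord = as.integer(h %% EMBED_DIM) + 1L,
            sign = if ((h %/% EMBED_DIM) %% 2 == 0) 1L else -1L)
  assign(key, slot, envir = .kcat_embed_cache)
  slot
}

#' Deterministic stub embedding of an amino-acid sequence
#'
#' Projects the sequence's 3-mer count vector through a seeded sparse
#' random projection (each distinct 3-mer adds its count, with a fixed
#' random sign, to one fixed random coordinate) and L2-normalises the
#' result. Deterministic across processes for a given seed; different seeds
#' give unrelated projections.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param seed Integer seed fixing the projection.
#' @return Numeric vector of length 1280.
#' @export
stub_embed <- function(sequence, seed = 101L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  v <- numeric(EMBED_DIM)
  if (n < 3L) {
    kmers <- sequence
    counts <- 1L
  } else {
    all_kmers <- vapply(seq_len(n - 2L), function(i) {
      paste(chars[i:(i + 2L)], collapse = "")
    }, character(1))
    tab <- table(all_kmers)
    kmers <- names(tab)
    counts <- as.integer(tab)
  }
  for (i in seq_along(kmers)) {
    s <- kmer_slot(kmers[i], seed)
    v[s[["coord"]]] <- v[s[["coord"]]] + s[["sign"]] * counts[i]
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Embed enzyme sequences
#'
#' Computes a fixed-length 1280-dimensional representation for each
#' sequence. Sequences longer than 1024 residues are truncated to their
#' first 1024 residues before the backend is called. The `"stub"` backend is
#' computed locally (see [stub_embed()]); precomputed transformer vectors
#' are supplied via [load_embeddings()] and the `"precomputed"` backend.
#'
#' @param sequences Character vector of amino-acid sequences, or a tibble
#'   with columns `enzyme_id` and `sequence`.
#' @param backend `"stub"` or `"precomputed"`.
#' @param seed Projection seed for the stub backend.
#' @param precomputed Named matrix from [load_embeddings()], required for
#'   `backend = "precomputed"`; rownames are matched against sequence names.
#' @return Numeric matrix (n x 1280); rownames are enzyme ids when supplied.
#' @export
embed_sequences <- function(sequences, backend = c("stub", "precomputed"),
                            seed = 101L, precomputed = NULL) {
  backend <- match.arg(backend)
  if (is.data.frame(sequences)) {
    ids <- sequences$enzyme_id
    seqs <- sequences$sequence
  } else {
    ids <- names(sequences)
    seqs <- unname(sequences)
  }
  if (length(seqs) == 0L) abort("no sequences to embed")
  if (any(!nzchar(seqs))) abort("empty sequence cannot be embedded")
  seqs <- substr(seqs, 1L, EMBED_TRUNCATE)

  if (backend == "stub") {
    uniq <- unique(seqs)
    emb_u <- t(vapply(uniq, stub_embed, numeric(EMBED_DIM), seed = seed))
    out <- emb_u[match(seqs, uniq), , drop = FALSE]
  } else {
    if (is.null(precomputed)) {
      abort("backend 'precomputed' requires an embedding matrix")
    }
    missing_ids <- setdiff(ids, rownames(precomputed))
    if (length(missing_ids) > 0) {
      abort(paste0("no precomputed embedding for: ",
                   paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    out <- precomputed[ids, , drop = FALSE]
  }
  rownames(out) <- ids
  out
}

#' Load precomputed enzyme embeddings
#'
#' Reads an embedding matrix (CSV of numbers, one row per enzyme) and a
#' newline-delimited id index, validates the 1280 dimension and row/index
#' agreement, and returns an id-indexed matrix.
#'
#' @param matrix_file CSV file of the n x 1280 matrix (no header).
#' @param index_file Text file with one enzyme id per line.
#' @return Numeric matrix with enzyme ids as rownames.
#' @export
load_embeddings <- function(matrix_file, index_file) {
  mat <- as.matrix(utils::read.csv(matrix_file, header = FALSE))
  ids <- readLines(index_file)
  ids <- ids[nzchar(ids)]
  if (ncol(mat) != EMBED_DIM) {
    abort(sprintf("embedding dimension must be %d, found %d",
                  EMBED_DIM, ncol(mat)))
  }
  if (nrow(mat) != length(ids)) {
    abort(sprintf("matrix has %d rows but index lists %d ids",
                  nrow(mat), length(ids)))
  }
  if (anyDuplicated(ids)) {
    abort("duplicate enzyme ids in embedding index")
  }
  dimnames(mat) <- list(ids, NULL)
  mat
}
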