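## Identity-aware dataset splitting.
##
## The split unit is the exact amino-acid sequence: all records sharing a
## sequence land on the same side of the train/test split and inside a single
## CV fold. Test records are afterwards stratified by their maximal global
## sequence identity to the training set and by reaction similarity.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap opening 10 and gap
#' extension 0.5 (the EMBOSS-needle defaults); identity is the number of
#' matches divided by the alignment length (gaps included), in percent.
#'
#' @param seq_a,seq_b Amino-acid sequences.
#' @return Identity percentage in \[0, 100\].
#' @export
global_identity <- function(seq_a, seq_b) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (seq_a == seq_b) return(100)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  # matches over the full alignment length, end gaps included: every
  # residue of both sequences appears exactly once in a global alignment,
  # so its length is n_a + n_b minus the number of aligned residue pairs
  100 * Biostrings::nmatch(pa) /
    (nchar(seq_a) + nchar(seq_b) -
       (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa)))
}

#' Maximal identity of a query sequence to a set of sequences
#'
#' @param test_seq Query amino-acid sequence.
#' @param train_seqs Character vector of training sequences (non-empty).
#' @return Maximal global identity in percent.
#' @export
max_identity_to_train <- function(test_seq, train_seqs) {
  train_seqs <- unique(train_seqs)
  if (length(train_seqs) == 0L) {
    abort("training sequence set is empty")
  }
  if (test_seq %in% train_seqs) return(100)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(train_seqs), Biostrings::AAString(test_seq),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  max(100 * Biostrings::nmatch(pa) /
        (nchar(train_seqs) + nchar(test_seq) -
           (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))))
}

#' Identity bucket of a maximal-identity percentage
#'
#' Buckets are half-open as <40, \[40, 80), \[80, 99), and >= 99 percent.
#'
#' @param pct Numeric vector of identity percentages.
#' @return Factor with levels `I0_40`, `I40_80`, `I80_99`, `I99_100`.
#' @export
identity_bucket <- function(pct) {
  cut(pct, breaks = c(-Inf, 40, 80, 99, Inf), right = FALSE,
      labels = c("I0_40", "I40_80", "I80_99", "I99_100"))
}

#' Sequence-grouped train/test split
#'
#' Records are grouped by exact amino-acid sequence; whole groups are drawn
#' at random (seeded) into the test set until the test fraction by record
#' count is reached within two percentage points. A single group larger than
#' the target test size is forced to train with a warning.
#'
#' @param curated Curated tibble with a `sequence` column.
#' @param test_fraction Target test share by record count (default 0.2).
#' @param seed Integer seed.
#' @return The input tibble with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(curated, test_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(curated), "sequence" %in% names(curated))
  n <- nrow(curated)
  groups <- split(seq_len(n), curated$sequence)
  sizes <- lengths(groups)
  target <- test_fraction * n
  hi <- (test_fraction + 0.02) * n
  lo <- (test_fraction - 0.02) * n

  ord <- with_local_seed(derive_seed(seed, "split"),
                         sample.int(length(groups)))
  test_idx <- integer(0)
  test_n <- 0
  for (g in ord) {
    if (test_n >= target) break
    if (test_n + sizes[g] <= hi) {
      test_idx <- c(test_idx, groups[[g]])
      test_n <- test_n + sizes[g]
    } else if (sizes[g] > hi) {
      warn(sprintf(
        "sequence group of %d records exceeds the test-set target; forced to train",
        sizes[g]))
    }
  }
  if (test_n < lo) {
    warn(sprintf("test share %.1f%% below target %.0f%% - 2%%",
                 100 * test_n / n, 100 * test_fraction))
  }
  curated$split <- "train"
  curated$split[test_idx] <- "test"
  curated
}

#' Assign cross-validation folds to training records
#'
#' Sequence groups are partitioned into `k` folds, greedily balanced by
#' record count (largest group first, each to the currently smallest fold;
#' a seeded shuffle breaks ties). No sequence spans two folds.
#'
#' @param train Tibble of training records with a `sequence` column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return The input tibble with an added integer `cv_fold` column in
#'   `0:(k-1)`.
#' @export
assign_cv_folds <- function(train, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(train), "sequence" %in% names(train))
  groups <- split(seq_len(nrow(train)), train$sequence)
  if (length(groups) < k) {
    warn(sprintf("only %d sequence groups for %d folds; some folds are empty",
                 length(groups), k))
  }
  ord <- with_local_seed(derive_seed(seed, "cv"),
                         sample.int(length(groups)))
  groups <- groups[ord]
  groups <- groups[order(-lengths(groups))]
  fold_sizes <- numeric(k)
  fold <- integer(nrow(train))
  for (g in seq_along(groups)) {
    f <- which.min(fold_sizes)
    fold[groups[[g]]] <- f - 1L
    fold_sizes[f] <- fold_sizes[f] + length(groups[[g]])
  }
  train$cv_fold <- fold
  train
}

#' Identity and reaction strata for test records
#'
#' For every test record computes (i) the maximal global sequence identity to
#' any training sequence plus its identity bucket, and (ii) whether the exact
#' reaction occurs in the training set, the maximal (min-max normalised)
#' structural-fingerprint similarity to training reactions, and the
#' reaction-similarity bucket (\[0, 0.4), \[0.4, 0.8), \[0.8, 1\]).
#'
#' @param split_tbl Output of [split_train_test()] with columns `sequence`,
#'   `reaction_smiles`, `reaction_key` and `split`.
#' @return The test rows of `split_tbl` with added columns
#'   `max_train_identity`, `identity_bucket_`, `reaction_seen`,
#'   `max_reaction_similarity`, `reaction_bucket`.
#' @export
annotate_test_strata <- function(split_tbl) {
  stopifnot(all(c("sequence", "reaction_key", "split") %in% names(split_tbl)))
  train <- split_tbl[split_tbl$split == "train", ]
  test <- split_tbl[split_tbl$split == "test", ]
  if (nrow(train) == 0L) abort("training set is empty")
  if (nrow(test) == 0L) abort("test set is empty")

  train_seqs <- unique(train$sequence)
  uniq_test_seqs <- unique(test$sequence)
  max_id <- vapply(uniq_test_seqs, max_identity_to_train, numeric(1),
                   train_seqs = train_seqs)
  test$max_train_identity <- max_id[match(test$sequence, uniq_test_seqs)]
  test$identity_bucket_ <- identity_bucket(test$max_train_identity)

  strata <- reaction_strata(test, train)
  test$reaction_seen <- strata$reaction_seen
  test$max_reaction_similarity <- strata$max_reaction_similarity
  test$reaction_bucket <- strata$reaction_bucket
  test
}

#' Reaction strata of test records relative to training reactions
#'
#' Exact reaction-key matches are flagged as seen (similarity 1). For unseen
#' reactions the raw Jaccard similarities of structural reaction fingerprints
#' against all training reactions are min-max normalised as one collection,
#' and the maximum per test reaction is reported. Buckets: \[0, 0.4),
#' \[0.4, 0.8), \[0.8, 1\].
#'
#' @param test_records,train_records Tibbles with columns `reaction_smiles`
#'   and `reaction_key`.
#' @return Tibble with columns `reaction_seen`, `max_reaction_similarity`,
#'   `reaction_bucket`, one row per test record.
#' @export
reaction_strata <- function(test_records, train_records) {
  if (nrow(train_records) == 0L) abort("no training reactions")
  train_keys <- unique(train_records$reaction_key)
  seen <- test_records$reaction_key %in% train_keys

  uniq_train <- train_records[!duplicated(train_records$reaction_key),
                              c("reaction_smiles", "reaction_key")]
  uniq_test <- test_records[!duplicated(test_records$reaction_key),
                            c("reaction_smiles", "reaction_key")]
  train_fps <- lapply(uniq_train$reaction_smiles, reaction_fingerprint,
                      kind = "structural")
  test_fps <- lapply(uniq_test$reaction_smiles, reaction_fingerprint,
                     kind = "structural")

  raw <- matrix(0, nrow = length(test_fps), ncol = length(train_fps))
  for (i in seq_along(test_fps)) {
    for (j in seq_along(train_fps)) {
      raw[i, j] <- reaction_similarity(test_fps[[i]], train_fps[[j]])
    }
  }
  norm <- matrix(normalize_similarities(as.numeric(raw)), nrow = nrow(raw))
  max_sim_uniq <- apply(norm, 1, max)
  sim <- max_sim_uniq[match(test_records$reaction_key, uniq_test$reaction_key)]
  sim[seen] <- 1

  tibble(
    reaction_seen = seen,
    max_reaction_similarity = sim,
    reaction_bucket = cut(sim, breaks = c(-Inf, 0.4, 0.8, Inf), right = FALSE,
                          labels = c("S0_04", "S04_08", "S08_10"))
  )
}
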