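## Dataset readers and writers.
##
## The measurement CSV schema: enzyme_id, sequence, reaction_smiles (or
## substrates_inchi + products_inchi, semicolon-separated per side), kcat_s,
## ec, source, organism, wild_type. kcat_s must parse as a positive number;
## wild_type as a logical.

DATASET_COLUMNS <- c("enzyme_id", "sequence", "kcat_s", "ec", "source",
                     "organism", "wild_type")

#' Read a kcat measurement table
#'
#' Validates the schema, types the columns, and converts per-side InChI
#' lists into reaction SMILES when no `reaction_smiles` column is present.
#' Row numbers are preserved for error messages.
#'
#' @param path CSV file path.
#' @return Typed tibble with a `record_id` column (from the file or row
#'   numbers).
#' @export
read_kcat_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  has_smiles <- "reaction_smiles" %in% names(raw)
  has_inchi <- all(c("substrates_inchi", "products_inchi") %in% names(raw))
  if (!has_smiles && !has_inchi) {
    abort(paste0("need either a reaction_smiles column or ",
                 "substrates_inchi + products_inchi columns"))
  }

  kcat <- suppressWarnings(as.numeric(raw$kcat_s))
  bad <- which(is.na(kcat) | kcat <= 0)
  if (length(bad) > 0) {
    abort(sprintf("row %d: kcat_s must be a positive number (got '%s')",
                  bad[1], raw$kcat_s[bad[1]]))
  }
  wt <- toupper(trimws(raw$wild_type)) %in% c("TRUE", "T", "1", "YES")

  if (!has_smiles) {
    subs <- strsplit(raw$substrates_inchi, ";", fixed = TRUE)
    prods <- strsplit(raw$products_inchi, ";", fixed = TRUE)
    raw$reaction_smiles <- vapply(seq_len(nrow(raw)), function(i) {
      r <- parse_reaction(substrates = trimws(subs[[i]]),
                          products = trimws(prods[[i]]))
      r$key
    }, character(1))
  }

  out <- tibble(
    record_id = if ("record_id" %in% names(raw)) raw$record_id else
      sprintf("R%05d", seq_len(nrow(raw))),
    enzyme_id = raw$enzyme_id,
    sequence = toupper(raw$sequence),
    reaction_smiles = raw$reaction_smiles,
    kcat_s = kcat,
    ec = raw$ec,
    source = raw$source,
    organism = raw$organism,
    wild_type = wt
  )
  dup <- duplicated(out[, c("enzyme_id", "reaction_smiles", "kcat_s",
                            "source")])
  if (any(dup)) {
    warn(sprintf("%d duplicated (enzyme, reaction, kcat, source) row(s)",
                 sum(dup)))
  }
  out
}

#' Write a kcat measurement table
#'
#' @param records Tibble in the [read_kcat_dataset()] schema.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_kcat_dataset <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param tbl Tibble with `enzyme_id` and `sequence` columns.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(tbl, path) {
  x <- Biostrings::AAStringSet(tbl$sequence)
  names(x) <- tbl$enzyme_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file of amino-acid sequences
#'
#' @param path FASTA file.
#' @return Tibble with `enzyme_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(enzyme_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' Write a split assignment
#'
#' Two-column CSV (record id, train/test assignment) plus a JSON sidecar
#' with the seed and the test-side strata.
#'
#' @param split_tbl Output of [split_train_test()] (optionally annotated).
#' @param path CSV path; the sidecar gets extension `.json`.
#' @param seed The seed used to create the split.
#' @return The path, invisibly.
#' @export
write_split <- function(split_tbl, path, seed = NA_integer_) {
  readr::write_csv(split_tbl[, c("record_id", "split")], path)
  sidecar <- sub("\\.csv$", ".json", path)
  strata <- split_tbl[split_tbl$split == "test",
                      intersect(c("record_id", "max_train_identity",
                                  "identity_bucket_", "reaction_seen",
                                  "max_reaction_similarity",
                                  "reaction_bucket"), names(split_tbl))]
  jsonlite::write_json(list(seed = seed, test_strata = strata), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
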