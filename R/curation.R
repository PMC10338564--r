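## Curation cascade: raw merged measurements -> modelling dataset.
##
## Stage order follows the curation narrative of multi-source kinetic
## databases: exact deduplication, geometric-mean aggregation per
## enzyme-reaction pair (with the 1%-of-maximum exclusion), removal of
## probable non-natural reactions (10x rule within an enzyme), removal of
## probable suboptimal measurements (100x rule within a reaction or EC
## class), removal of rows whose representations cannot be computed, of
## mass-imbalanced reactions, and of implausible outliers. All rules operate
## on aggregated (geometric-mean) kcat values.

#' @importFrom dplyr group_by ungroup mutate filter select arrange summarise
#'   n distinct across all_of first left_join bind_rows row_number
NULL

#' Attach canonical reaction keys
#'
#' Parses each distinct `reaction_smiles` once and adds the canonical
#' `reaction_key` column. Unparsable reactions get an `NA` key (they are
#' removed later by [curate_filter_representation()]).
#'
#' @param records Tibble with a `reaction_smiles` column.
#' @return The tibble with an added `reaction_key` column.
#' @export
add_reaction_keys <- function(records) {
  uniq <- unique(records$reaction_smiles)
  keys <- vapply(uniq, function(s) {
    tryCatch(as_kcat_reaction(s)$key, error = function(e) NA_character_)
  }, character(1))
  records$reaction_key <- keys[match(records$reaction_smiles, uniq)]
  records
}

#' Remove exact duplicate measurements
#'
#' Collapses rows identical on enzyme id, sequence, reaction key and kcat
#' value to a single row; the source column is ignored, so the same
#' measurement reported by two databases counts as one.
#'
#' @param records Raw measurement tibble (with `reaction_key`; see
#'   [add_reaction_keys()]).
#' @return Deduplicated tibble.
#' @export
curate_deduplicate <- function(records) {
  dup <- duplicated(records[, c("enzyme_id", "sequence", "reaction_key",
                                "kcat_s")])
  records[!dup, , drop = FALSE]
}

#' Aggregate measurements per enzyme-reaction pair
#'
#' Within each (sequence, reaction key) group, values smaller than 1% of the
#' group maximum are excluded (they were likely measured under non-optimal
#' conditions), and the geometric mean of the survivors becomes the group's
#' kcat. The target variable `y` is log10 of that geometric mean.
#'
#' @param records Deduplicated measurement tibble.
#' @param low_value_fraction Exclusion threshold relative to the group
#'   maximum (default 0.01).
#' @return Curated tibble, one row per (sequence, reaction key), with columns
#'   `kcat_geomean`, `y` and `n_source_values`.
#' @export
curate_aggregate <- function(records, low_value_fraction = 0.01) {
  stopifnot(all(records$kcat_s > 0))
  records |>
    group_by(.data$sequence, .data$reaction_key) |>
    summarise(
      enzyme_id = first(.data$enzyme_id),
      reaction_smiles = first(.data$reaction_smiles),
      ec = first(.data$ec),
      organism = first(.data$organism),
      kcat_geomean = {
        keep <- .data$kcat_s >= low_value_fraction * max(.data$kcat_s)
        geometric_mean(.data$kcat_s[keep])
      },
      n_source_values = sum(.data$kcat_s >=
                              low_value_fraction * max(.data$kcat_s)),
      .groups = "drop"
    ) |>
    mutate(y = log10(.data$kcat_geomean)) |>
    arrange(.data$sequence, .data$reaction_key)
}

#' Drop probable non-natural reactions (10x rule)
#'
#' Within each enzyme (exact sequence), a row is removed when a measurement
#' for a *different* reaction of the same enzyme is more than ten times
#' higher: secondary reactions are much slower than the natural one.
#'
#' @param curated Aggregated tibble from [curate_aggregate()].
#' @param ratio Removal threshold (default 10).
#' @return Filtered tibble.
#' @export
curate_filter_non_natural <- function(curated, ratio = 10) {
  curated |>
    group_by(.data$sequence) |>
    filter({
      max_other <- vapply(seq_along(.data$kcat_geomean), function(i) {
        others <- .data$kcat_geomean[-i]
        if (length(others) == 0) -Inf else max(others)
      }, numeric(1))
      !(max_other > ratio * .data$kcat_geomean)
    }) |>
    ungroup()
}

#' Drop probable suboptimal measurements (100x rule)
#'
#' A row is removed when another measurement for the same reaction key, or
#' for the same EC number, is more than one hundred times higher. Rows with
#' a missing EC number are only subject to the reaction-key criterion.
#'
#' @param curated Aggregated tibble.
#' @param ratio Removal threshold (default 100).
#' @return Filtered tibble.
#' @export
curate_filter_suboptimal <- function(curated, ratio = 100) {
  key_max <- tapply(curated$kcat_geomean, curated$reaction_key, max)
  has_ec <- !is.na(curated$ec) & nzchar(curated$ec)
  ec_max <- tapply(curated$kcat_geomean[has_ec], curated$ec[has_ec], max)
  mk <- unname(key_max[curated$reaction_key])
  me <- rep(-Inf, nrow(curated))
  me[has_ec] <- unname(ec_max[curated$ec[has_ec]])
  drop <- (mk > ratio * curated$kcat_geomean) |
    (me > ratio * curated$kcat_geomean)
  curated[!drop, , drop = FALSE]
}

#' Drop rows whose representations cannot be computed
#'
#' Attempts the reaction fingerprint and the enzyme embedding for every row;
#' rows for which either computation fails are removed. The failure reasons
#' are recorded in the `removed` attribute of the result.
#'
#' @param curated Aggregated tibble.
#' @param fingerprinter Function reaction_smiles -> fingerprint (default
#'   DRFP).
#' @param embedder Function sequence -> embedding vector (default stub).
#' @return Filtered tibble with attribute `removed` (tibble of row ids and
#'   reasons).
#' @export
curate_filter_representation <- function(
    curated,
    fingerprinter = function(s) reaction_fingerprint(s, kind = "drfp"),
    embedder = function(s) stub_embed(s)) {
  uniq_rxn <- unique(curated$reaction_smiles)
  rxn_ok <- vapply(uniq_rxn, function(s) {
    !inherits(tryCatch(fingerprinter(s), error = function(e) e), "error")
  }, logical(1))
  uniq_seq <- unique(curated$sequence)
  seq_ok <- vapply(uniq_seq, function(s) {
    !inherits(tryCatch(embedder(s), error = function(e) e), "error")
  }, logical(1))
  ok <- rxn_ok[match(curated$reaction_smiles, uniq_rxn)] &
    seq_ok[match(curated$sequence, uniq_seq)] &
    !is.na(curated$reaction_key)
  removed <- tibble(
    sequence = curated$sequence[!ok],
    reaction_smiles = curated$reaction_smiles[!ok],
    reason = ifelse(
      !rxn_ok[match(curated$reaction_smiles[!ok], uniq_rxn)] |
        is.na(curated$reaction_key[!ok]),
      "reaction fingerprint failed", "enzyme embedding failed")
  )
  out <- curated[ok, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Drop mass-imbalanced reactions
#'
#' Keeps rows whose reaction passes [mass_balance_ok()]: the summed
#' molecular weights of the two sides agree within tolerance.
#'
#' @param curated Aggregated tibble.
#' @param rel_tol Relative tolerance (default 0.01).
#' @param abs_tol Absolute floor in g/mol (default 1.5).
#' @return Filtered tibble.
#' @export
curate_filter_mass_imbalance <- function(curated, rel_tol = 0.01,
                                         abs_tol = 1.5) {
  uniq <- unique(curated$reaction_smiles)
  ok <- vapply(uniq, function(s) {
    tryCatch(mass_balance_ok(s, rel_tol = rel_tol, abs_tol = abs_tol),
             error = function(e) FALSE)
  }, logical(1))
  curated[ok[match(curated$reaction_smiles, uniq)], , drop = FALSE]
}

#' Drop kcat outliers
#'
#' Keeps rows with aggregated kcat between 10^-2.5 and 10^5 per second,
#' bounds inclusive; values strictly below or above are implausible for
#' enzyme turnover and usually reflect reporting errors.
#'
#' @param curated Aggregated tibble.
#' @param lower,upper Inclusive bounds in s^-1.
#' @return Filtered tibble.
#' @export
curate_filter_outliers <- function(curated, lower = 10^-2.5, upper = 10^5) {
  # small relative slack so values exactly on a bound survive the float
  # round trip through the log-scale geometric mean
  keep <- curated$kcat_geomean >= lower * (1 - 1e-12) &
    curated$kcat_geomean <= upper * (1 + 1e-12)
  curated[keep, , drop = FALSE]
}

#' Run the full curation cascade
#'
#' Applies, in order: deduplication, geometric-mean aggregation,
#' non-natural-reaction filter (10x), suboptimal-measurement filter (100x),
#' representation-failure filter, mass-balance filter, and outlier filter.
#' Per-stage input/output counts are recorded in a log.
#'
#' @param records Raw measurement tibble (schema of [read_kcat_dataset()]).
#' @param config Optional named list overriding thresholds:
#'   `low_value_fraction`, `non_natural_ratio`, `suboptimal_ratio`,
#'   `mass_rel_tol`, `mass_abs_tol`, `outlier_lower`, `outlier_upper`.
#' @return Curated tibble with attribute `curation_log` (see
#'   [curation_log()]).
#' @export
run_curation <- function(records, config = list()) {
  cfg <- utils::modifyList(list(
    low_value_fraction = 0.01, non_natural_ratio = 10,
    suboptimal_ratio = 100, mass_rel_tol = 0.01, mass_abs_tol = 1.5,
    outlier_lower = 10^-2.5, outlier_upper = 10^5
  ), config)

  if (!"reaction_key" %in% names(records)) {
    records <- add_reaction_keys(records)
  }
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out, n_removed = n_in - n_out)
  }

  s1 <- curate_deduplicate(records)
  note("deduplicate", nrow(records), nrow(s1))
  s2 <- curate_aggregate(s1, cfg$low_value_fraction)
  note("aggregate", nrow(s1), nrow(s2))
  s3 <- curate_filter_non_natural(s2, cfg$non_natural_ratio)
  note("filter_non_natural", nrow(s2), nrow(s3))
  s4 <- curate_filter_suboptimal(s3, cfg$suboptimal_ratio)
  note("filter_suboptimal", nrow(s3), nrow(s4))
  s5 <- curate_filter_representation(s4)
  note("filter_representation", nrow(s4), nrow(s5))
  s6 <- curate_filter_mass_imbalance(s5, cfg$mass_rel_tol, cfg$mass_abs_tol)
  note("filter_mass_imbalance", nrow(s5), nrow(s6))
  s7 <- curate_filter_outliers(s6, cfg$outlier_lower, cfg$outlier_upper)
  note("filter_outliers", nrow(s6), nrow(s7))

  if (nrow(s7) == 0L) {
    abort("curation removed every record; inspect the curation log")
  }
  attr(s7, "curation_log") <- bind_rows(log)
  attr(s7, "removed_representation") <- attr(s5, "removed")
  s7
}

#' Per-stage curation log
#'
#' @param curated Result of [run_curation()].
#' @return Tibble with columns `stage`, `n_in`, `n_out`, `n_removed`.
#' @export
curation_log <- function(curated) {
  log <- attr(curated, "curation_log")
  if (is.null(log)) abort("no curation log attached; use run_curation()")
  log
}
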