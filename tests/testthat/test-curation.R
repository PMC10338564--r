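make_records <- function(...) {
  rows <- list(...)
  tbl <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      enzyme_id = r[["id"]], sequence = r[["seq"]],
      reaction_smiles = r[["rxn"]], kcat_s = as.numeric(r[["kcat"]]),
      ec = if (is.null(r[["ec"]])) NA_character_ else r[["ec"]],
      source = "brenda",
      organism = "Escherichia coli", wild_type = TRUE)
  }))
  add_reaction_keys(tbl)
}

rxn1 <- "CCO>>CC=O"
rxn2 <- "CCCO>>CCC=O"
rxn3 <- "CCCCO>>CCCC=O"

test_that("deduplication collapses only exact duplicates", {
  rec <- make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 5),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 5),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 7),
    list(id = "e2", seq = "MKL", rxn = rxn1, kcat = 5),
    list(id = "e2", seq = "MKL", rxn = rxn2, kcat = 2))
  out <- curate_deduplicate(rec)
  expect_equal(nrow(out), 4)
  expect_equal(nrow(curate_deduplicate(out)), 4)  # idempotent
})

test_that("aggregation applies the 1% rule then the geometric mean", {
  rec <- make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 1.0),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 10.0),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 0.05))
  out <- curate_aggregate(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$kcat_geomean, sqrt(10))
  expect_equal(out$n_source_values, 2)
  expect_equal(out$y, log10(sqrt(10)))

  single <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 3.7)))
  expect_equal(single$kcat_geomean, 3.7)
  same <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 2),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 2),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 2)))
  expect_equal(same$kcat_geomean, 2)
})

test_that("aggregation is invariant to input row order", {
  rec <- make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 1),
    list(id = "e1", seq = "MKV", rxn = rxn2, kcat = 4),
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 9),
    list(id = "e2", seq = "MKL", rxn = rxn1, kcat = 2))
  a <- curate_aggregate(rec)
  b <- curate_aggregate(rec[c(3, 1, 4, 2), ])
  expect_equal(a, b)
})

test_that("the 10x non-natural rule follows the worked examples", {
  agg <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 100),
    list(id = "e1", seq = "MKV", rxn = rxn2, kcat = 5)))
  out <- curate_filter_non_natural(agg)
  expect_equal(nrow(out), 1)
  expect_equal(out$kcat_geomean, 100)

  agg2 <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 100),
    list(id = "e1", seq = "MKV", rxn = rxn2, kcat = 20)))
  expect_equal(nrow(curate_filter_non_natural(agg2)), 2)

  agg3 <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 100)))
  expect_equal(nrow(curate_filter_non_natural(agg3)), 1)
})

test_that("the 100x suboptimal rule uses reaction key and EC number", {
  agg <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 500, ec = "1.1.1.1"),
    list(id = "e2", seq = "MKL", rxn = rxn1, kcat = 1, ec = "1.1.1.2")))
  out <- curate_filter_suboptimal(agg)
  expect_equal(nrow(out), 1)
  expect_equal(out$kcat_geomean, 500)

  # same EC, only 50x apart: both kept
  agg2 <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 50, ec = "1.1.1.1"),
    list(id = "e2", seq = "MKL", rxn = rxn2, kcat = 1, ec = "1.1.1.1")))
  expect_equal(nrow(curate_filter_suboptimal(agg2)), 2)

  # same EC, 500x apart: low one removed even with different reactions
  agg3 <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 500, ec = "1.1.1.1"),
    list(id = "e2", seq = "MKL", rxn = rxn2, kcat = 1, ec = "1.1.1.1")))
  expect_equal(nrow(curate_filter_suboptimal(agg3)), 1)

  # missing EC: only the reaction-key criterion applies
  agg4 <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 500),
    list(id = "e2", seq = "MKL", rxn = rxn2, kcat = 1)))
  expect_equal(nrow(curate_filter_suboptimal(agg4)), 2)
})

test_that("representation failures are filtered with reasons", {
  agg <- curate_aggregate(make_records(
    list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 5),
    list(id = "e2", seq = "MKL", rxn = rxn2, kcat = 5)))
  agg$reaction_smiles[2] <- "not>>parsable"
  agg$reaction_key[2] <- NA_character_
  out <- curate_filter_representation(agg)
  expect_equal(nrow(out), 1)
  expect_equal(nrow(attr(out, "removed")), 1)

  clean <- curate_filter_representation(
    curate_aggregate(make_records(
      list(id = "e1", seq = "MKV", rxn = rxn1, kcat = 5))))
  expect_equal(nrow(clean), 1)
})

test_that("the outlier filter keeps its inclusive boundaries", {
  agg <- curate_aggregate(make_records(
    list(id = "e1", seq = "A", rxn = rxn1, kcat = 10^-3),
    list(id = "e2", seq = "C", rxn = rxn1, kcat = 10^-2.5),
    list(id = "e3", seq = "D", rxn = rxn1, kcat = 10^5),
    list(id = "e4", seq = "E", rxn = rxn1, kcat = 2e5),
    list(id = "e5", seq = "F", rxn = rxn1, kcat = 10)))
  out <- curate_filter_outliers(agg)
  expect_setequal(out$sequence, c("C", "D", "F"))
})

test_that("curation removes exactly the planted decoys on the synthetic fixture", {
  ds <- synth_fixture()
  cur <- curated_fixture()
  log <- curation_log(cur)
  tp <- ds$truth$pair_classes

  counts <- table(tp$class)
  expect_equal(log$n_removed[log$stage == "deduplicate"],
               length(ds$truth$duplicate_record_ids))
  expect_equal(log$n_removed[log$stage == "filter_non_natural"],
               unname(counts["non_natural"]))
  expect_equal(log$n_removed[log$stage == "filter_suboptimal"],
               unname(counts["suboptimal"]))
  expect_equal(log$n_removed[log$stage == "filter_representation"], 0)
  expect_equal(log$n_removed[log$stage == "filter_mass_imbalance"],
               unname(counts["mass_imbalanced"]))
  expect_equal(log$n_removed[log$stage == "filter_outliers"],
               unname(counts["outlier"]))

  # surviving set is exactly the clean pairs, with no false removals
  expect_setequal(paste(cur$sequence, cur$reaction_key),
                  paste(tp$sequence, tp$reaction_key)[tp$class == "clean"])
})

test_that("curation stages are idempotent and never grow the data", {
  cur <- curated_fixture()
  log <- curation_log(cur)
  expect_true(all(log$n_out <= log$n_in))
  expect_true(all(log$n_in - log$n_removed == log$n_out))

  expect_equal(nrow(curate_filter_non_natural(cur)), nrow(cur))
  expect_equal(nrow(curate_filter_suboptimal(cur)), nrow(cur))
  expect_equal(nrow(curate_filter_outliers(cur)), nrow(cur))
  expect_false(any(duplicated(cur[, c("sequence", "reaction_key")])))
})

test_that("clean input passes every stage unchanged", {
  cfg <- synthetic_config(
    n_families = 12L, seed = 7L,
    decoy_rates = list(duplicates = 0, outliers = 0, mass_imbalanced = 0,
                       non_natural_10x = 0, suboptimal_100x = 0))
  ds <- generate_dataset(cfg)
  cur <- run_curation(ds$records)
  log <- curation_log(cur)
  post_agg <- log[log$stage != "deduplicate" & log$stage != "aggregate", ]
  expect_true(all(post_agg$n_removed == 0))
  expect_equal(log$n_removed[log$stage == "deduplicate"], 0)
})
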