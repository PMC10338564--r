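## End-to-end pipeline: simulate (or load) -> curate -> split -> train ->
## evaluate. This is the programmatic equivalent of the command-line
## subcommand chain and the entry point the acceptance checks use.

#' Run the full kcat prediction pipeline
#'
#' Curates the measurement table, makes the sequence-grouped 80/20 split and
#' 5-fold CV assignment, fits the two-component boosted-tree ensemble with a
#' random-search budget, and evaluates the ensemble and both components on
#' the held-out test set, stratified by identity bucket and reaction
#' stratum.
#'
#' @param records Measurement tibble ([read_kcat_dataset()] schema). If
#'   `NULL`, a synthetic dataset is generated from `synth_config`.
#' @param synth_config [synthetic_config()] used when `records` is `NULL`.
#' @param n_trials Total random-search budget (default 50, split across the
#'   two component searches).
#' @param test_fraction Held-out share (default 0.2).
#' @param seed Integer seed driving simulation, splitting and training.
#' @param embeddings Optional precomputed embedding matrix.
#' @param curation_config Threshold overrides for [run_curation()].
#' @return A list of class `kcat_pipeline` with `curated`, `split`, `model`,
#'   `predictions` (test tibble with `y_pred_*` columns), and `reports`
#'   (named list of `kcat_eval` for ensemble / reaction_only / enzyme_only).
#' @export
run_kcat_pipeline <- function(records = NULL,
                              synth_config = synthetic_config(),
                              n_trials = 50L, test_fraction = 0.2,
                              seed = 1L, embeddings = NULL,
                              curation_config = list()) {
  if (is.null(records)) {
    synth_config$seed <- derive_seed(seed, "synth")
    records <- generate_dataset(synth_config)$records
  }
  curated <- run_curation(records, config = curation_config)
  split_tbl <- split_train_test(curated, test_fraction = test_fraction,
                                seed = seed)
  train <- split_tbl[split_tbl$split == "train", ]
  train <- assign_cv_folds(train, k = 5L, seed = seed)
  test <- annotate_test_strata(split_tbl)

  model <- fit_kcat_model(train, n_trials = n_trials, seed = seed,
                          embeddings = embeddings)

  test$y_pred <- predict(model, test, rule = "mean_of_two")
  test$y_pred_reaction <- predict(model, test, rule = "reaction_only")
  test$y_pred_enzyme <- predict(model, test, rule = "enzyme_only")

  reports <- list(
    ensemble = stratified_report(test, test$y_pred),
    reaction_only = stratified_report(test, test$y_pred_reaction),
    enzyme_only = stratified_report(test, test$y_pred_enzyme)
  )
  structure(list(curated = curated, split = split_tbl, train = train,
                 model = model, predictions = test, reports = reports,
                 seed = seed),
            class = "kcat_pipeline")
}

#' @export
print.kcat_pipeline <- function(x, ...) {
  cat("<kcat_pipeline> seed", x$seed, "\n")
  cat("curated records:", nrow(x$curated),
      "| train:", nrow(x$train), "| test:", nrow(x$predictions), "\n")
  ov <- x$reports$ensemble$overall
  cat(sprintf("ensemble held-out R^2 = %.3f, MSE = %.3f, r = %.3f\n",
              ov$r2, ov$mse, ov$pearson_r))
  invisible(x)
}

#' Prediction table for new enzyme-reaction queries
#'
#' Mirrors the prediction-service output: predicted log10 kcat and kcat in
#' s^-1 per query, plus the maximal sequence identity of the query enzyme to
#' the training enzymes and the maximal reaction similarity to training
#' reactions, which together indicate how much to trust the prediction.
#'
#' @param model A fitted `kcat_model`.
#' @param queries Tibble with `enzyme_id`, `sequence`, `reaction_smiles`.
#' @return Tibble with `enzyme_id`, `y_pred_log10`, `kcat_pred_s`,
#'   `max_train_identity_pct`, `max_reaction_similarity`.
#' @export
predict_kcat_table <- function(model, queries) {
  queries <- add_reaction_keys(queries)
  y_pred <- predict(model, queries)
  ref <- model$train_reference
  train_seqs <- unique(ref$sequence)
  ident <- vapply(queries$sequence, max_identity_to_train, numeric(1),
                  train_seqs = train_seqs)
  strata <- reaction_strata(queries, ref)
  tibble(
    enzyme_id = queries$enzyme_id,
    y_pred_log10 = y_pred,
    kcat_pred_s = 10^y_pred,
    max_train_identity_pct = unname(ident),
    max_reaction_similarity = strata$max_reaction_similarity
  )
}
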