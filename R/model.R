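## Gradient-boosted kcat regression.
##
## Feature blocks (DRFP 2048, enzyme embedding 1280, joint 3328) feed
## boosted regression trees (xgboost, squared-error objective). Random-search
## cross-validation over the declared hyperparameter space selects the
## configuration with the highest mean out-of-fold R^2; the final predictor
## averages the reaction-only and enzyme-only models on the log10 scale.

#' Default hyperparameter search space
#'
#' Log-uniform learning rate \[0.01, 0.5\] and regularisation coefficients
#' alpha/lambda \[1e-5, 10\]; uniform integer tree depth \[2, 12\] and
#' boosting rounds \[50, 1500\]; uniform max delta step \[0, 5\] and minimum
#' child weight \[1, 20\].
#'
#' @return Named list describing the sampling ranges.
#' @export
default_search_space <- function() {
  list(
    learning_rate = c(0.01, 0.5),      # log-uniform
    reg_alpha = c(1e-5, 10),           # log-uniform
    reg_lambda = c(1e-5, 10),          # log-uniform
    max_depth = c(2L, 12L),            # uniform integer
    max_delta_step = c(0, 5),          # uniform
    n_rounds = c(50L, 1500L),          # uniform integer
    min_child_weight = c(1, 20)        # uniform
  )
}

sample_hyperparams <- function(space, n, seed) {
  lu <- function(r, n) exp(stats::runif(n, log(r[1]), log(r[2])))
  with_local_seed(seed, tibble(
    trial = seq_len(n),
    learning_rate = lu(space$learning_rate, n),
    reg_alpha = lu(space$reg_alpha, n),
    reg_lambda = lu(space$reg_lambda, n),
    max_depth = sample(space$max_depth[1]:space$max_depth[2], n,
                       replace = TRUE),
    max_delta_step = stats::runif(n, space$max_delta_step[1],
                                  space$max_delta_step[2]),
    n_rounds = sample(space$n_rounds[1]:space$n_rounds[2], n,
                      replace = TRUE),
    min_child_weight = stats::runif(n, space$min_child_weight[1],
                                    space$min_child_weight[2])
  ))
}

r_squared <- function(y_true, y_pred) {
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) abort("zero variance in y_true; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

gbm_params <- function(hp, seed) {
  list(
    objective = "reg:squarederror",
    eta = hp$learning_rate,
    alpha = hp$reg_alpha,
    lambda = hp$reg_lambda,
    max_depth = as.integer(hp$max_depth),
    max_delta_step = hp$max_delta_step,
    min_child_weight = hp$min_child_weight,
    tree_method = "hist",
    max_bin = 8,
    nthread = 1,
    seed = as.integer(seed)
  )
}

#' Train one gradient-boosted regressor
#'
#' Squared-error boosted trees; deterministic given the data, the
#' hyperparameters and the seed.
#'
#' @param X Numeric feature matrix (dense or `dgCMatrix`), n >= 20 rows.
#' @param y Numeric target (log10 kcat).
#' @param hp Named list/row with `learning_rate`, `reg_alpha`, `reg_lambda`,
#'   `max_depth`, `max_delta_step`, `n_rounds`, `min_child_weight`.
#' @param seed Integer seed.
#' @return An `xgb.Booster`.
#' @export
train_gbm <- function(X, y, hp, seed = 1L) {
  if (nrow(X) < 20L) abort("need at least 20 training rows")
  if (anyNA(y) || any(!is.finite(y))) abort("non-finite values in y")
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = gbm_params(hp, seed), data = dtrain,
                     nrounds = as.integer(hp$n_rounds), verbose = 0)
}

#' Random-search cross-validation for boosted-tree hyperparameters
#'
#' Draws `n_trials` seeded configurations from the search space, evaluates
#' each by mean out-of-fold R^2 over the provided CV folds, and returns the
#' best configuration together with the full trial table.
#'
#' @param X Feature matrix.
#' @param y Target vector.
#' @param folds Integer fold labels (from [assign_cv_folds()]), one per row.
#' @param space Search space (default [default_search_space()]).
#' @param n_trials Number of random draws (>= 1).
#' @param seed Integer seed.
#' @return List with `best_hp` (one-row tibble), `best_cv_r2`, and `trials`
#'   (tibble with per-trial mean CV R^2).
#' @export
random_search_cv <- function(X, y, folds, space = default_search_space(),
                             n_trials = 25L, seed = 1L) {
  if (n_trials < 1L) abort("n_trials must be at least 1")
  stopifnot(length(folds) == nrow(X), length(y) == nrow(X))
  hp_tbl <- sample_hyperparams(space, n_trials, derive_seed(seed, "hp"))

  fold_ids <- sort(unique(folds))
  fold_data <- lapply(fold_ids, function(f) {
    idx <- folds != f
    if (sum(idx) == 0L || sum(!idx) == 0L) return(NULL)
    list(
      dtrain = xgboost::xgb.DMatrix(X[idx, , drop = FALSE],
                                    label = y[idx], nthread = 1),
      X_val = X[!idx, , drop = FALSE],
      y_val = y[!idx]
    )
  })
  fold_data <- fold_data[!vapply(fold_data, is.null, logical(1))]
  if (length(fold_data) == 0L) abort("no usable CV folds")

  cv_r2 <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    hp <- hp_tbl[t, ]
    r2s <- vapply(fold_data, function(fd) {
      booster <- xgboost::xgb.train(
        params = gbm_params(hp, derive_seed(seed, paste0("fit", t))),
        data = fd$dtrain, nrounds = as.integer(hp$n_rounds), verbose = 0)
      pred <- predict(booster, xgboost::xgb.DMatrix(fd$X_val, nthread = 1))
      r_squared(fd$y_val, pred)
    }, numeric(1))
    cv_r2[t] <- mean(r2s)
  }
  hp_tbl$cv_r2 <- cv_r2
  best <- which.max(cv_r2)
  list(best_hp = hp_tbl[best, ], best_cv_r2 = cv_r2[best], trials = hp_tbl)
}

#' Assemble model features for curated records
#'
#' Builds the feature matrix for the requested block: the DRFP reaction
#' fingerprint (2048 columns), the enzyme embedding (1280 columns), or their
#' concatenation (`"joint"`, 3328 columns), row-aligned with the curated
#' records and the target `y`.
#'
#' @param curated Curated tibble with `reaction_smiles`, `sequence`, `y`.
#' @param block `"drfp"`, `"embedding"` or `"joint"`.
#' @param n_bits,max_radius DRFP parameters.
#' @param embed_seed Stub-embedding projection seed.
#' @param embeddings Optional precomputed embedding matrix keyed by
#'   `enzyme_id` (overrides the stub backend).
#' @return List with `X` (matrix), `y`, and `block`.
#' @export
assemble_features <- function(curated, block = c("joint", "drfp", "embedding"),
                              n_bits = 2048L, max_radius = 3L,
                              embed_seed = 101L, embeddings = NULL) {
  block <- match.arg(block)
  X_parts <- list()
  if (block %in% c("drfp", "joint")) {
    uniq <- unique(curated$reaction_smiles)
    fps <- t(vapply(uniq, function(s) {
      as.integer(reaction_fingerprint(s, kind = "drfp", n_bits = n_bits,
                                      max_radius = max_radius))
    }, integer(n_bits)))
    X_parts$drfp <- fps[match(curated$reaction_smiles, uniq), ,
                        drop = FALSE]
  }
  if (block %in% c("embedding", "joint")) {
    if (is.null(embeddings)) {
      X_parts$embedding <- embed_sequences(curated$sequence,
                                           backend = "stub",
                                           seed = embed_seed)
    } else {
      X_parts$embedding <- embed_sequences(
        tibble(enzyme_id = curated$enzyme_id, sequence = curated$sequence),
        backend = "precomputed", precomputed = embeddings)
    }
  }
  X <- do.call(cbind, unname(X_parts))
  colnames(X) <- NULL
  rownames(X) <- NULL
  # both blocks are sparse by construction (binary bits / count sketch)
  X <- Matrix::Matrix(X, sparse = TRUE)
  list(X = X, y = curated$y, block = block)
}

#' Fit the two-model kcat ensemble
#'
#' Runs a random-search CV for the reaction-only (DRFP) and enzyme-only
#' (embedding) boosted-tree models, refits each on the full training data
#' with its best hyperparameters, and combines them with the mean-of-two
#' rule: the final prediction is the arithmetic mean of the two component
#' predictions on the log10 scale. A joint model over the concatenated
#' features can be added for comparison.
#'
#' @param train Curated training tibble with a `cv_fold` column (see
#'   [assign_cv_folds()]).
#' @param n_trials Total random-search budget shared across the component
#'   searches (default 50; 60/40 reaction/enzyme without the joint model).
#' @param seed Integer seed.
#' @param include_joint Also fit the joint-feature model (default FALSE).
#' @param space Hyperparameter search space.
#' @param embed_seed Stub-embedding seed.
#' @param embeddings Optional precomputed embedding matrix.
#' @return A `kcat_model` object.
#' @export
fit_kcat_model <- function(train, n_trials = 50L, seed = 1L,
                           include_joint = FALSE,
                           space = default_search_space(),
                           embed_seed = 101L, embeddings = NULL) {
  if (!"cv_fold" %in% names(train)) {
    abort("train must carry a cv_fold column; see assign_cv_folds()")
  }
  blocks <- c("drfp", "embedding")
  if (include_joint) blocks <- c(blocks, "joint")
  # total budget split across the component searches; the reaction block is
  # several times cheaper per trial, so it takes the larger share
  shares <- if (include_joint) {
    c(drfp = 0.4, embedding = 0.3, joint = 0.3)
  } else {
    c(drfp = 0.6, embedding = 0.4)
  }
  budgets <- round(n_trials * shares)
  budgets[budgets < 1] <- 1L

  boosters <- list()
  searches <- list()
  for (b in blocks) {
    feats <- assemble_features(train, block = b, embed_seed = embed_seed,
                               embeddings = embeddings)
    search <- random_search_cv(feats$X, feats$y, train$cv_fold,
                               space = space, n_trials = budgets[[b]],
                               seed = derive_seed(seed, b))
    boosters[[b]] <- train_gbm(feats$X, feats$y, search$best_hp,
                               seed = derive_seed(seed, paste0(b, "_final")))
    searches[[b]] <- search
  }

  structure(list(
    boosters = boosters,
    searches = searches,
    ensemble_rule = "mean_of_two",
    embed_seed = embed_seed,
    embeddings = embeddings,
    seed = seed,
    train_reference = train[, intersect(
      c("enzyme_id", "sequence", "reaction_smiles", "reaction_key", "y"),
      names(train))]
  ), class = "kcat_model")
}

#' @export
print.kcat_model <- function(x, ...) {
  cat("<kcat_model> ensemble rule:", x$ensemble_rule, "\n")
  for (b in names(x$boosters)) {
    cat(sprintf("  %-10s best CV R^2 = %.3f\n", b, x$searches[[b]]$best_cv_r2))
  }
  invisible(x)
}

#' Predict log10 kcat for curated records
#'
#' Applies the requested rule: `"mean_of_two"` averages the reaction-only
#' and enzyme-only predictions on the log10 scale; the `*_only` rules pass
#' through a single component model.
#'
#' @param object A `kcat_model`.
#' @param newdata Curated tibble with `reaction_smiles` and `sequence`.
#' @param rule Ensemble rule (default the model's own).
#' @param ... Unused.
#' @return Numeric vector of predicted log10 kcat values.
#' @export
predict.kcat_model <- function(object, newdata,
                               rule = c("default", "mean_of_two",
                                        "joint_only", "reaction_only",
                                        "enzyme_only"), ...) {
  rule <- match.arg(rule)
  if (rule == "default") rule <- object$ensemble_rule
  predict_block <- function(b) {
    if (is.null(object$boosters[[b]])) {
      abort(paste0("ensemble rule needs the '", b,
                   "' booster, which was not fitted"))
    }
    nd <- newdata
    if (is.null(nd$y)) nd$y <- NA_real_
    feats <- assemble_features(nd, block = b,
                               embed_seed = object$embed_seed,
                               embeddings = object$embeddings)
    predict(object$boosters[[b]],
            xgboost::xgb.DMatrix(feats$X, nthread = 1))
  }
  switch(rule,
    mean_of_two = (predict_block("drfp") + predict_block("embedding")) / 2,
    joint_only = predict_block("joint"),
    reaction_only = predict_block("drfp"),
    enzyme_only = predict_block("embedding")
  )
}

#' Global-mean baseline
#'
#' Predicts the training-set mean log10 kcat for every query.
#'
#' @param train_y Training target values (log10 s^-1).
#' @return A function taking a row count and returning constant predictions.
#' @export
baseline_global_mean <- function(train_y) {
  m <- mean(train_y)
  function(n) rep(m, n)
}

#' Homolog-mean baseline
#'
#' Ranks training enzymes by global sequence identity to the query and
#' predicts the mean of the per-sequence mean log10 kcat values of the `k`
#' most similar training enzymes (the log of their geometric-mean kcat).
#' Ties at rank `k` are broken by lexicographic sequence order.
#'
#' @param query_seq Query amino-acid sequence.
#' @param train_records Training tibble with `sequence` and `y`.
#' @param k Number of neighbours (default 3).
#' @return Predicted log10 kcat.
#' @export
baseline_homolog_mean <- function(query_seq, train_records, k = 3L) {
  per_seq <- tapply(train_records$y, train_records$sequence, mean)
  seqs <- names(per_seq)
  if (length(seqs) < k) {
    abort(sprintf("need at least %d distinct training sequences", k))
  }
  ids <- vapply(seqs, function(s) global_identity(query_seq, s), numeric(1))
  ord <- order(-ids, seqs)
  mean(per_seq[ord[seq_len(k)]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted kcat model
#'
#' One row per component model with its selected hyperparameters and mean
#' CV R^2.
#'
#' @param x A `kcat_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kcat_model
#' @export
tidy.kcat_model <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$searches), function(b) {
    hp <- x$searches[[b]]$best_hp
    hp$block <- b
    hp$cv_r2 <- x$searches[[b]]$best_cv_r2
    hp
  }))[, c("block", "learning_rate", "reg_alpha", "reg_lambda", "max_depth",
          "max_delta_step", "n_rounds", "min_child_weight", "cv_r2")]
}

#' Glance at a fitted kcat model
#'
#' @param x A `kcat_model`.
#' @param ... Unused.
#' @return One-row tibble with the ensemble rule, component count, and the
#'   best component CV R^2 values.
#' @method glance kcat_model
#' @export
glance.kcat_model <- function(x, ...) {
  tibble(
    ensemble_rule = x$ensemble_rule,
    n_components = length(x$boosters),
    cv_r2_reaction = x$searches$drfp$best_cv_r2 %||% NA_real_,
    cv_r2_enzyme = x$searches$embedding$best_cv_r2 %||% NA_real_,
    n_train = nrow(x$train_reference)
  )
}
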