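small_train <- function(n = 60, seed = 9) {
  set.seed(seed)
  X <- matrix(rbinom(n * 30, 1, 0.5), n)
  y <- 2 * X[, 1] - 1.5 * X[, 2] + rnorm(n, sd = 0.05)
  list(X = X, y = y)
}

default_hp <- function(n_rounds = 200) {
  list(learning_rate = 0.1, reg_alpha = 0.01, reg_lambda = 1,
       max_depth = 5L, max_delta_step = 0, n_rounds = n_rounds,
       min_child_weight = 1)
}

test_that("feature blocks have the declared widths", {
  cur <- tibble::tibble(
    enzyme_id = c("a", "b"),
    sequence = c(strrep("MKV", 30), strrep("ACD", 30)),
    reaction_smiles = c("CCO>>CC=O", "CCCO>>CCC=O"),
    y = c(1, 2))
  expect_equal(ncol(assemble_features(cur, "drfp")$X), 2048)
  expect_equal(ncol(assemble_features(cur, "embedding")$X), 1280)
  expect_equal(ncol(assemble_features(cur, "joint")$X), 3328)

  # id alignment survives row shuffles
  f1 <- assemble_features(cur, "joint")
  f2 <- assemble_features(cur[2:1, ], "joint")
  expect_equal(f1$X[1, ], f2$X[2, ])
  expect_equal(f1$y, rev(f2$y))
})

test_that("gbm fits a perfectly determined target and is deterministic", {
  d <- small_train()
  b <- train_gbm(d$X, d$y, default_hp(), seed = 1)
  pred <- predict(b, xgboost::xgb.DMatrix(d$X, nthread = 1))
  expect_gt(1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2), 0.99)

  b2 <- train_gbm(d$X, d$y, default_hp(), seed = 1)
  pred2 <- predict(b2, xgboost::xgb.DMatrix(d$X, nthread = 1))
  expect_identical(pred, pred2)

  const <- train_gbm(d$X, rep(1.3, nrow(d$X)), default_hp(50), seed = 1)
  cp <- predict(const, xgboost::xgb.DMatrix(d$X, nthread = 1))
  expect_true(all(abs(cp - 1.3) < 1e-6))

  expect_error(train_gbm(d$X[1:5, ], d$y[1:5], default_hp()), "20")
  expect_error(train_gbm(d$X, c(d$y[-1], NA), default_hp()), "non-finite")
})

test_that("random search returns the argmax trial and is reproducible", {
  d <- small_train(n = 80)
  folds <- rep(0:4, each = 16)
  s1 <- random_search_cv(d$X, d$y, folds, n_trials = 5, seed = 3)
  expect_equal(nrow(s1$trials), 5)
  expect_equal(s1$best_cv_r2, max(s1$trials$cv_r2))
  s2 <- random_search_cv(d$X, d$y, folds, n_trials = 5, seed = 3)
  expect_identical(s1$trials, s2$trials)

  one <- random_search_cv(d$X, d$y, folds, n_trials = 1, seed = 4)
  expect_equal(one$best_hp$trial, 1)
  expect_error(random_search_cv(d$X, d$y, folds, n_trials = 0), "at least 1")
})

test_that("hyperparameter draws stay inside the declared space", {
  space <- default_search_space()
  hp <- kcatboost:::sample_hyperparams(space, 200, 12)
  expect_true(all(hp$learning_rate >= 0.01 & hp$learning_rate <= 0.5))
  expect_true(all(hp$reg_alpha >= 1e-5 & hp$reg_alpha <= 10))
  expect_true(all(hp$max_depth %in% 2:12))
  expect_true(all(hp$n_rounds >= 50 & hp$n_rounds <= 1500))
  expect_true(all(hp$min_child_weight >= 1 & hp$min_child_weight <= 20))
  expect_true(all(hp$max_delta_step >= 0 & hp$max_delta_step <= 5))
})

test_that("the ensemble prediction is the mean of its two components", {
  cur <- curated_fixture()
  set.seed(31)
  sub <- cur[sample(nrow(cur), 150), ]
  sub <- suppressWarnings(assign_cv_folds(sub, k = 5, seed = 2))
  model <- fit_kcat_model(sub, n_trials = 4, seed = 2)
  newdata <- cur[sample(nrow(cur), 40), ]
  pr <- predict(model, newdata, rule = "reaction_only")
  pe <- predict(model, newdata, rule = "enzyme_only")
  pm <- predict(model, newdata, rule = "mean_of_two")
  expect_equal(pm, (pr + pe) / 2)
  expect_true(all(pm >= pmin(pr, pe) - 1e-9 & pm <= pmax(pr, pe) + 1e-9))
  expect_error(predict(model, newdata, rule = "joint_only"), "joint")

  td <- tidy(model)
  expect_equal(td$block, c("drfp", "embedding"))
  expect_equal(nrow(glance(model)), 1)
})

test_that("model bundles round-trip through disk", {
  cur <- curated_fixture()
  set.seed(33)
  sub <- suppressWarnings(assign_cv_folds(cur[sample(nrow(cur), 120), ],
                                          k = 5, seed = 2))
  model <- fit_kcat_model(sub, n_trials = 2, seed = 5)
  dir <- tempfile()
  save_kcat_model(model, dir)
  model2 <- load_kcat_model(dir)
  newdata <- cur[1:20, ]
  expect_equal(predict(model, newdata), predict(model2, newdata),
               tolerance = 1e-6)
})

test_that("baselines behave per their definitions", {
  f <- baseline_global_mean(c(0, 1, 2))
  expect_equal(f(4), rep(1, 4))

  train <- tibble::tibble(
    sequence = c("MKTAYIAKQR", "MKTAYIAKQA", "CCCCCCCCCC", "DDDDDDDDDD"),
    y = c(0, 1, 2, 3))
  # k = 3 neighbours of an exact-match query
  expect_equal(baseline_homolog_mean("MKTAYIAKQR", train, k = 1), 0)
  got <- baseline_homolog_mean("MKTAYIAKQR", train, k = 2)
  expect_equal(got, mean(c(0, 1)))
  expect_error(baseline_homolog_mean("MKTA", train[1:2, ], k = 3),
               "at least 3")

  # three neighbours with per-sequence means {0,1,2} average to 1
  expect_equal(baseline_homolog_mean("MKTAYIAKQR", train[1:3, ], k = 3), 1)
})
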