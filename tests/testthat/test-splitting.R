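test_that("global identity matches the brute-force aligner", {
  expect_equal(global_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  expect_equal(global_identity("AAAA", "CCCC"), 0)
  expect_equal(global_identity("MKTAYIAKQR", "MKTAYIAKQA"), 90)

  set.seed(11)
  aas <- c("A", "C", "D", "E", "G", "K", "L", "R", "S", "T")
  for (i in 1:8) {
    a <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:12, 1), replace = TRUE), collapse = "")
    expect_equal(global_identity(a, b), oracle_nw_identity(a, b),
                 tolerance = 1e-8)
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
})

test_that("max identity to train handles exact matches and empty sets", {
  expect_equal(max_identity_to_train("MKTA", c("XXXX", "MKTA")), 100)
  expect_error(max_identity_to_train("MKTA", character(0)), "empty")
  got <- max_identity_to_train("MKTAYIAKQR",
                               c("MKTAYIAKQA", "CCCCCCCCCC"))
  expect_equal(got, 90)
})

test_that("identity buckets follow the quoted half-open edges", {
  expect_equal(as.character(identity_bucket(c(0, 39.99, 40, 79.9, 80,
                                              98.9, 99, 100))),
               c("I0_40", "I0_40", "I40_80", "I40_80", "I80_99",
                 "I80_99", "I99_100", "I99_100"))
})

test_that("train/test split never separates records of one sequence", {
  set.seed(20)
  for (s in 1:100) {
    n_seq <- sample(10:30, 1)
    seqs <- replicate(n_seq, paste(sample(LETTERS[1:20],
                                          sample(5:15, 1),
                                          replace = TRUE), collapse = ""))
    tbl <- tibble::tibble(
      record_id = sprintf("r%03d", 1:60),
      sequence = sample(seqs, 60, replace = TRUE))
    split_tbl <- suppressWarnings(split_train_test(tbl, seed = s))
    sides <- tapply(split_tbl$split, split_tbl$sequence,
                    function(x) length(unique(x)))
    expect_true(all(sides == 1))

    train <- split_tbl[split_tbl$split == "train", ]
    train <- suppressWarnings(assign_cv_folds(train, k = 5, seed = s))
    folds <- tapply(train$cv_fold, train$sequence,
                    function(x) length(unique(x)))
    expect_true(all(folds == 1))
  }
})

test_that("split respects the target fraction and is seed-reproducible", {
  tbl <- tibble::tibble(
    record_id = sprintf("r%03d", 1:100),
    sequence = rep(sprintf("S%02d", 1:10), each = 10))
  s1 <- split_train_test(tbl, test_fraction = 0.2, seed = 5)
  s2 <- split_train_test(tbl, test_fraction = 0.2, seed = 5)
  expect_identical(s1$split, s2$split)
  expect_equal(sum(s1$split == "test"), 20)

  # a group larger than the whole test target is forced to train
  big <- tibble::tibble(record_id = sprintf("r%03d", 1:100),
                        sequence = c(rep("BIG", 90),
                                     sprintf("S%02d", 1:10)))
  warns <- capture_warnings(
    sb <- split_train_test(big, test_fraction = 0.2, seed = 1))
  expect_true(any(grepl("forced to train", warns)))
  expect_true(all(sb$split[sb$sequence == "BIG"] == "train"))
})

test_that("cv folds are greedily balanced", {
  tbl <- tibble::tibble(record_id = sprintf("r%02d", 1:25),
                        sequence = rep(sprintf("S%d", 1:5), each = 5))
  f <- assign_cv_folds(tbl, k = 5, seed = 2)
  expect_equal(sort(unique(f$cv_fold)), 0:4)
  expect_true(all(table(f$cv_fold) == 5))

  # unit-size groups: fold sizes within one of each other
  tbl2 <- tibble::tibble(record_id = sprintf("r%02d", 1:23),
                         sequence = sprintf("S%02d", 1:23))
  f2 <- assign_cv_folds(tbl2, k = 5, seed = 3)
  sizes <- table(f2$cv_fold)
  expect_lte(max(sizes) - min(sizes), 1)

  # degenerate: one sequence only occupies one fold
  tbl3 <- tibble::tibble(record_id = sprintf("r%02d", 1:10),
                         sequence = "ONLY")
  expect_warning(f3 <- assign_cv_folds(tbl3, k = 5, seed = 4))
  expect_equal(length(unique(f3$cv_fold)), 1)
})

test_that("reaction strata flag seen reactions and bucket similarities", {
  train <- tibble::tibble(
    reaction_smiles = c("CCO>>CC=O", "CCCO>>CCC=O"),
    sequence = c("AAA", "CCC"))
  train <- add_reaction_keys(train)
  test <- tibble::tibble(
    reaction_smiles = c("CCO>>CC=O", "OCC1OC(O)C(O)C(O)C1O>>OCC1(O)OC(CO)C(O)C1O"),
    sequence = c("DDD", "EEE"))
  test <- add_reaction_keys(test)
  strata <- reaction_strata(test, train)
  expect_true(strata$reaction_seen[1])
  expect_false(strata$reaction_seen[2])
  expect_equal(strata$max_reaction_similarity[1], 1)
  expect_true(all(strata$max_reaction_similarity >= 0 &
                    strata$max_reaction_similarity <= 1))
  expect_error(reaction_strata(test, train[0, ]), "no training reactions")
})
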