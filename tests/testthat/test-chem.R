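test_that("reaction parsing yields canonical, order-invariant keys", {
  r <- parse_reaction("CCO>>CC=O")
  expect_length(r$substrates, 1)
  expect_length(r$products, 1)

  a <- parse_reaction("CCO.O>>CC=O.[H][H]")
  b <- parse_reaction("O.CCO>>[H][H].CC=O")
  expect_identical(a$key, b$key)

  expect_error(parse_reaction("notasmiles>>C"), class = "kcat_parse_error")
  expect_error(parse_reaction("CCO>>"), class = "kcat_parse_error")
})

test_that("fingerprint dimensions match their contracts", {
  r <- parse_reaction("CCO.O=C1C=CC(=O)C=C1>>CC=O.Oc1ccc(O)cc1")
  expect_length(molecule_fingerprint("CCO"), 1638)
  expect_length(reaction_fingerprint(r, "structural"), 3276)
  expect_length(reaction_fingerprint(r, "difference"), 2048)
  expect_length(reaction_fingerprint(r, "drfp"), 2048)
  expect_true(all(reaction_fingerprint(r, "structural") %in% 0:1))
  expect_true(all(reaction_fingerprint(r, "drfp") %in% 0:1))
})

test_that("molecule fingerprint is deterministic and richer for larger molecules", {
  f1 <- molecule_fingerprint("C")
  f2 <- molecule_fingerprint("C")
  expect_identical(f1, f2)
  atp <- "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O"
  expect_gte(sum(molecule_fingerprint(atp)), sum(f1))
})

test_that("identity reactions give zero difference/drfp and mirrored structural halves", {
  xx <- parse_reaction("OCC1OC(O)C(O)C(O)C1O>>OCC1OC(O)C(O)C(O)C1O")
  expect_true(all(reaction_fingerprint(xx, "difference") == 0L))
  expect_true(all(reaction_fingerprint(xx, "drfp") == 0L))
  s <- reaction_fingerprint(xx, "structural")
  expect_identical(s[1:1638], s[1639:3276])
})

test_that("difference fingerprint is antisymmetric, drfp symmetric, under reversal", {
  fwd <- parse_reaction("CC(=O)OCC.O>>CC(=O)O.CCO")
  rev <- parse_reaction("CC(=O)O.CCO>>CC(=O)OCC.O")
  expect_identical(as.integer(reaction_fingerprint(fwd, "difference")),
                   -as.integer(reaction_fingerprint(rev, "difference")))
  expect_identical(as.integer(reaction_fingerprint(fwd, "drfp")),
                   as.integer(reaction_fingerprint(rev, "drfp")))
  sf <- reaction_fingerprint(fwd, "structural")
  sr <- reaction_fingerprint(rev, "structural")
  expect_identical(sf[1:1638], sr[1639:3276])
  expect_identical(sf[1639:3276], sr[1:1638])
})

test_that("all fingerprints are invariant to reactant order within a side", {
  subs <- c("CCO", "O=C1C=CC(=O)C=C1", "O")
  prods <- c("CC=O", "Oc1ccc(O)cc1", "O")
  base <- parse_reaction(paste0(paste(subs, collapse = "."), ">>",
                                paste(prods, collapse = ".")))
  ref <- lapply(c("structural", "difference", "drfp"), function(k) {
    reaction_fingerprint(base, k)
  })
  set.seed(42)
  for (i in 1:100) {
    r <- parse_reaction(paste0(
      paste(sample(subs), collapse = "."), ">>",
      paste(sample(prods), collapse = ".")))
    for (k in seq_along(ref)) {
      expect_identical(
        as.integer(reaction_fingerprint(
          r, c("structural", "difference", "drfp")[k])),
        as.integer(ref[[k]]))
    }
  }
})

test_that("difference fingerprint separates ethanol oxidation", {
  expect_gt(sum(reaction_fingerprint("CCO>>CC=O", "difference") != 0), 0)
})

test_that("shared substructures contribute no drfp bits", {
  # methane's only environment token also occurs inside both sides
  with_c <- reaction_fingerprint("CCO.C>>CC=O.C", "drfp")
  without <- reaction_fingerprint("CCO>>CC=O", "drfp")
  expect_identical(as.integer(with_c), as.integer(without))
})

test_that("reaction similarity matches a brute-force Jaccard oracle", {
  a <- integer(64); a[c(2, 3, 4)] <- 1L
  b <- integer(64); b[c(3, 4, 5)] <- 1L
  expect_equal(reaction_similarity(a, b), 0.5)
  expect_equal(reaction_similarity(a, a), 1)
  d <- integer(64); d[10:12] <- 1L
  expect_equal(reaction_similarity(a, d), 0)
  expect_error(reaction_similarity(a, integer(32)), "mismatch")
  expect_warning(sim0 <- reaction_similarity(integer(8), integer(8)))
  expect_equal(sim0, 1)

  set.seed(7)
  for (i in 1:100) {
    x <- rbinom(128, 1, 0.2)
    y <- rbinom(128, 1, 0.2)
    if (sum(x | y) == 0) next
    expect_equal(reaction_similarity(x, y), oracle_jaccard(x, y))
    expect_equal(reaction_similarity(x, y), reaction_similarity(y, x))
  }
})

test_that("similarity normalisation is a monotone min-max rescaling", {
  expect_equal(normalize_similarities(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  expect_equal(suppressMessages(normalize_similarities(0.4)), 1)
  expect_equal(normalize_similarities(c(0, 0.25, 1)), c(0, 0.25, 1))
  set.seed(1)
  x <- runif(50)
  nx <- normalize_similarities(x)
  expect_identical(order(x), order(nx))
  expect_true(all(nx >= 0 & nx <= 1))
})

test_that("mass balance agrees with formula-weight arithmetic", {
  glucose <- "OCC1OC(O)C(O)C(O)C1O"
  fructose <- "OCC1(O)OC(CO)C(O)C1O"
  expect_true(mass_balance_ok(paste0(glucose, ">>", glucose)))
  expect_true(mass_balance_ok(paste0(glucose, ">>", fructose)))
  expect_false(mass_balance_ok(paste0(glucose, ">>O")))
  # oracle cross-check of the underlying weights
  expect_equal(parse_molecule(glucose)$mol_weight,
               oracle_formula_weight("C6H12O6"), tolerance = 1e-3)
  expect_equal(parse_molecule("O")$mol_weight,
               oracle_formula_weight("H2O"), tolerance = 1e-3)
})

test_that("InChI input maps to the same molecule as SMILES", {
  m1 <- parse_molecule("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
  m2 <- parse_molecule("CCO")
  expect_identical(m1$cansmi, m2$cansmi)
})
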