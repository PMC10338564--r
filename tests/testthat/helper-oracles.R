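# Independent brute-force oracles used to freeze expected values.

# Affine-gap Needleman-Wunsch (Gotoh) with BLOSUM62, gap open 10 /
# extend 0.5; returns matches and alignment length from the traceback.
# Intended for short sequences only.
oracle_nw_identity <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0L; alen <- 0L
  while (i > 1 || j > 1) {
    alen <- alen + 1L
    if (state == 1 && i > 1 && j > 1) {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
      s <- S[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 || j == 1) {
      cand <- c(M[i - 1, j] - 10 - 0.5, X[i - 1, j] - 0.5)
      state <- if (i == 2 && j == 1) 1 else c(1, 2)[which.max(cand)]
      i <- i - 1
    } else {
      cand <- c(M[i, j - 1] - 10 - 0.5, Y[i, j - 1] - 0.5)
      state <- if (j == 2 && i == 1) 1 else c(1, 3)[which.max(cand)]
      j <- j - 1
    }
  }
  100 * matches / alen
}

# Exact signed-rank p-value by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs),
                                    mean(v_all <= v_obs))))
}

# Exact rank-sum p-value by enumerating all choose(n_a + n_b, n_a)
# labelings; statistic is the Mann-Whitney U of sample a.
oracle_rank_sum_p <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- utils::combn(length(pooled), n_a)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n_a * (n_a + 1) / 2)
  switch(alternative,
         greater = mean(u_all >= u_obs),
         less = mean(u_all <= u_obs),
         two.sided = min(1, 2 * min(mean(u_all >= u_obs),
                                    mean(u_all <= u_obs))))
}

# Jaccard similarity of two binary vectors via explicit index sets.
oracle_jaccard <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- union(ia, ib)
  if (length(u) == 0) return(1)
  length(intersect(ia, ib)) / length(u)
}

# Molecular weight from a molecular formula string (e.g. "C6H12O6").
oracle_formula_weight <- function(formula) {
  masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
              S = 32.06)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    k <- gsub("[^0-9]", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    total <- total + masses[[el]] * k
  }
  total
}

# Shared synthetic fixture (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

synth_fixture <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(synthetic_config(seed = 1L))
  }
  .fixture_env$ds
}

curated_fixture <- function() {
  if (is.null(.fixture_env$cur)) {
    .fixture_env$cur <- run_curation(synth_fixture()$records)
  }
  .fixture_env$cur
}
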