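## Evaluation: regression metrics on the log10 scale, stratified reports,
## and the rank-based statistical comparisons between models.

#' Regression metrics on log10 kcat
#'
#' The coefficient of determination R^2 = 1 - SSres/SStot (not the squared
#' correlation), the mean squared error, the Pearson correlation, the mean
#' absolute deviation on the log10 scale, and its back-transformed fold
#' deviation 10^MAD.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2, finite.
#' @return One-row tibble with `n`, `r2`, `mse`, `pearson_r`,
#'   `mean_abs_dev_log10`, `fold_deviation`.
#' @export
eval_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (length(y_true) < 2L) abort("need at least two observations")
  if (anyNA(c(y_true, y_pred)) || any(!is.finite(c(y_true, y_pred)))) {
    abort("non-finite values in inputs")
  }
  if (stats::var(y_true) <= 0) {
    abort("zero variance in y_true; R^2 undefined")
  }
  pearson <- if (stats::var(y_pred) <= 0) {
    NA_real_
  } else {
    stats::cor(y_true, y_pred)
  }
  mad_log10 <- mean(abs(y_true - y_pred))
  tibble(
    n = length(y_true),
    r2 = r_squared(y_true, y_pred),
    mse = mean((y_true - y_pred)^2),
    pearson_r = pearson,
    mean_abs_dev_log10 = mad_log10,
    fold_deviation = 10^mad_log10
  )
}

#' Stratified evaluation report
#'
#' Computes the overall metrics plus per-stratum metrics by identity bucket
#' and by reaction stratum. Strata with fewer than two records are omitted
#' with a note. The per-stratum `n` values partition the total.
#'
#' @param test_annotated Output of [annotate_test_strata()] with a `y`
#'   column.
#' @param y_pred Predicted log10 kcat values, aligned with the rows.
#' @return A list of class `kcat_eval` with elements `overall`,
#'   `by_identity`, `by_reaction`, each a tibble of metrics.
#' @export
stratified_report <- function(test_annotated, y_pred) {
  stopifnot(nrow(test_annotated) == length(y_pred))
  strat <- function(labels) {
    labels <- as.character(labels)
    out <- list()
    for (lv in unique(labels)) {
      idx <- labels == lv
      if (sum(idx) < 2L) {
        inform(sprintf("stratum '%s' has %d record(s); omitted", lv,
                       sum(idx)))
        next
      }
      if (stats::var(test_annotated$y[idx]) <= 0) {
        inform(sprintf("stratum '%s' has zero target variance; omitted", lv))
        next
      }
      m <- eval_metrics(test_annotated$y[idx], y_pred[idx])
      m$stratum <- lv
      out[[length(out) + 1L]] <- m
    }
    if (length(out) == 0L) return(tibble())
    dplyr::bind_rows(out)[, c("stratum", "n", "r2", "mse", "pearson_r",
                              "mean_abs_dev_log10", "fold_deviation")]
  }
  structure(list(
    overall = eval_metrics(test_annotated$y, y_pred),
    by_identity = strat(test_annotated$identity_bucket_),
    by_reaction = strat(ifelse(test_annotated$reaction_seen, "seen",
                               as.character(test_annotated$reaction_bucket)))
  ), class = "kcat_eval")
}

#' @export
print.kcat_eval <- function(x, ...) {
  cat("<kcat_eval>\noverall:\n")
  print(as.data.frame(x$overall), row.names = FALSE)
  cat("by identity bucket:\n")
  print(as.data.frame(x$by_identity), row.names = FALSE)
  cat("by reaction stratum:\n")
  print(as.data.frame(x$by_reaction), row.names = FALSE)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `kcat_eval`.
#' @param ... Unused.
#' @return Tibble of all strata (including `overall`).
#' @method tidy kcat_eval
#' @export
tidy.kcat_eval <- function(x, ...) {
  overall <- x$overall
  overall$stratum <- "overall"
  dplyr::bind_rows(
    overall[, c("stratum", names(overall)[names(overall) != "stratum"])],
    dplyr::mutate(x$by_identity, facet = "identity"),
    dplyr::mutate(x$by_reaction, facet = "reaction")
  )
}

#' Glance at an evaluation report
#'
#' @param x A `kcat_eval`.
#' @param ... Unused.
#' @return The one-row overall metrics tibble.
#' @method glance kcat_eval
#' @export
glance.kcat_eval <- function(x, ...) x$overall

#' One-sided Wilcoxon signed-rank test on paired absolute errors
#'
#' Paired comparison of two models' absolute errors. Zero differences are
#' dropped and ties receive mid-ranks. For up to 25 non-zero pairs the
#' p-value comes from the exact permutation distribution of the positive
#' rank sum (computed by convolution, so ties are handled exactly); beyond
#' that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param abs_err_a,abs_err_b Paired absolute-error vectors (length >= 5).
#' @param alternative `"less"` (errors of a smaller than b), `"greater"`, or
#'   `"two.sided"`.
#' @return The p-value.
#' @export
wilcoxon_signed_rank <- function(abs_err_a, abs_err_b,
                                 alternative = c("less", "greater",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(abs_err_a) == length(abs_err_b))
  if (length(abs_err_a) < 5L) abort("need at least 5 pairs")
  d <- abs_err_a - abs_err_b
  d <- d[d != 0]
  if (length(d) == 0L) abort("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])

  if (n <= 25L) {
    # exact distribution of V = sum of positive mid-ranks over all 2^n
    # sign assignments, by polynomial convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    width <- sum(r2) + 1L
    f <- numeric(width)
    f[1] <- 1
    for (ri in r2) {
      g <- f / 2
      g[(ri + 1L):width] <- g[(ri + 1L):width] + f[1:(width - ri)] / 2
      f <- g
    }
    v2 <- round(2 * v_obs)
    p_ge <- sum(f[(v2 + 1L):width])
    p_le <- sum(f[1:(v2 + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    p_ge <- stats::pnorm((v_obs - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((v_obs + 0.5 - mu) / sigma)
  }
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' One-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Independent-sample comparison of two error distributions.
#'
#' @param errors_a,errors_b Numeric samples.
#' @param alternative `"less"`, `"greater"`, or `"two.sided"`.
#' @return The p-value.
#' @export
mann_whitney <- function(errors_a, errors_b,
                         alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  exact <- length(errors_a) <= 25L && length(errors_b) <= 25L &&
    !any(duplicated(c(errors_a, errors_b)))
  res <- suppressWarnings(stats::wilcox.test(
    errors_a, errors_b, alternative = alternative, exact = exact,
    correct = TRUE))
  unname(res$p.value)
}

#' One-sided binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p0); used to test whether one model
#' improves on another in more head-to-head comparisons than chance.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @return The upper-tail p-value.
#' @export
binomial_one_sided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}
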