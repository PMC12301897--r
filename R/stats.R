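new_perm_result <- function(observed, null_stats, p, seed, sided) {
  structure(list(observed_stat = observed,
                 n_permutations = length(null_stats),
                 p_value = p,
                 null_quantiles = stats::quantile(null_stats,
                                                  c(0.025, 0.5, 0.975),
                                                  names = FALSE),
                 sided = sided, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s): observed %.4g, p = %.3g (%d samples)\n",
    x$sided, x$observed_stat, x$p_value, x$n_permutations))
  cat(sprintf("  null 2.5%%/50%%/97.5%%: %.4g / %.4g / %.4g\n",
              x$null_quantiles[1], x$null_quantiles[2], x$null_quantiles[3]))
  invisible(x)
}

#' Permutation test for a difference in means
#'
#' Statistic `mean(A) - mean(B)`; the null is built by shuffling pooled group
#' membership with group sizes preserved. Two-sided p-value with add-one
#' smoothing, `p = (1 + #{|t*| >= |t|}) / (n + 1)`, so the smallest
#' attainable p is `1 / (n + 1)`.
#'
#' @param a,b numeric vectors (non-empty).
#' @param n number of permutations (default 100000).
#' @param seed integer RNG seed.
#' @return object of class `perm_result`.
#' @export
perm_test_mean_diff <- function(a, b, n = 100000L, seed = 1L) {
  stopifnot(length(a) > 0, length(b) > 0, n >= 1)
  observed <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a); nt <- length(pooled)
  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(nt, na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 0)
  })
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (n + 1)
  new_perm_result(observed, null_stats, p, seed, "two-sided")
}

#' Permutation test for biomarker balanced accuracy
#'
#' Tests whether classification of pathology by a *fixed* threshold pair
#' beats random label assignment: the labels are permuted, the pair is held
#' fixed, and the balanced accuracy recomputed. One-sided (greater), with
#' add-one smoothing.
#'
#' @param gaps numeric vector of corrected gaps.
#' @param labels logical pathology labels.
#' @param pair threshold pair from [optimize_thresholds()] (fit upstream,
#'   e.g. during cross-validation).
#' @param n number of permutations (default 100000).
#' @param seed integer RNG seed.
#' @return object of class `perm_result`.
#' @export
perm_test_bacc <- function(gaps, labels, pair, n = 100000L, seed = 1L) {
  stopifnot(length(gaps) == length(labels), n >= 1)
  if (!any(labels) || all(labels))
    stop("class error: both classes must be present", call. = FALSE)
  pred <- classify_gaps(pair, gaps)
  observed <- bacc_labels(labels, pred)
  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n), function(i)
      bacc_labels(sample(labels), pred), 0)
  })
  p <- (1 + sum(null_stats >= observed)) / (n + 1)
  new_perm_result(observed, null_stats, p, seed, "greater")
}

#' Paired t-test on brain age versus chronological age
#'
#' Classical two-sided paired t-test on `x - y`.
#'
#' @param x,y equal-length numeric vectors (>= 2 pairs).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("paired t undefined: zero variance of differences", call. = FALSE)
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Kolmogorov-Smirnov two-sample test
#'
#' Two-sided test of distribution equality. The exact null distribution is
#' used where feasible (small tie-free samples; the asymptotic
#' approximation is markedly conservative there), the asymptotic one
#' otherwise. Ties are tolerated.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p`.
#' @export
ks_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided rank-sum test of stochastic dominance (normal approximation
#' with continuity correction; ties tolerated).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic` (U for the first sample), `p`.
#' @export
wmw_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Brunner-Munzel two-sample test
#'
#' Tests `P(A < B) + 0.5 P(A = B) = 1/2` (stochastic equality) without
#' assuming equal variances, using the rank-based studentized statistic with
#' Satterthwaite-style degrees of freedom. Two-sided. Small samples
#' (< 10 per group) trigger a warning, as the t-approximation is then rough.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p`, `p_hat` (the estimated
#'   `P(A < B) + 0.5 P(A = B)`).
#' @export
brunner_munzel <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  if (n1 < 10 || n2 < 10)
    warning("Brunner-Munzel with fewer than 10 per group: ",
            "t-approximation may be inaccurate")
  nt <- n1 + n2
  r <- rank(c(a, b))
  r1 <- r[seq_len(n1)]; r2 <- r[-seq_len(n1)]
  m1 <- mean(r1); m2 <- mean(r2)
  # within-group ranks remove the internal ordering contribution
  v1 <- sum((r1 - rank(a) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(b) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (v1 == 0 && v2 == 0)
    stop("Brunner-Munzel undefined: no rank variability", call. = FALSE)
  statistic <- n1 * n2 * (m2 - m1) / (nt * sqrt(n1 * v1 + n2 * v2))
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(statistic), df)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  list(statistic = statistic, df = df, p = p, p_hat = p_hat)
}
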