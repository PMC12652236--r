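#' Permutation test on the distance between two group means
#'
#' Core resampling engine: the observed statistic is the absolute distance
#' between the means of groups `a` and `b`. Under the null the group labels
#' are exchangeable, so each permutation draws `length(a)` trials from the
#' pooled values without replacement, assigns the rest to the other group
#' and recomputes the distance. The p-value carries the add-one correction
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p is never 0 and the
#' strongest attainable level with 10,000 permutations is just under 1e-4.
#'
#' @param a,b Numeric score vectors.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A `permutation_result`: `observed` (signed mean difference),
#'   `statistic` (absolute), `p_value`, `permuted_mean`, `permuted_sd`,
#'   `n_permutations`, `n_a`, `n_b`, `seed`.
#' @export
perm_mean_diff_test <- function(a, b, n_perm = 10000L, seed = 1L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  if (n < 2) stop("pooled group has fewer than 2 values")
  observed <- mean(a) - mean(b)
  s_tot <- sum(pool)
  set.seed(seed)
  null_dist <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    sa <- sum(pool[idx])
    abs(sa / na - (s_tot - sa) / (n - na))
  }, numeric(1))
  res <- list(observed = observed, statistic = abs(observed),
              p_value = (1 + sum(null_dist >= abs(observed))) / (1 + n_perm),
              permuted_mean = mean(null_dist),
              permuted_sd = stats::sd(null_dist),
              n_permutations = n_perm, n_a = na, n_b = n - na, seed = seed)
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> |mean diff| = %.4g, p = %.4g (%d perms, n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_permutations, x$n_a, x$n_b))
  invisible(x)
}

#' Within-session trial-shuffle test
#'
#' Tests whether a trial group's mean PC1 score differs from the standard
#' trials by shuffling trial identities (10,000 permutations by default).
#' The standard pool always excludes the first ten trials of the session;
#' the test group is removed from the pool as well. Supported groups:
#' `deviant` (20 trials in the default paradigm), `first10` (10 trials),
#' `one_after`, `first_view` (standard-condition first-view trials), and
#' `left_vs_right`, which contrasts standard trials seen from left
#' (`theta < -15` degrees) versus right (`theta > 15`) head angles.
#'
#' @param scores A `score_table` (gaze columns required for the angle
#'   groups).
#' @param test_group One of `"deviant"`, `"first10"`, `"one_after"`,
#'   `"first_view"`, `"left_vs_right"`.
#' @param n_perm,seed Permutation parameters.
#' @return A `permutation_result` (with `test_group` attached).
#' @export
session_permutation_test <- function(scores,
                                     test_group = c("deviant", "first10",
                                                    "one_after", "first_view",
                                                    "left_vs_right"),
                                     n_perm = 10000L, seed = 1L) {
  test_group <- match.arg(test_group)
  masks <- group_masks(scores)
  if (test_group == "left_vs_right") {
    a <- scores$score[masks$left]
    b <- scores$score[masks$right]
    if (!length(a) || !length(b))
      stop("empty left or right angle group")
  } else {
    sel <- masks[[test_group]]
    if (!any(sel)) stop("empty test group: ", test_group)
    a <- scores$score[sel]
    b <- scores$score[masks$standard & !sel]
    if (length(b) <= length(a))
      stop("standard pool (excluding the first 10 trials) must exceed the test group size")
  }
  res <- perm_mean_diff_test(a, b, n_perm = n_perm, seed = seed)
  res$test_group <- test_group
  res
}

#' Across-session group test
#'
#' Compares per-session scalar summaries between two groups of sessions by
#' shuffling session identities (10,000 permutations by default), with the
#' same absolute-mean-distance statistic and add-one correction as the
#' within-session test. Paired designs (e.g. standard-vs-deviant
#' differences against left-vs-right differences) are supported by passing
#' difference vectors.
#'
#' @param values_a,values_b Per-session scalars.
#' @param n_perm,seed Permutation parameters.
#' @return A `permutation_result`.
#' @export
group_permutation_test <- function(values_a, values_b, n_perm = 10000L,
                                   seed = 1L) {
  if (length(values_a) + length(values_b) < 2)
    stop("need at least two sessions in total")
  perm_mean_diff_test(values_a, values_b, n_perm = n_perm, seed = seed)
}

#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation between two equal-length vectors
#' (e.g. per-trial head and eye angles), with the two-sided p-value from the
#' t transform.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
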