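#' Directional count pair
#'
#' A labelled pair of counts feeding the exact binomial tests (e.g. markers
#' that worsen vs relieve a process, or affinity-increasing vs -decreasing
#' SNPs).
#'
#' @param label short description.
#' @param k_a,k_b non-negative counts.
#' @param side_a,side_b names of the two directions.
#' @return object of class `count_split` with `n = k_a + k_b`.
#' @export
count_split <- function(label, k_a, k_b, side_a = "a", side_b = "b") {
  stopifnot(k_a >= 0, k_b >= 0)
  structure(list(label = label, k_a = as.integer(k_a), k_b = as.integer(k_b),
                 n = as.integer(k_a + k_b), side_a = side_a, side_b = side_b),
            class = "count_split")
}

#' @export
print.count_split <- function(x, ...) {
  cat(sprintf("<count_split> %s: %s %d | %s %d (n = %d)\n",
              x$label, x$side_a, x$k_a, x$side_b, x$k_b, x$n))
  invisible(x)
}

#' Exact binomial tail probability
#'
#' Exact summation of binomial probabilities over the named tail,
#' `P(X <= k)` or `P(X >= k)` for `X ~ Binomial(n, theta)`.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials.
#' @param theta success probability in (0, 1).
#' @param side `"le"` for the lower tail, `"ge"` for the upper tail.
#' @return tail probability.
#' @examples
#' binom_tail(2, 26, 0.5)            # 352 / 2^26
#' @export
binom_tail <- function(k, n, theta, side = c("le", "ge")) {
  side <- match.arg(side)
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly between 0 and 1")
  }
  if (k < 0 || k > n) stop("k must lie in 0..n")
  if (side == "le") {
    stats::pbinom(k, n, theta)
  } else {
    stats::pbinom(k - 1, n, theta, lower.tail = FALSE)
  }
}

#' Bonferroni adjustment
#'
#' @param p_raw raw p-value.
#' @param m multiplicity (number of tests), `m >= 1`.
#' @return `min(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < 1) stop("multiplicity m must be >= 1")
  pmin(1, m * p_raw)
}

test_result <- function(statistic, p_raw, m, method, extra = list()) {
  structure(c(list(statistic = statistic, p_raw = p_raw, m = m,
                   p_adj = bonferroni(p_raw, m), method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat = %s, p = %.3g, p_adj = %.3g (m = %d)\n",
              x$method, format(x$statistic), x$p_raw, x$p_adj, as.integer(x$m)))
  invisible(x)
}

#' Directional bias test for a count split
#'
#' One-sided exact binomial tail in the direction of the observed excess
#' relative to the reference ratio `theta0`, Bonferroni-adjusted with
#' multiplicity `m`. `theta0` is the probability of the `k_a` side under
#' the null; for the neutral-drift comparison it is the whole-genome ratio
#' of affinity-increasing to all affinity-changing promoter SNPs, which is
#' an external input and therefore has no default.
#'
#' @param split a `count_split`.
#' @param theta0 null probability of side `a`.
#' @param m Bonferroni multiplicity (default 1 = no adjustment).
#' @return a `test_result` (statistic = `k_a`; `side` records the tail).
#' @export
direction_bias_test <- function(split, theta0, m = 1) {
  stopifnot(inherits(split, "count_split"))
  if (split$n == 0L) stop("empty count split")
  side <- if (split$k_a / split$n >= theta0) "ge" else "le"
  p <- binom_tail(split$k_a, split$n, theta0, side = side)
  test_result(split$k_a, p, m, "exact binomial (one-sided)",
              extra = list(side = side, theta0 = theta0, n = split$n,
                           label = split$label))
}

#' Concordance test for DEG-direction counts
#'
#' One-sided exact binomial at `theta = 0.5` on a (worsen, relief) count
#' pair, tail taken in the direction of the observed excess.
#'
#' @param split a `count_split` with `k_a` = worsen, `k_b` = relief.
#' @param m Bonferroni multiplicity.
#' @return a `test_result`.
#' @examples
#' deg_concordance_test(count_split("atheroprotection", 2, 24), m = 3)
#' @export
deg_concordance_test <- function(split, m = 1) {
  direction_bias_test(split, theta0 = 0.5, m = m)
}

#' Sign test for the lowest bar among subset means
#'
#' Under the null that each of `m` subsets is equally likely to have the
#' smallest mean, observing the focal subset strictly below all others has
#' probability `0.5^(m-1)` (each non-focal subset independently exceeds
#' it). When the focal subset is not strictly lowest (including ties), the
#' test returns p = 1 with a tie flag.
#'
#' @param values_by_subset named list of numeric vectors (or of precomputed
#'   means), one per subset; at least 2 subsets.
#' @param focal name or index of the focal subset.
#' @return a `test_result` with `lowest` and `tie` flags.
#' @export
lowest_bar_sign_test <- function(values_by_subset, focal) {
  m <- length(values_by_subset)
  if (m < 2L) stop("need at least 2 subsets")
  means <- vapply(values_by_subset, function(v) mean(as.numeric(v)), numeric(1))
  if (is.character(focal)) focal <- match(focal, names(values_by_subset))
  stopifnot(!is.na(focal), focal >= 1, focal <= m)
  others <- means[-focal]
  tie <- any(abs(others - means[focal]) < .Machine$double.eps^0.5)
  lowest <- !tie && all(means[focal] < others)
  p <- if (lowest) 0.5^(m - 1) else 1
  test_result(means[focal], p, 1, "lowest-bar sign test",
              extra = list(lowest = lowest, tie = tie, n_subsets = m))
}

#' Mann-Whitney U test
#'
#' Exact null distribution (rank enumeration) when both samples are small
#' (`min(n) <= 8`) and tie-free; otherwise the normal approximation with
#' tie correction. The method actually used is recorded on the result.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @return a `test_result` with statistic `U` and field `exact`.
#' @examples
#' mannwhitney_u(c(1, 2), c(3, 4), alternative = "less")  # U = 0, p = 1/6
#' @export
mannwhitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  test_result(unname(wt$statistic), wt$p.value, 1,
              if (exact) "Mann-Whitney U (exact)" else
                "Mann-Whitney U (normal approximation, tie-corrected)",
              extra = list(exact = exact, alternative = alternative))
}

#' Two-sample z test on means (parametric companion to Mann-Whitney)
#'
#' A z statistic on the difference of sample means with SEM-based standard
#' error, `z = (mean(x) - mean(y)) / sqrt(sem_x^2 + sem_y^2)`. This is the
#' package's parametric large-sample comparison of subset means.
#'
#' @inheritParams mannwhitney_u
#' @return a `test_result` with statistic `z`.
#' @export
mean_z_test <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per sample")
  mx <- mean_sem(x); my <- mean_sem(y)
  z <- (mx$mean - my$mean) / sqrt(mx$sem^2 + my$sem^2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  test_result(z, p, 1, "two-sample z on means",
              extra = list(alternative = alternative))
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector (at least 1 value; the SEM requires 2 and
#'   is `NA` with a flag otherwise).
#' @return list with `mean`, `sem`, `n` and `sem_defined`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  n <- length(values)
  sem <- if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_
  list(mean = mean(values), sem = sem, n = n, sem_defined = n >= 2L)
}
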