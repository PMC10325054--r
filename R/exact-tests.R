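#' Signed-rank test with exact small-sample enumeration
#'
#' Wilcoxon signed-rank test of paired differences (or of a sample
#' against `mu`). Zero differences are dropped (Wilcoxon convention).
#' For `n <= exact_limit` retained differences the null distribution of
#' the positive-rank sum is computed exactly by enumerating all 2^n sign
#' patterns (via a generating-polynomial convolution over doubled
#' midranks, so ties are handled exactly); otherwise a tie-corrected
#' normal approximation with continuity correction is used. Two-sided
#' exact p is `min(1, 2 * min(P(V <= v), P(V >= v)))`, matching the
#' convention of [stats::wilcox.test()] in the tie-free case.
#'
#' @param x Numeric sample (or paired differences if `y` is `NULL`).
#' @param y Optional paired sample; the test is on `x - y`.
#' @param mu Null location for the differences.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_limit Largest n for which the exact enumeration is used.
#' @return List with `statistic` (V, positive-rank sum), `n` (non-zero
#'   differences), `p`, `exact` (logical) and `alternative`.
#' @export
#' @examples
#' signed_rank_test(c(2, 2, 2, 2, 2, 2), mu = 1)$p  # 1/32
signed_rank_test <- function(x, y = NULL, mu = 0,
                             alternative = c("two.sided", "greater", "less"),
                             exact_limit = 16L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x - mu else (x - y) - mu
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0L, p = 1, exact = TRUE,
                alternative = alternative))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of the positive-rank sum over all 2^n sign patterns:
    # convolve generating polynomials in doubled ranks (integers even
    # with midranks)
    w <- as.integer(round(2 * r))
    probs <- 1
    for (wi in w) {
      new <- numeric(length(probs) + wi)
      new[seq_along(probs)] <- probs / 2
      new[seq_along(probs) + wi] <- new[seq_along(probs) + wi] + probs / 2
      probs <- new
    }
    support <- (seq_along(probs) - 1) / 2
    ple <- sum(probs[support <= v + 1e-9])
    pge <- sum(probs[support >= v - 1e-9])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(ple, pge)),
                greater = pge,
                less = ple)
    exact <- TRUE
  } else {
    ev <- n * (n + 1) / 4
    ties <- table(abs(d))
    sdv <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- v - ev
    cc <- 0.5
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-(abs(z) - cc) / sdv),
                greater = stats::pnorm(-(z - cc) / sdv),
                less = stats::pnorm((z + cc) / sdv))
    p <- min(1, max(0, p))
    exact <- FALSE
  }
  list(statistic = v, n = n, p = p, exact = exact, alternative = alternative)
}

#' Rank-sum (Mann-Whitney) test with exact small-sample enumeration
#'
#' Two-sample rank-sum test. When the number of group assignments
#' `choose(m + n, m)` is at most `max_enum`, the null distribution of
#' the first sample's rank sum is obtained by exhaustive enumeration of
#' all assignments (exact under ties, using midranks); otherwise a
#' tie-corrected normal approximation with continuity correction is
#' used. Two-sided exact p is `min(1, 2 * min(P <= , P >= ))`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (location
#'   of `x` relative to `y`).
#' @param max_enum Enumeration budget.
#' @return List with `statistic` (U for the first sample), `rank_sum`,
#'   `p`, `exact`, `alternative`.
#' @export
#' @examples
#' rank_sum_test(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))$p  # 0.1
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          max_enum = 2e5) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  m <- length(x); n <- length(y)
  if (m < 1 || n < 1) stop("both samples must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  w <- sum(r[seq_len(m)])
  u <- w - m * (m + 1) / 2
  if (choose(m + n, m) <= max_enum) {
    combs <- utils::combn(m + n, m)
    sums <- colSums(matrix(r[combs], nrow = m))
    ple <- mean(sums <= w + 1e-9)
    pge <- mean(sums >= w - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(ple, pge)),
                greater = pge,
                less = ple)
    exact <- TRUE
  } else {
    ew <- m * (m + n + 1) / 2
    ties <- table(all_v)
    N <- m + n
    sdw <- sqrt(m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z <- w - ew
    cc <- 0.5
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-(abs(z) - cc) / sdw),
                greater = stats::pnorm(-(z - cc) / sdw),
                less = stats::pnorm((z + cc) / sdw))
    p <- min(1, max(0, p))
    exact <- FALSE
  }
  list(statistic = u, rank_sum = w, p = p, exact = exact,
       alternative = alternative)
}
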