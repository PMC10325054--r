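#' Plug-in mutual information of a joint count table
#'
#' Shannon mutual information (bits) of the empirical joint distribution
#' given by a nonnegative count table (rows = response symbols,
#' columns = stimulus symbols), computed by the entropy decomposition
#' `I(R;S) = H(R) + H(S) - H(R,S)` with the `0 log 0 = 0` convention.
#' Always nonnegative (up to floating point), invariant under bijective
#' relabeling of symbols, and bounded by `min(H(R), H(S))`.
#'
#' @param joint Nonnegative numeric matrix of counts (or joint
#'   probabilities; normalization is internal).
#' @return Mutual information in bits.
#' @export
#' @examples
#' mi_plugin(matrix(c(5, 0, 0, 5), 2))  # 1 bit
mi_plugin <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0) || !all(is.finite(joint))) {
    stop("joint table must be finite and nonnegative")
  }
  tot <- sum(joint)
  if (tot <= 0) stop("joint table must contain at least one count")
  p <- joint / tot
  h <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  mi <- h(rowSums(p)) + h(colSums(p)) - h(p)
  max(mi, 0)
}

# discretize counts: integers capped at `cap` (tail pooled)
cap_counts <- function(counts, cap) pmin(as.integer(counts), as.integer(cap))

mi_from_samples <- function(r_wind, r_nowind, cap) {
  r <- c(cap_counts(r_wind, cap), cap_counts(r_nowind, cap))
  s <- c(rep("wind", length(r_wind)), rep("nowind", length(r_nowind)))
  joint <- table(factor(r, levels = 0:cap), s)
  mi_plugin(unclass(joint))
}

#' Stimulus mutual information of a unit's spike counts
#'
#' For one wind condition, quantifies how informative the unit's 1-s
#' spike counts are about the binary stimulus variable
#' (condition-wind vs no-wind). For each post-onset second, the samples
#' are that second's counts over the condition's epochs (stimulus
#' present) pooled with the baseline-bin counts (stimulus absent), and
#' the plug-in MI of the resulting joint table is computed, with counts
#' capped at `cap` (tail pooled) to limit plug-in bias. The baseline MI
#' — the estimator's bias floor — is computed per baseline second by
#' the same construction with that baseline second playing the role of
#' the stimulus-present sample against the remaining baseline seconds
#' (a leave-one-bin-out pseudo-stimulus, so true MI is 0 and the sample
#' sizes match the post-onset estimate). Normalized MI is each
#' post-onset second's MI divided by the mean baseline MI.
#'
#' @param binned A [bin_spikes()] result whose epochs include the
#'   requested condition.
#' @param condition `"low"` (0.5 m/s) or `"high"` (1.5 m/s).
#' @param cap Count cap for the response discretization.
#' @return Object of class `mi_result`: list with `unit_id`,
#'   `condition`, `mi` (bits, post-onset seconds), `baseline_mi` (bits,
#'   baseline seconds), `normalized` (dimensionless; `NA` when the mean
#'   baseline MI is 0), `cap`.
#' @export
mutual_information <- function(binned, condition = c("low", "high"),
                               cap = 10) {
  condition <- match.arg(condition)
  stopifnot(inherits(binned, "binned_response"))
  speed <- if (condition == "low") 0.5 else 1.5
  speeds <- attr(binned, "speeds")
  sel <- which(speeds == speed)
  if (length(sel) < 2) stop("need >= 2 epochs of the requested condition")
  bl <- baseline_cols(binned)
  po <- post_cols(binned)
  base_counts <- as.vector(binned[sel, bl])
  mi <- vapply(po, function(cl) {
    mi_from_samples(binned[sel, cl], base_counts, cap)
  }, numeric(1))
  base_mi <- vapply(bl, function(cl) {
    mi_from_samples(binned[sel, cl], as.vector(binned[sel, setdiff(bl, cl)]),
                    cap)
  }, numeric(1))
  floor_mi <- mean(base_mi)
  norm <- if (floor_mi > 0) mi / floor_mi else rep(NA_real_, length(mi))
  structure(list(unit_id = attr(binned, "unit_id"),
                 condition = condition,
                 mi = stats::setNames(mi, paste0("s", seq_along(po))),
                 baseline_mi = base_mi,
                 normalized = stats::setNames(norm, paste0("s", seq_along(po))),
                 cap = cap),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("MI (", x$condition, " wind) for unit '", x$unit_id, "': ",
      paste(names(x$mi), signif(x$mi, 3), sep = "=", collapse = ", "),
      " bits; baseline floor ", signif(mean(x$baseline_mi), 3), "\n", sep = "")
  invisible(x)
}

#' Population test of normalized MI against 1
#'
#' Two-tailed signed-rank test, per post-onset second, of the units'
#' normalized MI values against 1 (the no-information level after
#' baseline normalization), at a Bonferroni-style corrected alpha.
#'
#' @param mi_results List of [mutual_information()] results (one per
#'   unit, same condition).
#' @param alpha Corrected significance level (default 0.003).
#' @return Data frame (`second`, `median_normalized`, `p`,
#'   `significant`, `n`).
#' @export
normalized_mi_test <- function(mi_results, alpha = 0.003) {
  normd <- do.call(rbind, lapply(mi_results, `[[`, "normalized"))
  ok <- stats::complete.cases(normd)
  normd <- normd[ok, , drop = FALSE]
  if (nrow(normd) < 5) stop("need >= 5 units with defined normalized MI")
  out <- lapply(seq_len(ncol(normd)), function(s) {
    v <- normd[, s]
    ts <- signed_rank_test(v, mu = 1, alternative = "two.sided")
    data.frame(second = s, median_normalized = stats::median(v),
               p = ts$p, significant = ts$p < alpha, n = length(v))
  })
  do.call(rbind, out)
}
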