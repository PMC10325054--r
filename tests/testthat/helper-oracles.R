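# Independent oracles used to check the package's statistics.
# These deliberately follow different computational routes than the
# implementation (conditional-probability double sums, brute-force
# enumerations) so agreement is informative.

# MI via the conditional-probability double sum
# sum_r sum_s P(r) P(s|r) log2(P(s|r) / P(s)), with 0 log 0 = 0.
oracle_mi <- function(joint) {
  joint <- as.matrix(joint)
  N <- sum(joint)
  pr <- rowSums(joint) / N
  ps <- colSums(joint) / N
  total <- 0
  for (i in seq_len(nrow(joint))) {
    if (pr[i] == 0) next
    for (j in seq_len(ncol(joint))) {
      psr <- joint[i, j] / sum(joint[i, ])
      if (psr > 0) total <- total + pr[i] * psr * log2(psr / ps[j])
    }
  }
  total
}

# exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# patterns (midranks for tied magnitudes)
oracle_signed_rank_p <- function(d, mu = 0, alternative = "two.sided") {
  d <- d - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ple <- mean(v_all <= v_obs + 1e-9)
  pge <- mean(v_all >= v_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(ple, pge)),
         greater = pge,
         less = ple)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  sums <- combn(length(r), m, function(ii) sum(r[ii]))
  ple <- mean(sums <= w_obs + 1e-9)
  pge <- mean(sums >= w_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(ple, pge)),
         greater = pge,
         less = ple)
}

# two-sided Fisher exact p by hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H from the definition, with tie correction
oracle_kw_H <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), times = lengths(groups))
  N <- length(v)
  r <- rank(v)
  rb <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(ni * (rb - (N + 1) / 2)^2)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exhaustive arrangement-shuffle p: enumerate every assignment of the
# values to the valued positions and compare mean within-group variances
oracle_shuffle_p <- function(values, scheme) {
  ids <- names(values)
  grp <- scheme$groups[ids]
  gidx <- split(seq_along(values), grp)
  gidx <- gidx[lengths(gidx) >= 2]
  stat <- function(v) mean(vapply(gidx, function(ii) var(v[ii]), numeric(1)))
  obs <- stat(values)
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  stats_all <- vapply(perm_all(as.numeric(values)), stat, numeric(1))
  mean(stats_all <= obs + 1e-12)
}

# deterministic small simulation config used across tests
quick_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_frames = 300, ...)
}

# build a binned_response object directly from a count matrix
# (epochs x 8 bins spanning -4..4 s)
make_binned <- function(counts, unit_id = "u1", region = "SO",
                        speeds = rep(0.5, nrow(counts))) {
  m <- as.matrix(counts)
  colnames(m) <- -4:3
  structure(m, class = c("binned_response", "matrix"),
            unit_id = unit_id, region = region,
            bin_edges = seq(-4, 4), speeds = speeds)
}
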