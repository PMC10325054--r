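test_that("peri-stimulus binning uses exact half-open 1-s bins", {
  ep <- wind_epoch_series(onset_s = c(20, 60), speed_mps = c(0.5, 0.5))
  u0 <- unit_spike_train("u0", "SO", numeric(0))
  b0 <- bin_spikes(u0, ep)
  expect_true(all(b0 == 0))
  expect_equal(dim(b0), c(2, 8))
  # spikes at onset+0.5 and onset+1.5
  u1 <- unit_spike_train("u1", "SO", c(20.5, 21.5))
  b1 <- bin_spikes(u1, ep)
  expect_equal(unname(b1[1, 5:8]), c(1, 1, 0, 0))
  expect_true(all(b1[2, ] == 0))
  # a spike exactly on a bin edge lands in the later (right) bin
  u2 <- unit_spike_train("u2", "SO", c(21, 20 - 4))
  b2 <- bin_spikes(u2, ep)
  expect_equal(unname(b2[1, ]), c(1, 0, 0, 0, 0, 1, 0, 0))
  # overlapping peri-stimulus windows are rejected
  ep_bad <- wind_epoch_series(onset_s = c(20, 34.5), speed_mps = c(0.5, 1.5))
  expect_error(bin_spikes(u1, ep_bad, window = c(-8, 8)), "overlap")
  expect_error(wind_epoch_series(c(0, 5), c(0.5, 0.5)), "overlap")
  expect_error(unit_spike_train("u", "SO", c(1, NA)), "NA")
  expect_error(unit_spike_train("u", "SO", -1), "nonnegative")
})

test_that("z-scoring is against the pre-onset baseline bins", {
  # baseline bins (2, 1, 3, 2): mean 2, sd ~0.816; post bin mean 4
  counts <- matrix(rep(c(2, 1, 3, 2, 4, 2, 2, 2), each = 6), nrow = 6)
  z <- zscore_response(make_binned(counts))
  expect_false(z$degenerate)
  expect_equal(z$baseline_mean, 2)
  expect_equal(unname(z$z[5]), (4 - 2) / sd(c(2, 1, 3, 2)))
  expect_equal(unname(z$z[6]), 0)
  # post bins equal to the baseline mean give z = 0
  # silent unit: degenerate flag, no infinities
  zs <- zscore_response(make_binned(matrix(0, 4, 8)))
  expect_true(zs$degenerate)
  expect_true(all(is.na(zs$z)))
})

test_that("GLM classification recovers constructed rate changes", {
  set.seed(61)
  # x3 rate in post seconds 1-2: flagged excited in nearly all simulations
  flags <- vapply(1:40, function(i) {
    counts <- cbind(matrix(rpois(30 * 4, 5), 30),   # baseline
                    matrix(rpois(30 * 2, 15), 30),  # seconds 1-2
                    matrix(rpois(30 * 2, 5), 30))   # seconds 3-4
    cl <- classify_response_glm(make_binned(counts))
    all(cl$labels[c("s1", "s2")] == "excited")
  }, logical(1))
  expect_gte(mean(flags), 0.95)
  # complete suppression: inhibited despite Wald separation
  counts0 <- cbind(matrix(rpois(30 * 4, 5), 30), matrix(0L, 30, 4))
  cl0 <- classify_response_glm(make_binned(counts0))
  expect_true(all(cl0$labels == "inhibited"))
  expect_false(cl0$degenerate)
  # an all-silent unit cannot be classified
  expect_true(classify_response_glm(make_binned(matrix(0L, 4, 8)))$degenerate)
  expect_error(classify_response_glm(make_binned(matrix(1, 1, 8))), "epochs")
})

test_that("response percentages count non-degenerate units per second", {
  mk_cls <- function(labels, region = "SO", degenerate = FALSE) {
    structure(list(unit_id = "u", region = region,
                   labels = stats::setNames(labels, paste0("s", 1:4)),
                   p_values = rep(NA_real_, 4), coefficients = rep(0, 4),
                   alpha = 0.05, degenerate = degenerate),
              class = "response_classification")
  }
  none4 <- rep("none", 4)
  cls <- c(lapply(1:3, function(i) mk_cls(c("none", "excited", "none", "none"))),
           lapply(1:7, function(i) mk_cls(none4)))
  pc <- response_percentages(cls)
  expect_equal(pc$pct_excited, c(0, 30, 0, 0))
  expect_equal(pc$pct_inhibited, rep(0, 4))
  # degenerate units are excluded from the denominator
  cls2 <- c(cls, list(mk_cls(none4, degenerate = TRUE)))
  expect_equal(response_percentages(cls2)$n[1], 10)
  # all-none population
  expect_true(all(response_percentages(lapply(1:4, function(i) mk_cls(none4))
                                       )$pct_excited == 0))
  expect_error(response_percentages(cls, region = "pad"), "no units")
})

test_that("latency is the supra-threshold maximal bin with early tie-break", {
  expect_equal(response_latency(c(0.5, 3.0, 1.0, 0.2)), 2L)
  expect_true(is.na(response_latency(c(1.2, 1.9, 0.3, -0.5))))
  expect_equal(response_latency(c(3, 3, 0, 0)), 1L)
  expect_true(is.na(response_latency(rep(NA_real_, 4))))
  # accepts a zscore_response result and uses its post-onset bins
  counts <- matrix(rep(c(2, 1, 3, 2, 2, 9, 2, 2), each = 8), nrow = 8)
  expect_equal(response_latency(zscore_response(make_binned(counts))), 2L)
})

test_that("plug-in MI matches the double-sum oracle and its bounds", {
  # deterministic equiprobable binary channel: exactly 1 bit
  expect_equal(mi_plugin(matrix(c(5, 0, 0, 5), 2)), 1)
  # identical conditional distributions: zero information
  expect_equal(mi_plugin(matrix(c(3, 6, 3, 6), 2)), 0)
  # explicit small table vs oracle
  tab <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(mi_plugin(tab), oracle_mi(tab), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:25) {
    tb <- matrix(rpois(8, 3), 4, 2)
    if (sum(tb) == 0) next
    expect_equal(mi_plugin(tb), oracle_mi(tb), tolerance = 1e-12)
    expect_gte(mi_plugin(tb), 0)
    # bounded by the stimulus entropy (binary S: <= 1 bit)
    ps <- colSums(tb) / sum(tb)
    hs <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
    expect_lte(mi_plugin(tb), hs + 1e-12)
    # invariant under relabeling of response symbols
    expect_equal(mi_plugin(tb[sample(4), ]), mi_plugin(tb), tolerance = 1e-12)
  }
  expect_error(mi_plugin(matrix(-1, 1, 2)), "nonnegative")
  expect_error(mi_plugin(matrix(0, 2, 2)), "at least one")
})

test_that("stimulus MI separates coupled from uncoupled units", {
  set.seed(81)
  n_ep <- 500
  # stimulus-independent counts: plug-in MI stays near its bias floor
  counts <- matrix(rpois(n_ep * 8, 4), n_ep)
  mi0 <- mutual_information(make_binned(counts), "low")
  expect_true(all(mi0$mi <= 0.05))
  # strong coupling: post-onset counts shifted far above baseline
  counts2 <- cbind(matrix(rpois(n_ep * 4, 1), n_ep),
                   matrix(rpois(n_ep * 4, 8), n_ep))
  mi2 <- mutual_information(make_binned(counts2), "low")
  expect_true(all(mi2$mi > 0.5))
  expect_true(all(mi2$normalized > 5))
  expect_error(mutual_information(make_binned(counts, speeds = rep(1.5, n_ep)),
                                  "low"), "epochs")
})

test_that("population normalized-MI test flags coupled units only", {
  mk_mi <- function(normalized) {
    structure(list(unit_id = "u", condition = "low",
                   mi = rep(0.1, 4), baseline_mi = rep(0.1, 4),
                   normalized = stats::setNames(normalized, paste0("s", 1:4)),
                   cap = 10),
              class = "mi_result")
  }
  # all exactly 1: zero differences, p = 1 by convention
  flat <- lapply(1:8, function(i) mk_mi(rep(1, 4)))
  rf <- normalized_mi_test(flat)
  expect_true(all(rf$p == 1))
  expect_false(any(rf$significant))
  # strong uniform elevation at second 2
  set.seed(91)
  up <- lapply(1:12, function(i) mk_mi(c(1 + rnorm(1, 0, 0.01), 3,
                                         1 + rnorm(1, 0, 0.01), 1)))
  ru <- normalized_mi_test(up)
  expect_true(ru$significant[2])
  expect_equal(ru$p[2], oracle_signed_rank_p(rep(3, 12), mu = 1),
               tolerance = 1e-12)
  expect_error(normalized_mi_test(flat[1:3]), "5 units")
})
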