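test_that("displacement is the distance to the coordinate-wise median", {
  tr <- whisker_trajectory("w", c(0, 3, 0), c(0, 4, 0))
  ds <- displacement_series(tr)
  expect_equal(ds$d, c(0, 5, 0))
  expect_equal(c(ds$median_x, ds$median_y), c(0, 0))
  # constant trajectory: zero displacement
  expect_equal(displacement_series(whisker_trajectory("w", rep(2, 5),
                                                      rep(-1, 5)))$d,
               rep(0, 5))
  expect_error(whisker_trajectory("w", numeric(0), numeric(0)), "at least one")
})

test_that("displacement is translation-invariant and scale-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    tr <- whisker_trajectory("w", rnorm(n), rnorm(n))
    d0 <- displacement_series(tr)$d
    sh <- whisker_trajectory("w", tr$x + 7.3, tr$y - 2.1)
    expect_equal(displacement_series(sh)$d, d0)
    sc <- whisker_trajectory("w", 3 * tr$x, 3 * tr$y)
    expect_equal(displacement_series(sc)$d, 3 * d0)
  }
})

test_that("displacement summaries report the requested center and spread", {
  s <- displacement_series(whisker_trajectory("a", c(0, 3, 0), c(0, 4, 0)))
  z <- displacement_series(whisker_trajectory("b", rep(1, 3), rep(1, 3)))
  sm <- summarize_displacement(list(s, z), "mean_sem")
  expect_equal(sm$center[sm$whisker_id == "a"], 5 / 3)
  expect_equal(sm$center[sm$whisker_id == "b"], 0)
  expect_equal(sm$spread[sm$whisker_id == "b"], 0)
  smm <- summarize_displacement(list(s), "median_iqr")
  expect_equal(smm$center, 0)
  expect_equal(sm$rank[sm$whisker_id == "a"], 1L)
  expect_error(summarize_displacement(list(s), "mode_x"))
})

test_that("likelihood filtering drops low-confidence frames when asked", {
  tr <- whisker_trajectory("w", c(0, 100, 0, 0), c(0, 0, 0, 0),
                           likelihood = c(1, 0.1, 1, 1))
  expect_equal(max(displacement_series(tr, min_likelihood = 0.5)$d), 0)
  expect_gt(max(displacement_series(tr)$d), 10)
  expect_error(displacement_series(whisker_trajectory("w", 1, 1),
                                   min_likelihood = 0.5), "no likelihood")
})

test_that("Kruskal-Wallis omnibus matches the definition-formula oracle", {
  # identical groups: H ~ 0, p ~ 1
  cmp <- compare_whiskers(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                          posthoc = "dunn")
  expect_equal(cmp$H, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1)
  # small random instances, with and without ties
  set.seed(21)
  for (i in 1:20) {
    gs <- lapply(1:3, function(j) sample(1:6, sample(2:4, 1), replace = TRUE))
    names(gs) <- c("a", "b", "c")
    cmp <- compare_whiskers(gs, posthoc = "dunn")
    expect_equal(cmp$H, oracle_kw_H(gs), tolerance = 1e-10)
  }
  expect_error(compare_whiskers(list(a = 1, b = c(1, 2))), "a")
})

test_that("omnibus p is consistent with the exhaustive rank-permutation null", {
  # 2 groups of 3 distinct values: compare the chi-square p against the
  # exact permutation distribution of H over all C(6,3) = 20 splits
  gs <- list(a = c(1.2, 3.4, 5.6), b = c(2.1, 4.3, 9.9))
  cmp <- compare_whiskers(gs, posthoc = "dunn")
  pooled <- unlist(gs)
  hs <- combn(6, 3, function(ii) {
    oracle_kw_H(list(pooled[ii], pooled[-ii]))
  })
  p_exact <- mean(hs >= oracle_kw_H(gs) - 1e-12)
  expect_equal(cmp$H, oracle_kw_H(gs), tolerance = 1e-10)
  # the exact permutation p is a proper p-value and agrees with the
  # asymptotic one in its qualitative conclusion at this tiny n
  expect_gt(p_exact, 0)
  expect_lte(p_exact, 1)
  expect_equal(cmp$p > 0.05, p_exact > 0.05)
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(31)
  rej <- vapply(1:200, function(i) {
    gs <- lapply(1:3, function(j) rnorm(20))
    names(gs) <- c("a", "b", "c")
    compare_whiskers(gs, posthoc = "dunn")$p < 0.05
  }, logical(1))
  ci <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), ci)
})

test_that("post hoc methods separate a strongly shifted group", {
  set.seed(41)
  gs <- list(lSO = rnorm(40, 10), A1 = rnorm(40, 0), C3 = rnorm(40, 0))
  for (ph in c("dunn", "tukey")) {
    cmp <- compare_whiskers(gs, posthoc = ph)
    expect_lt(cmp$posthoc["lSO", "C3"], 0.01)
    expect_gt(cmp$posthoc["A1", "C3"], 0.05)
    expect_equal(cmp$posthoc["lSO", "A1"], cmp$posthoc["A1", "lSO"])
  }
})

test_that("displacement ratios against 1 follow the signed-rank convention", {
  mk <- function(centers) {
    data.frame(whisker_id = names(centers), n = 10, center = unname(centers),
               spread = 0, rank = rank(-centers, ties.method = "min"))
  }
  ctr <- c(a = 1, b = 2, c = 0.5, d = 1.4, e = 0.9, f = 2.2)
  same <- displacement_ratio(mk(ctr), mk(ctr))
  expect_true(all(same$ratios$ratio == 1))
  expect_equal(same$p, 1)
  dbl <- displacement_ratio(mk(2 * ctr), mk(ctr))
  expect_true(all(dbl$ratios$ratio == 2))
  expect_equal(dbl$p, oracle_signed_rank_p(rep(2, 6), mu = 1))
  expect_error(displacement_ratio(mk(ctr), mk(c(ctr[-1], g = 1))), "whisker set")
  ctr0 <- ctr; ctr0["a"] <- 0
  expect_error(displacement_ratio(mk(ctr), mk(ctr0)), "undefined")
})

test_that("high/low amplitude ratio is recovered from synthetic trajectories", {
  meds <- vapply(1:20, function(s) {
    amps <- lapply(default_amplitudes(), function(a) {
      c(low = unname(a["low"]), high = unname(3 * a["low"]))
    })
    cfg <- sim_config(seed = s, n_frames = 1500, whisker_amplitudes = amps)
    lo <- summarize_displacement(lapply(gen_whisker_trajectories(cfg, 0.5),
                                        displacement_series))
    hi <- summarize_displacement(lapply(gen_whisker_trajectories(cfg, 1.5),
                                        displacement_series))
    stats::median(displacement_ratio(hi, lo)$ratios$ratio)
  }, numeric(1))
  expect_true(all(meds > 2.5 & meds < 3.5))
})

test_that("bending angle reproduces constructed geometry", {
  straight_x <- whisker_shape("w", cbind(seq(0, 10, 0.5), 0))
  straight_y <- whisker_shape("w", cbind(0, seq(0, 10, 0.5)))
  expect_equal(bending_angle(straight_x, straight_x), 0)
  expect_equal(bending_angle(straight_x, straight_y, 0.75), 90)
  rot <- function(pts, deg) {
    th <- deg * pi / 180
    pts %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2))
  }
  curved <- whisker_shape("w", cbind(0:20, 0.02 * (0:20)^2))
  r30 <- whisker_shape("w", rot(curved$points, 30))
  expect_equal(bending_angle(curved, r30), 30, tolerance = 1e-9)
  # symmetric in its arguments
  expect_equal(bending_angle(r30, curved), bending_angle(curved, r30))
  # jointly applied rigid motion leaves the angle unchanged
  mv <- function(s, deg, dx, dy) {
    whisker_shape(s$whisker_id, sweep(rot(s$points, deg), 2, c(-dx, -dy)))
  }
  expect_equal(bending_angle(mv(curved, 77, 1, -2), mv(r30, 77, 1, -2)),
               bending_angle(curved, r30), tolerance = 1e-9)
  shifted <- whisker_shape("w", sweep(curved$points, 2, c(-5, 0)))
  expect_error(bending_angle(curved, shifted), "base point")
  expect_error(bending_angle(curved, r30, fraction = 0), "fraction")
})

test_that("wind rise time crosses thresholds where constructed", {
  # step trace 0 -> v at t = 2 s
  dt <- 0.01
  t <- seq(0, 10, dt)
  step <- ifelse(t >= 2, 1.5, 0)
  for (f in c(0.2, 0.8, 0.95)) {
    expect_equal(wind_rise_time(data.frame(t_s = t, speed_mps = step), f), 2,
                 tolerance = dt)
  }
  # calibrated exponential: 80% crossing at 1.5 s
  expo <- 0.5 * (1 - exp(-t / (1.5 / log(5))))
  expect_equal(wind_rise_time(data.frame(t_s = t, speed_mps = expo), 0.8), 1.5,
               tolerance = dt)
  expect_true(is.na(wind_rise_time(rep(0, 100), 0.8)))
  expect_error(wind_rise_time(step, 1.2), "threshold_fraction")
})
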