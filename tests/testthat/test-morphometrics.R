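scheme_from_groups <- function(groups) {
  lay <- pad_layout()
  full <- stats::setNames(rep("rest", nrow(lay)), lay$whisker_id)
  full[names(groups)] <- groups
  arrangement_scheme("custom", groups = full)
}

test_that("mean within-group variance follows the unbiased estimator", {
  sch <- scheme_from_groups(c(A1 = "g1", A2 = "g1", B1 = "g2", B2 = "g2"))
  vals <- c(A1 = 1, A2 = 3, B1 = 2, B2 = 4)
  expect_equal(mean_within_group_variance(vals, sch), 2)
  # all values equal
  expect_equal(mean_within_group_variance(c(A1 = 5, A2 = 5, B1 = 5, B2 = 5),
                                          sch), 0)
  # one group holding all values equals the overall sample variance
  one <- scheme_from_groups(c(A1 = "g", A2 = "g", B1 = "g", B2 = "g"))
  v <- c(A1 = 1.4, A2 = -0.3, B1 = 2.2, B2 = 0.9)
  expect_equal(mean_within_group_variance(v, one), var(v))
  # invariant under group relabeling and constant shifts
  relab <- scheme_from_groups(c(A1 = "x9", A2 = "x9", B1 = "q", B2 = "q"))
  expect_equal(mean_within_group_variance(vals, relab),
               mean_within_group_variance(vals, sch))
  expect_equal(mean_within_group_variance(vals + 100, sch),
               mean_within_group_variance(vals, sch))
  # singleton groups are skipped; all-singleton input errors
  skew <- scheme_from_groups(c(A1 = "g1", A2 = "g1", B1 = "solo"))
  expect_equal(mean_within_group_variance(c(A1 = 1, A2 = 3, B1 = 99), skew), 2)
  lone <- scheme_from_groups(c(A1 = "g1", B1 = "g2"))
  expect_error(mean_within_group_variance(c(A1 = 1, B1 = 2), lone),
               "no group")
})

test_that("shuffle test matches the exhaustive-assignment oracle", {
  sch <- scheme_from_groups(c(A1 = "g1", A2 = "g1", B1 = "g2", B2 = "g2"))
  vals <- c(A1 = 1, A2 = 1.2, B1 = 5, B2 = 5.5)
  res <- shuffle_arrangement_test(vals, sch, n_shuffles = 100, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$p, oracle_shuffle_p(vals, sch))
  # 5- and 6-position instances across several random value sets and groupings
  set.seed(5)
  ids6 <- c("A1", "A2", "A3", "B1", "B2", "B3")
  for (i in 1:8) {
    k <- sample(5:6, 1)
    ids <- ids6[1:k]
    grp <- stats::setNames(sample(c("u", "v"), k, replace = TRUE), ids)
    if (length(unique(grp)) < 2) grp[1] <- setdiff(c("u", "v"), grp[1])[1]
    sch_i <- scheme_from_groups(grp)
    vals_i <- stats::setNames(round(rnorm(k), 2), ids)
    res_i <- shuffle_arrangement_test(vals_i, sch_i, seed = i)
    expect_true(res_i$exhaustive)
    expect_equal(res_i$p, oracle_shuffle_p(vals_i, sch_i), tolerance = 1e-12)
  }
  # degenerate constant values: observed and null all zero, p = 1
  sch26 <- arrangement_scheme("semicircles_A1")
  const <- stats::setNames(rep(3, 26), pad_layout()$whisker_id)
  expect_equal(shuffle_arrangement_test(const, sch26, n_shuffles = 50)$p, 1)
  expect_error(shuffle_arrangement_test(const, sch26, n_shuffles = 0),
               "n_shuffles")
})

test_that("optimal-arrangement selection recovers constructed structure", {
  lay <- pad_layout()
  schemes <- standard_schemes(lay)
  # values constant within rows, varying across rows -> rows wins
  rows_groups <- schemes$rows$groups
  row_vals <- stats::setNames(match(rows_groups, unique(rows_groups)) * 10 +
                                0.01 * seq_along(rows_groups),
                              names(rows_groups))
  sel <- select_optimal_arrangement(row_vals, schemes, n_shuffles = 300,
                                    seed = 2)
  expect_identical(sel$best, "rows")
  # values constant within semicircles -> semicircles_A1 wins with the
  # smallest p among schemes
  sc_groups <- schemes$semicircles_A1$groups
  sc_vals <- stats::setNames(match(sc_groups, unique(sc_groups)) * 10 +
                               0.01 * seq_along(sc_groups),
                             names(sc_groups))
  sel2 <- select_optimal_arrangement(sc_vals, schemes, n_shuffles = 300,
                                     seed = 2)
  expect_identical(sel2$best, "semicircles_A1")
  expect_equal(unname(sel2$p["semicircles_A1"]), min(sel2$p))
  # exact ties resolve to the declared scheme order
  const <- stats::setNames(rep(1, 26), lay$whisker_id)
  sel3 <- select_optimal_arrangement(const, schemes, n_shuffles = 50, seed = 1)
  expect_identical(sel3$best, names(schemes)[1])
  expect_error(select_optimal_arrangement(row_vals, schemes[1]), "2 candidate")
})

test_that("semicircle-structured synthetic values are detected reliably", {
  schemes <- standard_schemes()
  sc_groups <- schemes$semicircles_A1$groups
  centers <- stats::setNames(10 * match(sc_groups, unique(sc_groups)),
                             names(sc_groups))
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    vals <- centers + rnorm(length(centers), 0, 0.5)
    select_optimal_arrangement(vals, schemes, n_shuffles = 200,
                               seed = s)$best == "semicircles_A1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fold change normalizes by the reference whisker mean", {
  vals <- c(lSO = 2, lSO = 4, A1 = 6, B2 = 1.5)
  fc <- fold_change_vs_reference(vals)
  expect_equal(mean(fc[names(fc) == "lSO"]), 1)
  expect_equal(unname(fc[names(fc) == "A1"]), 2)
  expect_equal(unname(fold_change_vs_reference(c(A1 = 2, B1 = 4), "A1")),
               c(1, 2))
  # scale invariance
  expect_equal(fold_change_vs_reference(10 * vals), fc)
  expect_error(fold_change_vs_reference(c(A1 = 1), "lSO"), "reference")
  expect_error(fold_change_vs_reference(c(lSO = 0, A1 = 2)), "zero")
})

test_that("aperture angle is the largest polar gap", {
  sq <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
  expect_equal(aperture_angle(sq, c(0, 0)), 90)
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(cos(th), sin(th))
  expect_equal(aperture_angle(semi, c(0, 0)), 180, tolerance = 1e-6)
  # dense full circle: aperture shrinks toward 0
  full <- seq(0, 2 * pi, length.out = 721)[-721]
  expect_lt(aperture_angle(cbind(cos(full), sin(full)), c(0, 0)), 1)
  # invariance under rotation about the center and uniform scaling
  rot <- function(p, deg) {
    t <- deg * pi / 180
    p %*% t(matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2))
  }
  expect_equal(aperture_angle(rot(semi, 33), c(0, 0)), 180, tolerance = 1e-6)
  expect_equal(aperture_angle(5 * semi, c(0, 0)), 180, tolerance = 1e-6)
  expect_error(aperture_angle(sq[1, , drop = FALSE], c(0, 0)), "2 planar")
  expect_error(aperture_angle(rbind(c(1, 1), c(1, 1)), c(1, 1)), "coincide")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 1, 3, 5)
  ct <- correlate(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate(a, a)$r, 1)
  expect_equal(correlate(a, -a)$r, -1)
  # pairwise-complete handling
  expect_equal(correlate(c(a, NA), c(b, 3))$n, 4)
  expect_error(correlate(a, rep(1, 4)), "zero variance")
  expect_error(correlate(1:2, 2:3), "3 complete pairs")
})
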