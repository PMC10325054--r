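#' Mean within-group variance of a whisker-indexed quantity
#'
#' For an arrangement scheme partitioning the pad, computes the unbiased
#' sample variance (denominator n - 1) of the values inside each group
#' and returns the unweighted mean across groups. Groups with fewer than
#' two valued members are skipped (a singleton's sample variance is
#' undefined). Small values indicate that the quantity is spatially
#' structured along the arrangement.
#'
#' @param values Named numeric vector, whisker id -> value. Whiskers may
#'   repeat (replicates); all values of a whisker share its group.
#' @param scheme An [arrangement_scheme()].
#' @return The mean within-group variance (scalar).
#' @export
#' @examples
#' sch <- arrangement_scheme("custom", groups = stats::setNames(
#'   c("g1", "g1", rep("g2", 24)), pad_layout()$whisker_id))
mean_within_group_variance <- function(values, scheme) {
  stopifnot(inherits(scheme, "arrangement_scheme"))
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by whisker id")
  unknown <- setdiff(ids, names(scheme$groups))
  if (length(unknown)) {
    stop("valued whisker(s) not covered by the scheme: ",
         paste(unique(unknown), collapse = ", "))
  }
  g <- scheme$groups[ids]
  vars <- tapply(as.numeric(values), g, function(v) {
    if (length(v) < 2) NA_real_ else stats::var(v)
  })
  vars <- vars[!is.na(vars)]
  if (length(vars) == 0) stop("no group has >= 2 valued members")
  mean(vars)
}

#' Arrangement shuffle test
#'
#' Tests whether a whisker-indexed quantity is spatially structured
#' along an arrangement: the observed mean within-group variance is
#' compared against a null distribution obtained by randomly permuting
#' the assignment of values to the valued pad positions and recomputing
#' the statistic. Small p means more spatially structured (lower
#' within-group variance) than chance. For sampled permutations the
#' p-value uses the add-one convention
#' `(1 + #\{null <= observed\}) / (1 + n_shuffles)`; when the number of
#' distinct whiskers is small enough that all assignments fit within
#' `exhaustive_limit`, every permutation is enumerated instead and p is
#' the exact proportion of assignments whose statistic is at or below
#' the observed one.
#'
#' @param values Named numeric vector, whisker id -> value (replicates
#'   allowed; replicate blocks move together under permutation).
#' @param scheme An [arrangement_scheme()].
#' @param n_shuffles Number of random permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_limit Enumerate all assignments when the factorial
#'   of the number of distinct whiskers does not exceed this.
#' @return Object of class `shuffle_result`: list with `arrangement`,
#'   `observed`, `null_distribution`, `p`, `n_shuffles` (null draws
#'   actually used), `exhaustive`, `seed`.
#' @export
shuffle_arrangement_test <- function(values, scheme, n_shuffles = 10000,
                                     seed = 1L, exhaustive_limit = 720) {
  stopifnot(inherits(scheme, "arrangement_scheme"))
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  ids <- names(values)
  if (length(unique(ids)) < 3) stop("need values on at least 3 whiskers")
  obs <- mean_within_group_variance(values, scheme)

  # permute whisker identities among the valued positions; replicates of
  # a whisker travel together
  uids <- unique(ids)
  idx_by_w <- split(seq_along(values), factor(ids, levels = uids))
  v <- as.numeric(values)
  g_of <- scheme$groups
  if (length(uids) == length(v)) {
    # no replicates: permuting whisker identities is equivalent to
    # permuting the values against fixed group index sets (fast path)
    gidx <- split(seq_along(uids), g_of[uids])
    gidx <- gidx[vapply(gidx, length, 1L) >= 2]
    stat_for <- function(perm) {
      vp <- v[match(uids, perm)]
      mean(vapply(gidx, function(ii) stats::var(vp[ii]), numeric(1)))
    }
  } else {
    stat_for <- function(perm) {
      gids <- character(length(v))
      for (k in seq_along(uids)) gids[idx_by_w[[k]]] <- perm[k]
      grp <- g_of[gids]
      vars <- tapply(v, grp, function(z) if (length(z) < 2) NA_real_ else stats::var(z))
      mean(vars, na.rm = TRUE)
    }
  }
  exhaustive <- factorial(length(uids)) <= exhaustive_limit
  if (exhaustive) {
    perms <- all_permutations(uids)
    null_dist <- vapply(perms, stat_for, numeric(1))
    p <- mean(null_dist <= obs + 1e-12)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    null_dist <- vapply(seq_len(n_shuffles), function(b) stat_for(sample(uids)),
                        numeric(1))
    p <- (1 + sum(null_dist <= obs + 1e-12)) / (1 + n_shuffles)
  }
  structure(list(arrangement = scheme$name, observed = obs,
                 null_distribution = null_dist, p = p,
                 n_shuffles = length(null_dist), exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "shuffle_result")
}

# all permutations of a vector (small n only)
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (tail_perm in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], tail_perm)
    }
  }
  out
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("Arrangement shuffle test (", x$arrangement, "): observed mean ",
      "within-group variance = ", signif(x$observed, 5),
      ", p = ", signif(x$p, 4), " (", x$n_shuffles, " shuffles)\n", sep = "")
  invisible(x)
}

#' Select the optimal spatial arrangement
#'
#' Runs the arrangement shuffle test for each candidate scheme and
#' selects the one with the minimal observed mean within-group variance
#' (ties broken by the declared scheme order).
#'
#' @param values Named numeric vector, whisker id -> value.
#' @param schemes Named list of [arrangement_scheme()] objects
#'   (default: the six standard schemes).
#' @param n_shuffles,seed Passed to [shuffle_arrangement_test()].
#' @return List with `best` (scheme name), `observed` (named vector of
#'   observed statistics), `p` (named vector of shuffle p-values) and
#'   `tests` (the full `shuffle_result` objects).
#' @export
select_optimal_arrangement <- function(values, schemes = standard_schemes(),
                                       n_shuffles = 10000, seed = 1L) {
  if (length(schemes) < 2) stop("need at least 2 candidate schemes")
  tests <- lapply(schemes, function(s) {
    shuffle_arrangement_test(values, s, n_shuffles = n_shuffles, seed = seed)
  })
  obs <- vapply(tests, `[[`, numeric(1), "observed")
  p <- vapply(tests, `[[`, numeric(1), "p")
  best <- names(schemes)[which.min(obs)]
  list(best = best, observed = obs, p = p, tests = tests)
}

#' Fold change relative to a reference whisker
#'
#' Divides every value by the mean of the reference whisker's values
#' (default: the long supra-orbital whisker), so the reference averages
#' to 1 and other whiskers are expressed as fold changes.
#'
#' @param values Named numeric vector, whisker id -> value (replicates
#'   allowed).
#' @param reference Reference whisker id.
#' @return Numeric vector of normalized values, same names and order.
#' @export
fold_change_vs_reference <- function(values, reference = "lSO") {
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by whisker id")
  ref <- as.numeric(values[ids == reference])
  if (length(ref) < 1) stop("no values for reference whisker '", reference, "'")
  m <- mean(ref)
  if (m == 0) stop("reference whisker mean is zero")
  values / m
}

#' Ring-wulst aperture angle from a planar point set
#'
#' Operationalizes the aperture of a ring-wulst outline as the largest
#' angular gap: polar angles of the ring points about the hair-shaft
#' center are sorted and the maximal gap between consecutive angles
#' (including the wrap-around) is returned in degrees. A closed ring of
#' dense points gives a small aperture; a C-shaped (open) ring gives a
#' large one. Invariant under rotation about the center and under
#' uniform scaling.
#'
#' @param ring_points Two-column numeric matrix of ring points.
#' @param shaft_center Length-2 numeric center point.
#' @return Aperture angle in degrees, in `[0, 360)`.
#' @export
#' @examples
#' pts <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
#' aperture_angle(pts, c(0, 0))  # 90
aperture_angle <- function(ring_points, shaft_center) {
  p <- as.matrix(ring_points)
  if (nrow(p) < 2 || ncol(p) != 2) stop("need >= 2 planar ring points")
  dx <- p[, 1] - shaft_center[1]
  dy <- p[, 2] - shaft_center[2]
  r2 <- dx^2 + dy^2
  if (all(r2 == 0)) stop("all ring points coincide with the shaft center")
  ang <- sort(atan2(dy[r2 > 0], dx[r2 > 0]) * 180 / pi)
  gaps <- c(diff(ang), 360 - (ang[length(ang)] - ang[1]))
  max(gaps)
}

#' Pearson correlation of paired whisker quantities
#'
#' Pearson r and two-sided p-value on pairwise-complete records.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `r`, `p`, `n` (complete pairs).
#' @export
correlate <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
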