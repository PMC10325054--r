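#' Whisker trajectory
#'
#' A tracked 2D tip time series for one whisker at a fixed frame rate.
#'
#' @param whisker_id Whisker label (e.g. `"lSO"`, `"A1"`).
#' @param x,y Equal-length numeric coordinate series (>= 1 frame).
#' @param frame_rate Frames per second (> 0).
#' @param likelihood Optional per-frame tracking likelihood in `[0, 1]`.
#' @return Object of class `whisker_trajectory`.
#' @export
whisker_trajectory <- function(whisker_id, x, y, frame_rate = 100,
                               likelihood = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("trajectory must contain at least one frame")
  if (!is.finite(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (!is.null(likelihood) && length(likelihood) != length(x)) {
    stop("likelihood must match trajectory length")
  }
  structure(list(whisker_id = as.character(whisker_id),
                 x = as.numeric(x), y = as.numeric(y),
                 frame_rate = frame_rate, likelihood = likelihood),
            class = "whisker_trajectory")
}

#' @export
print.whisker_trajectory <- function(x, ...) {
  cat("Whisker trajectory '", x$whisker_id, "': ", length(x$x),
      " frames @ ", x$frame_rate, " fps\n", sep = "")
  invisible(x)
}

#' Tip displacement about the median position
#'
#' Displacement is the per-frame Euclidean distance of the tracked tip
#' from its coordinate-wise median position,
#' `sqrt((X - x_t)^2 + (Y - y_t)^2)` with `(X, Y)` the medians of the
#' whole series. It is translation-invariant and scale-equivariant, and
#' for a static head isolates airflow-driven jitter.
#'
#' @param traj A [whisker_trajectory()].
#' @param min_likelihood Optional threshold; frames with tracking
#'   likelihood below it are dropped before computing the median and the
#'   distances (`NULL`, the default, keeps all frames).
#' @return Object of class `displacement_series`: list with
#'   `whisker_id`, `d` (nonnegative distances, input units), `median_x`,
#'   `median_y`.
#' @export
#' @examples
#' tr <- whisker_trajectory("lSO", c(0, 3, 0), c(0, 4, 0))
#' displacement_series(tr)$d  # 0 5 0
displacement_series <- function(traj, min_likelihood = NULL) {
  stopifnot(inherits(traj, "whisker_trajectory"))
  x <- traj$x
  y <- traj$y
  if (!is.null(min_likelihood)) {
    if (is.null(traj$likelihood)) {
      stop("trajectory has no likelihood column to filter on")
    }
    keep <- traj$likelihood >= min_likelihood
    x <- x[keep]
    y <- y[keep]
  }
  if (length(x) < 1) stop("trajectory is empty (after filtering)")
  mx <- stats::median(x)
  my <- stats::median(y)
  structure(list(whisker_id = traj$whisker_id,
                 d = sqrt((x - mx)^2 + (y - my)^2),
                 median_x = mx, median_y = my),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat("Displacement of '", x$whisker_id, "': n = ", length(x$d),
      ", mean = ", signif(mean(x$d), 4), "\n", sep = "")
  invisible(x)
}

#' Per-whisker displacement summary
#'
#' Summarizes a set of displacement series into one row per whisker:
#' center and spread per the requested mode, plus the displacement rank
#' order (rank 1 = largest center).
#'
#' @param series List of [displacement_series()] objects.
#' @param mode `"mean_sem"` (mean and standard error) or
#'   `"median_iqr"` (median and interquartile range).
#' @return Data frame (`whisker_id`, `n`, `center`, `spread`, `rank`)
#'   sorted by decreasing center.
#' @export
summarize_displacement <- function(series, mode = c("mean_sem", "median_iqr")) {
  mode <- match.arg(mode)
  if (length(series) < 1) stop("need at least one displacement series")
  rows <- lapply(series, function(s) {
    stopifnot(inherits(s, "displacement_series"))
    d <- s$d
    if (mode == "mean_sem") {
      ctr <- mean(d)
      spr <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0
    } else {
      ctr <- stats::median(d)
      spr <- stats::IQR(d)
    }
    data.frame(whisker_id = s$whisker_id, n = length(d),
               center = ctr, spread = spr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$center, ties.method = "min")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

#' Omnibus and post hoc comparison of displacement across whiskers
#'
#' Kruskal-Wallis test (tie-corrected) of pooled per-frame displacement
#' values grouped by whisker, followed by pairwise post hoc tests:
#' Dunn's rank z-test or Tukey's HSD on the raw values.
#'
#' @param series_by_whisker Named list: whisker id -> numeric vector of
#'   displacement values, or a list of [displacement_series()].
#' @param posthoc `"tukey"` or `"dunn"`.
#' @param p_adjust p-adjustment method for Dunn's pairwise p-values
#'   (passed to [stats::p.adjust()]); Tukey p-values are family-wise by
#'   construction.
#' @return Object of class `whisker_comparison`: list with `H`, `df`,
#'   `p`, `n`, `posthoc` (symmetric pairwise p-value matrix) and
#'   `method`.
#' @export
compare_whiskers <- function(series_by_whisker, posthoc = c("tukey", "dunn"),
                             p_adjust = "none") {
  posthoc <- match.arg(posthoc)
  vals <- lapply(series_by_whisker, function(s) {
    if (inherits(s, "displacement_series")) s$d else as.numeric(s)
  })
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    names(vals) <- paste0("g", seq_along(vals))
  }
  if (length(vals) < 2) stop("need at least 2 whiskers to compare")
  small <- names(vals)[vapply(vals, length, 1L) < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  g <- factor(rep(names(vals), times = vapply(vals, length, 1L)),
              levels = names(vals))
  v <- unlist(vals, use.names = FALSE)
  kw <- stats::kruskal.test(v, g)
  pmat <- if (posthoc == "dunn") {
    dunn_posthoc(v, g, p_adjust = p_adjust)
  } else {
    tukey_posthoc(v, g)
  }
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, n = length(v), posthoc = pmat,
                 method = posthoc),
            class = "whisker_comparison")
}

#' @export
print.whisker_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H(", x$df, ", ", x$n, ") = ", signif(x$H, 6),
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  cat("Post hoc:", x$method, "(pairwise p-value matrix in $posthoc)\n")
  invisible(x)
}

# Dunn's post hoc: pairwise z-tests on mean ranks with tie correction.
dunn_posthoc <- function(v, g, p_adjust = "none") {
  r <- rank(v)
  N <- length(v)
  mr <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  k <- length(lev)
  pm <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  pr <- c()
  idx <- which(upper.tri(pm), arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z <- (mr[i] - mr[j]) / se
    pr[q] <- 2 * stats::pnorm(-abs(z))
  }
  pr <- stats::p.adjust(pr, method = p_adjust)
  for (q in seq_len(nrow(idx))) {
    pm[idx[q, 1], idx[q, 2]] <- pm[idx[q, 2], idx[q, 1]] <- pr[q]
  }
  diag(pm) <- 1
  pm
}

tukey_posthoc <- function(v, g) {
  tk <- stats::TukeyHSD(stats::aov(v ~ g))$g
  lev <- levels(g)
  k <- length(lev)
  pm <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (q in seq_along(pairs)) {
    a <- pairs[[q]][1]; b <- pairs[[q]][2]
    pm[a, b] <- pm[b, a] <- tk[q, "p adj"]
  }
  diag(pm) <- 1
  pm
}

#' High/low wind displacement ratio and test against 1
#'
#' Per-whisker ratio of displacement centers between the high and low
#' wind conditions, with a signed-rank test of the ratios against 1
#' across whiskers (exact for small samples; zero differences dropped).
#'
#' @param high,low Summary data frames from [summarize_displacement()]
#'   over the same whisker set.
#' @param alternative Test sidedness for the signed-rank test
#'   (`"two.sided"`, `"greater"`, `"less"`).
#' @return List with `ratios` (data frame `whisker_id`, `ratio`),
#'   `statistic`, `p`, `alternative`.
#' @export
displacement_ratio <- function(high, low, alternative = "two.sided") {
  if (!setequal(high$whisker_id, low$whisker_id)) {
    stop("high and low summaries must cover the same whisker set")
  }
  low <- low[match(high$whisker_id, low$whisker_id), ]
  if (any(low$center <= 0)) {
    stop("zero (or negative) low-wind center: ratio undefined for ",
         paste(low$whisker_id[low$center <= 0], collapse = ", "))
  }
  ratio <- high$center / low$center
  ts <- signed_rank_test(ratio, mu = 1, alternative = alternative)
  list(ratios = data.frame(whisker_id = high$whisker_id, ratio = ratio,
                           stringsAsFactors = FALSE),
       statistic = ts$statistic, p = ts$p, alternative = alternative)
}

#' Whisker shape polyline
#'
#' Ordered planar polyline from base to tip, in mm.
#'
#' @param whisker_id Label.
#' @param points Two-column numeric matrix (x, y), first row = base.
#' @return Object of class `whisker_shape` with the cumulative arc
#'   length stored in `$arc_length`.
#' @export
whisker_shape <- function(whisker_id, points) {
  points <- as.matrix(points)
  if (nrow(points) < 2 || ncol(points) != 2) {
    stop("shape needs >= 2 planar points")
  }
  seglen <- sqrt(rowSums(diff(points)^2))
  if (sum(seglen) <= 0) stop("shape has zero arc length")
  structure(list(whisker_id = as.character(whisker_id),
                 points = points, arc_length = sum(seglen)),
            class = "whisker_shape")
}

# Point at a given fraction of total arc length, linearly interpolated
# along the polyline segments.
arc_point <- function(shape, fraction) {
  p <- shape$points
  seglen <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seglen))
  target <- fraction * s[length(s)]
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(seglen))
  w <- (target - s[i]) / seglen[i]
  p[i, ] + w * (p[i + 1, ] - p[i, ])
}

#' Bending angle between a rest and a deflected whisker shape
#'
#' Locates the point at `fraction` of total arc length along each
#' polyline and returns the unsigned angle (degrees, in `[0, 180]`) at
#' the shared base between the two base-to-point radii. Invariant to
#' rigid motion applied to both shapes jointly, and symmetric in its
#' shape arguments.
#'
#' @param rest,deflected [whisker_shape()] objects sharing a base point.
#' @param fraction Arc-length fraction in `(0, 1]`; 0.75 by convention.
#' @param base_tol Tolerance (same units as coordinates) for the base
#'   registration check.
#' @return Angle in degrees.
#' @export
bending_angle <- function(rest, deflected, fraction = 0.75, base_tol = 1e-6) {
  stopifnot(inherits(rest, "whisker_shape"), inherits(deflected, "whisker_shape"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  b1 <- rest$points[1, ]
  b2 <- deflected$points[1, ]
  if (sqrt(sum((b1 - b2)^2)) > base_tol) {
    stop("shapes do not share a base point within tolerance")
  }
  v1 <- arc_point(rest, fraction) - b1
  v2 <- arc_point(deflected, fraction) - b2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate radius at the requested fraction")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Rise time of a wind trace
#'
#' First time the trace exceeds `threshold_fraction` of its steady-state
#' mean (mean over a trailing window), with linear interpolation between
#' samples.
#'
#' @param trace A `wind_trace` data frame (`t_s`, `speed_mps`) or a
#'   numeric speed vector with sample period `dt`.
#' @param threshold_fraction Fraction of the steady-state mean, in
#'   (0, 1).
#' @param steady_window Fraction of the trace tail used to estimate the
#'   steady-state mean.
#' @param dt Sample period when `trace` is a bare numeric vector.
#' @return Crossing time in seconds, or `NA_real_` ("not reached").
#' @export
wind_rise_time <- function(trace, threshold_fraction,
                           steady_window = 0.2, dt = 0.01) {
  if (is.data.frame(trace)) {
    t <- trace$t_s
    v <- trace$speed_mps
  } else {
    v <- as.numeric(trace)
    t <- (seq_along(v) - 1) * dt
  }
  if (length(v) < 1) stop("empty trace")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  ntail <- max(1, ceiling(steady_window * length(v)))
  ss <- mean(utils::tail(v, ntail))
  thr <- threshold_fraction * ss
  above <- v > thr
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(t[1])
  # linear interpolation between the bracketing samples
  t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
}
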