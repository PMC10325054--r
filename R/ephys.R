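#' Unit spike train
#'
#' @param unit_id Unit label.
#' @param region Recording region label (e.g. `"SO"` or `"pad"`).
#' @param spike_times Spike times in seconds, nonnegative; stored
#'   sorted.
#' @return Object of class `unit_spike_train`.
#' @export
unit_spike_train <- function(unit_id, region, spike_times) {
  st <- as.numeric(spike_times)
  if (anyNA(st)) stop("spike times must not contain NA")
  if (length(st) && min(st) < 0) stop("spike times must be nonnegative")
  if (is.unsorted(st)) st <- sort(st)
  structure(list(unit_id = as.character(unit_id),
                 region = as.character(region),
                 spike_times = st),
            class = "unit_spike_train")
}

#' @export
print.unit_spike_train <- function(x, ...) {
  cat("Unit '", x$unit_id, "' (", x$region, "): ",
      length(x$spike_times), " spikes\n", sep = "")
  invisible(x)
}

#' Wind epoch series
#'
#' Stimulus schedule: onsets, speeds and the common epoch duration.
#' Epochs must not overlap, including each epoch's 4-s pre-onset
#' baseline window.
#'
#' @param onset_s Epoch onsets, seconds.
#' @param speed_mps Wind speed per epoch, m/s.
#' @param duration_s Common epoch duration, seconds.
#' @param pre_s Pre-onset baseline extent used in the overlap check.
#' @return Object of class `wind_epoch_series` (data frame `onset_s`,
#'   `speed_mps` with a `duration_s` attribute).
#' @export
wind_epoch_series <- function(onset_s, speed_mps, duration_s = 10, pre_s = 4) {
  if (length(onset_s) != length(speed_mps)) {
    stop("onset_s and speed_mps must have equal length")
  }
  o <- order(onset_s)
  onset_s <- onset_s[o]
  speed_mps <- speed_mps[o]
  if (length(onset_s) > 1) {
    gaps <- diff(onset_s)
    if (any(gaps < duration_s + pre_s)) {
      stop("epochs overlap (including the ", pre_s, "-s pre-onset window)")
    }
  }
  out <- data.frame(onset_s = onset_s, speed_mps = speed_mps)
  attr(out, "duration_s") <- duration_s
  class(out) <- c("wind_epoch_series", "data.frame")
  out
}

#' Peri-stimulus spike counts
#'
#' Counts spikes of one unit in half-open 1-s bins `[t, t + 1)` spanning
#' a window around every epoch onset (default -4 to +4 s, so the onset
#' sits at the left edge of the first post-onset bin).
#'
#' @param unit A [unit_spike_train()].
#' @param epochs A [wind_epoch_series()]; optionally pre-filtered to one
#'   condition.
#' @param window Length-2 window around onset, seconds.
#' @param bin Bin width, seconds.
#' @return Object of class `binned_response`: integer matrix
#'   (epochs x bins) with bin left edges as column names and attributes
#'   `unit_id`, `region`, `bin_edges`, `speeds`.
#' @export
bin_spikes <- function(unit, epochs, window = c(-4, 4), bin = 1) {
  stopifnot(inherits(unit, "unit_spike_train"))
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1
  if (nrow(epochs) > 1) {
    span <- diff(range(epochs$onset_s))
    if (any(diff(sort(epochs$onset_s)) < (window[2] - window[1]))) {
      stop("peri-stimulus windows overlap between epochs")
    }
    stopifnot(span >= 0)
  }
  st <- unit$spike_times
  m <- matrix(0L, nrow = nrow(epochs), ncol = nb)
  for (e in seq_len(nrow(epochs))) {
    rel <- st - epochs$onset_s[e]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      idx <- floor((rel - window[1]) / bin) + 1
      tab <- tabulate(idx, nbins = nb)
      m[e, ] <- tab
    }
  }
  colnames(m) <- utils::head(edges, -1)
  structure(m, class = c("binned_response", "matrix"),
            unit_id = unit$unit_id, region = unit$region,
            bin_edges = edges, speeds = epochs$speed_mps)
}

baseline_cols <- function(binned) {
  edges <- attr(binned, "bin_edges")
  which(utils::head(edges, -1) < 0 & edges[-1] <= 0)
}

post_cols <- function(binned) {
  edges <- attr(binned, "bin_edges")
  which(utils::head(edges, -1) >= 0)
}

#' Z-scored peri-stimulus response
#'
#' Trial-averages the binned counts and z-scores every bin against the
#' pre-onset baseline bins: `z = (mean_bin - baseline_mean) /
#' baseline_sd`, where mean and SD are taken over the trial-averaged
#' baseline bins. Units with zero baseline SD are flagged degenerate
#' (all-`NA` z) rather than producing infinite scores.
#'
#' @param binned A [bin_spikes()] result.
#' @return List with `z` (per-bin z-scores, named by bin left edge),
#'   `baseline_mean`, `baseline_sd`, `degenerate` (logical).
#' @export
zscore_response <- function(binned) {
  stopifnot(inherits(binned, "binned_response"))
  mb <- colMeans(binned)
  bl <- baseline_cols(binned)
  if (length(bl) < 2) stop("need >= 2 baseline bins")
  bmean <- mean(mb[bl])
  bsd <- stats::sd(mb[bl])
  if (!is.finite(bsd) || bsd == 0) {
    return(list(z = stats::setNames(rep(NA_real_, length(mb)), names(mb)),
                baseline_mean = bmean, baseline_sd = bsd, degenerate = TRUE))
  }
  list(z = (mb - bmean) / bsd, baseline_mean = bmean, baseline_sd = bsd,
       degenerate = FALSE)
}

#' Poisson-GLM classification of a unit's wind response
#'
#' Fits a Poisson regression of per-epoch per-bin spike counts on a
#' five-level period factor (baseline = the pre-onset bins, reference
#' level; post-onset seconds 1-4), then labels each post-onset second
#' `excited` (significantly positive coefficient), `inhibited`
#' (significantly negative) or `none` via a per-coefficient Wald test at
#' level `alpha`. When a period separates completely (e.g. all-zero
#' counts, where the Wald statistic degenerates), the period's p-value
#' falls back to a likelihood-ratio test against the model with that
#' period merged into baseline.
#'
#' @param binned A [bin_spikes()] result (>= 2 epochs).
#' @param alpha Significance level per post-onset second.
#' @return Object of class `response_classification`: list with
#'   `unit_id`, `region`, `labels` (length 4, seconds 1-4), `p_values`,
#'   `coefficients`, `alpha`, `degenerate` (logical; `TRUE` when the
#'   fit failed and the unit should be excluded).
#' @export
classify_response_glm <- function(binned, alpha = 0.05) {
  stopifnot(inherits(binned, "binned_response"))
  if (nrow(binned) < 2) stop("need >= 2 epochs to classify")
  bl <- baseline_cols(binned)
  po <- post_cols(binned)
  if (length(po) < 1) stop("no post-onset bins")
  period <- c(rep("baseline", length(bl)), paste0("s", seq_along(po)))
  cols <- c(bl, po)
  counts <- as.vector(binned[, cols])
  per <- factor(rep(period, each = nrow(binned)),
                levels = c("baseline", paste0("s", seq_along(po))))
  labs <- stats::setNames(rep("none", length(po)), paste0("s", seq_along(po)))
  pv <- stats::setNames(rep(NA_real_, length(po)), names(labs))
  cf <- pv
  fit <- tryCatch(
    suppressWarnings(stats::glm(counts ~ per, family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged) || all(counts == 0)) {
    return(structure(list(unit_id = attr(binned, "unit_id"),
                          region = attr(binned, "region"),
                          labels = labs, p_values = pv, coefficients = cf,
                          alpha = alpha, degenerate = TRUE),
                     class = "response_classification"))
  }
  sm <- summary(fit)$coefficients
  for (k in seq_along(po)) {
    nm <- paste0("pers", k)
    if (!nm %in% rownames(sm)) next
    est <- sm[nm, "Estimate"]
    se <- sm[nm, "Std. Error"]
    p <- sm[nm, "Pr(>|z|)"]
    if (!is.finite(se) || se > 50 || abs(est) > 20) {
      # complete separation: likelihood-ratio test vs the model with this
      # period collapsed into baseline
      per2 <- per
      levels(per2)[levels(per2) == paste0("s", k)] <- "baseline"
      fit2 <- suppressWarnings(stats::glm(counts ~ per2,
                                          family = stats::poisson()))
      p <- stats::pchisq(fit2$deviance - fit$deviance, df = 1,
                         lower.tail = FALSE)
    }
    cf[k] <- est
    pv[k] <- p
    if (is.finite(p) && p < alpha) {
      labs[k] <- if (est > 0) "excited" else "inhibited"
    }
  }
  structure(list(unit_id = attr(binned, "unit_id"),
                 region = attr(binned, "region"),
                 labels = labs, p_values = pv, coefficients = cf,
                 alpha = alpha, degenerate = FALSE),
            class = "response_classification")
}

#' @export
print.response_classification <- function(x, ...) {
  cat("Unit '", x$unit_id, "' (", x$region, "): ",
      paste(names(x$labels), x$labels, sep = "=", collapse = ", "),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Percentages of excited and inhibited units per post-onset second
#'
#' Fraction (percent) of non-degenerate units labeled excited or
#' inhibited in each post-onset second, optionally restricted to one
#' region.
#'
#' @param classifications List of [classify_response_glm()] results.
#' @param region Optional region filter.
#' @return Data frame (`second`, `pct_excited`, `pct_inhibited`, `n`).
#' @export
response_percentages <- function(classifications, region = NULL) {
  if (!is.null(region)) {
    classifications <- Filter(function(cl) cl$region == region,
                              classifications)
    if (!length(classifications)) stop("no units in region '", region, "'")
  }
  classifications <- Filter(function(cl) !cl$degenerate, classifications)
  if (!length(classifications)) stop("no non-degenerate classified units")
  labm <- do.call(rbind, lapply(classifications, `[[`, "labels"))
  n <- nrow(labm)
  data.frame(
    second = seq_len(ncol(labm)),
    pct_excited = 100 * colMeans(labm == "excited"),
    pct_inhibited = 100 * colMeans(labm == "inhibited"),
    n = n,
    row.names = NULL
  )
}

#' Response latency from z-scored bins
#'
#' Latency is the post-onset bin (1-4) where the z-score is maximal,
#' provided that maximum surpasses the threshold (default 2 SD); ties go
#' to the earliest bin. Returns `NA` when the threshold is never
#' surpassed or the z-profile is degenerate.
#'
#' @param z Numeric z-scores for post-onset bins 1-4, or the list
#'   returned by [zscore_response()] (its post-onset bins are used).
#' @param threshold Z threshold in baseline SDs.
#' @return Integer bin index in 1-4, or `NA_integer_`.
#' @export
#' @examples
#' response_latency(c(0.5, 3, 1, 0.2))  # 2
response_latency <- function(z, threshold = 2) {
  if (is.list(z) && !is.null(z$z)) {
    nmz <- suppressWarnings(as.numeric(names(z$z)))
    z <- z$z[!is.na(nmz) & nmz >= 0]
  }
  z <- as.numeric(z)
  if (!length(z) || all(is.na(z))) return(NA_integer_)
  mx <- max(z, na.rm = TRUE)
  if (!is.finite(mx) || mx <= threshold) return(NA_integer_)
  which.max(z)
}
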