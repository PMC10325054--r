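#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators, so that one
#' integer seed plus one config object fully determines all generated
#' inputs. Defaults encode the study conditions the analyses assume:
#' 100 fps tracking, wind speeds 0.5 and 1.5 m/s, 10-s wind epochs,
#' hand-flap turning probabilities with a toward-stimulus bias, and
#' morphometry correlations (length-diameter r = 0.83, aperture-ratio
#' r = -0.66) with the long supra-orbital (lSO) whisker as the extreme
#' length/diameter ratio.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param frame_rate Tracking frame rate, frames/s.
#' @param n_frames Frames per trajectory.
#' @param whisker_amplitudes Named list, whisker id -> numeric
#'   `c(low, high)`: tip jitter SD (coordinate units, cm) at 0.5 and
#'   1.5 m/s wind.
#' @param morph_params List of morphometry means/SDs and target
#'   correlations; see Details.
#' @param ephys_params List: `n_units` (named, per region), `baseline_hz`,
#'   `gain_profile` (length 4, multiplicative rate gain in post-onset
#'   seconds 1-4 for excited units; inhibited units divide by it),
#'   `fractions` (per region, named `c(excited, inhibited)`; remainder is
#'   null), `region_gain_atten` (per region, scales gain deviations
#'   from 1).
#' @param epoch_params List: `duration_s`, `n_per_speed`, `gap_s`,
#'   `speeds`.
#' @param behavior_params List: `probs` (named list of
#'   `c(toward, away, none)` probability triples per condition label),
#'   `n_animals`, `trials_per_session`.
#'
#' @details `morph_params` fields: `mean_length` (mm), `sd_length`,
#' `mean_diameter` (um), `sd_diameter`, `r_length_diameter` (target
#' Pearson correlation), `mean_aperture` (deg), `sd_aperture`,
#' `r_aperture_ratio` (target correlation of ring-wulst aperture with
#' the length/diameter ratio, typically negative), `n_per_whisker`
#' (replicates per whisker type), `lso_length_shift` (mm added to lSO
#' mean length) and `lso_diameter_scale` (multiplier < 1 thinning the
#' lSO), which jointly give lSO the maximal configured mean ratio.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       frame_rate = 100,
                       n_frames = 6000,
                       whisker_amplitudes = default_amplitudes(),
                       morph_params = list(),
                       ephys_params = list(),
                       epoch_params = list(),
                       behavior_params = list()) {
  morph <- utils::modifyList(list(
    mean_length = 25, sd_length = 8,
    mean_diameter = 100, sd_diameter = 25,
    r_length_diameter = 0.83,
    mean_aperture = 180, sd_aperture = 60,
    r_aperture_ratio = -0.66,
    n_per_whisker = 4,
    lso_length_shift = 2,
    lso_diameter_scale = 0.55,
    lso_aperture_shift = -120
  ), morph_params)
  ephys <- utils::modifyList(list(
    n_units = c(SO = 40, pad = 40),
    baseline_hz = 5,
    # submaximal in second 1 (wind still ramping; 80% of mean at ~1.5 s),
    # peak in second 2, decay thereafter
    gain_profile = c(2, 3, 2, 1.5),
    fractions = list(SO = c(excited = 0.3, inhibited = 0.1),
                     pad = c(excited = 0.1, inhibited = 0.1)),
    region_gain_atten = c(SO = 1, pad = 0.3)
  ), ephys_params)
  epochs <- utils::modifyList(list(
    duration_s = 10,
    n_per_speed = 10,
    gap_s = 10,
    speeds = c(0.5, 1.5)
  ), epoch_params)
  behavior <- utils::modifyList(list(
    probs = list(
      hand = c(toward = 0.31, away = 0.07, none = 0.62),
      cardboard = c(toward = 0.48, away = 0.10, none = 0.42),
      wind_trim = c(toward = 0.20, away = 0.10, none = 0.70),
      nonwind_trim = c(toward = 0.29, away = 0.10, none = 0.61),
      lidocaine = c(toward = 0.18, away = 0.08, none = 0.74),
      ringer = c(toward = 0.23, away = 0.08, none = 0.69)
    ),
    n_animals = 7,
    trials_per_session = 16
  ), behavior_params)

  cfg <- structure(list(
    seed = as.integer(seed),
    frame_rate = frame_rate,
    n_frames = as.integer(n_frames),
    whisker_amplitudes = whisker_amplitudes,
    morph_params = morph,
    ephys_params = ephys,
    epoch_params = epochs,
    behavior_params = behavior
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$frame_rate) || cfg$frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  amp <- unlist(cfg$whisker_amplitudes)
  if (any(!is.finite(amp)) || any(amp < 0)) {
    stop("whisker amplitudes must be finite and >= 0")
  }
  m <- cfg$morph_params
  if (m$sd_length <= 0 || m$sd_diameter <= 0 || m$sd_aperture <= 0) {
    stop("morphometry SDs must be strictly positive")
  }
  if (abs(m$r_length_diameter) >= 1 || abs(m$r_aperture_ratio) >= 1) {
    stop("target correlations must lie in (-1, 1)")
  }
  e <- cfg$ephys_params
  if (e$baseline_hz < 0) stop("baseline rate must be >= 0")
  if (length(e$gain_profile) != 4 || any(e$gain_profile < 0)) {
    stop("gain_profile must give 4 nonnegative gains (post-onset seconds 1-4)")
  }
  for (fr in e$fractions) {
    if (sum(fr) > 1 + 1e-12 || any(fr < 0)) {
      stop("excited/inhibited fractions must be nonnegative and sum to <= 1")
    }
  }
  ep <- cfg$epoch_params
  if (ep$duration_s <= 0 || ep$gap_s < 0 || ep$n_per_speed < 1) {
    stop("epoch schedule parameters out of range")
  }
  if (ep$gap_s < 4) {
    stop("inter-epoch gap must be >= 4 s so the pre-onset baseline window fits")
  }
  b <- cfg$behavior_params
  for (p in b$probs) {
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("each behavior probability triple must be nonnegative and sum to 1")
    }
  }
  if (b$n_animals < 1) stop("n_animals must be >= 1")
  if (b$trials_per_session < 1) stop("trials_per_session must be >= 1")
  invisible(cfg)
}

#' Default per-whisker tip-jitter amplitudes
#'
#' Amplitudes (coordinate units, cm; jitter SD) per whisker at low
#' (0.5 m/s) and high (1.5 m/s) wind. The low-wind profile makes the
#' lSO tip the most displaced, followed by alpha, beta and A1; the
#' wind-responsive subset (lSO, sSO, alpha, beta, delta, A1-A3, B1-B4,
#' C1) roughly triples its amplitude at high wind while the remaining
#' whiskers change little.
#'
#' @param layout A `pad_layout` giving the whisker set.
#' @return Named list of `c(low, high)` amplitude pairs.
#' @export
default_amplitudes <- function(layout = pad_layout()) {
  ids <- layout$whisker_id
  responsive <- c("lSO", "sSO", "alpha", "beta", "delta",
                  "A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1")
  low <- stats::setNames(rep(0.03, length(ids)), ids)
  low[intersect(responsive, ids)] <- 0.08
  low[c("alpha", "beta", "A1")] <- 0.15
  low["lSO"] <- 0.30
  high <- stats::setNames(
    ifelse(names(low) %in% responsive, low * 3, low * 1.2), names(low))
  out <- lapply(ids, function(w) c(low = unname(low[w]), high = unname(high[w])))
  stats::setNames(out, ids)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  tracking: ", length(x$whisker_amplitudes), " whiskers, ",
      x$n_frames, " frames @ ", x$frame_rate, " fps\n", sep = "")
  cat("  epochs: ", x$epoch_params$n_per_speed, " per speed (",
      paste(x$epoch_params$speeds, collapse = ", "), " m/s), ",
      x$epoch_params$duration_s, " s each\n", sep = "")
  cat("  ephys: ", paste(names(x$ephys_params$n_units),
                         x$ephys_params$n_units, collapse = ", "),
      " units, baseline ", x$ephys_params$baseline_hz, " Hz\n", sep = "")
  cat("  behavior: ", x$behavior_params$n_animals, " animals x ",
      x$behavior_params$trials_per_session, " trials\n", sep = "")
  invisible(x)
}

# Seed the global RNG from the config seed plus a small stream offset,
# restoring the caller's RNG state on exit. Keeps every generator
# deterministic in (cfg, offset) without clobbering user randomness.
with_sim_rng <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((cfg$seed %% 1000000L) * 1000L + offset)
  force(expr)
}
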