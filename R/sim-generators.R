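#' Generate whisker-tip trajectories under a wind condition
#'
#' Emulates pose-tracked whisker tips on an anesthetized (static) head:
#' each tip jitters isotropically (Gaussian) about a fixed base point,
#' with jitter SD equal to the configured amplitude of that whisker at
#' the requested wind speed. At `wind_speed = 0` all amplitudes are 0.
#'
#' @param cfg A [sim_config()].
#' @param wind_speed One of 0, 0.5 or 1.5 (m/s).
#' @param layout Pad layout supplying the base points (grid positions
#'   read as cm).
#' @return Named list of [whisker_trajectory()] objects, one per whisker
#'   in `cfg$whisker_amplitudes`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_frames = 50)
#' trajs <- gen_whisker_trajectories(cfg, 0.5)
#' trajs$lSO
gen_whisker_trajectories <- function(cfg, wind_speed, layout = pad_layout()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!wind_speed %in% c(0, 0.5, 1.5)) {
    stop("wind_speed must be one of 0, 0.5, 1.5 (m/s)")
  }
  ids <- names(cfg$whisker_amplitudes)
  unknown <- setdiff(ids, layout$whisker_id)
  if (length(unknown)) {
    stop("whisker id(s) not in the pad layout: ", paste(unknown, collapse = ", "))
  }
  idx <- match(ids, layout$whisker_id)
  pick <- if (wind_speed == 0) NA else if (wind_speed == 0.5) 1L else 2L
  n <- cfg$n_frames
  with_sim_rng(cfg, 11L + round(wind_speed * 10), {
    out <- lapply(seq_along(ids), function(i) {
      amp <- if (is.na(pick)) 0 else cfg$whisker_amplitudes[[i]][pick]
      bx <- layout$col[idx[i]]
      by <- -layout$row[idx[i]]
      whisker_trajectory(
        whisker_id = ids[i],
        x = bx + stats::rnorm(n, 0, amp),
        y = by + stats::rnorm(n, 0, amp),
        frame_rate = cfg$frame_rate
      )
    })
    stats::setNames(out, ids)
  })
}

#' Generate a whisker morphometry table
#'
#' Samples per-whisker length (mm), base diameter (um) and ring-wulst
#' aperture (deg) records from a correlated Gaussian model, clipped at
#' physical bounds. Length and diameter share the configured Pearson
#' correlation; aperture is coupled (with the configured, typically
#' negative, correlation) to the standardized length-minus-diameter
#' contrast, a linear proxy for the log length/diameter ratio. The lSO
#' whisker's means are shifted (slightly longer, markedly thinner) so
#' its configured mean ratio is the maximum on the pad.
#'
#' @param cfg A [sim_config()].
#' @param layout Pad layout giving the whisker set.
#' @return A data frame (`whisker_id`, `rat`, `length_mm`,
#'   `diameter_um`, `aperture_deg`, `ratio`) with one row per whisker
#'   per replicate; `ratio` is length/diameter after unit matching
#'   (dimensionless).
#' @export
gen_morphology_table <- function(cfg, layout = pad_layout()) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$morph_params
  ids <- layout$whisker_id
  nrep <- m$n_per_whisker
  n <- length(ids) * nrep
  r <- m$r_length_diameter
  ra <- m$r_aperture_ratio
  with_sim_rng(cfg, 22L, {
    zl <- stats::rnorm(n)
    zd <- r * zl + sqrt(1 - r^2) * stats::rnorm(n)
    # standardized ratio proxy: difference of the standardized coordinates
    zp <- (zl - zd) / sqrt(2 * (1 - r))
    za <- ra * zp + sqrt(1 - ra^2) * stats::rnorm(n)
    w <- rep(ids, each = nrep)
    is_lso <- w == "lSO"
    mu_l <- rep(m$mean_length, n) + ifelse(is_lso, m$lso_length_shift, 0)
    mu_d <- rep(m$mean_diameter, n) * ifelse(is_lso, m$lso_diameter_scale, 1)
    len <- pmax(mu_l + m$sd_length * zl, 0.5)
    dia <- pmax(mu_d + m$sd_diameter * zd, 5)
    mu_a <- rep(m$mean_aperture, n) + ifelse(is_lso, m$lso_aperture_shift, 0)
    ap <- pmin(pmax(mu_a + m$sd_aperture * za, 0), 359.9)
    data.frame(
      whisker_id = w,
      rat = rep(seq_len(nrep), times = length(ids)),
      length_mm = len,
      diameter_um = dia,
      aperture_deg = ap,
      ratio = morph_ratio(len, dia),
      stringsAsFactors = FALSE
    )
  })
}

#' Length/base-diameter ratio
#'
#' Dimensionless ratio of whisker length (mm) to base diameter (um),
#' after converting the diameter to mm.
#'
#' @param length_mm Whisker length in mm.
#' @param diameter_um Base diameter in um.
#' @return `length_mm / (diameter_um / 1000)`.
#' @export
morph_ratio <- function(length_mm, diameter_um) {
  if (any(length_mm <= 0) || any(diameter_um <= 0)) {
    stop("lengths and diameters must be strictly positive")
  }
  length_mm / (diameter_um / 1000)
}

#' Generate spike trains and a wind-epoch schedule
#'
#' Builds a balanced randomized sequence of low-wind, high-wind and
#' no-wind blocks (equal counts, shuffled order, fixed duration and
#' inter-block gap), then simulates every unit as an inhomogeneous
#' Poisson process: null units fire at the constant baseline rate;
#' excited units multiply the baseline by the per-second gain profile
#' during post-onset seconds 1-4 of wind epochs; inhibited units divide
#' by it. Per-region attenuation scales gain deviations from 1, so one
#' region can respond strongly and the other weakly.
#'
#' @param cfg A [sim_config()].
#' @return List with `units` (list of [unit_spike_train()] objects,
#'   each carrying a `true_class` attribute) and `epochs`
#'   (a [wind_epoch_series()] of the wind blocks).
#' @export
gen_spike_trains <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  e <- cfg$ephys_params
  ep <- cfg$epoch_params
  with_sim_rng(cfg, 33L, {
    conds <- sample(rep(c(ep$speeds, 0), each = ep$n_per_speed))
    starts <- ep$gap_s + (seq_along(conds) - 1) * (ep$duration_s + ep$gap_s)
    total_t <- max(starts) + ep$duration_s + ep$gap_s
    wind <- conds > 0
    epochs <- wind_epoch_series(onset_s = starts[wind], speed_mps = conds[wind],
                                duration_s = ep$duration_s)

    # piecewise-constant gain segments: modulated seconds 1-4 of each
    # wind epoch, plus baseline stretches covering the rest
    on <- starts[wind]
    mod_start <- rep(on, each = 4) + rep(0:3, times = length(on))
    mod_gain <- rep(e$gain_profile, times = length(on))
    bounds <- sort(unique(c(0, mod_start, mod_start + 1, total_t)))
    seg_start <- bounds[-length(bounds)]
    seg_dur <- diff(bounds)
    seg_gain <- rep(1, length(seg_start))
    hit <- match(seg_start, mod_start)
    seg_gain[!is.na(hit)] <- mod_gain[hit[!is.na(hit)]]

    units <- list()
    uid <- 0L
    for (region in names(e$n_units)) {
      nu <- e$n_units[[region]]
      fr <- e$fractions[[region]]
      n_exc <- round(fr[["excited"]] * nu)
      n_inh <- round(fr[["inhibited"]] * nu)
      classes <- c(rep("excited", n_exc), rep("inhibited", n_inh),
                   rep("none", nu - n_exc - n_inh))
      att <- e$region_gain_atten[[region]]
      g_region <- 1 + att * (seg_gain - 1)
      for (k in seq_len(nu)) {
        uid <- uid + 1L
        mult <- switch(classes[k],
                       excited = g_region,
                       inhibited = 1 / pmax(g_region, 1e-12),
                       none = rep(1, length(seg_gain)))
        rate <- e$baseline_hz * mult
        counts <- stats::rpois(length(rate), rate * seg_dur)
        times <- rep(seg_start, counts) + stats::runif(sum(counts)) * rep(seg_dur, counts)
        ust <- unit_spike_train(
          unit_id = sprintf("%s_%03d", region, k),
          region = region,
          spike_times = sort(times)
        )
        attr(ust, "true_class") <- classes[k]
        units[[uid]] <- ust
      }
    }
    list(units = units, epochs = epochs)
  })
}

#' Generate a behavior trial table
#'
#' Draws one multinomial response (toward / away / none, relative to the
#' stimulus side) per trial, with the probability triple set by each
#' session's treatment label. Stimulus sides are balanced within each
#' session and shuffled. In a paired design every animal runs one
#' session under each of the two treatments.
#'
#' @param cfg A [sim_config()].
#' @param treatments Character: treatment label(s), matched against
#'   `names(cfg$behavior_params$probs)`. For unpaired designs each
#'   treatment gets its own cohort of `n_animals` animals (one session
#'   each); for paired designs give exactly two labels shared by one
#'   cohort.
#' @param paired Logical; if `TRUE`, each animal receives both
#'   treatments in two sessions.
#' @return A [behavior_trial_table()] data frame.
#' @export
gen_behavior_trials <- function(cfg, treatments = "hand", paired = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  b <- cfg$behavior_params
  if (b$n_animals < 1) stop("n_animals must be >= 1")
  missing_p <- setdiff(treatments, names(b$probs))
  if (length(missing_p)) {
    stop("no probability triple configured for treatment(s): ",
         paste(missing_p, collapse = ", "))
  }
  if (paired && length(treatments) != 2) {
    stop("paired designs need exactly two treatments")
  }
  nt <- b$trials_per_session
  # distinct RNG substream per design so repeated calls with different
  # treatment sets are statistically independent
  offset <- 400L + sum(utf8ToInt(paste(treatments, collapse = "|"))) %% 100L
  with_sim_rng(cfg, offset, {
    rows <- list()
    session <- function(animal, tr) {
      sides <- sample(rep(c("left", "right"), length.out = nt))
      p <- b$probs[[tr]]
      resp <- sample(c("toward", "away", "none"), nt, replace = TRUE, prob = p)
      stim <- if (tr %in% c("hand", "cardboard")) tr else "cardboard"
      data.frame(animal_id = animal, trial = seq_len(nt), side = sides,
                 stim_type = stim, treatment = tr, response = resp,
                 stringsAsFactors = FALSE)
    }
    if (paired) {
      for (a in seq_len(b$n_animals)) {
        for (tr in treatments) {
          rows[[length(rows) + 1L]] <- session(sprintf("rat%02d", a), tr)
        }
      }
    } else {
      a <- 0L
      for (tr in treatments) {
        for (k in seq_len(b$n_animals)) {
          a <- a + 1L
          rows[[length(rows) + 1L]] <- session(sprintf("rat%02d", a), tr)
        }
      }
    }
    behavior_trial_table(do.call(rbind, rows))
  })
}

#' Generate a wind-speed trace
#'
#' First-order exponential rise toward the commanded mean speed with
#' additive turbulence noise. The default time constant
#' `tau = 1.5 / log(5)` s places the noise-free 80%-of-mean crossing at
#' 1.5 s after onset, matching anemometer characterizations of fan
#' onset dynamics.
#'
#' @param cfg A [sim_config()].
#' @param mean_speed Steady-state speed, m/s (0 gives an identically
#'   zero trace).
#' @param duration_s Trace duration, s.
#' @param tau Rise time constant, s.
#' @param noise_sd Turbulence SD as a fraction of `mean_speed`.
#' @param dt Sample period, s.
#' @return Data frame (`t_s`, `speed_mps`) of class `wind_trace`.
#' @export
gen_wind_trace <- function(cfg, mean_speed, duration_s = 10,
                           tau = 1.5 / log(5), noise_sd = 0.1, dt = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  if (mean_speed < 0) stop("mean_speed must be >= 0")
  t <- seq(0, duration_s, by = dt)
  with_sim_rng(cfg, 55L, {
    v <- mean_speed * (1 - exp(-t / tau)) +
      stats::rnorm(length(t), 0, noise_sd * mean_speed)
    structure(data.frame(t_s = t, speed_mps = v),
              class = c("wind_trace", "data.frame"))
  })
}
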