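#' Configuration for the synthetic overnight generator
#'
#' The defaults are the study conditions the package calibrates against:
#' ~7 h of beat-by-beat recording at ~1 s beat intervals, per-night surge
#' counts Poisson-distributed with per-factor means 19.5 (sleep-apnea
#' related) and 16.4 (non-related), surge amplitudes Normal(26.0, 4.3) mmHg
#' truncated to \[15, 60\], and a baseline level of 122.2 mmHg so that the
#' mean surge peak lands at 122.2 + 26.0 = 148.2 mmHg.  Confusers are
#' sub-threshold surge-shaped bumps that exercise the classifier; artifacts
#' are short flagged spikes.
#'
#' @param duration_s Recording length, seconds.
#' @param mean_beat_interval_s Mean inter-beat interval, seconds.
#' @param beat_interval_jitter_sd SD of the inter-beat interval, seconds.
#' @param baseline_sbp_mmHg Baseline systolic level, mmHg.
#' @param drift_amplitude_mmHg Amplitude of the slow sinusoidal baseline
#'   drift, mmHg.
#' @param drift_period_s Period of the baseline drift, seconds.
#' @param beat_noise_sd_mmHg SD of per-beat measurement noise, mmHg.
#' @param sa_surge_rate Expected sleep-apnea-related surges per night.
#' @param nonsa_surge_rate Expected non-SA surges per night.
#' @param surge_count_dispersion Optional negative-binomial size parameter
#'   for the per-night surge counts; `NULL` (default) uses Poisson counts.
#' @param amplitude_mean,amplitude_sd Normal parameters of the planted surge
#'   amplitude, mmHg.
#' @param amplitude_min,amplitude_max Truncation bounds of the amplitude
#'   draw, mmHg; the lower bound must not fall below the detector's default
#'   minimum amplitude so that planted surges stay detectable by
#'   construction.
#' @param upward_duration_range Uniform bounds of the start-to-peak rise
#'   time, seconds.
#' @param downward_duration_range Uniform bounds of the peak-to-end fall
#'   time, seconds.
#' @param confuser_rate Expected sub-threshold confuser bumps per night.
#' @param confuser_amplitude_range Uniform bounds of confuser amplitude,
#'   mmHg.
#' @param artifact_rate Expected motion-artifact spikes per night.
#' @param artifact_magnitude_range Uniform bounds of the spike magnitude
#'   (either sign), mmHg.
#' @param artifact_len_range Integer bounds of the spike length, beats.
#' @param sa_event_lead_s Gap between the end of the triggering PSG event
#'   and the surge start, seconds.
#' @param psg_event_duration_range Uniform bounds of PSG event duration,
#'   seconds.
#' @param seed Default seed used when [generate_night()] is called without
#'   one.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_s = 25200,
                       mean_beat_interval_s = 1.0,
                       beat_interval_jitter_sd = 0.05,
                       baseline_sbp_mmHg = 122.2,
                       drift_amplitude_mmHg = 5,
                       drift_period_s = 5400,
                       beat_noise_sd_mmHg = 2.0,
                       sa_surge_rate = 19.5,
                       nonsa_surge_rate = 16.4,
                       surge_count_dispersion = NULL,
                       amplitude_mean = 26.0,
                       amplitude_sd = 4.3,
                       amplitude_min = 15,
                       amplitude_max = 60,
                       upward_duration_range = c(10, 40),
                       downward_duration_range = c(15, 60),
                       confuser_rate = 30,
                       confuser_amplitude_range = c(5, 12),
                       artifact_rate = 5,
                       artifact_magnitude_range = c(30, 80),
                       artifact_len_range = c(1, 3),
                       sa_event_lead_s = 10,
                       psg_event_duration_range = c(10, 60),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  rates <- c(cfg$sa_surge_rate, cfg$nonsa_surge_rate, cfg$confuser_rate,
             cfg$artifact_rate)
  if (any(rates < 0)) stop("all event rates must be >= 0")
  if (cfg$amplitude_min >= cfg$amplitude_max) {
    stop("amplitude truncation bounds must be ordered")
  }
  if (cfg$amplitude_min < detector_config()$min_amplitude_mmHg) {
    stop("amplitude_min below the detector's default minimum amplitude; ",
         "planted surges would be undetectable by construction")
  }
  for (r in list(cfg$upward_duration_range, cfg$downward_duration_range,
                 cfg$confuser_amplitude_range, cfg$psg_event_duration_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      stop("range parameters must be ordered positive pairs")
    }
  }
  cfg
}

# Raised-cosine surge template evaluated at times t for a surge starting at
# s with the given amplitude and rise/fall durations.  Smooth and unimodal,
# with an analytic apex at s + up.
surge_template <- function(t, s, amplitude, up, down) {
  out <- numeric(length(t))
  rise <- t >= s & t <= s + up
  fall <- t > s + up & t <= s + up + down
  out[rise] <- amplitude / 2 * (1 - cos(pi * (t[rise] - s) / up))
  out[fall] <- amplitude / 2 * (1 + cos(pi * (t[fall] - s - up) / down))
  out
}

# Draw from Normal(mean, sd) truncated to [lo, hi] by rejection.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Place n events of the given total durations so that their guarded
# intervals [start - pre_margin, end + post_margin] are pairwise disjoint
# and fall inside [lo, hi].  Up to `attempts` redraws per event.
place_events <- function(n, durations, lo, hi, pre_margin, post_margin,
                         attempts = 100) {
  starts <- numeric(0)
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(attempts)) {
      s <- runif(1, lo, hi - durations[i])
      iv <- c(s - pre_margin, s + durations[i] + post_margin)
      if (nrow(occupied) == 0 ||
          all(iv[2] < occupied[, 1] | iv[1] > occupied[, 2])) {
        occupied <- rbind(occupied, iv)
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("night too crowded: could not place event ", i)
  }
  starts
}

draw_count <- function(rate, dispersion) {
  if (rate == 0) return(0L)
  if (is.null(dispersion)) rpois(1, rate)
  else rnbinom(1, size = dispersion, mu = rate)
}

#' Generate one synthetic overnight recording
#'
#' Builds a beat-by-beat SBP series as baseline + slow sinusoidal drift +
#' planted raised-cosine surges + sub-threshold confuser bumps + per-beat
#' noise, then injects flagged artifact spikes.  Every planted surge is
#' annotated with exact start/peak/end beat indices (the peak index is the
#' maximum of the noise-free signal within the surge span, so annotations do
#' not chase noise).  Each SA-class surge is preceded by one PSG event
#' ending `sa_event_lead_s` before the surge start; non-SA surges have no
#' event nearby.  Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `series` ([beat_series()]), `labels`
#'   (`surge_annotations` with `source = "label"` and planted `sa_class`),
#'   and `events` (`psg_events`, possibly empty).
#' @export
generate_night <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  night_id <- sprintf("sim%04d", as.integer(seed))
  with_seed(seed, {
    # beat grid
    n_est <- ceiling(config$duration_s / config$mean_beat_interval_s * 1.1) + 50
    iv <- rnorm(n_est, config$mean_beat_interval_s,
                config$beat_interval_jitter_sd)
    iv <- pmax(iv, 0.3)
    tt <- cumsum(iv)
    tt <- tt[tt <= config$duration_s]
    n <- length(tt)

    phase <- runif(1, 0, 2 * pi)
    clean <- config$baseline_sbp_mmHg +
      config$drift_amplitude_mmHg * sin(2 * pi * tt / config$drift_period_s + phase)

    n_sa <- draw_count(config$sa_surge_rate, config$surge_count_dispersion)
    n_nonsa <- draw_count(config$nonsa_surge_rate, config$surge_count_dispersion)
    n_surge <- n_sa + n_nonsa
    n_conf <- draw_count(config$confuser_rate, NULL)
    n_art <- draw_count(config$artifact_rate, NULL)

    amp <- rnorm_trunc(n_surge, config$amplitude_mean, config$amplitude_sd,
                       config$amplitude_min, config$amplitude_max)
    up <- runif(n_surge, config$upward_duration_range[1],
                config$upward_duration_range[2])
    down <- runif(n_surge, config$downward_duration_range[1],
                  config$downward_duration_range[2])
    conf_amp <- runif(n_conf, config$confuser_amplitude_range[1],
                      config$confuser_amplitude_range[2])
    conf_up <- runif(n_conf, config$upward_duration_range[1],
                     config$upward_duration_range[2])
    conf_down <- runif(n_conf, config$downward_duration_range[1],
                       config$downward_duration_range[2])

    # The guard margin keeps one surge's PSG event (which may reach
    # sa_event_lead_s + max event duration before the start) out of every
    # other surge's association window.
    pre_margin <- config$sa_event_lead_s + config$psg_event_duration_range[2] + 10
    lo <- pre_margin + 60
    hi <- config$duration_s - 60
    starts <- place_events(n_surge + n_conf,
                           c(up + down, conf_up + conf_down),
                           lo, hi, pre_margin, 10)
    surge_start <- starts[seq_len(n_surge)]
    conf_start <- if (n_conf > 0) starts[n_surge + seq_len(n_conf)] else numeric(0)
    is_sa <- c(rep(TRUE, n_sa), rep(FALSE, n_nonsa))

    for (i in seq_len(n_surge)) {
      clean <- clean + surge_template(tt, surge_start[i], amp[i], up[i], down[i])
    }
    for (i in seq_len(n_conf)) {
      clean <- clean + surge_template(tt, conf_start[i], conf_amp[i],
                                      conf_up[i], conf_down[i])
    }

    # PSG events precede SA-class surges only
    if (n_sa > 0) {
      ev_end <- surge_start[is_sa] - config$sa_event_lead_s
      ev_dur <- runif(n_sa, config$psg_event_duration_range[1],
                      config$psg_event_duration_range[2])
      ev_kind <- sample(c("apnea", "hypopnea", "desaturation"), n_sa,
                        replace = TRUE)
      events <- psg_events(night_id, ev_kind, ev_end - ev_dur, ev_end)
      events <- events[order(events$start_s), , drop = FALSE]
      rownames(events) <- NULL
      class(events) <- c("psg_events", "data.frame")
    } else {
      events <- psg_events(character(0), character(0), numeric(0), numeric(0))
    }

    sbp <- clean + rnorm(n, 0, config$beat_noise_sd_mmHg)
    dbp <- sbp - 45 + rnorm(n, 0, 2)  # synthetic stand-in; no DBP dynamics
    quality <- rep("valid", n)

    # artifact spikes: short flagged excursions of either sign
    if (n_art > 0) {
      art_at <- sample(seq(10L, n - 10L), n_art)
      art_len <- sample(seq(config$artifact_len_range[1],
                            config$artifact_len_range[2]), n_art,
                        replace = TRUE)
      art_mag <- runif(n_art, config$artifact_magnitude_range[1],
                       config$artifact_magnitude_range[2]) *
        sample(c(-1, 1), n_art, replace = TRUE)
      for (i in seq_len(n_art)) {
        idx <- art_at[i]:min(art_at[i] + art_len[i] - 1L, n)
        sbp[idx] <- sbp[idx] + art_mag[i]
        quality[idx] <- "artifact"
      }
    }

    series <- beat_series(tt, sbp, dbp = dbp, quality = quality,
                          night_id = night_id)

    if (n_surge > 0) {
      # annotation landmarks live on valid beats only: an artifact spike on
      # a landmark would corrupt the planted geometry
      vi <- which(quality == "valid")
      start_idx <- vi[nearest_beat(tt[vi], surge_start)]
      end_idx <- vi[nearest_beat(tt[vi], surge_start + up + down)]
      peak_idx <- integer(n_surge)
      for (i in seq_len(n_surge)) {
        span <- vi[vi >= start_idx[i] & vi <= end_idx[i]]
        peak_idx[i] <- span[which.max(clean[span])]
      }
      labels <- surge_annotations(series, start_idx, peak_idx, end_idx,
                                  source = "label",
                                  sa_class = ifelse(is_sa, "sa", "non_sa"))
    } else {
      labels <- empty_annotations(night_id)
    }

    list(series = series, labels = labels, events = events)
  })
}

# Nearest beat index to each time (vectorized).
nearest_beat <- function(tt, t) {
  pos <- findInterval(t, tt, all.inside = TRUE)
  hi <- pmin(pos + 1L, length(tt))
  ifelse(abs(t - tt[pos]) <= abs(tt[hi] - t), pos, hi)
}

#' Derive intermittent cuff-style readings from a beat series
#'
#' Emulates every-30-minute cuff-oscillometric monitoring: one reading per
#' interval, computed as the median SBP of valid beats in a 60 s window
#' centered on the sample time (a cuff reading integrates over roughly that
#' long).  Windows containing no valid beat are skipped with a warning.
#'
#' @param series A [beat_series()].
#' @param interval_s Sampling interval, seconds.
#' @param window_s Averaging window width, seconds.
#' @return An [intermittent_series()].
#' @export
generate_intermittent <- function(series, interval_s = 1800, window_s = 60) {
  last_t <- series$time_s[n_beats(series)]
  if (last_t < interval_s) {
    stop("series shorter than one sampling interval")
  }
  k_max <- floor((last_t + window_s / 2) / interval_s)
  at <- seq_len(k_max) * interval_s
  vi <- valid_idx(series)
  vt <- series$time_s[vi]
  vs <- series$sbp[vi]
  keep <- logical(length(at))
  val <- numeric(length(at))
  for (i in seq_along(at)) {
    inwin <- vs[vt >= at[i] - window_s / 2 & vt <= at[i] + window_s / 2]
    if (length(inwin) == 0) {
      warning(sprintf("no valid beats in window at %.0f s; reading skipped",
                      at[i]))
    } else {
      keep[i] <- TRUE
      val[i] <- median(inwin)
    }
  }
  intermittent_series(at[keep], val[keep], night_id = series$night_id)
}
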