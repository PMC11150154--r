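#' Feature groups of the surge catalogue
#' @export
FEATURE_GROUPS <- c("reactivity", "recovery", "amplitude", "upward",
                    "downward", "whole")

# Catalogue definition: 6 groups x 8 features = 48, in fixed order.
.catalogue <- local({
  def <- rbind(
    c("react_onset_slope", "reactivity", "least-squares SBP slope over the first 5 beats of the rise (mmHg/s)"),
    c("react_diff_sd", "reactivity", "SD of successive SBP differences over [start, peak] (mmHg)"),
    c("react_max_accel", "reactivity", "maximum positive second difference of SBP in the rise (mmHg)"),
    c("react_time_to_25", "reactivity", "time from start to first beat at or above 25% amplitude (s)"),
    c("react_time_to_75", "reactivity", "time from start to first beat at or above 75% amplitude (s)"),
    c("react_t75_t25_ratio", "reactivity", "ratio of the 75% and 25% rise times"),
    c("react_n_reversals", "reactivity", "count of beat-to-beat SBP drops within the rise"),
    c("react_prestart_range", "reactivity", "SBP range of the stability window of valid beats ending at the start (mmHg)"),
    c("rec_onset_slope", "recovery", "least-squares SBP slope over the first 5 beats of the fall (mmHg/s)"),
    c("rec_diff_sd", "recovery", "SD of successive SBP differences over [peak, end] (mmHg)"),
    c("rec_max_decel", "recovery", "maximum negative second difference of SBP in the fall, sign-flipped (mmHg)"),
    c("rec_time_to_25", "recovery", "time from peak to first beat at or below peak minus 25% amplitude (s)"),
    c("rec_time_to_75", "recovery", "time from peak to first beat at or below peak minus 75% amplitude (s)"),
    c("rec_t75_t25_ratio", "recovery", "ratio of the 75% and 25% fall times"),
    c("rec_n_reversals", "recovery", "count of beat-to-beat SBP rises within the fall"),
    c("rec_undershoot", "recovery", "max(0, start SBP - end SBP) (mmHg)"),
    c("amplitude", "amplitude", "peak SBP minus start SBP (mmHg)"),
    c("peak_sbp", "amplitude", "SBP at the peak beat (mmHg)"),
    c("start_sbp", "amplitude", "SBP at the start beat (mmHg)"),
    c("end_sbp", "amplitude", "SBP at the end beat (mmHg)"),
    c("relative_amplitude_pct", "amplitude", "100 * amplitude / start SBP (%)"),
    c("max_beat_rise", "amplitude", "maximum single-beat SBP rise within [start, end] (mmHg)"),
    c("area_above_start", "amplitude", "trapezoid area of SBP above the start SBP over [start, end] (mmHg*s)"),
    c("peak_above_night_median", "amplitude", "peak SBP minus the night median of valid SBP (mmHg)"),
    c("up_duration_s", "upward", "time from start to peak (s)"),
    c("up_mean_slope", "upward", "amplitude / upward duration (mmHg/s)"),
    c("up_max_slope", "upward", "maximum beat-to-beat rise rate in the rise (mmHg/s)"),
    c("up_n_beats", "upward", "number of valid beats in [start, peak]"),
    c("up_frac_rising", "upward", "fraction of strictly rising beat-to-beat steps in the rise"),
    c("up_area_above_start", "upward", "trapezoid area above the start SBP over [start, peak] (mmHg*s)"),
    c("up_time_to_half", "upward", "time from start to first beat at or above 50% amplitude (s)"),
    c("up_ls_slope", "upward", "least-squares SBP slope over [start, peak] (mmHg/s)"),
    c("down_duration_s", "downward", "time from peak to end (s)"),
    c("down_mean_slope", "downward", "(peak SBP - end SBP) / downward duration (mmHg/s)"),
    c("down_max_fall", "downward", "maximum beat-to-beat fall rate in the fall (mmHg/s)"),
    c("down_n_beats", "downward", "number of valid beats in [peak, end]"),
    c("down_frac_falling", "downward", "fraction of strictly falling beat-to-beat steps in the fall"),
    c("down_area_above_start", "downward", "trapezoid area above the start SBP over [peak, end] (mmHg*s)"),
    c("down_time_to_half", "downward", "time from peak to first beat at or below peak minus 50% amplitude (s)"),
    c("down_ls_slope", "downward", "least-squares SBP slope over [peak, end] (mmHg/s)"),
    c("whole_duration_s", "whole", "time from start to end (s)"),
    c("whole_up_down_ratio", "whole", "upward duration / downward duration"),
    c("whole_n_beats", "whole", "number of valid beats in [start, end]"),
    c("whole_mean_sbp", "whole", "mean SBP over [start, end] (mmHg)"),
    c("whole_sd_sbp", "whole", "sample SD of SBP over [start, end] (mmHg)"),
    c("whole_symmetry", "whole", "min(up, down) / max(up, down) durations"),
    c("whole_dur_above_half", "whole", "total time with SBP at or above 50% amplitude (s)"),
    c("whole_mean_beat_interval", "whole", "mean inter-beat interval over the segment (s)")
  )
  data.frame(name = def[, 1], group = def[, 2], definition = def[, 3],
             stringsAsFactors = FALSE)
})

#' The surge feature catalogue
#'
#' Exactly 48 named features in six groups of eight, each computable from
#' the (start, peak, end) points, the SBP beats between them, and the
#' pre-start stability window (plus, for one level feature, the night
#' median).  The group structure mirrors a clinician's reading of a surge:
#' how sharply it reacts, how it recovers, how large it is, and the rising,
#' falling and whole-episode durations.
#'
#' @return A data frame with columns `name`, `group`, `definition`, in
#'   stable catalogue order (group order, then index).
#' @export
feature_catalogue <- function() .catalogue

ls_slope <- function(t, y) {
  if (length(t) < 2) return(0)
  t0 <- t - mean(t)
  d <- sum(t0^2)
  if (d == 0) return(0)
  sum(t0 * (y - mean(y))) / d
}

trapezoid <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

# Time from t[1] until y first crosses `thr` in direction `dir` ("ge"/"le");
# NA if never crossed.
time_to_cross <- function(t, y, thr, dir) {
  hit <- if (dir == "ge") which(y >= thr) else which(y <= thr)
  if (length(hit) == 0) return(NA_real_)
  t[hit[1]] - t[1]
}

#' Extract the 48-feature vectors of surge candidates
#'
#' Every catalogue feature is computed from the valid beats within
#' `[start, end]` (the start, peak and end beats are always included), plus
#' the pre-start stability window and the night median for the two context
#' features.  Deterministic; all values finite for any annotation meeting
#' its invariants.
#'
#' @param series A [beat_series()].
#' @param cand A `surge_annotations` data frame (candidates, detections or
#'   labels).
#' @param stability_beats Length of the pre-start window used by the
#'   baseline-range feature, beats.
#' @return A numeric matrix with one row per annotation and 48 named
#'   columns in catalogue order.
#' @export
extract_features <- function(series, cand, stability_beats = 10) {
  cat_names <- feature_catalogue()$name
  out <- matrix(NA_real_, nrow = nrow(cand), ncol = length(cat_names),
                dimnames = list(NULL, cat_names))
  if (nrow(cand) == 0) return(out)
  night_median <- median(series$sbp[series$quality == "valid"])
  for (i in seq_len(nrow(cand))) {
    out[i, ] <- features_one(series, cand$start_idx[i], cand$peak_idx[i],
                             cand$end_idx[i], night_median, stability_beats)
  }
  out
}

features_one <- function(series, s, p, e, night_median, stability_beats) {
  idx <- sort(unique(c(s, p, e,
                       intersect(s:e, which(series$quality == "valid")))))
  if (length(idx) < 3) stop("degenerate segment: fewer than 3 beats")
  t <- series$time_s[idx]
  y <- series$sbp[idx]
  ip <- match(p, idx)
  y_s <- series$sbp[s]; y_p <- series$sbp[p]; y_e <- series$sbp[e]
  amp <- y_p - y_s
  t_up <- t[1:ip]; y_up <- y[1:ip]
  t_dn <- t[ip:length(t)]; y_dn <- y[ip:length(y)]
  up_dur <- t_up[length(t_up)] - t_up[1]
  dn_dur <- t_dn[length(t_dn)] - t_dn[1]
  d_up <- diff(y_up); d_dn <- diff(y_dn)

  # pre-start stability window: up to stability_beats valid beats ending at s
  pre <- which(series$quality == "valid" & seq_along(series$sbp) <= s)
  pre <- tail(pre, stability_beats)
  pre_range <- if (length(pre) >= 2) diff(range(series$sbp[pre])) else 0

  t25 <- time_to_cross(t_up, y_up, y_s + 0.25 * amp, "ge")
  t75 <- time_to_cross(t_up, y_up, y_s + 0.75 * amp, "ge")
  r25 <- time_to_cross(t_dn, y_dn, y_p - 0.25 * amp, "le")
  r75 <- time_to_cross(t_dn, y_dn, y_p - 0.75 * amp, "le")
  # rise thresholds are always crossed (the peak attains full amplitude);
  # fall thresholds may not be (fallback ends) and are capped at the fall span
  if (is.na(r25)) r25 <- dn_dur
  if (is.na(r75)) r75 <- dn_dur

  half <- y_s + 0.5 * amp
  above <- y >= half
  dur_above <- sum(diff(t)[above[-length(above)] & above[-1]])

  c(
    react_onset_slope = ls_slope(head(t_up, 5), head(y_up, 5)),
    react_diff_sd = if (length(d_up) >= 2) sd(d_up) else 0,
    react_max_accel = if (length(d_up) >= 2) max(diff(d_up)) else 0,
    react_time_to_25 = t25,
    react_time_to_75 = t75,
    react_t75_t25_ratio = if (t25 > 0) t75 / t25 else 1,
    react_n_reversals = sum(d_up < 0),
    react_prestart_range = pre_range,
    rec_onset_slope = ls_slope(head(t_dn, 5), head(y_dn, 5)),
    rec_diff_sd = if (length(d_dn) >= 2) sd(d_dn) else 0,
    rec_max_decel = if (length(d_dn) >= 2) max(-diff(d_dn)) else 0,
    rec_time_to_25 = r25,
    rec_time_to_75 = r75,
    rec_t75_t25_ratio = if (r25 > 0) r75 / r25 else 1,
    rec_n_reversals = sum(d_dn > 0),
    rec_undershoot = max(0, y_s - y_e),
    amplitude = amp,
    peak_sbp = y_p,
    start_sbp = y_s,
    end_sbp = y_e,
    relative_amplitude_pct = 100 * amp / y_s,
    max_beat_rise = max(diff(y)),
    area_above_start = trapezoid(t, y - y_s),
    peak_above_night_median = y_p - night_median,
    up_duration_s = up_dur,
    up_mean_slope = amp / up_dur,
    up_max_slope = max(d_up / diff(t_up)),
    up_n_beats = length(y_up),
    up_frac_rising = mean(d_up > 0),
    up_area_above_start = trapezoid(t_up, y_up - y_s),
    up_time_to_half = time_to_cross(t_up, y_up, y_s + 0.5 * amp, "ge"),
    up_ls_slope = ls_slope(t_up, y_up),
    down_duration_s = dn_dur,
    down_mean_slope = (y_p - y_e) / dn_dur,
    down_max_fall = max(-d_dn / diff(t_dn)),
    down_n_beats = length(y_dn),
    down_frac_falling = mean(d_dn < 0),
    down_area_above_start = trapezoid(t_dn, y_dn - y_s),
    down_time_to_half = {
      th <- time_to_cross(t_dn, y_dn, y_p - 0.5 * amp, "le")
      if (is.na(th)) dn_dur else th
    },
    down_ls_slope = ls_slope(t_dn, y_dn),
    whole_duration_s = t[length(t)] - t[1],
    whole_up_down_ratio = up_dur / dn_dur,
    whole_n_beats = length(y),
    whole_mean_sbp = mean(y),
    whole_sd_sbp = sd(y),
    whole_symmetry = min(up_dur, dn_dur) / max(up_dur, dn_dur),
    whole_dur_above_half = dur_above,
    whole_mean_beat_interval = mean(diff(t))
  )
}
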