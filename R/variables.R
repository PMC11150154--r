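#' Conventional nocturnal BP variables from intermittent readings
#'
#' The four standard summaries of every-30-minute cuff SBP: mean, sample
#' standard deviation, coefficient of variation (100*SD/mean, %) and
#' average real variability (mean absolute successive difference).
#'
#' @param readings An [intermittent_series()] with at least 2 readings.
#' @param population_sd Use the population (divide by n) instead of the
#'   sample (n-1) SD.
#' @return A `conventional_variables` list: `mean_sbp`, `sd_sbp`,
#'   `cv_sbp_percent`, `arv_sbp`.
#' @export
conventional_variables <- function(readings, population_sd = FALSE) {
  x <- readings$sbp
  n <- length(x)
  if (n < 2) stop("at least 2 readings are required")
  m <- mean(x)
  s <- sd(x)
  if (population_sd) s <- s * sqrt((n - 1) / n)
  structure(list(
    mean_sbp = m,
    sd_sbp = s,
    cv_sbp_percent = if (m > 0) 100 * s / m else NA_real_,
    arv_sbp = mean(abs(diff(x)))
  ), class = "conventional_variables")
}

#' Per-surge severity measures
#'
#' One row per surge: peak SBP (highest beat value is the annotated peak
#' beat), amplitude (peak SBP minus start SBP), and the upward, downward and
#' total durations.
#'
#' @param series A [beat_series()].
#' @param surges A `surge_annotations` data frame.
#' @return A data frame with columns `night_id`, `sa_class`, `peak`,
#'   `amplitude`, `upward_duration_s`, `downward_duration_s`,
#'   `total_duration_s`.
#' @export
surge_measures <- function(series, surges) {
  validate_annotations(surges, series)
  data.frame(
    night_id = surges$night_id,
    sa_class = surges$sa_class,
    peak = series$sbp[surges$peak_idx],
    amplitude = series$sbp[surges$peak_idx] - series$sbp[surges$start_idx],
    upward_duration_s = surges$peak_s - surges$start_s,
    downward_duration_s = surges$end_s - surges$peak_s,
    total_duration_s = surges$end_s - surges$start_s,
    stringsAsFactors = FALSE
  )
}

summarize_measures <- function(m) {
  if (nrow(m) == 0) {
    return(list(n_surges = 0L, mean_peak = NA_real_, max_peak = NA_real_,
                mean_amplitude = NA_real_, mean_upward_duration_s = NA_real_,
                mean_downward_duration_s = NA_real_,
                mean_total_duration_s = NA_real_))
  }
  list(n_surges = nrow(m),
       mean_peak = mean(m$peak),
       max_peak = max(m$peak),
       mean_amplitude = mean(m$amplitude),
       mean_upward_duration_s = mean(m$upward_duration_s),
       mean_downward_duration_s = mean(m$downward_duration_s),
       mean_total_duration_s = mean(m$total_duration_s))
}

#' Night-level surge variables
#'
#' Summaries of the per-surge severity measures: count, mean and maximum
#' peak SBP, mean amplitude and mean durations, overall and split by
#' sleep-apnea class.  Empty classes report a zero count and `NA` means
#' (never zero, which would silently bias cohort summaries).
#'
#' @param series A [beat_series()].
#' @param surges A `surge_annotations` data frame (detections or labels,
#'   optionally classified by [categorize_sa()]).
#' @return A `surge_variables` list with the overall summary plus `sa` and
#'   `non_sa` sub-lists of the same shape.
#' @export
surge_variables <- function(series, surges) {
  m <- surge_measures(series, surges)
  out <- summarize_measures(m)
  out$sa <- summarize_measures(m[m$sa_class == "sa", , drop = FALSE])
  out$non_sa <- summarize_measures(m[m$sa_class == "non_sa", , drop = FALSE])
  structure(out, class = "surge_variables")
}

#' Attribute surges to sleep apnea using PSG events
#'
#' A surge is SA-related iff some apnea, hypopnea or desaturation event
#' overlaps the window from `window_s` seconds before the surge start up to
#' the surge peak (interval endpoints inclusive); otherwise non-SA-related.
#' Input order is preserved and any previous `sa_class` is overwritten.
#'
#' @param surges A `surge_annotations` data frame.
#' @param events A `psg_events` data frame (may be empty).
#' @param window_s Association lookback before the surge start, seconds.
#' @return The annotations with `sa_class` set to `"sa"` or `"non_sa"`.
#' @export
categorize_sa <- function(surges, events, window_s = 30) {
  if (nrow(surges) == 0) return(surges)
  cls <- vapply(seq_len(nrow(surges)), function(i) {
    lo <- surges$start_s[i] - window_s
    hi <- surges$peak_s[i]
    hit <- nrow(events) > 0 &&
      any(events$start_s <= hi & events$end_s >= lo)
    if (hit) "sa" else "non_sa"
  }, character(1))
  surges$sa_class <- cls
  surges
}
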