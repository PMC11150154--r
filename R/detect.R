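#' Configuration for surge candidate detection
#'
#' Candidate peaks are strict local maxima of the valid-beat SBP within a
#' centered sliding time window.  The start point is located where stable
#' pre-surge SBP ends; the end point is where SBP has decayed by
#' `decay_fraction` of the amplitude (peak SBP minus start SBP).  The decay
#' fraction of 0.75 is the defining constant of the end point; the window,
#' stability and lookback spans are engineering defaults sized so that a
#' surge lasting several tens of seconds fits well inside them, and all are
#' exposed here.
#'
#' @param window_s Sliding-window width for the local-maximum test, seconds.
#' @param min_amplitude_mmHg Minimum candidate amplitude (prominence over
#'   the start SBP), mmHg.
#' @param stability_beats Number of trailing valid beats forming the
#'   stability window for start detection.
#' @param stability_range_mmHg Maximum SBP range within a stable window,
#'   mmHg.
#' @param max_lookback_s How far before the peak the start may be sought,
#'   seconds.
#' @param decay_fraction Fraction of the amplitude that must be lost at the
#'   end point, in (0, 1).
#' @param max_recovery_s How far after the peak the end may be sought,
#'   seconds.
#' @param gap_split_s Inter-beat time gap above which the recording is split
#'   into independently processed segments, seconds.
#' @return A `detector_config` list.
#' @export
detector_config <- function(window_s = 60,
                            min_amplitude_mmHg = 15,
                            stability_beats = 10,
                            stability_range_mmHg = 5,
                            max_lookback_s = 120,
                            decay_fraction = 0.75,
                            max_recovery_s = 180,
                            gap_split_s = 10) {
  cfg <- structure(as.list(environment()), class = "detector_config")
  if (!(cfg$decay_fraction > 0 && cfg$decay_fraction < 1)) {
    stop("decay_fraction must lie in (0, 1)")
  }
  if (any(c(cfg$window_s, cfg$max_lookback_s, cfg$max_recovery_s,
            cfg$gap_split_s) <= 0)) {
    stop("all durations must be > 0")
  }
  if (cfg$min_amplitude_mmHg < 0) stop("min_amplitude_mmHg must be >= 0")
  if (cfg$stability_beats < 2) stop("stability_beats must be >= 2")
  cfg
}

# Per-valid-beat view of a series: original indices, times, SBP, and the
# segment id (recordings are split where consecutive valid beats are more
# than gap_split_s apart).
valid_view <- function(series, gap_split_s) {
  vi <- valid_idx(series)
  vt <- series$time_s[vi]
  seg <- if (length(vt) > 1) cumsum(c(0L, as.integer(diff(vt) > gap_split_s)))
         else rep(0L, length(vt))
  list(idx = vi, t = vt, sbp = series$sbp[vi], seg = seg)
}

#' Find candidate surge peaks by sliding-window local maxima
#'
#' A valid beat is returned iff its SBP is the maximum over the valid beats
#' within the centered time window, no earlier in-window beat attains the
#' same value (so a plateau yields exactly its earliest beat), and at least
#' one in-window beat lies strictly below it (so a constant stretch yields
#' nothing).  Artifact and gap beats are transparent; the window never
#' crosses a segment split.
#'
#' @param series A [beat_series()].
#' @param config A [detector_config()].
#' @return Strictly increasing integer vector of beat indices.
#' @export
find_candidate_peaks <- function(series, config = detector_config()) {
  validate_beat_series(series)
  v <- valid_view(series, config$gap_split_s)
  nv <- length(v$idx)
  if (nv == 0) return(integer(0))
  if (diff(range(series$time_s)) < config$window_s) {
    warning("series shorter than the sliding window; no candidates")
    return(integer(0))
  }
  half <- config$window_s / 2
  # window bounds in valid-beat positions
  lo <- findInterval(v$t - half, v$t, left.open = TRUE) + 1L
  hi <- findInterval(v$t + half, v$t)
  # segment bounds
  seg_first <- match(v$seg, v$seg)
  seg_last <- nv + 1L - match(v$seg, rev(v$seg))
  lo <- pmax(lo, seg_first)
  hi <- pmin(hi, seg_last)
  # prefilter: weak local maximum vs immediate in-segment neighbours,
  # strictly above the previous one (plateau -> earliest beat survives)
  prev_ok <- c(TRUE, v$sbp[-1] > v$sbp[-nv]) | seg_first == seq_len(nv)
  next_ok <- c(v$sbp[-nv] >= v$sbp[-1], TRUE) | seg_last == seq_len(nv)
  cand <- which(prev_ok & next_ok)
  out <- integer(0)
  for (j in cand) {
    w <- v$sbp[lo[j]:hi[j]]
    m <- max(w)
    if (v$sbp[j] < m) next
    rel <- j - lo[j] + 1L
    if (any(w[seq_len(rel - 1L)] == m)) next   # earlier beat attains the max
    if (all(w >= m)) next                      # flat window: no maximum
    out <- c(out, v$idx[j])
  }
  out
}

#' Locate the start point of a surge candidate
#'
#' Walks backward from the peak looking for the end of stable pre-surge
#' SBP: the latest valid beat `s` whose trailing window of
#' `stability_beats` valid beats has range at most `stability_range_mmHg`
#' and sits more than one stability range below the peak (so the flat apex
#' of a slow surge is not mistaken for baseline).  The returned beat is then
#' backed up along any strictly decreasing run, so the start lands at the
#' stable level rather than partway up a gentle rise.  If no stable window
#' exists within `max_lookback_s`, the beat of minimum SBP in the lookback
#' is returned and flagged as a fallback (attribute `"fallback"`).
#'
#' @param series A [beat_series()].
#' @param peak Beat index of a candidate peak (a valid beat).
#' @param config A [detector_config()].
#' @return A beat index with logical attribute `"fallback"`.
#' @export
locate_start <- function(series, peak, config = detector_config()) {
  v <- valid_view(series, config$gap_split_s)
  p <- match(peak, v$idx)
  if (is.na(p)) stop("peak must be a valid beat")
  seg0 <- v$seg[p]
  lb_t <- v$t[p] - config$max_lookback_s
  first <- p
  while (first > 1 && v$seg[first - 1L] == seg0 && v$t[first - 1L] >= lb_t) {
    first <- first - 1L
  }
  if (first == p) stop("no valid beats before peak within lookback")
  sb <- config$stability_beats
  for (s in seq(p - 1L, first, by = -1L)) {
    w0 <- s - sb + 1L
    if (w0 < first) break
    w <- v$sbp[w0:s]
    if (max(w) - min(w) <= config$stability_range_mmHg &&
        v$sbp[p] - max(w) > config$stability_range_mmHg) {
      r <- s
      while (r > first && v$sbp[r - 1L] < v$sbp[r]) r <- r - 1L
      return(structure(v$idx[r], fallback = FALSE))
    }
  }
  span <- first:(p - 1L)
  mn <- min(v$sbp[span])
  r <- span[max(which(v$sbp[span] == mn))]  # latest minimum
  structure(v$idx[r], fallback = TRUE)
}

#' Locate the end point of a surge candidate
#'
#' The end is the first valid beat after the peak whose SBP has decayed by
#' `decay_fraction` of the amplitude, i.e. SBP at or below
#' `sbp[peak] - decay_fraction * (sbp[peak] - sbp[start])`.  If no beat
#' within `max_recovery_s` crosses that level, the beat of minimum SBP in
#' the span is returned and flagged as a fallback.
#'
#' @param series A [beat_series()].
#' @param start,peak Beat indices with `start < peak` and positive
#'   amplitude.
#' @param config A [detector_config()].
#' @return A beat index with logical attribute `"fallback"`.
#' @export
locate_end <- function(series, start, peak, config = detector_config()) {
  stopifnot(start < peak)
  amplitude <- series$sbp[peak] - series$sbp[start]
  if (amplitude <= 0) stop("amplitude must be positive")
  v <- valid_view(series, config$gap_split_s)
  p <- match(peak, v$idx)
  if (is.na(p)) stop("peak must be a valid beat")
  seg0 <- v$seg[p]
  last <- p
  while (last < length(v$idx) && v$seg[last + 1L] == seg0 &&
         v$t[last + 1L] - v$t[p] <= config$max_recovery_s) {
    last <- last + 1L
  }
  if (last == p) stop("truncated candidate: peak at final beat")
  thr <- series$sbp[peak] - config$decay_fraction * amplitude
  span <- (p + 1L):last
  crossed <- which(v$sbp[span] <= thr)
  if (length(crossed)) {
    return(structure(v$idx[span[crossed[1]]], fallback = FALSE))
  }
  r <- span[which.min(v$sbp[span])]
  structure(v$idx[r], fallback = TRUE)
}

#' Detect surge candidates in a night
#'
#' Composes [find_candidate_peaks()], [locate_start()] and [locate_end()],
#' then discards candidates below the minimum amplitude, candidates whose
#' fallback start/end swallowed an adjacent candidate's peak, and resolves
#' residual interval overlaps by clipping starts at the previous candidate's
#' end (re-checking the amplitude).  Deterministic.
#'
#' @param series A [beat_series()].
#' @param config A [detector_config()].
#' @return A `surge_annotations` data frame with `source = "candidate"` and
#'   an extra `amplitude_mmHg` column.
#' @export
detect_candidates <- function(series, config = detector_config()) {
  peaks <- find_candidate_peaks(series, config)
  if (length(peaks) == 0) return(empty_annotations(series$night_id))
  rows <- list()
  for (pk in peaks) {
    st <- tryCatch(locate_start(series, pk, config), error = function(e) NULL)
    if (is.null(st)) next
    en <- tryCatch(locate_end(series, st, pk, config), error = function(e) NULL)
    if (is.null(en)) next
    amp <- series$sbp[pk] - series$sbp[st]
    if (amp < config$min_amplitude_mmHg) next
    rows[[length(rows) + 1L]] <- list(
      start = as.integer(st), peak = pk, end = as.integer(en), amp = amp,
      fb_start = attr(st, "fallback"), fb_end = attr(en, "fallback")
    )
  }
  if (length(rows) == 0) return(empty_annotations(series$night_id))
  all_peaks <- vapply(rows, `[[`, integer(1), "peak")
  # fallback intervals that contain another candidate's peak are unreliable
  keep <- vapply(rows, function(r) {
    others <- setdiff(all_peaks, r$peak)
    if (r$fb_start && any(others >= r$start & others < r$peak)) return(FALSE)
    if (r$fb_end && any(others > r$peak & others <= r$end)) return(FALSE)
    TRUE
  }, logical(1))
  rows <- rows[keep]
  if (length(rows) == 0) return(empty_annotations(series$night_id))
  # resolve residual overlaps: clip at the previous kept end
  kept <- list()
  prev_end <- -1L
  for (r in rows) {
    if (r$start < prev_end) {
      r$start <- prev_end
      if (r$start >= r$peak) next
      r$amp <- series$sbp[r$peak] - series$sbp[r$start]
      if (r$amp < config$min_amplitude_mmHg) next
    }
    kept[[length(kept) + 1L]] <- r
    prev_end <- r$end
  }
  if (length(kept) == 0) return(empty_annotations(series$night_id))
  ann <- surge_annotations(
    series,
    start_idx = vapply(kept, `[[`, integer(1), "start"),
    peak_idx = vapply(kept, `[[`, integer(1), "peak"),
    end_idx = vapply(kept, `[[`, integer(1), "end"),
    source = "candidate"
  )
  ann$amplitude_mmHg <- series$sbp[ann$peak_idx] - series$sbp[ann$start_idx]
  ann
}
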