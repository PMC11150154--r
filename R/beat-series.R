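#' Quality flag vocabulary for beat-by-beat recordings
#'
#' Every beat carries one flag: `"valid"` (usable pressure value),
#' `"artifact"` (motion or sensor spike, value retained but excluded from all
#' algorithmic windows) or `"gap"` (placeholder inside a signal dropout).
#' Unknown strings are rejected, never silently mapped.
#'
#' @export
QUALITY_LEVELS <- c("valid", "artifact", "gap")

#' Construct a beat-by-beat blood pressure series
#'
#' A `beat_series` holds one overnight recording: one systolic (and
#' optionally diastolic) pressure per cardiac beat, with a per-beat quality
#' flag.  It is the substrate of candidate detection and of every surge
#' variable.
#'
#' @param time_s Numeric vector, seconds from recording start; strictly
#'   increasing.
#' @param sbp Systolic BP per beat, mmHg.  Valid beats must lie in
#'   \[30, 300\]; flagged beats may fall outside.
#' @param dbp Optional diastolic BP per beat, mmHg; where present and the
#'   beat is valid it must be below `sbp`.
#' @param quality Per-beat flag, one of [QUALITY_LEVELS]; defaults to all
#'   `"valid"`.
#' @param night_id Identifier of the recording night.
#' @return An object of class `beat_series`: a list with elements
#'   `night_id`, `time_s`, `sbp`, `dbp` (possibly `NULL`) and `quality`.
#' @examples
#' bs <- beat_series(time_s = 0:9, sbp = rep(120, 10))
#' n_beats(bs)
#' @export
beat_series <- function(time_s, sbp, dbp = NULL, quality = NULL,
                        night_id = "night") {
  time_s <- as.numeric(time_s)
  sbp <- as.numeric(sbp)
  if (is.null(quality)) quality <- rep("valid", length(time_s))
  quality <- as.character(quality)
  if (!is.null(dbp)) dbp <- as.numeric(dbp)
  x <- structure(
    list(night_id = as.character(night_id)[1], time_s = time_s, sbp = sbp,
         dbp = dbp, quality = quality),
    class = "beat_series"
  )
  validate_beat_series(x)
  x
}

#' Validate a beat series against its invariants
#'
#' Checks equal lengths (at least 2 beats), strictly increasing time,
#' systolic range on valid beats, SBP > DBP where both are present, and the
#' quality vocabulary.  Errors name the first offending row (1-based).
#'
#' @param x A [beat_series()] object.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_beat_series <- function(x) {
  stopifnot(inherits(x, "beat_series"))
  n <- length(x$time_s)
  if (n < 2) stop("beat_series must contain at least 2 beats")
  if (length(x$sbp) != n || length(x$quality) != n ||
      (!is.null(x$dbp) && length(x$dbp) != n)) {
    stop("beat_series fields have unequal lengths")
  }
  bad_q <- which(!x$quality %in% QUALITY_LEVELS)
  if (length(bad_q)) {
    stop(sprintf("unknown quality flag '%s' at row %d",
                 x$quality[bad_q[1]], bad_q[1]))
  }
  dt <- diff(x$time_s)
  if (anyNA(x$time_s) || any(dt <= 0)) {
    i <- if (anyNA(x$time_s)) which(is.na(x$time_s))[1] else which(dt <= 0)[1] + 1L
    stop(sprintf("time_s not strictly increasing at row %d", i))
  }
  valid <- x$quality == "valid"
  bad <- which(valid & (is.na(x$sbp) | x$sbp < 30 | x$sbp > 300))
  if (length(bad)) {
    stop(sprintf("sbp %.1f outside [30, 300] on valid row %d",
                 x$sbp[bad[1]], bad[1]))
  }
  if (!is.null(x$dbp)) {
    bad <- which(valid & !is.na(x$dbp) & x$dbp >= x$sbp)
    if (length(bad)) {
      stop(sprintf("dbp >= sbp on valid row %d", bad[1]))
    }
  }
  invisible(TRUE)
}

#' Number of beats in a series
#' @param x A [beat_series()].
#' @return Integer beat count.
#' @export
n_beats <- function(x) length(x$time_s)

#' @export
print.beat_series <- function(x, ...) {
  dur <- diff(range(x$time_s))
  cat(sprintf("<beat_series '%s': %d beats over %.0f s, %d valid>\n",
              x$night_id, n_beats(x), dur, sum(x$quality == "valid")))
  invisible(x)
}

# Indices of valid beats.
valid_idx <- function(series) which(series$quality == "valid")

#' Construct a set of surge annotations
#'
#' Annotations describe surge episodes as (start, peak, end) beat-index
#' triples against one night's [beat_series()].  Expert labels, algorithm
#' detections and raw candidates all share this shape, distinguished by
#' `source`.  Times in seconds are derived from the series so that files and
#' matching can work in seconds while the algorithms use indices.
#'
#' @param series The [beat_series()] the indices refer to.
#' @param start_idx,peak_idx,end_idx Integer beat indices (1-based),
#'   `start_idx < peak_idx < end_idx`.
#' @param source One of `"label"`, `"detection"`, `"candidate"` (recycled).
#' @param sa_class One of `"sa"`, `"non_sa"`, `"unassigned"` (recycled).
#' @return A `surge_annotations` data frame with columns `night_id`,
#'   `start_idx`, `peak_idx`, `end_idx`, `start_s`, `peak_s`, `end_s`,
#'   `source`, `sa_class`, sorted by start time.
#' @export
surge_annotations <- function(series, start_idx, peak_idx, end_idx,
                              source = "label", sa_class = "unassigned") {
  n <- length(start_idx)
  ann <- data.frame(
    night_id = rep(series$night_id, n),
    start_idx = as.integer(start_idx),
    peak_idx = as.integer(peak_idx),
    end_idx = as.integer(end_idx),
    start_s = series$time_s[start_idx],
    peak_s = series$time_s[peak_idx],
    end_s = series$time_s[end_idx],
    source = rep_len(as.character(source), n),
    sa_class = rep_len(as.character(sa_class), n),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("surge_annotations", "data.frame")
  validate_annotations(ann, series)
  ann <- ann[order(ann$start_s), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Validate surge annotations against their series
#'
#' @param ann A `surge_annotations` data frame.
#' @param series The companion [beat_series()].
#' @return Invisibly `TRUE`, or an error naming the offending record.
#' @export
validate_annotations <- function(ann, series) {
  if (nrow(ann) == 0) return(invisible(TRUE))
  nb <- n_beats(series)
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    if (a$start_idx < 1 || a$end_idx > nb) {
      stop(sprintf("annotation %d: indices outside series bounds", i))
    }
    if (!(a$start_idx < a$peak_idx && a$peak_idx < a$end_idx)) {
      stop(sprintf("annotation %d: requires start < peak < end", i))
    }
    if (series$sbp[a$peak_idx] < series$sbp[a$start_idx]) {
      stop(sprintf("annotation %d: peak SBP below start SBP", i))
    }
  }
  invisible(TRUE)
}

empty_annotations <- function(night_id = "night") {
  ann <- data.frame(
    night_id = character(), start_idx = integer(), peak_idx = integer(),
    end_idx = integer(), start_s = numeric(), peak_s = numeric(),
    end_s = numeric(), source = character(), sa_class = character(),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("surge_annotations", "data.frame")
  ann
}

#' Construct polysomnography event annotations
#'
#' PSG scoring provides apnea, hypopnea and oxygen-desaturation intervals;
#' they drive the sleep-apnea attribution of surges in [categorize_sa()].
#'
#' @param night_id Night identifier (recycled).
#' @param kind One of `"apnea"`, `"hypopnea"`, `"desaturation"`.
#' @param start_s,end_s Event interval in seconds, `start_s < end_s`.
#' @return A `psg_events` data frame.
#' @export
psg_events <- function(night_id, kind, start_s, end_s) {
  kinds <- c("apnea", "hypopnea", "desaturation")
  ev <- data.frame(
    night_id = as.character(night_id),
    kind = as.character(kind),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    stringsAsFactors = FALSE
  )
  bad <- which(!ev$kind %in% kinds)
  if (length(bad)) stop(sprintf("unknown PSG event kind '%s' at record %d",
                                ev$kind[bad[1]], bad[1]))
  bad <- which(ev$start_s >= ev$end_s)
  if (length(bad)) stop(sprintf("PSG event %d: start_s >= end_s", bad[1]))
  class(ev) <- c("psg_events", "data.frame")
  ev
}

#' Construct an intermittent (cuff-oscillometric) SBP series
#'
#' Conventional nocturnal BP monitoring measures SBP intermittently, nominally
#' every 30 minutes.  Spacing is not enforced; gross deviations from the
#' nominal interval are reported as a message only.
#'
#' @param time_s Reading timestamps, seconds; strictly increasing.
#' @param sbp SBP per reading, mmHg.
#' @param night_id Night identifier.
#' @param nominal_interval_s Expected spacing used for the spacing check.
#' @return An `intermittent_series` list with `night_id`, `time_s`, `sbp`.
#' @export
intermittent_series <- function(time_s, sbp, night_id = "night",
                                nominal_interval_s = 1800) {
  time_s <- as.numeric(time_s)
  sbp <- as.numeric(sbp)
  if (length(time_s) != length(sbp)) stop("time_s and sbp lengths differ")
  if (any(diff(time_s) <= 0)) {
    stop(sprintf("time_s not strictly increasing at reading %d",
                 which(diff(time_s) <= 0)[1] + 1L))
  }
  if (length(time_s) > 1) {
    dt <- diff(time_s)
    if (any(abs(dt - nominal_interval_s) > nominal_interval_s / 2)) {
      message("intermittent readings deviate from nominal ",
              nominal_interval_s, " s spacing")
    }
  }
  structure(list(night_id = as.character(night_id)[1],
                 time_s = time_s, sbp = sbp),
            class = "intermittent_series")
}
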