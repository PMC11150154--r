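#' Read a beat-by-beat series from CSV
#'
#' Expected header `time_s,sbp,dbp,quality`; the `dbp` and `quality` columns
#' are optional (missing quality defaults to `"valid"`).  Rows flagged
#' `artifact` or `gap` are retained, but downstream algorithms exclude them
#' from their windows.
#'
#' @param path CSV file path.
#' @param night_id Night identifier; defaults to the file name without
#'   extension.
#' @return A validated [beat_series()].
#' @export
read_beat_series <- function(path, night_id = NULL) {
  if (is.null(night_id)) night_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sbp")
  if (!all(need %in% names(df))) {
    stop("beat series CSV must have columns time_s,sbp (dbp,quality optional)")
  }
  beat_series(
    time_s = df$time_s, sbp = df$sbp,
    dbp = if ("dbp" %in% names(df)) df$dbp else NULL,
    quality = if ("quality" %in% names(df)) df$quality else NULL,
    night_id = night_id
  )
}

#' Write a beat-by-beat series to CSV
#'
#' Times are written at 3 decimal places and pressures at 1; the quality
#' column is always written.  The output is readable by
#' [read_beat_series()].
#'
#' @param series A [beat_series()].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_beat_series <- function(series, path) {
  validate_beat_series(series)
  df <- data.frame(
    time_s = sprintf("%.3f", series$time_s),
    sbp = sprintf("%.1f", series$sbp),
    stringsAsFactors = FALSE
  )
  if (!is.null(series$dbp)) df$dbp <- sprintf("%.1f", series$dbp)
  df$quality <- series$quality
  tryCatch(
    write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write beat series to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

# Snap annotation times (seconds) to the nearest valid beat index.
# Distances above warn_s trigger a warning, above err_s an error.
snap_to_beat <- function(series, t, warn_s = 2, err_s = 10, what = "time") {
  vi <- valid_idx(series)
  vt <- series$time_s[vi]
  pos <- findInterval(t, vt, all.inside = TRUE)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(vt))
  pick <- ifelse(abs(t - vt[lo]) <= abs(vt[hi] - t), lo, hi)
  dist <- abs(vt[pick] - t)
  if (any(dist > err_s)) {
    i <- which(dist > err_s)[1]
    stop(sprintf("%s %.1f s is %.1f s from the nearest valid beat", what,
                 t[i], dist[i]))
  }
  if (any(dist > warn_s)) {
    i <- which(dist > warn_s)[1]
    warning(sprintf("%s %.1f s snapped across %.1f s to the nearest valid beat",
                    what, t[i], dist[i]))
  }
  vi[pick]
}

#' Read surge annotations from TSV
#'
#' Expected header `night_id<TAB>start_s<TAB>peak_s<TAB>end_s` with an
#' optional `class` column (`sa`, `non_sa` or `unassigned`).  Times are
#' snapped to the nearest valid beat of the companion series; a snap of more
#' than 2 s warns and more than 10 s errors, since labels that far from any
#' usable beat indicate a mismatched series.  The result is sorted by start
#' time.
#'
#' @param path TSV file path.
#' @param series The companion [beat_series()] for the night.
#' @param source Annotation source tag, usually `"label"` or `"detection"`.
#' @return A `surge_annotations` data frame (see [surge_annotations()]).
#' @export
read_annotations <- function(path, series, source = "label") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("night_id", "start_s", "peak_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns night_id,start_s,peak_s,end_s[,class]")
  }
  if (nrow(df) == 0) return(empty_annotations(series$night_id))
  bad <- which(df$start_s >= df$end_s | df$peak_s < df$start_s |
                 df$peak_s > df$end_s)
  if (length(bad)) {
    stop(sprintf("annotation record %d: peak_s must lie within [start_s, end_s]",
                 bad[1]))
  }
  surge_annotations(
    series,
    start_idx = snap_to_beat(series, df$start_s, what = "start_s"),
    peak_idx = snap_to_beat(series, df$peak_s, what = "peak_s"),
    end_idx = snap_to_beat(series, df$end_s, what = "end_s"),
    source = source,
    sa_class = if ("class" %in% names(df)) df$class else "unassigned"
  )
}

#' Write surge annotations to TSV
#'
#' @param ann A `surge_annotations` data frame.
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(
    night_id = ann$night_id,
    start_s = sprintf("%.3f", ann$start_s),
    peak_s = sprintf("%.3f", ann$peak_s),
    end_s = sprintf("%.3f", ann$end_s),
    class = ann$sa_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read PSG events from TSV
#'
#' Expected header `night_id<TAB>kind<TAB>start_s<TAB>end_s` with kinds
#' `apnea`, `hypopnea` or `desaturation`.
#'
#' @param path TSV file path.
#' @return A `psg_events` data frame.
#' @export
read_psg_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("night_id", "kind", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("PSG TSV must have columns night_id,kind,start_s,end_s")
  }
  psg_events(df$night_id, df$kind, df$start_s, df$end_s)
}

#' Write PSG events to TSV
#' @param events A `psg_events` data frame.
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
write_psg_events <- function(events, path) {
  out <- data.frame(
    night_id = events$night_id, kind = events$kind,
    start_s = sprintf("%.3f", events$start_s),
    end_s = sprintf("%.3f", events$end_s),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intermittent SBP series from CSV
#'
#' Expected header `time_s,sbp`.
#'
#' @param path CSV file path.
#' @param night_id Night identifier; defaults to the file name.
#' @return An [intermittent_series()].
#' @export
read_intermittent <- function(path, night_id = NULL) {
  if (is.null(night_id)) night_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "sbp") %in% names(df))) {
    stop("intermittent CSV must have columns time_s,sbp")
  }
  intermittent_series(df$time_s, df$sbp, night_id = night_id)
}

#' Write an intermittent SBP series to CSV
#' @param readings An [intermittent_series()].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_intermittent <- function(readings, path) {
  df <- data.frame(time_s = sprintf("%.3f", readings$time_s),
                   sbp = sprintf("%.1f", readings$sbp),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Bundles the sub-configurations of every stage.  Fields left `NULL` take
#' the stage defaults.
#'
#' @param detector A [detector_config()].
#' @param learner A [learner_config()].
#' @param matcher A [match_config()].
#' @param sim A [sim_config()].
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detector = detector_config(),
                            learner = learner_config(),
                            matcher = match_config(),
                            sim = sim_config(),
                            seed = 1L) {
  structure(list(detector = detector, learner = learner, matcher = matcher,
                 sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys not present in the file keep their defaults; unknown keys within a
#' stage are rejected by the stage constructor.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  pipeline_config(
    detector = build(detector_config, raw$detector),
    learner = build(learner_config, raw$learner),
    matcher = build(match_config, raw$matcher),
    sim = build(sim_config, raw$sim),
    seed = raw$seed %||% 1L
  )
}
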