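#' Configuration for AND-rule learning
#'
#' The classifier is a conjunction of per-feature threshold conditions, at
#' most one per feature group.  Thresholds are searched on a per-feature
#' quantile grid; grid resolution is sized so that even a full six-condition
#' rule stays within the exhaustive-search budget (`grid_steps^6` must not
#' exceed `max_grid_size`).
#'
#' @param grid_quantile_range Lower and upper quantiles delimiting each
#'   feature's threshold grid.
#' @param grid_steps Number of grid points per feature.
#' @param min_single_feature_f Inclusion floor: a group whose best
#'   single-feature F-measure falls below this is dropped.
#' @param max_conditions Maximum number of conditions (1 to 6).
#' @param tie_break Tie-break policy among equal-F grid points; the single
#'   supported policy prefers higher recall, then the most permissive
#'   thresholds.
#' @param max_grid_size Hard cap on the number of threshold combinations
#'   the exhaustive search may enumerate.
#' @return A `learner_config` list.
#' @export
learner_config <- function(grid_quantile_range = c(0.05, 0.95),
                           grid_steps = 13,
                           min_single_feature_f = 0.5,
                           max_conditions = 6,
                           tie_break = "higher_recall_then_lower_threshold",
                           max_grid_size = 1e7) {
  cfg <- structure(as.list(environment()), class = "learner_config")
  if (cfg$grid_steps < 1) stop("grid must be non-empty")
  if (cfg$min_single_feature_f < 0 || cfg$min_single_feature_f > 1) {
    stop("min_single_feature_f must lie in [0, 1]")
  }
  if (cfg$max_conditions < 1 || cfg$max_conditions > 6) {
    stop("max_conditions must lie in 1..6")
  }
  cfg$tie_break <- match.arg(cfg$tie_break,
                             "higher_recall_then_lower_threshold")
  cfg
}

f_measure <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Sweep all thresholds of one feature and return the F-optimal one
#'
#' Candidate thresholds are the distinct observed values.  F-measure is the
#' balanced harmonic mean of recall and precision over the candidate set.
#' Ties are broken toward the smaller positive region (the larger threshold
#' for `ge`, the smaller for `le`).
#'
#' @param values Numeric feature values, one per candidate.
#' @param labels Logical labels (`TRUE` = surge).
#' @param direction `"ge"` (positive iff value >= threshold) or `"le"`.
#' @return A list with `threshold` and `f`.
#' @export
sweep_threshold <- function(values, labels, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (!any(labels)) stop("unlearnable feature: no positive labels")
  u <- sort(unique(values))
  pos_hist <- tabulate(match(values[labels], u), nbins = length(u))
  neg_hist <- tabulate(match(values[!labels], u), nbins = length(u))
  if (direction == "ge") {
    tp <- rev(cumsum(rev(pos_hist)))
    fp <- rev(cumsum(rev(neg_hist)))
  } else {
    tp <- cumsum(pos_hist)
    fp <- cumsum(neg_hist)
  }
  fn <- sum(labels) - tp
  f <- f_measure(tp, fp, fn)
  best <- which(f == max(f))
  pick <- if (direction == "ge") max(best) else min(best)
  list(threshold = u[pick], f = f[pick])
}

#' Select one discriminative feature per group
#'
#' Each catalogue feature is swept in both directions and characterized by
#' its best single-feature F.  Within each group only the strongest feature
#' is kept ("no duplicated categories"); groups whose best F falls below
#' the inclusion floor are dropped; at most `max_conditions` features are
#' returned, ordered by descending F.
#'
#' @param features Feature matrix from [extract_features()].
#' @param labels Logical labels per candidate.
#' @param config A [learner_config()].
#' @return A data frame with columns `feature`, `group`, `direction`, `f`.
#' @export
select_features <- function(features, labels, config = learner_config()) {
  cat <- feature_catalogue()
  per <- lapply(seq_len(nrow(cat)), function(i) {
    vals <- features[, cat$name[i]]
    ge <- sweep_threshold(vals, labels, "ge")
    le <- sweep_threshold(vals, labels, "le")
    if (ge$f >= le$f) list(direction = "ge", f = ge$f)
    else list(direction = "le", f = le$f)
  })
  tab <- data.frame(
    feature = cat$name, group = cat$group,
    direction = vapply(per, `[[`, character(1), "direction"),
    f = vapply(per, `[[`, numeric(1), "f"),
    stringsAsFactors = FALSE
  )
  best <- do.call(rbind, lapply(split(tab, factor(tab$group, FEATURE_GROUPS)),
                                function(g) g[which.max(g$f), ]))
  best <- best[best$f >= config$min_single_feature_f, , drop = FALSE]
  if (nrow(best) == 0) stop("no discriminative features above the floor")
  best <- best[order(-best$f), , drop = FALSE]
  best <- head(best, config$max_conditions)
  rownames(best) <- NULL
  best
}

# Reverse (upper-tail) cumulative sum along dimension d of array a.
rev_cumsum_dim <- function(a, d) {
  nd <- length(dim(a))
  perm <- c(d, seq_len(nd)[-d])
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  for (r in seq(dp[1] - 1L, 1L)) m[r, ] <- m[r, ] + m[r + 1L, ]
  aperm(array(m, dp), match(seq_len(nd), perm))
}

#' Exhaustive grid search for the joint AND-rule thresholds
#'
#' For each selected feature a threshold grid is taken at evenly spaced
#' quantiles of its training values.  The full Cartesian product of grids is
#' evaluated exactly (via k-dimensional cumulative counts, equivalent to
#' brute force) and the combination maximizing the F-measure of the
#' AND-conjunction is returned.  Equal-F ties prefer higher recall, then
#' the most permissive thresholds.
#'
#' @param features Feature matrix from [extract_features()].
#' @param labels Logical labels per candidate.
#' @param selected Selection table from [select_features()] (or any data
#'   frame with `feature` and `direction` columns).
#' @param config A [learner_config()].
#' @return A `decision_rule`: list with `conditions` (data frame `feature`,
#'   `direction`, `threshold`) and `training_f`.
#' @export
grid_search_rule <- function(features, labels, selected,
                             config = learner_config()) {
  if (nrow(selected) == 0) stop("empty feature selection")
  labels <- as.logical(labels)
  npos <- sum(labels)
  k <- nrow(selected)
  probs <- seq(config$grid_quantile_range[1], config$grid_quantile_range[2],
               length.out = config$grid_steps)
  grids <- lapply(seq_len(k), function(m) {
    vals <- features[, selected$feature[m]]
    # the most permissive observed value is always on the grid, so a
    # condition can be a no-op instead of clipping the tail of the data
    g <- sort(unique(c(unname(quantile(vals, probs, type = 7)),
                       if (selected$direction[m] == "ge") min(vals)
                       else max(vals))))
    # permissive-first ordering: ascending for ge, descending for le
    if (selected$direction[m] == "ge") g else rev(g)
  })
  sizes <- vapply(grids, length, integer(1))
  if (prod(sizes) > config$max_grid_size) {
    stop("grid too large (", format(prod(sizes), big.mark = ","),
         " combinations); use fewer conditions or a coarser grid")
  }
  # j[i, m]: number of grid positions (in permissive-first order) whose
  # condition candidate i satisfies; accepted at position a iff a <= j.
  j <- vapply(seq_len(k), function(m) {
    vals <- features[, selected$feature[m]]
    g <- grids[[m]]
    if (selected$direction[m] == "ge") {
      findInterval(vals, g)                       # #(g <= value)
    } else {
      length(g) - findInterval(vals, rev(g), left.open = TRUE)  # #(g >= value)
    }
  }, numeric(nrow(features)))
  j <- matrix(j, ncol = k)

  hdim <- sizes + 1L
  hist_of <- function(rows) {
    h <- array(0, dim = hdim)
    if (length(rows)) {
      lin <- as.integer(j[rows, 1] + 1)
      mult <- 1
      for (m in seq_len(k)[-1]) {
        mult <- mult * hdim[m - 1]
        lin <- lin + as.integer(j[rows, m]) * mult
      }
      t <- tabulate(lin, nbins = prod(hdim))
      h <- array(t, dim = hdim)
    }
    for (m in seq_len(k)) h <- rev_cumsum_dim(h, m)
    h
  }
  C_pos <- hist_of(which(labels))
  C_neg <- hist_of(which(!labels))
  sub <- lapply(sizes, function(g) 1 + seq_len(g))
  tp <- do.call(`[`, c(list(C_pos), sub, list(drop = FALSE)))
  fp <- do.call(`[`, c(list(C_neg), sub, list(drop = FALSE)))
  f <- f_measure(tp, fp, npos - tp)
  fmax <- max(f)
  best <- which(f == fmax)
  best <- best[tp[best] == max(tp[best])]
  pick <- min(best)  # most permissive in condition order
  a <- arrayInd(pick, .dim = sizes)[1, ]
  conditions <- data.frame(
    feature = selected$feature,
    direction = selected$direction,
    threshold = vapply(seq_len(k), function(m) grids[[m]][a[m]], numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(conditions = conditions, training_f = fmax),
            class = "decision_rule")
}

#' Apply an AND-rule to candidate feature vectors
#'
#' A candidate is positive iff every condition holds; thresholds are
#' inclusive (`ge`: value >= threshold, `le`: value <= threshold).
#'
#' @param rule A `decision_rule`.
#' @param features Feature matrix from [extract_features()].
#' @return Logical vector, one element per candidate.
#' @export
apply_rule <- function(rule, features) {
  cond <- rule$conditions
  if (is.null(cond) || nrow(cond) == 0) stop("rule has no conditions")
  missing <- setdiff(cond$feature, colnames(features))
  if (length(missing)) {
    stop("rule references unknown feature(s): ",
         paste(missing, collapse = ", "))
  }
  out <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(cond))) {
    v <- features[, cond$feature[i]]
    out <- out & if (cond$direction[i] == "ge") v >= cond$threshold[i]
                 else v <= cond$threshold[i]
  }
  out
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("<decision_rule: %d conditions, training F = %.3f>\n",
              nrow(x$conditions), x$training_f))
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("  %s %s %.4g\n", x$conditions$feature[i],
                ifelse(x$conditions$direction[i] == "ge", ">=", "<="),
                x$conditions$threshold[i]))
  }
  invisible(x)
}

# Short deterministic checksum of the feature catalogue, recorded in models
# so a rule is never applied against a renamed catalogue unnoticed.
catalogue_version <- function() {
  s <- paste(feature_catalogue()$name, collapse = "|")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

# Internal: label candidates of one night against expert labels using the
# evaluation matcher, so training and test semantics coincide.
label_candidates <- function(cand, labels, matcher) {
  if (nrow(cand) == 0) return(logical(0))
  m <- match_detections(cand, labels, matcher)
  out <- rep(FALSE, nrow(cand))
  out[m$pairing$detection] <- TRUE
  out
}

#' Train a surge detector on labelled nights
#'
#' Runs candidate detection on every night, labels each candidate by
#' matching it to the expert labels with the evaluation matcher, extracts
#' the 48 features, selects at most one feature per group and fits the
#' joint thresholds by exhaustive grid search.
#'
#' @param nights A list of nights, each a list with elements `series` (a
#'   [beat_series()]) and `labels` (a `surge_annotations` data frame).
#' @param detector A [detector_config()].
#' @param learner A [learner_config()].
#' @param matcher A [match_config()].
#' @return A `surge_model`: list with the three configs, the fitted
#'   `decision_rule`, and a `meta` record (candidate counts, training F,
#'   catalogue version).
#' @export
train_detector <- function(nights, detector = detector_config(),
                           learner = learner_config(),
                           matcher = match_config()) {
  if (length(nights) == 0) stop("no nights supplied")
  n_labels <- sum(vapply(nights, function(x) nrow(x$labels), integer(1)))
  if (n_labels == 0) stop("no labels in any night")
  prep <- lapply(nights, function(night) {
    cand <- detect_candidates(night$series, detector)
    list(features = extract_features(night$series, cand,
                                     detector$stability_beats),
         positive = label_candidates(cand, night$labels, matcher))
  })
  fit <- fit_rule(prep, learner)
  structure(list(detector = detector, learner = learner, matcher = matcher,
                 rule = fit$rule,
                 meta = list(n_candidates = fit$n, n_positive = fit$npos,
                             training_f = fit$rule$training_f,
                             catalogue_version = catalogue_version())),
            class = "surge_model")
}

# Pool prepared nights (features + candidate labels) and fit the rule.
fit_rule <- function(prep, learner) {
  features <- do.call(rbind, lapply(prep, `[[`, "features"))
  positive <- unlist(lapply(prep, `[[`, "positive"))
  if (is.null(features) || nrow(features) == 0 || !any(positive)) {
    stop("detector misses all labels - tune the detector configuration")
  }
  selected <- select_features(features, positive, learner)
  rule <- grid_search_rule(features, positive, selected, learner)
  list(rule = rule, n = nrow(features), npos = sum(positive))
}

#' Run a trained model on one night
#'
#' @param series A [beat_series()].
#' @param model A `surge_model` from [train_detector()] / [read_model()].
#' @return Detections: a `surge_annotations` data frame with
#'   `source = "detection"`.
#' @export
detect_surges <- function(series, model) {
  stopifnot(inherits(model, "surge_model"))
  cand <- detect_candidates(series, model$detector)
  if (nrow(cand) == 0) return(cand)
  feats <- extract_features(series, cand, model$detector$stability_beats)
  keep <- apply_rule(model$rule, feats)
  out <- cand[keep, , drop = FALSE]
  out$source <- rep("detection", nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a trained model to JSON
#' @param model A `surge_model`.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "surge_model"))
  payload <- list(
    detector = unclass(model$detector),
    learner = unclass(model$learner),
    matcher = unclass(model$matcher),
    rule = list(conditions = model$rule$conditions,
                training_f = model$rule$training_f),
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trained model from JSON
#' @param path Model JSON path written by [write_model()].
#' @return A `surge_model`.
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$meta$catalogue_version, catalogue_version())) {
    warning("model was trained against a different feature catalogue version")
  }
  structure(list(
    detector = do.call(detector_config, raw$detector),
    learner = do.call(learner_config, raw$learner),
    matcher = do.call(match_config, raw$matcher),
    rule = structure(list(conditions = raw$rule$conditions,
                          training_f = raw$rule$training_f),
                     class = "decision_rule"),
    meta = raw$meta
  ), class = "surge_model")
}
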