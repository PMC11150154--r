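#' Configuration for detection-to-label matching
#'
#' A detection matches a label when its peak time falls inside the label's
#' interval widened by `tolerance_s` on each side.  Peak containment rather
#' than interval overlap is used because start/end placement is where
#' algorithm and labeller disagree most; the peak is the stable landmark.
#'
#' @param tolerance_s Slack added to each side of a label interval, seconds.
#' @return A `match_config` list.
#' @export
match_config <- function(tolerance_s = 10) {
  if (tolerance_s < 0) stop("tolerance_s must be >= 0")
  structure(list(tolerance_s = tolerance_s), class = "match_config")
}

#' Match detections to expert labels
#'
#' Greedy one-to-one matching in time order: each detection (by peak time)
#' is paired with the earliest unmatched label whose widened interval
#' `[start_s - tol, end_s + tol]` contains the detected peak time.  Matched
#' pairs are true positives; unmatched detections false positives;
#' unmatched labels false negatives.
#'
#' @param detected,labels `surge_annotations` data frames from the same
#'   night.
#' @param config A [match_config()].
#' @return A list with `tp`, `fp`, `fn` and `pairing` (data frame with
#'   `detection` and `label` row indices).
#' @export
match_detections <- function(detected, labels, config = match_config()) {
  if (nrow(detected) > 0 && nrow(labels) > 0 &&
      !identical(unique(detected$night_id), unique(labels$night_id))) {
    stop("detections and labels come from different nights")
  }
  det_ord <- order(detected$peak_s)
  lab_ord <- order(labels$start_s)
  matched_lab <- rep(FALSE, nrow(labels))
  pairs_det <- integer(0)
  pairs_lab <- integer(0)
  tol <- config$tolerance_s
  for (d in det_ord) {
    pk <- detected$peak_s[d]
    for (l in lab_ord) {
      if (matched_lab[l]) next
      if (pk >= labels$start_s[l] - tol && pk <= labels$end_s[l] + tol) {
        matched_lab[l] <- TRUE
        pairs_det <- c(pairs_det, d)
        pairs_lab <- c(pairs_lab, l)
        break
      }
    }
  }
  tp <- length(pairs_det)
  list(tp = tp, fp = nrow(detected) - tp, fn = nrow(labels) - tp,
       pairing = data.frame(detection = pairs_det, label = pairs_lab))
}

#' Detection metrics from TP/FP/FN counts
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F = their harmonic mean.
#' Conventions for empty denominators: recall = 1 when there are no labels,
#' precision = 1 when there are no detections, F = 0 when both recall and
#' precision are 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An `eval_report` list with the counts and the three metrics.
#' @export
compute_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0")
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, f_measure = f),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: TP %d, FP %d, FN %d | recall %.3f, precision %.3f, F %.3f>\n",
              x$tp, x$fp, x$fn, x$recall, x$precision, x$f_measure))
  if (!is.null(x$per_fold)) {
    cat(sprintf("  %d folds: recall %.3f +/- %.3f, precision %.3f +/- %.3f\n",
                nrow(x$per_fold), x$mean_sd$recall_mean, x$mean_sd$recall_sd,
                x$mean_sd$precision_mean, x$mean_sd$precision_sd))
  }
  invisible(x)
}

#' Evaluate one night's detections against labels
#'
#' @param detected,labels `surge_annotations` data frames from the same
#'   night.
#' @param config A [match_config()].
#' @return An `eval_report`.
#' @export
evaluate_detections <- function(detected, labels, config = match_config()) {
  m <- match_detections(detected, labels, config)
  compute_metrics(m$tp, m$fp, m$fn)
}

#' Night-level k-fold cross-validation of the full pipeline
#'
#' Nights (never beats) are shuffled by `seed` and split into `k` folds of
#' sizes differing by at most one.  For each fold a rule is trained on the
#' remaining nights and evaluated on the held-out nights; TP/FP/FN are
#' pooled within each fold before computing recall and precision, and the
#' mean and SD across folds are reported.  Folds with no labels are warned
#' about and excluded from the fold aggregates.
#'
#' @param nights A list of nights, each a list with `series` and `labels`
#'   (see [train_detector()]).
#' @param k Number of folds, at most the number of nights.
#' @param seed Integer seed for the night shuffle.
#' @param detector A [detector_config()].
#' @param learner A [learner_config()].
#' @param matcher A [match_config()].
#' @return An `eval_report` with pooled counts plus `per_fold` (data frame)
#'   and `mean_sd` (recall/precision mean and SD across folds).
#' @export
cross_validate <- function(nights, k = 5, seed = 1,
                           detector = detector_config(),
                           learner = learner_config(),
                           matcher = match_config()) {
  n <- length(nights)
  if (k > n) stop("k must not exceed the number of nights")
  # candidates and features depend only on the series and detector; compute
  # them once, not once per fold
  prep <- lapply(nights, function(night) {
    cand <- detect_candidates(night$series, detector)
    list(cand = cand,
         features = extract_features(night$series, cand,
                                     detector$stability_beats),
         positive = label_candidates(cand, night$labels, matcher),
         labels = night$labels)
  })
  fold_of <- integer(n)
  fold_of[with_seed(seed, sample(n))] <- rep(seq_len(k), length.out = n)
  per_fold <- data.frame(fold = seq_len(k), tp = 0L, fp = 0L, fn = 0L,
                         recall = NA_real_, precision = NA_real_,
                         f_measure = NA_real_)
  for (fold in seq_len(k)) {
    fit <- fit_rule(prep[fold_of != fold], learner)
    tp <- fp <- fn <- 0L
    for (i in which(fold_of == fold)) {
      p <- prep[[i]]
      det <- if (nrow(p$cand) == 0) p$cand else {
        keep <- apply_rule(fit$rule, p$features)
        p$cand[keep, , drop = FALSE]
      }
      m <- match_detections(det, p$labels, matcher)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    per_fold$tp[fold] <- tp
    per_fold$fp[fold] <- fp
    per_fold$fn[fold] <- fn
    if (tp + fn == 0) {
      warning(sprintf("fold %d contains no labels; excluded from aggregates",
                      fold))
      next
    }
    mt <- compute_metrics(tp, fp, fn)
    per_fold$recall[fold] <- mt$recall
    per_fold$precision[fold] <- mt$precision
    per_fold$f_measure[fold] <- mt$f_measure
  }
  ok <- !is.na(per_fold$recall)
  report <- compute_metrics(sum(per_fold$tp), sum(per_fold$fp),
                            sum(per_fold$fn))
  report$per_fold <- per_fold
  report$mean_sd <- list(
    recall_mean = mean(per_fold$recall[ok]),
    recall_sd = sd(per_fold$recall[ok]),
    precision_mean = mean(per_fold$precision[ok]),
    precision_sd = sd(per_fold$precision[ok])
  )
  report
}
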