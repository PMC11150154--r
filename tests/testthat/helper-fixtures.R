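# Programmatic fixtures and independent brute-force oracles.

flat_series <- function(n = 100, sbp = 120, dt = 1, night_id = "n1",
                        quality = NULL) {
  beat_series(time_s = seq_len(n) * dt, sbp = rep(sbp, n),
              quality = quality, night_id = night_id)
}

# Series with piecewise-linear (triangular) bumps on a flat baseline.
# bumps: list of list(at = start time, amp, up, down)
bump_series <- function(duration = 600, dt = 1, baseline = 120,
                        bumps = list(), night_id = "n1", quality = NULL) {
  t <- seq(dt, duration, by = dt)
  y <- rep(baseline, length(t))
  for (b in bumps) {
    rise <- t >= b$at & t <= b$at + b$up
    fall <- t > b$at + b$up & t <= b$at + b$up + b$down
    y[rise] <- y[rise] + b$amp * (t[rise] - b$at) / b$up
    y[fall] <- y[fall] + b$amp * (1 - (t[fall] - b$at - b$up) / b$down)
  }
  beat_series(t, y, quality = quality, night_id = night_id)
}

# O(n*w) oracle for the sliding-window peak test: full rescan of every
# window with the documented semantics (weak max, earliest plateau beat,
# at least one strictly lower in-window beat).  Assumes no segment splits.
brute_peaks <- function(series, config) {
  vi <- which(series$quality == "valid")
  t <- series$time_s[vi]
  y <- series$sbp[vi]
  half <- config$window_s / 2
  out <- integer(0)
  for (j in seq_along(vi)) {
    inw <- which(abs(t - t[j]) <= half)
    w <- y[inw]
    if (y[j] < max(w)) next
    earlier <- inw[inw < j]
    if (length(earlier) && any(y[earlier] == y[j])) next
    if (all(w >= y[j])) next
    out <- c(out, vi[j])
  }
  out
}

# Exhaustive enumeration oracle for the single-feature threshold sweep.
brute_sweep <- function(values, labels, direction) {
  u <- sort(unique(values))
  best <- NULL
  for (thr in u) {
    pred <- if (direction == "ge") values >= thr else values <= thr
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    better <- is.null(best) || f > best$f ||
      (f == best$f && ((direction == "ge" && thr > best$threshold) ||
                         (direction == "le" && thr < best$threshold)))
    if (better) best <- list(threshold = thr, f = f)
  }
  best
}

# Exhaustive enumeration oracle for the joint grid search, replicating the
# quantile grids and the documented tie-break (max F, then max TP, then
# most permissive thresholds in condition order).
brute_grid <- function(features, labels, selected, config) {
  probs <- seq(config$grid_quantile_range[1], config$grid_quantile_range[2],
               length.out = config$grid_steps)
  grids <- lapply(seq_len(nrow(selected)), function(m) {
    vals <- features[, selected$feature[m]]
    g <- sort(unique(c(unname(quantile(vals, probs, type = 7)),
                       if (selected$direction[m] == "ge") min(vals)
                       else max(vals))))
    if (selected$direction[m] == "ge") g else rev(g)
  })
  combos <- do.call(expand.grid, lapply(grids, seq_along))
  npos <- sum(labels)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    pred <- rep(TRUE, nrow(features))
    thr <- numeric(nrow(selected))
    for (m in seq_len(nrow(selected))) {
      thr[m] <- grids[[m]][combos[r, m]]
      v <- features[, selected$feature[m]]
      pred <- pred & if (selected$direction[m] == "ge") v >= thr[m]
                     else v <= thr[m]
    }
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    f <- if (2 * tp + fp + (npos - tp) == 0) 0 else
      2 * tp / (2 * tp + fp + (npos - tp))
    if (is.null(best) || f > best$f || (f == best$f && tp > best$tp)) {
      best <- list(f = f, tp = tp, thresholds = thr)
    }
    # ties at equal f and tp keep the earlier (more permissive) combo:
    # expand.grid enumerates the first grid fastest, matching the package
  }
  best
}

# A feature matrix in catalogue shape: constant (uninformative) filler, with
# chosen columns carrying signal.  A constant feature's best swept F equals
# the accept-all value 2p/(1+p), so with a sparse positive rate every
# signal-free group stays deterministically below the 0.5 inclusion floor.
signal_features <- function(n, n_pos, signal, seed = 1) {
  set.seed(seed)
  cat <- feature_catalogue()
  f <- matrix(0, nrow = n, ncol = 48, dimnames = list(NULL, cat$name))
  labels <- seq_len(n) <= n_pos
  for (nm in names(signal)) {
    s <- signal[[nm]]
    f[, nm] <- ifelse(labels, s$pos, s$neg) + rnorm(n, 0, s$sd %||% 0)
  }
  list(features = f, labels = labels)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Small nights for training tests: noise-free, confuser- and artifact-free.
clean_night <- function(seed) {
  cfg <- sim_config(duration_s = 3600, beat_noise_sd_mmHg = 0,
                    confuser_rate = 0, artifact_rate = 0,
                    sa_surge_rate = 4, nonsa_surge_rate = 3)
  nt <- generate_night(cfg, seed = seed)
  list(series = nt$series, labels = nt$labels, events = nt$events)
}
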