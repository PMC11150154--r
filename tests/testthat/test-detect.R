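test_that("a single triangular bump yields exactly one peak at its apex", {
  bs <- bump_series(bumps = list(list(at = 300, amp = 30, up = 30, down = 45)))
  cfg <- detector_config()
  pk <- find_candidate_peaks(bs, cfg)
  expect_length(pk, 1)
  expect_equal(bs$time_s[pk], 330)        # apex beat
  expect_equal(pk, brute_peaks(bs, cfg))
})

test_that("a constant series has no strict maximum", {
  bs <- flat_series(400)
  expect_equal(find_candidate_peaks(bs, detector_config()), integer(0))
})

test_that("two identical bumps far apart give two peaks in time order", {
  bs <- bump_series(duration = 900,
                    bumps = list(list(at = 200, amp = 25, up = 20, down = 30),
                                 list(at = 500, amp = 25, up = 20, down = 30)))
  cfg <- detector_config()
  pk <- find_candidate_peaks(bs, cfg)
  expect_length(pk, 2)
  expect_true(all(diff(pk) > 0))
  expect_equal(pk, brute_peaks(bs, cfg))
})

test_that("sliding-window peaks match a brute-force rescan on random series", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample(100:400, 1)
    # quantized random walk to provoke plateaus and ties
    y <- 120 + round(cumsum(rnorm(n, 0, 2)) / 2) * 2
    y <- pmin(pmax(y, 40), 280)
    q <- sample(c("valid", "artifact"), n, replace = TRUE, prob = c(0.95, 0.05))
    bs <- beat_series(cumsum(runif(n, 0.8, 1.2)), y, quality = q)
    cfg <- detector_config(window_s = sample(c(20, 40, 60), 1))
    expect_identical(find_candidate_peaks(bs, cfg), brute_peaks(bs, cfg))
  }
})

test_that("start lands on the last beat of a stable prefix before a steep rise", {
  bs <- bump_series(duration = 300,
                    bumps = list(list(at = 120, amp = 30, up = 30, down = 40)))
  cfg <- detector_config()
  pk <- find_candidate_peaks(bs, cfg)
  st <- locate_start(bs, pk, cfg)
  expect_false(attr(st, "fallback"))
  expect_equal(bs$time_s[st], 120)        # last flat beat
  expect_equal(bs$sbp[st], 120)
})

test_that("a rise from recording onset falls back to the lookback minimum", {
  t <- 1:200
  y <- 70 + 0.8 * t          # monotone rise too steep for the stability band
  bs <- beat_series(t, y)
  cfg <- detector_config()
  st <- locate_start(bs, 200L, cfg)
  expect_true(attr(st, "fallback"))
  lb <- which(t >= t[200] - cfg$max_lookback_s & t < t[200])
  expect_equal(as.integer(st), lb[which.min(y[lb])])
})

test_that("an artifact beat inside the stable plateau does not move the start", {
  mk <- function(quality) bump_series(
    duration = 300, quality = quality,
    bumps = list(list(at = 120, amp = 30, up = 30, down = 40)))
  clean <- mk(NULL)
  q <- rep("valid", n_beats(clean))
  q[112] <- "artifact"
  flagged <- mk(q)
  flagged$sbp[112] <- 190                  # spike, but flagged
  cfg <- detector_config()
  pk <- find_candidate_peaks(clean, cfg)
  expect_equal(as.integer(locate_start(flagged, pk, cfg)),
               as.integer(locate_start(clean, pk, cfg)))
})

test_that("the end point is the first beat crossing the 75% decay level", {
  # start 120, peak 140: the end is the first beat at or below 125
  bs <- bump_series(duration = 400,
                    bumps = list(list(at = 100, amp = 20, up = 20, down = 40)))
  cfg <- detector_config()
  pk <- find_candidate_peaks(bs, cfg)
  st <- locate_start(bs, pk, cfg)
  en <- locate_end(bs, st, pk, cfg)
  expect_false(attr(en, "fallback"))
  expect_lte(bs$sbp[en], 125)
  expect_gt(bs$sbp[en - 1L], 125)
})

test_that("an immediate deep drop ends the surge at the next beat", {
  y <- c(rep(120, 60), 140, 118, rep(118, 30))
  bs <- beat_series(seq_along(y), y)
  en <- locate_end(bs, 60L, 61L, detector_config())
  expect_equal(as.integer(en), 62L)
  expect_false(attr(en, "fallback"))
})

test_that("a plateau never crossing the decay level falls back to the span minimum", {
  y <- c(rep(120, 60), seq(120, 140, length.out = 10), rep(138, 250))
  bs <- beat_series(seq_along(y), y)
  cfg <- detector_config()
  en <- locate_end(bs, 60L, 70L, cfg)
  expect_true(attr(en, "fallback"))
  span <- which(bs$time_s > bs$time_s[70] &
                  bs$time_s <= bs$time_s[70] + cfg$max_recovery_s)
  expect_equal(bs$sbp[en], min(bs$sbp[span]))
})

test_that("a peak at the final beat is a truncated candidate", {
  y <- c(rep(120, 60), seq(121, 140, length.out = 20))
  bs <- beat_series(seq_along(y), y)
  expect_error(locate_end(bs, 60L, 80L, detector_config()), "truncated")
})

test_that("noise-free planted surges are recovered with exact peaks", {
  cfg <- sim_config(duration_s = 7200, beat_noise_sd_mmHg = 0,
                    confuser_rate = 0, artifact_rate = 0,
                    sa_surge_rate = 6, nonsa_surge_rate = 5)
  for (seed in 0:2) {
    nt <- generate_night(cfg, seed = seed)
    cand <- detect_candidates(nt$series)
    expect_equal(nrow(cand), nrow(nt$labels))
    expect_equal(cand$peak_idx, nt$labels$peak_idx)
  }
})

test_that("sub-threshold bumps yield no candidate", {
  bs <- bump_series(bumps = list(list(at = 300, amp = 8, up = 20, down = 30)))
  expect_equal(nrow(detect_candidates(bs, detector_config())), 0)
})

test_that("an empty baseline night yields no candidates", {
  bs <- flat_series(600)
  expect_equal(nrow(detect_candidates(bs, detector_config())), 0)
})

short_cfg <- function(...) {
  sim_config(duration_s = 7200, sa_surge_rate = 6, nonsa_surge_rate = 5,
             confuser_rate = 9, artifact_rate = 2, ...)
}

test_that("raising the minimum amplitude never adds candidates", {
  nt <- generate_night(short_cfg(), seed = 9)
  counts <- vapply(c(10, 15, 20, 25, 30), function(a) {
    nrow(detect_candidates(nt$series, detector_config(min_amplitude_mmHg = a)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected candidate amplitudes meet the configured minimum", {
  nt <- generate_night(short_cfg(), seed = 10)
  cfg <- detector_config()
  cand <- detect_candidates(nt$series, cfg)
  expect_true(all(cand$amplitude_mmHg >= cfg$min_amplitude_mmHg))
  expect_true(all(cand$start_idx < cand$peak_idx))
  expect_true(all(cand$peak_idx < cand$end_idx))
})

test_that("the decay inequality holds on every non-fallback end point", {
  nt <- generate_night(short_cfg(), seed = 11)
  cfg <- detector_config()
  pks <- find_candidate_peaks(nt$series, cfg)
  checked <- 0
  for (pk in pks) {
    st <- tryCatch(locate_start(nt$series, pk, cfg), error = function(e) NULL)
    if (is.null(st) || nt$series$sbp[pk] <= nt$series$sbp[st]) next
    en <- tryCatch(locate_end(nt$series, st, pk, cfg), error = function(e) NULL)
    if (is.null(en) || attr(en, "fallback")) next
    amp <- nt$series$sbp[pk] - nt$series$sbp[st]
    expect_lte(nt$series$sbp[en], nt$series$sbp[pk] - cfg$decay_fraction * amp)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("a long dropout splits the recording into independent segments", {
  y <- c(rep(120, 200), rep(120, 200))
  t <- c(1:200, 500 + 1:200)
  y[390] <- 150                            # lone spike in the second segment
  bs <- beat_series(t, y)
  cand <- detect_candidates(bs, detector_config())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$peak_idx, 390L)
  # start search must not cross the gap into the first segment
  expect_gte(cand$start_idx, 201L)
})
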