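test_that("threshold sweep reproduces hand-enumerated optima", {
  values <- c(10, 12, 14, 16, 1, 2, 3, 11)
  labels <- c(rep(TRUE, 4), rep(FALSE, 4))
  res <- sweep_threshold(values, labels, "ge")
  expect_equal(res$threshold, 10)
  expect_equal(res$f, 8 / 9)

  sep <- sweep_threshold(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE), "ge")
  expect_equal(sep$f, 1.0)

  allpos <- sweep_threshold(c(5, 7, 9), rep(TRUE, 3), "ge")
  expect_equal(allpos$threshold, 5)
  expect_equal(allpos$f, 1.0)

  expect_error(sweep_threshold(1:4, rep(FALSE, 4), "ge"), "unlearnable")
})

test_that("threshold sweep equals brute-force enumeration on random instances", {
  set.seed(7)
  for (case in 1:100) {
    n <- sample(5:50, 1)
    values <- round(rnorm(n, 10, 4), 1)    # rounding provokes ties
    labels <- runif(n) < 0.5
    if (!any(labels)) labels[sample(n, 1)] <- TRUE
    for (dir in c("ge", "le")) {
      got <- sweep_threshold(values, labels, dir)
      want <- brute_sweep(values, labels, dir)
      expect_equal(got$f, want$f)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("feature selection keeps one feature per group above the floor", {
  # 10/60 positives: constant groups sit at F = 2p/(1+p) ~ 0.29 < 0.5
  fx <- signal_features(60, 10, list(amplitude = list(pos = 30, neg = 10)))
  sel <- select_features(fx$features, fx$labels, learner_config())
  expect_equal(nrow(sel), 1)
  expect_equal(sel$feature, "amplitude")
  expect_equal(sel$f, 1.0)
})

test_that("of two strong same-group features only the stronger survives", {
  fx <- signal_features(60, 10, list(
    amplitude = list(pos = 30, neg = 10),
    peak_sbp = list(pos = 150, neg = 130, sd = 8)   # same group, overlapping
  ))
  sel <- select_features(fx$features, fx$labels, learner_config())
  expect_equal(sum(sel$group == "amplitude"), 1)
  expect_equal(sel$feature[sel$group == "amplitude"], "amplitude")
})

test_that("six separable groups yield six conditions, one per group", {
  fx <- signal_features(60, 10, list(
    amplitude = list(pos = 30, neg = 10),
    up_duration_s = list(pos = 25, neg = 5),
    down_duration_s = list(pos = 40, neg = 10),
    react_onset_slope = list(pos = 2, neg = 0.2),
    rec_onset_slope = list(pos = -2, neg = -0.2),
    whole_duration_s = list(pos = 60, neg = 20)
  ))
  sel <- select_features(fx$features, fx$labels, learner_config())
  expect_equal(nrow(sel), 6)
  expect_setequal(sel$group, FEATURE_GROUPS)
})

test_that("all groups below the floor is an error", {
  fx <- signal_features(60, 10, list())
  expect_error(select_features(fx$features, fx$labels, learner_config()),
               "no discriminative features")
})

test_that("a single-condition grid search reduces to the sweep on the grid", {
  fx <- signal_features(30, 15, list(amplitude = list(pos = 28, neg = 12, sd = 4)))
  cfg <- learner_config(grid_steps = 9)
  sel <- data.frame(feature = "amplitude", direction = "ge",
                    stringsAsFactors = FALSE)
  rule <- grid_search_rule(fx$features, fx$labels, sel, cfg)
  probs <- seq(0.05, 0.95, length.out = 9)
  grid <- sort(unique(c(unname(quantile(fx$features[, "amplitude"], probs)),
                        min(fx$features[, "amplitude"]))))
  fs <- vapply(grid, function(thr) {
    pred <- fx$features[, "amplitude"] >= thr
    tp <- sum(pred & fx$labels); fp <- sum(pred & !fx$labels)
    fn <- sum(!pred & fx$labels)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_equal(rule$training_f, max(fs))
  expect_true(rule$conditions$threshold %in% grid)
})

test_that("grid search equals brute-force enumeration on small instances", {
  set.seed(99)
  for (case in 1:100) {
    n <- sample(8:24, 1)
    fx <- signal_features(n, ceiling(n / 2), list(
      amplitude = list(pos = 25, neg = 15, sd = 6),
      up_duration_s = list(pos = 20, neg = 12, sd = 6)
    ), seed = case)
    sel <- data.frame(feature = c("amplitude", "up_duration_s"),
                      direction = sample(c("ge", "le"), 2, replace = TRUE),
                      stringsAsFactors = FALSE)
    cfg <- learner_config(grid_steps = sample(3:5, 1))
    got <- grid_search_rule(fx$features, fx$labels, sel, cfg)
    want <- brute_grid(fx$features, fx$labels, sel, cfg)
    expect_equal(got$training_f, want$f)
    expect_equal(got$conditions$threshold, want$thresholds)
  }
})

test_that("grid search recovers a planted two-condition rule within one step", {
  set.seed(123)
  n <- 300
  cat <- feature_catalogue()
  f <- matrix(rnorm(n * 48), nrow = n, dimnames = list(NULL, cat$name))
  f[, "amplitude"] <- runif(n, 0, 40)
  f[, "whole_symmetry"] <- runif(n, 0, 1)
  labels <- f[, "amplitude"] >= 20 & f[, "whole_symmetry"] >= 0.5
  # margins: clear the planted boundary so the quantile grid can straddle it
  keep <- abs(f[, "amplitude"] - 20) > 2 & abs(f[, "whole_symmetry"] - 0.5) > 0.05
  f <- f[keep, ]; labels <- labels[keep]
  sel <- data.frame(feature = c("amplitude", "whole_symmetry"),
                    direction = c("ge", "ge"), stringsAsFactors = FALSE)
  cfg <- learner_config(grid_steps = 13)
  rule <- grid_search_rule(f, labels, sel, cfg)
  expect_gte(rule$training_f, 0.9)
  grid_a <- sort(unique(unname(quantile(f[, "amplitude"],
                                        seq(0.05, 0.95, length.out = 13)))))
  step_a <- max(diff(grid_a))
  expect_lt(abs(rule$conditions$threshold[1] - 20), step_a + 1e-9)
  grid_s <- sort(unique(unname(quantile(f[, "whole_symmetry"],
                                        seq(0.05, 0.95, length.out = 13)))))
  expect_lt(abs(rule$conditions$threshold[2] - 0.5), max(diff(grid_s)) + 1e-9)
})

test_that("an oversized grid is refused with advice", {
  fx <- signal_features(20, 10, list(amplitude = list(pos = 30, neg = 10, sd = 3),
                                     up_duration_s = list(pos = 20, neg = 10, sd = 3),
                                     whole_sd_sbp = list(pos = 5, neg = 2, sd = 1)))
  sel <- data.frame(feature = c("amplitude", "up_duration_s", "whole_sd_sbp"),
                    direction = "ge", stringsAsFactors = FALSE)
  cfg <- learner_config(grid_steps = 13, max_grid_size = 100)
  expect_error(grid_search_rule(fx$features, fx$labels, sel, cfg),
               "fewer conditions")
})

test_that("rule application uses inclusive thresholds and AND semantics", {
  f <- matrix(c(26, 15, 20), ncol = 1, dimnames = list(NULL, "amplitude"))
  f <- cbind(f, whole_symmetry = c(0.9, 0.9, 0.4))
  rule <- structure(list(conditions = data.frame(
    feature = c("amplitude", "whole_symmetry"), direction = c("ge", "ge"),
    threshold = c(20, 0.5), stringsAsFactors = FALSE
  ), training_f = 1), class = "decision_rule")
  expect_identical(apply_rule(rule, f), c(TRUE, FALSE, FALSE))
  # boundary value exactly at the threshold is positive
  f2 <- rbind(f, c(20, 0.5))
  expect_true(apply_rule(rule, f2)[4])
  empty <- structure(list(conditions = data.frame()), class = "decision_rule")
  expect_error(apply_rule(empty, f), "no conditions")
  bad <- rule; bad$conditions$feature[2] <- "nonexistent"
  expect_error(apply_rule(bad, f), "unknown feature")
})

test_that("adding a condition never raises recall and never lowers precision", {
  set.seed(5)
  for (case in 1:20) {
    n <- 60
    f <- matrix(rnorm(n * 2), ncol = 2,
                dimnames = list(NULL, c("amplitude", "whole_sd_sbp")))
    labels <- runif(n) < 0.5
    r1 <- structure(list(conditions = data.frame(
      feature = "amplitude", direction = "ge", threshold = rnorm(1),
      stringsAsFactors = FALSE)), class = "decision_rule")
    r2 <- r1
    r2$conditions <- rbind(r2$conditions, data.frame(
      feature = "whole_sd_sbp", direction = "ge", threshold = rnorm(1),
      stringsAsFactors = FALSE))
    p1 <- apply_rule(r1, f); p2 <- apply_rule(r2, f)
    tp1 <- sum(p1 & labels); fp1 <- sum(p1 & !labels)
    tp2 <- sum(p2 & labels); fp2 <- sum(p2 & !labels)
    expect_lte(tp2, tp1)                       # recall can only drop
    # the AND rule never adds detections, so false positives cannot grow
    expect_true(all(which(p2) %in% which(p1)))
    expect_lte(fp2, fp1)
  }
})

test_that("training on clean separable nights reaches F = 1", {
  nights <- lapply(0:2, clean_night)
  model <- train_detector(nights)
  expect_s3_class(model, "surge_model")
  expect_equal(model$rule$training_f, 1.0)
  expect_gt(model$meta$n_positive, 0)
})

test_that("training is deterministic and invariant to night order", {
  nights <- lapply(0:2, clean_night)
  m1 <- train_detector(nights)
  m2 <- train_detector(nights)
  expect_identical(m1$rule, m2$rule)
  m3 <- train_detector(rev(nights))
  expect_identical(m1$rule$conditions, m3$rule$conditions)
})

test_that("nights without labels cannot train a rule", {
  bare <- generate_night(sim_config(duration_s = 3600, sa_surge_rate = 0,
                                    nonsa_surge_rate = 0, confuser_rate = 5),
                         seed = 1)
  expect_error(train_detector(list(list(series = bare$series,
                                        labels = bare$labels))),
               "no labels")
})

test_that("models round-trip through JSON", {
  nights <- lapply(0:1, clean_night)
  model <- train_detector(nights)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$rule$conditions, model$rule$conditions)
  expect_equal(back$rule$training_f, model$rule$training_f)
  expect_equal(back$detector$window_s, model$detector$window_s)
  expect_equal(back$meta$catalogue_version, model$meta$catalogue_version)
  # a trained model detects its own training surges
  det <- detect_surges(nights[[1]]$series, back)
  expect_gt(nrow(det), 0)
  expect_true(all(det$source == "detection"))
})
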