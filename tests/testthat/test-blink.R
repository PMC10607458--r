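test_that("fixed-threshold counting applies the three-frame run rule", {
  expect_equal(count_blinks_fixed(es(rep(0.25, 20))), 0)
  # one dip of exactly 3 frames counts, a 2-frame dip does not
  expect_equal(count_blinks_fixed(es(c(rep(0.25, 5), rep(0.1, 3), rep(0.25, 5)))), 1)
  expect_equal(count_blinks_fixed(es(c(rep(0.25, 5), rep(0.1, 2), rep(0.25, 5)))), 0)
  # two 4-frame dips separated by a single open frame are two blinks
  x <- c(rep(0.25, 3), rep(0.1, 4), 0.25, rep(0.1, 4), rep(0.25, 3))
  expect_equal(count_blinks_fixed(es(x)), 2)
  # boundary: comparison is <= at the threshold
  expect_equal(count_blinks_fixed(es(c(0.25, rep(0.163, 3), 0.25))), 1)
  expect_error(count_blinks_fixed(es(numeric(0))), "empty")
})

test_that("fixed-threshold counter agrees with the brute-force run oracle", {
  set.seed(21)
  for (i in 1:200) {
    x <- runif(sample(5:150, 1), 0, 0.3)
    x[runif(length(x)) < 0.05] <- NA # sprinkle dropout
    min_run <- sample(1:4, 1)
    expect_equal(
      count_blinks_fixed(es(x), threshold = 0.163, min_run = min_run),
      oracle_count_runs(x, 0.163, min_run)
    )
  }
})

test_that("missing frames break runs unless bridged", {
  x <- c(rep(0.25, 3), 0.1, 0.1, NA, 0.1, 0.1, rep(0.25, 3))
  expect_equal(count_blinks_fixed(es(x)), 0) # both fragments are too short
  expect_equal(count_blinks_fixed(es(x), bridge_gap = 1), 1) # dropout absorbed
  # a long gap is never bridged by a smaller allowance
  x2 <- c(rep(0.25, 3), rep(0.1, 3), NA, NA, NA, rep(0.1, 3), rep(0.25, 3))
  expect_equal(count_blinks_fixed(es(x2), bridge_gap = 1), 2)
  expect_equal(count_blinks_fixed(es(x2), bridge_gap = 3), 1)
})

test_that("dynamic thresholds follow the span formula", {
  s <- ear_summary(es(c(0.27527, 0.1, 0)))
  thr <- dynamic_thresholds(s)
  expect_equal(thr$full_threshold, 0.1281)
  expect_equal(thr$partial_threshold, 1.4 * 0.1281)

  s2 <- ear_summary(es(c(0.30, 0.2, 0.05)))
  thr2 <- dynamic_thresholds(s2)
  expect_equal(thr2$full_threshold, (0.1281 / 0.27527) * 0.25)
  expect_equal(thr2$partial_threshold / thr2$full_threshold, 1.4, tolerance = 1e-12)

  flat <- dynamic_thresholds(ear_summary(es(rep(0.2, 4))))
  expect_equal(flat$full_threshold, 0)
  expect_equal(flat$partial_threshold, 0)

  expect_error(
    dynamic_thresholds(structure(list(max_ear = 0.1, min_ear = 0.2), class = "ear_summary")),
    "invalid summary"
  )
})

test_that("events are segmented by the partial band and classified by their minimum", {
  open <- rep(0.25, 5)
  thr <- threshold_pair(0.10, 0.14)
  # dip bottoming below the full threshold -> one FULL event
  full_dip <- es(c(open, rep(0.05, 3), open))
  ev <- segment_events(full_dip, thr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "FULL")
  expect_equal(ev$min_ear, 0.05)
  # dip bottoming between the thresholds -> one PARTIAL event
  part_dip <- es(c(open, rep(0.12, 3), open))
  expect_equal(segment_events(part_dip, thr)$kind, "PARTIAL")
  # dip above the partial threshold -> no event
  expect_equal(nrow(segment_events(es(c(open, rep(0.2, 4), open)), thr)), 0)
  # entry/exit frames inside the partial band merge into the full event
  tra <- es(c(open, 0.12, rep(0.05, 3), 0.12, open))
  ev2 <- segment_events(tra, thr)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "FULL")
  expect_equal(ev2$n_frames, 5)
})

test_that("lowering the full threshold shifts events from full to partial only", {
  set.seed(22)
  x <- pmax(0, 0.25 + rnorm(600, 0, 0.002))
  dips <- seq(10, 580, by = 40)
  for (i in seq_along(dips)) {
    x[dips[i] + 0:3] <- runif(1, 0, 0.14)
  }
  s <- es(x)
  partial_thr <- 0.15
  fulls <- seq(0.14, 0, by = -0.02)
  counts <- t(vapply(fulls, function(f) {
    ev <- segment_events(s, threshold_pair(f, partial_thr))
    c(full = sum(ev$kind == "FULL"), partial = sum(ev$kind == "PARTIAL"), n = nrow(ev))
  }, numeric(3)))
  expect_true(all(diff(counts[, "full"]) <= 0))
  expect_true(all(diff(counts[, "partial"]) >= 0))
  # conservation: kinds partition the segmented events
  expect_true(all(counts[, "full"] + counts[, "partial"] == counts[, "n"]))
})

test_that("offset reference is shift-invariant, absolute is not", {
  x <- c(rep(0.30, 5), rep(0.10, 3), rep(0.30, 5)) # MinEAR well above zero
  s <- es(x)
  shift <- 0.05
  s_up <- es(x + shift)
  for (ref in c("absolute", "offset")) {
    thr <- dynamic_thresholds(ear_summary(s), reference = ref)
    thr_up <- dynamic_thresholds(ear_summary(s_up), reference = ref)
    # thresholds themselves depend only on the span
    expect_equal(thr_up$full_threshold, thr$full_threshold)
    n <- nrow(segment_events(s, thr))
    n_up <- nrow(segment_events(s_up, thr_up))
    if (ref == "offset") expect_equal(n_up, n) else expect_false(n_up == n)
  }
  # as printed, the absolute comparison cannot fire when MinEAR >> span
  thr_abs <- dynamic_thresholds(ear_summary(s_up), reference = "absolute")
  expect_equal(nrow(segment_events(s_up, thr_abs)), 0)
  # the offset mode recovers the dip
  thr_off <- dynamic_thresholds(ear_summary(s_up), reference = "offset")
  expect_equal(nrow(segment_events(s_up, thr_off)), 1)
})

test_that("metrics normalise counts to per-minute rates", {
  mk <- function(x, fps) {
    s <- es(x, fps = fps)
    compute_metrics(segment_events(s, dynamic_thresholds(ear_summary(s))), s)
  }
  # no events
  m0 <- mk(c(0.2, 0.25, rep(0.24, 1798)), 30)
  expect_equal(m0$full_count + m0$partial_count, 0)
  expect_equal(m0$full_rate_per_min, 0)
  # 15 full blinks in 30 s -> 30 per minute
  x <- rep(0.25, 900)
  for (st in seq(10, 850, by = 60)) x[st + 0:3] <- 0.02
  m <- mk(x, 30)
  expect_equal(m$full_count, 15)
  expect_equal(m$duration, 30)
  expect_equal(m$full_rate_per_min, 30)
  # open/close ratio is min/max in percent
  expect_equal(m$open_close_ratio_pct, 100 * 0.02 / 0.25)
})

test_that("threshold pairs validate their ordering", {
  expect_error(threshold_pair(0.2, 0.1), "partial_threshold")
  expect_error(threshold_pair(-0.1), "full_threshold")
  expect_equal(threshold_pair(0.1)$partial_threshold, 0.14)
})
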