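# Build a noise-free trapezoidal blink trace: baseline level with a linear
# descent to a plateau and a linear return, sampled at `fps`.
trapezoid_trace <- function(onset_s, closing_s, closed_s, reopening_s,
                            duration_s = 20, fps = 30, baseline = 10,
                            plateau = 0.2) {
  t <- (seq_len(duration_s * fps) - 1) / fps
  d <- rep(baseline, length(t))
  t1 <- onset_s; t2 <- t1 + closing_s; t3 <- t2 + closed_s
  t4 <- t3 + reopening_s
  ramp_dn <- t >= t1 & t < t2
  d[ramp_dn] <- baseline + (plateau - baseline) * (t[ramp_dn] - t1) / closing_s
  d[t >= t2 & t < t3] <- plateau
  ramp_up <- t >= t3 & t < t4
  d[ramp_up] <- plateau + (baseline - plateau) * (t[ramp_up] - t3) / reopening_s
  d
}

test_that("the running maximum tracks the open-eye amplitude", {
  d <- rep(10, 600)
  m <- track_max_distance(d, 30)
  expect_equal(m, rep(10, 600))
  # instant upward jump on exceedance, slow decay afterwards
  d2 <- c(rep(10, 100), 14, rep(10, 499))
  m2 <- track_max_distance(d2, 30)
  expect_equal(m2[101], 14)
  expect_true(all(diff(m2[101:600]) <= 0))
  expect_gt(m2[600], 10)
  # positive homogeneity: scaling the trace scales the tracker
  expect_equal(track_max_distance(3 * d2, 30), 3 * m2)
})

test_that("normalized openness is scale-free and clipped", {
  d <- trapezoid_trace(5, 0.1, 0.12, 0.18)
  m <- track_max_distance(d, 30)
  r <- normalize_trace(d, m)
  expect_true(all(r >= 0 & r <= 1.5))
  r3 <- normalize_trace(3 * d, track_max_distance(3 * d, 30))
  expect_equal(r3, r)
  expect_error(normalize_trace(d, rep(0, length(d))), "positive")
})

test_that("segmentation recovers a clean trapezoid blink with sub-sample accuracy", {
  fps <- 30
  for (onset in c(5.000, 5.013, 7.521)) {
    d <- trapezoid_trace(onset, 0.100, 0.200, 0.150, fps = fps)
    r <- normalize_trace(d, track_max_distance(d, fps))
    b <- segment_blinks(r, fps)
    expect_equal(nrow(b), 1)
    expect_lt(abs(b$closing_ms - 100), 1000 / fps)
    expect_lt(abs(b$closed_ms - 200), 1000 / fps)
    expect_lt(abs(b$reopening_ms - 150), 1000 / fps)
    expect_lt(abs(b$total_ms - 450), 1000 / fps)
  }
})

test_that("segmentation is equivariant under whole-sample time shifts", {
  fps <- 30
  d1 <- trapezoid_trace(5, 0.1, 0.15, 0.18)
  d2 <- trapezoid_trace(5 + 45 / fps, 0.1, 0.15, 0.18)
  b1 <- segment_blinks(normalize_trace(d1, track_max_distance(d1, fps)), fps)
  b2 <- segment_blinks(normalize_trace(d2, track_max_distance(d2, fps)), fps)
  expect_equal(b2$closing_start, b1$closing_start + 45)
  expect_equal(b2$closing_ms, b1$closing_ms, tolerance = 1e-6)
  expect_equal(b2$closed_ms, b1$closed_ms, tolerance = 1e-6)
})

test_that("flat traces, shallow dips and boundary blinks yield no events", {
  fps <- 30
  expect_equal(nrow(segment_blinks(rep(1, 300), fps)), 0)
  # a dip that never reaches the closed threshold is not a blink
  d <- trapezoid_trace(5, 0.1, 0.2, 0.15, plateau = 5)
  r <- normalize_trace(d, track_max_distance(d, fps))
  expect_equal(nrow(segment_blinks(r, fps)), 0)
  # a blink cut by the trace start is dropped
  d2 <- trapezoid_trace(0, 0.1, 0.2, 0.15)[-(1:2)]
  r2 <- normalize_trace(d2, track_max_distance(d2, fps))
  expect_equal(nrow(segment_blinks(r2, fps)), 0)
})

test_that("window features count blinks, microsleeps and PERCLOS correctly", {
  fps <- 30
  # one long closure (microsleep) plus one normal blink
  d <- trapezoid_trace(3, 0.1, 0.8, 0.15, duration_s = 20) +
    trapezoid_trace(10, 0.1, 0.12, 0.18, duration_s = 20) - 10
  r <- normalize_trace(d, track_max_distance(d, fps))
  b <- segment_blinks(r, fps)
  expect_equal(nrow(b), 2)
  f <- window_features(b, r, fps, 15, 15)
  expect_equal(unname(f["n_microsleep"]), 1)
  expect_equal(unname(f["mean_blink_ms"]), mean(b$total_ms))
  # PERCLOS equals the fraction of window samples below 0.3
  expect_equal(unname(f["perclos70"]), mean(r[1:(15 * fps)] < 0.3))
  # a window before any blink has zero blink features but real PERCLOS
  f0 <- window_features(b, r, fps, 2, 2)
  expect_equal(unname(f0["mean_blink_ms"]), 0)
  expect_equal(unname(f0["n_microsleep"]), 0)
})

test_that("the feature vector stacks four windows of six features", {
  s <- deprived_session()
  ctx <- session_blink_context(s)
  fv <- feature_vector(ctx, 90)
  expect_length(fv, 24)
  expect_true(all(grepl("_w(5|15|30|60)$", names(fv))))
  expect_error(feature_vector(ctx, 30), "at least 60")
  X <- feature_matrix(s, c(90, 120, 150))
  expect_equal(dim(X), c(3L, 24L))
  expect_equal(unname(X[1, ]), unname(fv))
  # features are invariant to a uniform camera-scale change
  s2 <- s
  s2$left_dist <- 2.5 * s$left_dist
  s2$right_dist <- 2.5 * s$right_dist
  expect_equal(feature_matrix(s2, c(90, 120)), feature_matrix(s, c(90, 120)),
               tolerance = 1e-8)
})
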