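test_that("derived seeds are deterministic, distinct and valid for set.seed", {
  expect_identical(derive_seed(1, "a", 2), derive_seed(1, "a", 2))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  seeds <- vapply(1:200, function(i) derive_seed(42, "x", i), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 195)
})

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(synthetic_config(duration_s = -1))
  expect_error(synthetic_config(stimulus_interval_s = c(10, 2)))
  expect_error(synthetic_config(drowsiness_process = list(level_range = c(0.5, 2))),
               "level_range")
  expect_error(synthetic_config(blink_model = list(base_rate = -2)),
               "blink_model")
  expect_error(synthetic_config(rt_model = list(alert_speed_mean = 0)),
               "rt_model")
})

test_that("alert sessions pin the latent drowsiness at zero, deprived stay in range", {
  cfg <- synthetic_config(duration_s = 240, seed = 11)
  d0 <- simulate_drowsiness(cfg, "alert", 5)
  expect_identical(unique(d0), 0)
  expect_length(d0, 240 * 30)
  d1 <- simulate_drowsiness(cfg, "deprived", 5)
  lr <- cfg$drowsiness_process$level_range
  expect_true(all(d1 >= lr[1] - 1e-12 & d1 <= lr[2] + 1e-12))
  # piecewise-constant per 60-s block
  blocks <- split(d1, rep(seq_len(4), each = 60 * 30))
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1, logical(1))))
})

test_that("session simulation is reproducible and seed-sensitive", {
  cfg <- synthetic_config(duration_s = 120, seed = 3)
  a <- simulate_session(cfg, "S01", "PVT1", "deprived", seed = 99)
  b <- simulate_session(cfg, "S01", "PVT1", "deprived", seed = 99)
  cc <- simulate_session(cfg, "S01", "PVT1", "deprived", seed = 100)
  expect_identical(a$left_dist, b$left_dist)
  expect_identical(a$rt, b$rt)
  expect_identical(a$blink_log, b$blink_log)
  expect_false(identical(a$left_dist, cc$left_dist))
})

test_that("the generator's blink log is a faithful schedule of the trace", {
  s <- alert_session()
  log <- s$blink_log
  expect_gt(nrow(log), 20)
  expect_true(all(diff(log$onset_s) > 0))
  # blinks never overlap: next onset after previous blink's end
  ends <- log$onset_s + log$total_ms / 1000
  expect_true(all(log$onset_s[-1] > ends[-nrow(log)]))
  expect_equal(log$total_ms,
               log$closing_ms + log$closed_ms + log$reopening_ms)
  # alert sessions produce no microsleeps and sub-500 ms blinks
  expect_false(any(log$microsleep))
  expect_true(all(log$total_ms < 500))
})

test_that("reaction times follow the reciprocal-normal drowsiness coupling", {
  cfg <- synthetic_config(duration_s = 600, seed = 21,
                          drowsiness_process = list(level_range = c(0.5, 1)))
  al <- simulate_session(cfg, "S01", "PVT1", "alert", seed = 1,
                         subject_speed = 1 / 280)
  de <- simulate_session(cfg, "S01", "PVT2", "deprived", seed = 2,
                         subject_speed = 1 / 280)
  expect_true(all(al$rt$rt_ms > 0 & al$rt$rt_ms <= 3000))
  expect_false(is.unsorted(al$rt$stimulus_time_s))
  expect_true(all(al$rt$stimulus_time_s < cfg$duration_s))
  # mean gap near the middle of the uniform [2, 10] range
  expect_gt(mean(diff(al$rt$stimulus_time_s)), 5)
  expect_lt(mean(diff(al$rt$stimulus_time_s)), 7)
  # drowsiness slows reactions, markedly
  expect_gt(median(de$rt$rt_ms), median(al$rt$rt_ms) + 100)
  # within the deprived session, higher latent level at the stimulus means
  # slower reactions (rank correlation)
  d_at <- de$latent[floor(de$rt$stimulus_time_s * de$fps) + 1]
  expect_gt(cor(d_at, de$rt$rt_ms, method = "spearman"), 0.2)
})

test_that("deprived sessions blink longer and reach microsleeps", {
  s <- deprived_session()
  a <- alert_session()
  expect_gt(mean(s$blink_log$closed_ms), mean(a$blink_log$closed_ms))
  cfg <- synthetic_config(duration_s = 600, seed = 77,
                          drowsiness_process = list(level_range = c(0.9, 1)))
  de <- simulate_session(cfg, "S01", "PVT2", "deprived", seed = 3)
  expect_gt(sum(de$blink_log$microsleep), 0)
  expect_true(all(de$blink_log$total_ms[de$blink_log$microsleep] > 500))
})

test_that("cohort simulation yields one session per subject and schedule slot", {
  sess <- tiny_cohort()
  expect_length(sess, 8)
  ids <- vapply(sess, function(s) paste(s$subject_id, s$pvt_id), character(1))
  expect_length(unique(ids), 8)
  tags <- vapply(sess, function(s) s$tag, character(1))
  expect_identical(sort(unique(tags)), c("alert", "deprived"))
  expect_error(simulate_cohort(synthetic_config(n_subjects = 1)),
               "at least 2")
})
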