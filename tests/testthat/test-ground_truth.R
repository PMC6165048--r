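mk_session <- function(id, rts, times = seq_along(rts)) {
  structure(list(subject_id = id, pvt_id = "PVT1", tag = "alert",
                 rt = data.frame(stimulus_time_s = times, rt_ms = rts)),
            class = "pvt_session")
}

test_that("normalization shifts each subject's alert speed onto the population mean", {
  ref <- list(mk_session("A", c(250, 300, 280)),
              mk_session("B", c(400, 380, 420)))
  mod <- fit_normalization(ref)
  expect_s3_class(mod, "rt_norm_model")
  expect_named(mod$mu, c("A", "B"))
  expect_equal(mod$mu_pop, mean(mod$mu))
  # after normalization both subjects have the same mean reciprocal RT
  za <- normalize_rt(c(250, 300, 280), "A", mod)
  zb <- normalize_rt(c(400, 380, 420), "B", mod)
  expect_equal(mean(1 / za), mean(1 / zb))
  expect_equal(mean(1 / za), mod$mu_pop)
})

test_that("a subject at the population mean is normalized by the identity", {
  mod <- structure(list(mu = c(A = 1 / 300), mu_pop = 1 / 300),
                   class = "rt_norm_model")
  x <- c(200, 350, 999)
  expect_equal(normalize_rt(x, "A", mod), x)
  expect_error(normalize_rt(x, "Z", mod), "not in normalization model")
})

test_that("degenerate reference data is excluded or rejected with diagnostics", {
  ref <- list(mk_session("A", c(250, 300)), mk_session("B", numeric(0)))
  expect_warning(mod <- fit_normalization(ref), "no reference RTs")
  expect_named(mod$mu, "A")
  expect_error(suppressWarnings(fit_normalization(list(mk_session("B", numeric(0))))),
               "no subject")
  # nonpositive shifted speed becomes NA with a warning
  mod2 <- structure(list(mu = c(A = 1 / 100), mu_pop = 1 / 1000),
                    class = "rt_norm_model")
  expect_warning(z <- normalize_rt(c(150, 500), "A", mod2), "nonpositive")
  expect_true(is.na(z[2]))
})

test_that("the shortest-timescale median RT picks the nearest event, earlier on ties", {
  times <- c(10, 12, 20)
  rts <- c(100, 200, 300)
  expect_equal(median_rt_m1(10.3, times, rts), 100)
  expect_equal(median_rt_m1(11.2, times, rts), 200)
  expect_equal(median_rt_m1(11, times, rts), 100)   # equidistant: earlier
  # empty window: linear interpolation in RT value between the neighbours
  expect_equal(median_rt_m1(16, times, rts), 200 + (300 - 200) * (16 - 12) / (20 - 12))
  # undefined outside the event support
  expect_true(is.na(median_rt_m1(8.5, times, rts)))
  expect_true(is.na(median_rt_m1(25, times, rts)))
  expect_true(all(is.na(median_rt_m1(c(1, 2), numeric(0), numeric(0)))))
})

test_that("windowed median RTs equal the brute-force harmonic mean", {
  set.seed(55)
  times <- sort(runif(80, 0, 400))
  rts <- runif(80, 200, 900)
  tt <- seq(30, 380, by = 7)
  for (lb in c(15, 30, 60)) {
    got <- median_rt_window(tt, times, rts, lb)
    want <- vapply(tt, function(t0) {
      sel <- times >= t0 - lb & times <= t0 + 5
      if (!any(sel)) NA_real_ else 1 / mean(1 / rts[sel])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("harmonic-mean medians never exceed the arithmetic window mean", {
  set.seed(56)
  times <- sort(runif(60, 0, 300))
  rts <- runif(60, 200, 900)
  tt <- seq(60, 240, by = 11)
  hm <- median_rt_window(tt, times, rts, 30)
  am <- vapply(tt, function(t0) {
    sel <- times >= t0 - 30 & times <= t0 + 5
    if (!any(sel)) NA_real_ else mean(rts[sel])
  }, numeric(1))
  expect_true(all(hm <= am + 1e-12, na.rm = TRUE))
})

test_that("median_rts drops non-finite normalized RTs before windowing", {
  times <- c(5, 10, 15)
  rts <- c(300, NA, 500)
  m <- median_rts(12, times, rts)
  expect_identical(colnames(m), c("m1", "m2", "m3", "m4"))
  expect_equal(unname(m[1, "m2"]), 1 / mean(1 / c(300, 500)))
})

test_that("label probabilities honor the 400/500 ms thresholds inclusively", {
  expect_equal(label_probability(c(399, 400, 450, 500, 501, NA)),
               c(0, 0, 0.5, 1, 1, NA))
})

test_that("training strata count the median RTs at or above 470 ms", {
  expect_identical(assign_stratum(c(400, 470, 480, 500)), 3L)
  expect_identical(assign_stratum(c(100, 200, 300, 400)), 0L)
  expect_identical(assign_stratum(rep(600, 4)), 4L)
  expect_true(is.na(assign_stratum(c(NA, 500, 500, 500))))
  m <- rbind(c(400, 470, 480, 500), rep(600, 4))
  expect_identical(assign_stratum(m), c(3L, 4L))
})

test_that("validation weights are half the reciprocal occurrence frequency", {
  expect_equal(validation_weights(0.5), 1)
  expect_equal(validation_weights(c(0.25, 0.75)), c(2, 2 / 3))
  expect_error(validation_weights(0), "inside")
  expect_error(validation_weights(1), "inside")
  m <- cbind(c(400, 400, 600, 600), c(400, 600, 600, 600),
             c(600, 400, 400, 400), c(600, 600, 600, 400))
  vw <- compute_validation_weights(m)
  expect_equal(dim(vw$freq), c(4L, 2L))
  expect_equal(rowSums(vw$freq), rep(1, 4))
  expect_equal(vw$weight, 1 / (2 * vw$freq))
})

test_that("session labeling produces coherent per-stimulus rows", {
  s <- deprived_session()
  mod <- tiny_norm_model()
  lab <- label_session(s, mod)
  expect_true(all(c("t", "m1", "m4", "p1", "p4", "stratum") %in% names(lab)))
  expect_true(all(lab$t >= 60))
  expect_true(all(lab$p1 %in% c(0, 0.5, 1) | is.na(lab$p1)))
  ok <- !is.na(lab$stratum)
  expect_true(all(lab$stratum[ok] %in% 0:4))
})
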