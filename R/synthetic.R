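#' Configuration for the synthetic PVT-session simulator
#'
#' Builds the configuration object consumed by [simulate_cohort()] and the
#' lower-level `simulate_*()` generators. A synthetic session couples two
#' observable streams through a latent drowsiness process `D(t)` in `[0, 1]`:
#'
#' * an eyelid-distance trace (two channels, pixels, 30 Hz) in which blinks
#'   become longer -- and microsleeps more frequent -- as `D` increases, and
#' * a log of PVT stimuli and reaction times in which the reaction *speed*
#'   (reciprocal RT, approximately normal for an individual) decreases
#'   linearly with `D`.
#'
#' Defaults describe a 10-minute PVT at 30 Hz with stimuli at uniform random
#' intervals between 2 and 10 s, an alert reaction speed corresponding to a
#' 280 ms mean RT, and a speed loss at `D = 1` that brings the mean RT above
#' 700 ms, so fully drowsy epochs produce median RTs well past the 500 ms
#' lapse threshold.
#'
#' @param duration_s Session length in seconds.
#' @param fps Trace sampling rate in Hz; `duration_s * fps` must be integer.
#' @param n_subjects Number of subjects in a cohort (at least 2, so that
#'   leave-one-subject-out folds exist).
#' @param pvt_schedule Character vector of session tags simulated per subject,
#'   e.g. `c("alert", "deprived")`. `"alert"` pins the latent drowsiness at 0
#'   (the reference, PVT1-like condition); `"deprived"` draws it from
#'   `level_range`.
#' @param drowsiness_process List with `kind` (`"piecewise-constant"` or
#'   `"smoothed-random-walk"`), `level_range` (subset of `[0, 1]`) and
#'   `volatility`. For the piecewise-constant process the latent level is
#'   constant over 1-minute blocks and drawn around the midpoint of
#'   `level_range` with spread proportional to `volatility` (`volatility = 0`
#'   gives a constant level; `volatility = 1` spans the full range). For the
#'   random walk, `volatility` is the per-second step standard deviation.
#' @param blink_model List with `base_rate` (blinks per minute), `baseline_px`
#'   (eyes-open eyelid distance, pixels), `base_durations_ms` (closing,
#'   closed, reopening phase durations at `D = 0`), `drowsy_duration_gain`
#'   (multiplier on all phase durations at `D = 1`), `microsleep_prob_at_D1`
#'   (per-blink probability, at `D = 1`, of an extended closed phase longer
#'   than 500 ms) and `noise_sd_frac` (per-channel Gaussian noise, as a
#'   fraction of `baseline_px`).
#' @param rt_model List with `alert_speed_mean`, `speed_loss_at_D1`,
#'   `speed_sd` and `subject_speed_sd`, all in 1/ms. A subject's alert speed
#'   is drawn once per subject; each reaction speed is drawn as
#'   `Normal(subject_speed - speed_loss_at_D1 * D, speed_sd)` truncated below
#'   at `1/3000` ms^-1.
#' @param stimulus_interval_s Length-2 range (seconds) of the uniform
#'   inter-stimulus gaps.
#' @param seed Master integer seed for a cohort.
#'
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(duration_s = 600,
                             fps = 30,
                             n_subjects = 8,
                             pvt_schedule = c("alert", "deprived"),
                             drowsiness_process = list(),
                             blink_model = list(),
                             rt_model = list(),
                             stimulus_interval_s = c(2, 10),
                             seed = 1L) {
  dp <- utils::modifyList(list(
    kind = "piecewise-constant",
    level_range = c(0.3, 1),
    volatility = 1,
    block_s = 60
  ), drowsiness_process)
  bm <- utils::modifyList(list(
    base_rate = 15,
    baseline_px = 10,
    base_durations_ms = c(closing = 100, closed = 120, reopening = 180),
    drowsy_duration_gain = 3,
    microsleep_prob_at_D1 = 0.25,
    noise_sd_frac = 0.02
  ), blink_model)
  rm_ <- utils::modifyList(list(
    alert_speed_mean = 1 / 280,
    speed_loss_at_D1 = 0.0022,
    speed_sd = 0.00045,
    subject_speed_sd = 0.00025
  ), rt_model)

  cfg <- structure(list(
    duration_s = duration_s, fps = fps, n_subjects = as.integer(n_subjects),
    pvt_schedule = pvt_schedule, drowsiness_process = dp, blink_model = bm,
    rt_model = rm_, stimulus_interval_s = stimulus_interval_s,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$duration_s > 0, cfg$fps > 0,
    abs(cfg$duration_s * cfg$fps - round(cfg$duration_s * cfg$fps)) < 1e-9,
    length(cfg$stimulus_interval_s) == 2,
    cfg$stimulus_interval_s[1] > 0,
    diff(cfg$stimulus_interval_s) >= 0
  )
  lr <- cfg$drowsiness_process$level_range
  if (length(lr) != 2 || lr[1] < 0 || lr[2] > 1 || lr[1] > lr[2])
    stop("drowsiness_process$level_range must be an ordered subset of [0, 1]")
  bm <- cfg$blink_model
  if (bm$base_rate <= 0 || bm$baseline_px <= 0 ||
      any(bm$base_durations_ms <= 0) || bm$drowsy_duration_gain < 1 ||
      bm$microsleep_prob_at_D1 < 0 || bm$microsleep_prob_at_D1 > 1)
    stop("invalid blink_model: rates and durations must be positive, gain >= 1, probability in [0, 1]")
  rm_ <- cfg$rt_model
  if (rm_$alert_speed_mean <= 0 || rm_$speed_sd < 0 ||
      rm_$subject_speed_sd < 0 || rm_$speed_loss_at_D1 < 0)
    stop("invalid rt_model: speeds must be positive, standard deviations nonnegative")
  invisible(cfg)
}

#' Derive a reproducible child seed from a master seed
#'
#' Hashes the master seed together with any number of string/number labels
#' into an integer in `[0, 2^31)`, suitable for `set.seed()`. All randomness
#' in the package flows from a master seed through this function, so any
#' component of a run can be reproduced in isolation.
#'
#' @param seed Master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Simulate the latent drowsiness process of one session
#'
#' Produces the latent level-of-drowsiness series `D(t)` on the trace grid.
#' `"alert"` sessions pin `D` at 0 (the rested, reference condition);
#' `"deprived"` sessions draw it from the configured drowsiness process.
#'
#' @param config A [synthetic_config()] object.
#' @param session_tag `"alert"` or `"deprived"`.
#' @param seed Integer seed.
#' @return Numeric vector of length `duration_s * fps`, with values in `[0, 1]`.
#' @export
simulate_drowsiness <- function(config, session_tag, seed) {
  n <- round(config$duration_s * config$fps)
  if (identical(session_tag, "alert")) return(numeric(n))
  if (!identical(session_tag, "deprived"))
    stop("unknown session_tag: ", session_tag)
  dp <- config$drowsiness_process
  lo <- dp$level_range[1]; hi <- dp$level_range[2]
  withr_seed(seed, {
    if (dp$kind == "piecewise-constant") {
      block_n <- round(dp$block_s * config$fps)
      n_blocks <- ceiling(n / block_n)
      centre <- (lo + hi) / 2
      lev <- centre + dp$volatility * stats::runif(n_blocks, -1, 1) * (hi - lo) / 2
      lev <- pmin(pmax(lev, lo), hi)
      rep(lev, each = block_n)[seq_len(n)]
    } else if (dp$kind == "smoothed-random-walk") {
      step_sd <- dp$volatility / sqrt(config$fps)
      d <- cumsum(stats::rnorm(n, 0, step_sd)) + (lo + hi) / 2
      # reflect into the admissible range, then smooth over ~2 s
      d <- reflect_into(d, lo, hi)
      k <- max(1L, round(2 * config$fps))
      d <- stats::filter(c(rep(d[1], k), d), rep(1 / k, k), sides = 1)
      pmin(pmax(as.numeric(d[-seq_len(k)]), lo), hi)
    } else stop("unknown drowsiness process kind: ", dp$kind)
  })
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# Evaluate code with a temporary RNG state seeded at `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a bilateral eyelid-distance trace given a latent drowsiness series
#'
#' Renders blinks as trapezoids (linear closing ramp, closed plateau near
#' zero, linear reopening ramp) on an eyes-open baseline. Phase durations are
#' scaled by `1 + (gain - 1) * D` at blink onset with multiplicative
#' per-blink jitter uniform in `[0.9, 1.1]`; with probability
#' `microsleep_prob_at_D1 * D` a blink's closed plateau is extended beyond
#' 500 ms (a microsleep). Left and right channels share the blink template
#' and receive independent Gaussian noise.
#'
#' @param D Latent drowsiness series on the trace grid (from
#'   [simulate_drowsiness()]).
#' @param config A [synthetic_config()] object.
#' @param seed Integer seed.
#' @return A list with `left_dist`, `right_dist` (pixels, same length as `D`)
#'   and `blink_log`, a data frame of ground-truth blink events
#'   (onset/phase times in seconds, durations in ms, microsleep flag) used as
#'   an oracle by the blink-segmentation tests.
#' @export
simulate_trace <- function(D, config, seed) {
  n <- length(D)
  fps <- config$fps
  dur <- n / fps
  bm <- config$blink_model
  base_s <- bm$base_durations_ms / 1000
  withr_seed(seed, {
    # --- schedule blinks sequentially so they never overlap
    onset <- numeric(0); closing <- numeric(0); closed <- numeric(0)
    reopening <- numeric(0); microsleep <- logical(0)
    t <- stats::rexp(1, rate = bm$base_rate / 60)
    while (t < dur) {
      d0 <- D[min(n, max(1L, floor(t * fps) + 1L))]
      gain <- 1 + (bm$drowsy_duration_gain - 1) * d0
      jit <- stats::runif(1, 0.9, 1.1)
      ph <- base_s * gain * jit
      is_ms <- stats::runif(1) < bm$microsleep_prob_at_D1 * d0
      if (is_ms) ph[2] <- stats::runif(1, 0.55, 1.4)
      if (t + sum(ph) >= dur) break
      onset <- c(onset, t); closing <- c(closing, ph[1])
      closed <- c(closed, ph[2]); reopening <- c(reopening, ph[3])
      microsleep <- c(microsleep, is_ms)
      t <- t + sum(ph) + 0.25 + stats::rexp(1, rate = bm$base_rate / 60)
    }
    # --- render the openness template at sample times
    tt <- (seq_len(n) - 1) / fps
    openness <- rep(1, n)
    plateau <- 0.02
    for (b in seq_along(onset)) {
      t0 <- onset[b]
      t1 <- t0 + closing[b]          # plateau start
      t2 <- t1 + closed[b]           # plateau end
      t3 <- t2 + reopening[b]        # fully reopened
      idx <- which(tt > t0 & tt < t3)
      for (i in idx) {
        ti <- tt[i]
        openness[i] <- if (ti < t1) {
          1 - (1 - plateau) * (ti - t0) / closing[b]
        } else if (ti <= t2) plateau else {
          plateau + (1 - plateau) * (ti - t2) / reopening[b]
        }
      }
    }
    base_px <- bm$baseline_px
    noise_sd <- bm$noise_sd_frac * base_px
    left <- pmax(base_px * openness + stats::rnorm(n, 0, noise_sd), 0)
    right <- pmax(base_px * openness + stats::rnorm(n, 0, noise_sd), 0)
    blink_log <- data.frame(
      onset_s = onset,
      closing_ms = closing * 1000,
      closed_ms = closed * 1000,
      reopening_ms = reopening * 1000,
      total_ms = (closing + closed + reopening) * 1000,
      microsleep = microsleep
    )
    list(left_dist = left, right_dist = right, blink_log = blink_log)
  })
}

#' Simulate PVT stimuli and reaction times given a latent drowsiness series
#'
#' Stimulus times accumulate uniform gaps drawn from
#' `config$stimulus_interval_s`. Each reaction speed is drawn from
#' `Normal(subject_speed - speed_loss_at_D1 * D(t), speed_sd)`, truncated
#' below at 1/3000 ms^-1, and the RT is its reciprocal.
#'
#' @param D Latent drowsiness series on the trace grid.
#' @param config A [synthetic_config()] object.
#' @param seed Integer seed.
#' @param subject_speed The subject's alert reaction speed in 1/ms (drawn
#'   once per subject by [simulate_cohort()]); defaults to the population
#'   mean.
#' @return Data frame with columns `stimulus_time_s` and `rt_ms`.
#' @export
simulate_rts <- function(D, config, seed,
                         subject_speed = config$rt_model$alert_speed_mean) {
  n <- length(D)
  fps <- config$fps
  dur <- n / fps
  rm_ <- config$rt_model
  lo <- config$stimulus_interval_s[1]; hi <- config$stimulus_interval_s[2]
  withr_seed(seed, {
    n_max <- ceiling(dur / lo) + 1
    times <- cumsum(stats::runif(n_max, lo, hi))
    times <- times[times < dur]
    d_at <- D[pmin(n, floor(times * fps) + 1L)]
    speed <- stats::rnorm(length(times),
                          mean = subject_speed - rm_$speed_loss_at_D1 * d_at,
                          sd = rm_$speed_sd)
    speed <- pmax(speed, 1 / 3000)
    data.frame(stimulus_time_s = times, rt_ms = 1 / speed)
  })
}

#' Simulate one synthetic PVT session
#'
#' @param config A [synthetic_config()] object.
#' @param subject_id,pvt_id Identifier tokens.
#' @param tag Session tag (`"alert"` or `"deprived"`).
#' @param seed Integer seed for this session.
#' @param subject_speed Subject alert reaction speed (1/ms).
#' @return An object of class `"pvt_session"`: a list with the trace
#'   (`time_s`, `left_dist`, `right_dist`), the RT log (`rt`), the latent
#'   drowsiness series (`latent`), the generator's `blink_log`, and metadata.
#' @export
simulate_session <- function(config, subject_id, pvt_id, tag, seed,
                             subject_speed = config$rt_model$alert_speed_mean) {
  D <- simulate_drowsiness(config, tag, derive_seed(seed, "drowsiness"))
  tr <- simulate_trace(D, config, derive_seed(seed, "trace"))
  rt <- simulate_rts(D, config, derive_seed(seed, "rts"), subject_speed)
  n <- length(D)
  structure(list(
    subject_id = subject_id, pvt_id = pvt_id, tag = tag,
    fps = config$fps, duration_s = config$duration_s,
    time_s = (seq_len(n) - 1) / config$fps,
    left_dist = tr$left_dist, right_dist = tr$right_dist,
    rt = rt, latent = D, blink_log = tr$blink_log, seed = seed
  ), class = "pvt_session")
}

#' @export
print.pvt_session <- function(x, ...) {
  cat(sprintf("<pvt_session> subject %s, pvt %s (%s): %.0f s at %g Hz, %d stimuli, %d blinks\n",
              x$subject_id, x$pvt_id, x$tag, x$duration_s, x$fps,
              nrow(x$rt), nrow(x$blink_log)))
  invisible(x)
}

#' Simulate a cohort of synthetic PVT sessions
#'
#' Generates one session per (subject, schedule tag). Each subject's alert
#' reaction speed is drawn once; all randomness is derived deterministically
#' from `config$seed`.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of [`pvt_session`][simulate_session] objects.
#' @export
simulate_cohort <- function(config) {
  validate_synthetic_config(config)
  if (config$n_subjects < 2)
    stop("n_subjects must be at least 2 (leave-one-subject-out needs >= 2 subjects)")
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  speeds <- withr_seed(derive_seed(config$seed, "subject_speeds"), {
    stats::rnorm(config$n_subjects, config$rt_model$alert_speed_mean,
                 config$rt_model$subject_speed_sd)
  })
  speeds <- pmax(speeds, 1 / 1000)
  sessions <- list()
  for (i in seq_along(subjects)) {
    for (j in seq_along(config$pvt_schedule)) {
      tag <- config$pvt_schedule[j]
      pvt_id <- sprintf("PVT%d", j)
      seed <- derive_seed(config$seed, subjects[i], pvt_id, tag)
      sessions[[length(sessions) + 1L]] <-
        simulate_session(config, subjects[i], pvt_id, tag, seed, speeds[i])
    }
  }
  sessions
}
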