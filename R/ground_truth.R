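#' Fit the inter-subject reaction-time normalization model
#'
#' Reaction times depend on individual skill as well as on drowsiness. Since
#' an individual's reaction *speed* (reciprocal RT) is approximately normal,
#' individual skill can be removed by shifting each subject's alert speed
#' distribution onto the population average. This function estimates, from
#' one rested reference session per subject (the PVT1-like, "alert"
#' session), the subject means `mu_k` of the reciprocal RTs, and their grand
#' mean `mu_pop` over the reference subjects.
#'
#' Subjects without any reference RTs are excluded with a warning (they
#' cannot be normalized and are dropped from downstream analyses).
#'
#' @param reference_sessions List of [`pvt_session`][simulate_session]
#'   objects (or lists with `subject_id` and `rt`), one or more per subject.
#' @return An object of class `"rt_norm_model"`: list with `mu` (named
#'   vector of per-subject mean reciprocal RTs, 1/ms) and `mu_pop`.
#' @export
fit_normalization <- function(reference_sessions) {
  subj <- vapply(reference_sessions, function(s) s$subject_id, character(1))
  mu <- c()
  for (id in unique(subj)) {
    rts <- unlist(lapply(reference_sessions[subj == id],
                         function(s) s$rt$rt_ms))
    rts <- rts[is.finite(rts) & rts > 0]
    if (length(rts) == 0) {
      warning("subject ", id, " has no reference RTs; excluded from normalization model")
      next
    }
    mu[id] <- mean(1 / rts)
  }
  if (length(mu) == 0) stop("no subject has reference RTs")
  structure(list(mu = mu, mu_pop = mean(mu)), class = "rt_norm_model")
}

#' Normalize reaction times across subjects
#'
#' Applies `x' = 1 / (1/x - mu_k + mu_pop)`: the subject's reciprocal-RT
#' distribution in the alert state is shifted onto the population average,
#' making the fixed 400/500 ms label thresholds comparable across subjects.
#' RTs whose shifted speed is nonpositive are returned as `NA` with a
#' warning; callers drop those events.
#'
#' @param x Vector of reaction times in ms.
#' @param subject_id Subject token present in `model`.
#' @param model An [`rt_norm_model`][fit_normalization].
#' @return Normalized reaction times in ms (`NA` where undefined).
#' @export
normalize_rt <- function(x, subject_id, model) {
  if (!subject_id %in% names(model$mu))
    stop("subject ", subject_id, " not in normalization model")
  speed <- 1 / x - model$mu[[subject_id]] + model$mu_pop
  bad <- !is.na(speed) & speed <= 0
  if (any(bad)) {
    warning(sum(bad), " RT(s) of subject ", subject_id,
            " have nonpositive shifted speed; returned as NA")
    speed[bad] <- NA_real_
  }
  1 / speed
}

#' Single-RT median at the shortest timescale
#'
#' The 5-s timescale "median RT" `m1` at evaluation time `t` is a single RT:
#' the event closest to `t` within the `[t - 1, t + 1]` window (earlier
#' event on ties), or, when the window is empty, the linear interpolation
#' (in RT value) between the previous and next events. It is undefined
#' (`NA`) before the first or after the last event.
#'
#' @param t Evaluation time(s), seconds.
#' @param times Sorted stimulus times, seconds.
#' @param rts Normalized RTs (ms) aligned with `times`.
#' @return `m1` in ms (`NA` where undefined), vectorized over `t`.
#' @export
median_rt_m1 <- function(t, times, rts) {
  if (length(times) == 0) return(rep(NA_real_, length(t)))
  # nearest event: compare the last event at-or-before t with the next one
  i_prev <- findInterval(t, times)                 # 0 if before first
  i_next <- pmin(i_prev + 1L, length(times))
  i_prev_c <- pmax(i_prev, 1L)
  d_prev <- abs(t - times[i_prev_c])
  d_next <- abs(times[i_next] - t)
  use_prev <- i_prev >= 1L & (d_prev <= d_next | i_prev == length(times))
  nearest <- ifelse(use_prev, i_prev_c, i_next)
  d_near <- abs(times[nearest] - t)
  out <- rep(NA_real_, length(t))
  in_win <- d_near <= 1
  out[in_win] <- rts[nearest[in_win]]
  # otherwise interpolate between surrounding events (undefined outside support)
  interp <- !in_win & i_prev >= 1L & i_prev < length(times)
  if (any(interp)) {
    i0 <- i_prev[interp]; i1 <- i0 + 1L
    w <- (t[interp] - times[i0]) / (times[i1] - times[i0])
    out[interp] <- (1 - w) * rts[i0] + w * rts[i1]
  }
  out
}

#' Windowed harmonic-mean median RT
#'
#' For the 15/30/60-s timescales, the "median RT" at `t` is the harmonic
#' mean of the normalized RTs whose stimulus falls in `[t - lookback,
#' t + 5]` seconds -- the median of the underlying reciprocal-normal RT
#' distribution, since reciprocal speeds are averaged. Undefined (`NA`) when
#' the window holds no event. Windows are deliberately non-causal (they are
#' used to build ground truth, not for inference).
#'
#' @param t Evaluation time(s), seconds.
#' @param times Sorted stimulus times, seconds.
#' @param rts Normalized RTs (ms) aligned with `times`.
#' @param lookback Window length into the past, seconds (15, 30 or 60).
#' @param lookahead Window extension into the future, seconds (default 5).
#' @return Harmonic-mean RT in ms (`NA` where undefined), vectorized over `t`.
#' @export
median_rt_window <- function(t, times, rts, lookback, lookahead = 5) {
  if (length(times) == 0) return(rep(NA_real_, length(t)))
  csum <- c(0, cumsum(1 / rts))
  # events with times in [t - lookback, t + lookahead]
  i_lo <- findInterval(t - lookback, times, left.open = TRUE)   # last idx < t-lb
  i_hi <- findInterval(t + lookahead, times)                    # last idx <= t+la
  k <- i_hi - i_lo
  s <- csum[i_hi + 1L] - csum[i_lo + 1L]
  ifelse(k > 0, k / s, NA_real_)
}

#' All four median RTs at given evaluation times
#'
#' @param t Evaluation time(s), seconds.
#' @param times Sorted stimulus times, seconds.
#' @param rts Normalized RTs (ms) aligned with `times`.
#' @return Matrix `length(t) x 4` with columns `m1..m4` (ms, `NA` where
#'   undefined): the single/interpolated RT and the harmonic means over the
#'   `[-15, +5]`, `[-30, +5]` and `[-60, +5]` s windows.
#' @export
median_rts <- function(t, times, rts) {
  keep <- is.finite(rts)
  times <- times[keep]; rts <- rts[keep]
  m <- cbind(
    m1 = median_rt_m1(t, times, rts),
    m2 = median_rt_window(t, times, rts, 15),
    m3 = median_rt_window(t, times, rts, 30),
    m4 = median_rt_window(t, times, rts, 60)
  )
  m
}

#' Ternary drowsiness label probability from a median RT
#'
#' `0` ("alert") for `m <= 400` ms, `1` ("drowsy") for `m >= 500` ms, and
#' `0.5` (indeterminate; discarded in binary evaluation) in between. The
#' 400 ms threshold sits near the upper tail of rested median RTs; 500 ms is
#' the conventional lapse threshold.
#'
#' @param m Median RT(s) in ms (may contain `NA`).
#' @return Values in `{0, 0.5, 1}` (`NA` preserved).
#' @export
label_probability <- function(m) {
  ifelse(m <= 400, 0, ifelse(m >= 500, 1, 0.5))
}

#' Training stratum of a sample
#'
#' Strata balance training epochs: each sample is assigned the count (0--4)
#' of its four median RTs that are greater than or equal to 470 ms. Samples
#' with any undefined median RT get `NA` and are excluded from the training
#' pool.
#'
#' @param m Matrix `n x 4` of median RTs (ms), or a length-4 vector.
#' @return Integer stratum 0..4 per row (`NA` if any median RT undefined).
#' @export
assign_stratum <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  out <- rowSums(m >= 470)
  out[rowSums(is.na(m)) > 0] <- NA
  as.integer(out)
}

#' Validation class-balancing weights
#'
#' The validation loss balances alert/drowsy contributions per timescale by
#' weighting each sample's i-th loss term with half the reciprocal of the
#' occurrence frequency of its side (median RT below vs at/above 470 ms):
#' `w = 1 / (2 f)`. A balanced side (`f = 0.5`) gets weight 1.
#'
#' @param f Occurrence frequencies in `(0, 1)` (any shape).
#' @return Weights of the same shape.
#' @export
validation_weights <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("occurrence frequencies must lie strictly inside (0, 1)")
  1 / (2 * f)
}

#' Validation weight table from validation-set median RTs
#'
#' Computes, per timescale, the fraction of validation samples whose median
#' RT is below vs at/above 470 ms, and the corresponding balancing weights.
#'
#' @param m Matrix `n x 4` of median RTs (ms) of the validation pool.
#' @return A list with `freq` and `weight`, both `4 x 2` matrices with
#'   columns `lt470` and `ge470`.
#' @export
compute_validation_weights <- function(m) {
  f_ge <- colMeans(m >= 470, na.rm = TRUE)
  freq <- cbind(lt470 = 1 - f_ge, ge470 = f_ge)
  list(freq = freq, weight = validation_weights(freq))
}

#' Label a session at chosen evaluation times
#'
#' Computes, at each evaluation time, the four median RTs (from the
#' subject's normalized RTs), the four ternary label probabilities, and the
#' training stratum.
#'
#' @param session A [`pvt_session`][simulate_session].
#' @param model An [`rt_norm_model`][fit_normalization].
#' @param t_eval Evaluation times (seconds). Default: the stimulus-anchored
#'   evaluation points of the session (see [sample_eval_points()]).
#' @return Data frame with columns `subject_id`, `pvt_id`, `t`, `m1..m4`,
#'   `p1..p4`, `stratum`.
#' @export
label_session <- function(session, model, t_eval = sample_eval_points(session)) {
  rts_norm <- suppressWarnings(
    normalize_rt(session$rt$rt_ms, session$subject_id, model))
  m <- median_rts(t_eval, session$rt$stimulus_time_s, rts_norm)
  p <- label_probability(m)
  colnames(p) <- paste0("p", 1:4)
  data.frame(
    subject_id = session$subject_id, pvt_id = session$pvt_id,
    t = t_eval, m, p, stratum = assign_stratum(m)
  )
}
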