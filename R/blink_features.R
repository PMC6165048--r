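#' Running maximum eyelid distance via adaptive exponential smoothing
#'
#' Tracks the eyes-open amplitude of a raw eyelid-distance trace:
#' `M_t = max(d_t, (1 - beta) * M_{t-1} + beta * d_t)`, initialized at the
#' 95th percentile of the first 5 seconds (or of the whole trace when it is
#' shorter). The max-clamp makes `M` jump up instantly when the eye opens
#' wider than ever; during closures `M` decays only geometrically at rate
#' `beta` per sample, so it keeps tracking the open-eye scale.
#'
#' @param d Raw eyelid-distance series (pixels), positive and finite.
#' @param fps Sampling rate in Hz.
#' @param beta Smoothing rate per sample (default 0.002).
#' @return Series `M` of the same length.
#' @export
track_max_distance <- function(d, fps, beta = 0.002) {
  stopifnot(all(is.finite(d)), length(d) > 0)
  n0 <- min(length(d), round(5 * fps))
  m0 <- stats::quantile(d[seq_len(n0)], 0.95, names = FALSE)
  as.numeric(track_max_rcpp(d, m0, beta))
}

#' Normalized eye openness
#'
#' Divides the raw distance by the running maximum: `r = d / M`, clipped to
#' `[0, 1.5]` for robustness against transient overshoots. A value of 1 is a
#' fully open eye; values below 0.3 count as "at least 70% closed"
#' (PERCLOS-70 convention).
#'
#' @param d Raw eyelid-distance series.
#' @param M Running maximum from [track_max_distance()].
#' @return Normalized openness series in `[0, 1.5]`.
#' @export
normalize_trace <- function(d, M) {
  if (any(M <= 0)) stop("running maximum must be positive everywhere")
  pmin(pmax(d / M, 0), 1.5)
}

#' Segment blinks from a normalized openness series
#'
#' Thresholds the first derivative (central difference, units 1/s) of the
#' normalized openness: a blink is a maximal run of steep descent
#' (`dr/dt < -vel_threshold`) that reaches `r < closed_threshold`, followed
#' by an optional closed run (`|dr/dt| <= vel_threshold`, openness below the
#' closed threshold), followed by a maximal run of steep ascent returning to
#' `r >= closed_threshold`. Partial blinks touching the trace boundaries are
#' dropped.
#'
#' Phase durations are estimated with sub-sample resolution: for each ramp a
#' line is fit (least squares) to the samples lying strictly between the
#' local open level (median openness just before/after the blink) and the
#' plateau level (minimum openness during the blink), and the ramp's corner
#' times are read off the fitted line at those two levels. The closing and
#' reopening durations are the corner-to-corner times of the two ramps, the
#' closed duration is the time between the closing ramp's lower corner and
#' the reopening ramp's lower corner, and the total is their sum. Counting
#' whole samples per run would quantize each phase to the sample period
#' *and* bias ramps long, because a central difference at a sample adjacent
#' to a ramp still sees half the ramp slope; the corner fit removes both
#' effects. When a ramp has fewer than two usable samples the durations
#' fall back to run counting.
#'
#' Blinks whose ramps are slower than `vel_threshold` are not detected; this
#' is inherent to velocity-threshold segmentation and the reason the
#' threshold is kept configurable.
#'
#' @param r Normalized openness series.
#' @param fps Sampling rate (Hz).
#' @param vel_threshold Velocity threshold in normalized openness per second
#'   (default 3).
#' @param closed_threshold Openness below which the eye counts as closed
#'   (default 0.3, matching PERCLOS-70).
#' @return Data frame of blink events with sample indices `closing_start`,
#'   `closing_end`, `reopening_start`, `reopening_end` and durations
#'   `closing_ms`, `closed_ms`, `reopening_ms`, `total_ms`; zero rows when
#'   no blink is found.
#' @export
# Corner times (open-level, plateau-level) of one ramp, by least-squares
# line fit through the mid-ramp samples of r[i_lo:i_hi]. Returns c(t_open,
# t_plateau) in seconds (sample i sits at (i-1)/fps), or NULL when fewer
# than two usable samples exist or the fitted slope is degenerate.
ramp_corners <- function(r, i_lo, i_hi, a_lvl, p_lvl, fps) {
  span <- a_lvl - p_lvl
  if (!is.finite(span) || span <= 0) return(NULL)
  ii <- i_lo:i_hi
  sel <- ii[r[ii] > p_lvl + 0.1 * span & r[ii] < a_lvl - 0.1 * span]
  if (length(sel) < 2)
    sel <- ii[r[ii] > p_lvl + 0.02 * span & r[ii] < a_lvl - 0.02 * span]
  if (length(sel) < 2) return(NULL)
  tt <- (sel - 1) / fps
  co <- stats::lm.fit(cbind(1, tt), r[sel])$coefficients
  if (!all(is.finite(co)) || co[2] == 0) return(NULL)
  c((a_lvl - co[1]) / co[2], (p_lvl - co[1]) / co[2])
}

segment_blinks <- function(r, fps, vel_threshold = 3, closed_threshold = 0.3) {
  stopifnot(fps > 0)
  n <- length(r)
  empty <- data.frame(closing_start = integer(0), closing_end = integer(0),
                      reopening_start = integer(0), reopening_end = integer(0),
                      closing_ms = numeric(0), closed_ms = numeric(0),
                      reopening_ms = numeric(0), total_ms = numeric(0))
  if (n < 5) return(empty)
  v <- c(0, (r[-(1:2)] - r[1:(n - 2)]) * fps / 2, 0)
  state <- ifelse(v < -vel_threshold, "C", ifelse(v > vel_threshold, "O", "S"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  out <- list()
  i <- 1L
  while (i <= k) {
    if (runs$values[i] == "C") {
      j <- i + 1L
      # optional closed run between the ramps
      if (j <= k && runs$values[j] == "S") j <- j + 1L
      if (j <= k && runs$values[j] == "O") {
        cs <- starts[i]; ce <- ends[i]
        os <- starts[j]; oe <- ends[j]
        reaches_closed <- min(r[ce:os]) < closed_threshold
        reopens <- r[oe] >= closed_threshold ||
          (oe < n && r[oe + 1L] >= closed_threshold)
        # the first/last velocity samples are zero by construction, so a
        # ramp starting (ending) on sample 2 (n - 1) may be truncated by the
        # trace boundary: drop it
        interior <- cs > 2L && oe < n - 1L
        if (reaches_closed && reopens && interior) {
          dt_ms <- 1000 / fps
          a_pre <- stats::median(r[max(1L, cs - 3L):(cs - 1L)])
          a_post <- stats::median(r[(oe + 1L):min(n, oe + 3L)])
          p_lvl <- min(r[ce:os])
          fc <- ramp_corners(r, max(1L, cs - 1L), min(n, ce + 1L),
                             a_pre, p_lvl, fps)
          fr <- ramp_corners(r, max(1L, os - 1L), min(n, oe + 1L),
                             a_post, p_lvl, fps)
          if (is.null(fc) || is.null(fr) ||
              fc[2] <= fc[1] || fr[1] <= fr[2] || fr[2] < fc[2]) {
            closing_ms <- (ce - cs + 1L) * dt_ms
            closed_ms <- (os - ce - 1L) * dt_ms
            reopening_ms <- (oe - os + 1L) * dt_ms
            total_ms <- (oe - cs + 1L) * dt_ms
          } else {
            closing_ms <- (fc[2] - fc[1]) * 1000
            closed_ms <- (fr[2] - fc[2]) * 1000
            reopening_ms <- (fr[1] - fr[2]) * 1000
            total_ms <- closing_ms + closed_ms + reopening_ms
          }
          out[[length(out) + 1L]] <- data.frame(
            closing_start = cs, closing_end = ce,
            reopening_start = os, reopening_end = oe,
            closing_ms = closing_ms, closed_ms = closed_ms,
            reopening_ms = reopening_ms, total_ms = total_ms
          )
        }
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Six ocular features over one causal time window
#'
#' Computes, over the window `(t_end - window_s, t_end]`, the mean blink,
#' closing, closed and reopening durations (ms), the number of microsleeps
#' (blinks with total duration above 500 ms), and PERCLOS-70 (fraction of
#' samples with normalized openness below 0.3). Blinks are attributed to the
#' window by their closing-start time. A window without blinks yields zeros
#' for the four means and the count; PERCLOS is always computed from the
#' trace.
#'
#' @param blinks Blink events from [segment_blinks()].
#' @param r Normalized openness series.
#' @param fps Sampling rate (Hz).
#' @param window_s Window length in seconds (5, 15, 30 or 60).
#' @param t_end Window end time in seconds (causal: the window looks back).
#' @param perclos_threshold Openness threshold for PERCLOS (default 0.3).
#' @return Named numeric vector of length 6.
#' @export
window_features <- function(blinks, r, fps, window_s, t_end,
                            perclos_threshold = 0.3) {
  t_blink <- (blinks$closing_start - 1) / fps
  sel <- t_blink >= (t_end - window_s) & t_blink <= t_end
  b <- blinks[sel, , drop = FALSE]
  i_hi <- min(length(r), floor(t_end * fps))
  i_lo <- max(1L, floor((t_end - window_s) * fps) + 1L)
  perclos <- mean(r[i_lo:i_hi] < perclos_threshold)
  if (nrow(b) == 0) {
    return(c(mean_blink_ms = 0, mean_closing_ms = 0, mean_closed_ms = 0,
             mean_reopening_ms = 0, n_microsleep = 0, perclos70 = perclos))
  }
  c(mean_blink_ms = mean(b$total_ms),
    mean_closing_ms = mean(b$closing_ms),
    mean_closed_ms = mean(b$closed_ms),
    mean_reopening_ms = mean(b$reopening_ms),
    n_microsleep = sum(b$total_ms > 500),
    perclos70 = perclos)
}

#' Blink context of a session (cached intermediate for feature extraction)
#'
#' Normalizes both eyes, averages them into a single openness series, and
#' segments blinks once, so that repeated calls to [feature_vector()] at
#' many evaluation times do not redo the work.
#'
#' @param session A [`pvt_session`][simulate_session] (or any list with
#'   `left_dist`, `right_dist`, `fps`).
#' @inheritParams segment_blinks
#' @return List with `r` (mean normalized openness), `blinks` and `fps`.
#' @export
session_blink_context <- function(session, vel_threshold = 3,
                                  closed_threshold = 0.3) {
  fps <- session$fps
  rl <- normalize_trace(session$left_dist,
                        track_max_distance(session$left_dist, fps))
  rr <- normalize_trace(session$right_dist,
                        track_max_distance(session$right_dist, fps))
  r <- (rl + rr) / 2
  list(r = r, fps = fps,
       blinks = segment_blinks(r, fps, vel_threshold, closed_threshold))
}

#' The 24-dimensional multi-window ocular feature vector
#'
#' Six ocular features computed over the four most recent windows of 5, 15,
#' 30 and 60 seconds ending at `t_end` (window-major order: the six features
#' of the 5-s window first). Features are computed on the mean of the left
#' and right normalized openness series.
#'
#' @param ctx A [session_blink_context()], or a `pvt_session` (context is
#'   then built on the fly).
#' @param t_end End time of the windows, seconds; must be at least 60 s into
#'   the trace.
#' @param windows_s Window lengths in seconds.
#' @return Named numeric vector of length 24.
#' @export
feature_vector <- function(ctx, t_end, windows_s = c(5, 15, 30, 60)) {
  if (inherits(ctx, "pvt_session")) ctx <- session_blink_context(ctx)
  if (t_end < max(windows_s))
    stop("t_end must be at least ", max(windows_s), " s into the trace")
  out <- unlist(lapply(windows_s, function(w) {
    f <- window_features(ctx$blinks, ctx$r, ctx$fps, w, t_end)
    names(f) <- paste0(names(f), "_w", w)
    f
  }))
  out
}

#' Feature matrix for many evaluation times of one session
#'
#' @param session A [`pvt_session`][simulate_session].
#' @param t_ends Evaluation times (seconds), each at least 60 s.
#' @return Matrix `length(t_ends) x 24`.
#' @export
feature_matrix <- function(session, t_ends) {
  ctx <- session_blink_context(session)
  t(vapply(t_ends, function(t0) feature_vector(ctx, t0), numeric(24)))
}
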