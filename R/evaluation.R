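#' Leave-one-subject-out folds with rotated validation sets
#'
#' Builds one fold per subject: the subject is the test set, the next
#' `val_size` subjects (cyclically, in a seed-shuffled order) form the
#' validation set, and the remainder the training set. By construction each
#' subject appears exactly once as test, `val_size` times in validation and
#' `n - 1 - val_size` times in training. With 29 subjects and the default
#' `val_size`, this gives the 23/5/1 design.
#'
#' @param subjects Character vector of subject ids (n >= 3).
#' @param seed Integer seed for the rotation order.
#' @param val_size Validation subjects per fold; default `round(5 n / 29)`,
#'   at least 1.
#' @return List of folds, each a list with `fold_id`, `train`, `val`,
#'   `test`.
#' @export
make_folds <- function(subjects, seed = 1L, val_size = NULL) {
  n <- length(subjects)
  if (n < 3) stop("need at least 3 subjects for train/val/test folds")
  if (is.null(val_size)) val_size <- max(1L, round(5 * n / 29))
  if (val_size > n - 2) stop("val_size leaves no training subjects")
  ord <- withr_seed(seed, sample(subjects))
  lapply(seq_len(n), function(i) {
    val <- ord[((i - 1 + seq_len(val_size)) %% n) + 1L]
    list(fold_id = i, test = ord[i], val = val,
         train = setdiff(ord, c(ord[i], val)))
  })
}

#' Stimulus-anchored evaluation times of a session
#'
#' One evaluation point per PVT stimulus, at the stimulus occurrence time,
#' excluding stimuli within the first minute (the 1-min input sequence must
#' exist in full; a stimulus at exactly 60 s is included). This makes the
#' shortest-timescale label perfectly time-synchronized with the sequence.
#'
#' @param session A [`pvt_session`][simulate_session].
#' @return Numeric vector of evaluation times (seconds).
#' @export
sample_eval_points <- function(session) {
  t <- session$rt$stimulus_time_s
  t[t >= 60]
}

#' Keep only samples with a definite label at one timescale
#'
#' Binary evaluation discards, independently at each timescale, the samples
#' whose ground-truth probability is 0.5 (median RT strictly between 400 and
#' 500 ms) or undefined.
#'
#' @param p Vector of ground-truth probabilities at one timescale.
#' @return Logical index of the retained samples.
#' @export
filter_definite <- function(p) {
  !is.na(p) & (p == 0 | p == 1)
}

#' Pooled classification metrics per timescale
#'
#' Aggregates predictions across all folds *before* computing metrics: the
#' confusion counts are pooled over samples, not averaged per subject.
#' Reports, per timescale, TN/FP/FN/TP, the true negative rate
#' (specificity), the true positive rate (sensitivity) and the global
#' accuracy, on the samples retained by [filter_definite()].
#'
#' @param decisions Matrix `n x 4` of binary decisions (0 = alert,
#'   1 = drowsy).
#' @param p Matrix `n x 4` of ground-truth probabilities in `{0, 0.5, 1}`.
#' @return Data frame with one row per timescale.
#' @export
aggregate_metrics <- function(decisions, p) {
  stopifnot(ncol(decisions) == 4, ncol(p) == 4, nrow(decisions) == nrow(p))
  out <- lapply(1:4, function(i) {
    keep <- filter_definite(p[, i])
    y <- p[keep, i]
    d <- decisions[keep, i]
    tn <- sum(y == 0 & d == 0); fp <- sum(y == 0 & d == 1)
    fn <- sum(y == 1 & d == 0); tp <- sum(y == 1 & d == 1)
    data.frame(
      timescale_s = c(5, 15, 30, 60)[i], n = length(y),
      tn = tn, fp = fp, fn = fn, tp = tp,
      tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      accuracy = if (length(y) > 0) (tn + tp) / length(y) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Combined level of drowsiness
#'
#' The sum of the four binary decisions: an integer LoD from 0 to 4, with
#' low levels driven by the responsive short-timescale classifiers and high
#' levels by the accurate long-timescale ones.
#'
#' @param decisions Matrix `n x 4` of binary decisions (or a length-4
#'   vector).
#' @return Integer vector of combined LoDs.
#' @export
combined_lod <- function(decisions) {
  if (is.null(dim(decisions))) decisions <- matrix(decisions, nrow = 1)
  as.integer(rowSums(decisions))
}

#' Histogram of the 16 joint decision patterns
#'
#' @param decisions Matrix `n x 4` of binary decisions.
#' @return Named integer vector over the 16 patterns `"0000".."1111"`
#'   (ordered by timescale: first character = 5 s), summing to `n`.
#' @export
outcome_histogram <- function(decisions) {
  if (is.null(dim(decisions))) decisions <- matrix(decisions, nrow = 1)
  pats <- apply(decisions, 1, paste, collapse = "")
  lv <- apply(expand.grid(0:1, 0:1, 0:1, 0:1)[, 4:1], 1, paste, collapse = "")
  table(factor(pats, levels = sort(lv)))
}

#' Fraction of timescale-monotone joint decisions
#'
#' A joint pattern is monotone when detection at one timescale implies
#' detection at all shorter timescales: `0000`, `1000`, `1100`, `1110`,
#' `1111`. Reported as a diagnostic of the learned timescale hierarchy (a
#' perfectly hierarchical system yields 1).
#'
#' @param decisions Matrix `n x 4` of binary decisions.
#' @return Fraction in `[0, 1]`.
#' @export
monotone_outcome_fraction <- function(decisions) {
  if (is.null(dim(decisions))) decisions <- matrix(decisions, nrow = 1)
  pats <- apply(decisions, 1, paste, collapse = "")
  mean(pats %in% c("0000", "1000", "1100", "1110", "1111"))
}
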