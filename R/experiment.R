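#' Configuration of the scaled-down synthetic benchmark
#'
#' The canonical small cohort used by the package's learnability benchmarks:
#' 8 subjects, one alert and one sleep-deprived 6-minute PVT each, with a
#' strong drowsiness effect (deprived latent level in `[0.5, 1]`, so the
#' deprived median RTs sit well past the 500 ms lapse threshold while alert
#' sessions stay near 280 ms). The corresponding training schedule
#' ([scaled_train_config()]) draws 24 sequences per stratum per epoch for 3
#' epochs -- enough for the strongly separated cohort, and small enough to
#' train a full leave-one-subject-out rotation on one CPU in minutes.
#'
#' @param seed Master seed of the cohort.
#' @param n_subjects Number of subjects.
#' @param duration_s Session length in seconds.
#' @return A [synthetic_config()].
#' @export
scaled_cohort_config <- function(seed = 1L, n_subjects = 8, duration_s = 360) {
  synthetic_config(
    duration_s = duration_s, n_subjects = n_subjects, seed = seed,
    drowsiness_process = list(level_range = c(0.5, 1))
  )
}

#' @rdname scaled_cohort_config
#' @export
scaled_train_config <- function(seed = 1L) {
  train_config(quota = 24L, max_epochs = 3L, patience = 3L, seed = seed)
}

#' Run a complete synthetic drowsiness-characterization experiment
#'
#' Simulates a cohort, fits the reaction-time normalization on the alert
#' (reference) sessions, builds rotated leave-one-subject-out folds, trains
#' the temporal CNN -- and optionally the ocular-feature proxy classifiers --
#' on each fold, predicts each fold's held-out test subject at the
#' stimulus-anchored evaluation points, and pools the test predictions
#' across folds into per-timescale metrics and combined-LoD diagnostics.
#'
#' Every random draw derives from `seed`; two runs with identical
#' configuration and seed produce identical reports.
#'
#' @param cohort_config A [synthetic_config()].
#' @param net_cfg A [net_config()].
#' @param tc A [train_config()] (its `seed` is overridden per fold,
#'   derived from `seed`).
#' @param seed Master seed of the experiment.
#' @param frame_stride Stride of the frame-level training pool (see
#'   [train_fold()]).
#' @param run_net,run_proxy Which systems to train and evaluate.
#' @param shuffle_labels Negative control: permute training/validation
#'   labels (test labels stay intact).
#' @param folds Optional precomputed folds; default [make_folds()] on the
#'   cohort's subjects.
#' @param verbose Print per-fold progress to stderr.
#' @return A list of class `"drowsinet_report"`: `net_metrics`,
#'   `proxy_metrics` (data frames from [aggregate_metrics()]),
#'   `net_histogram`, `net_monotone_fraction`, per-fold decisions, and the
#'   configuration seeds.
#' @export
run_experiment <- function(cohort_config = synthetic_config(),
                           net_cfg = net_config(),
                           tc = train_config(),
                           seed = cohort_config$seed,
                           frame_stride = 3L,
                           run_net = TRUE, run_proxy = TRUE,
                           shuffle_labels = FALSE,
                           folds = NULL,
                           verbose = FALSE) {
  sessions <- simulate_cohort(cohort_config)
  subj <- vapply(sessions, function(s) s$subject_id, character(1))
  tags <- vapply(sessions, function(s) s$tag, character(1))
  norm_model <- fit_normalization(sessions[tags == "alert"])
  subjects <- intersect(unique(subj), names(norm_model$mu))
  if (is.null(folds)) folds <- make_folds(subjects, seed = derive_seed(seed, "folds"))

  # anchored evaluation pool and (optionally) ocular features, cached per session
  eval_pool <- build_pool(sessions, norm_model, subjects, anchored = TRUE)
  feats <- NULL
  if (run_proxy) {
    feats <- matrix(NA_real_, nrow(eval_pool), 24)
    for (si in unique(eval_pool$session)) {
      rows <- which(eval_pool$session == si)
      feats[rows, ] <- feature_matrix(sessions[[si]], eval_pool$t[rows])
    }
    colnames(feats) <- names(feature_vector(sessions[[1]], 60))
  }
  pmat <- as.matrix(eval_pool[, paste0("p", 1:4)])

  net_dec <- NULL; net_p <- NULL; prox_dec <- NULL; prox_p <- NULL
  fold_rows <- list()
  for (f in folds) {
    test_rows <- which(eval_pool$subject_id %in% f$test)
    if (length(test_rows) == 0) next
    fold_rows[[length(fold_rows) + 1L]] <- test_rows
    if (run_net) {
      tc_f <- tc
      tc_f$seed <- derive_seed(seed, "net", f$fold_id)
      fit <- train_fold(sessions, f, norm_model, net_cfg, tc_f,
                        frame_stride = frame_stride,
                        shuffle_labels = shuffle_labels)
      x_test <- extract_batch(sessions, eval_pool[test_rows, ],
                              net_cfg$input_len)
      phat <- predict_drowsiness(fit$model, x_test)
      net_dec <- rbind(net_dec, (phat >= 0.5) + 0)
      net_p <- rbind(net_p, pmat[test_rows, , drop = FALSE])
      if (verbose)
        message(sprintf("fold %d (%s): %d epochs, val loss %.4f",
                        f$fold_id, f$test, nrow(fit$history),
                        min(fit$history$val_loss)))
    }
    if (run_proxy) {
      tr_rows <- which(eval_pool$subject_id %in% f$train)
      prx <- fit_proxy(feats[tr_rows, , drop = FALSE],
                       pmat[tr_rows, , drop = FALSE],
                       eval_pool$subject_id[tr_rows])
      prox_dec <- rbind(prox_dec, predict_proxy(prx, feats[test_rows, , drop = FALSE]))
      prox_p <- rbind(prox_p, pmat[test_rows, , drop = FALSE])
    }
  }

  report <- list(seed = seed, subjects = subjects, folds = folds)
  if (run_net) {
    report$net_metrics <- aggregate_metrics(net_dec, net_p)
    report$net_histogram <- outcome_histogram(net_dec)
    report$net_monotone_fraction <- monotone_outcome_fraction(net_dec)
    report$net_decisions <- net_dec
    report$net_labels <- net_p
  }
  if (run_proxy) {
    report$proxy_metrics <- aggregate_metrics(prox_dec, prox_p)
    report$proxy_decisions <- prox_dec
    report$proxy_labels <- prox_p
  }
  class(report) <- "drowsinet_report"
  report
}

#' @export
print.drowsinet_report <- function(x, ...) {
  cat("<drowsinet_report>", length(x$subjects), "subjects,",
      length(x$folds), "folds\n")
  if (!is.null(x$net_metrics)) {
    cat("\nTemporal CNN (pooled test metrics):\n")
    print(x$net_metrics, row.names = FALSE)
    cat(sprintf("monotone outcome fraction: %.3f\n", x$net_monotone_fraction))
  }
  if (!is.null(x$proxy_metrics)) {
    cat("\nOcular-feature proxy (pooled test metrics):\n")
    print(x$proxy_metrics, row.names = FALSE)
  }
  invisible(x)
}
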