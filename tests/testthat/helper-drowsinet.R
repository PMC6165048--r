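# Shared fixtures, built lazily and memoized for the duration of the test
# run. Everything is generated in code from fixed seeds; no files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small 4-subject cohort with short sessions: enough structure for the
# ground-truth, feature and evaluation tests without the cost of the full
# benchmark cohorts.
tiny_cohort <- function() {
  memo("tiny_cohort", simulate_cohort(
    synthetic_config(duration_s = 180, n_subjects = 4, seed = 7101)))
}

tiny_norm_model <- function() {
  memo("tiny_norm", {
    sess <- tiny_cohort()
    tags <- vapply(sess, function(s) s$tag, character(1))
    fit_normalization(sess[tags == "alert"])
  })
}

# One alert and one strongly deprived session of the same subject.
alert_session <- function() tiny_cohort()[[1]]
deprived_session <- function() tiny_cohort()[[2]]

# The scaled benchmark used by the stochastic acceptance criteria: one full
# rotated leave-one-subject-out experiment (network + proxy) per seed.
scaled_benchmark <- function(seed) {
  memo(paste0("bench", seed), run_experiment(
    scaled_cohort_config(seed = seed), tc = scaled_train_config(),
    seed = seed))
}
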