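# Shared fixtures, all generated in code.

# A small single-recording study: 16 channels covers C3/Cz/C4 and the two
# default channel groups; 12 trials per condition is the smallest count that
# feeds the 3/5/5-fold nesting comfortably.
tiny_config <- function(n_trials = 12, n_channels = 16, ...) {
  study_config(
    n_control_recordings = 1, n_patient_recordings = 0,
    patient_sessions = integer(0),
    n_channels = n_channels, n_trials_per_condition = n_trials, ...
  )
}

tiny_montage <- function(channels = c("C3", "C4"), order = 5L,
                         name = "test-SM") {
  structure(
    list(
      name = name, channels = channels, exclude = character(),
      model_order = as.integer(order)
    ),
    class = "montage_config"
  )
}

# Segment-style labelled data without any EEG: n_trials per class, 6
# sub-segments each; informative features get a class mean shift of
# `delta` (in units of the residual sd), plus a shared trial-level random
# effect so sub-segments are dependent as in real epochs.
make_labelled_features <- function(n_trials_per_class = 25, n_features = 26,
                                   n_informative = 4, delta = 1.5,
                                   trial_sd = 0.5, seed = 1) {
  set.seed(seed)
  n_tr <- 2 * n_trials_per_class
  n <- 6 * n_tr
  cond <- rep(rep(c("A", "B"), each = n_trials_per_class), each = 6)
  trial <- rep(seq_len(n_tr), each = 6)
  X <- matrix(rnorm(n * n_features), n, n_features)
  trial_fx <- matrix(rnorm(n_tr * n_features, sd = trial_sd), n_tr, n_features)
  X <- X + trial_fx[trial, ]
  if (n_informative > 0) {
    X[cond == "A", seq_len(n_informative)] <-
      X[cond == "A", seq_len(n_informative)] + delta
  }
  list(X = X, condition = cond, trial_id = trial)
}

# Band-power estimate at given channels/bins, averaged over all segments of
# one condition.
mean_band_power <- function(segments, condition, channels, bins) {
  idx <- which(segments$condition == condition)
  chs <- match(channels, segments$channel_labels)
  vals <- vapply(idx, function(i) {
    sp <- power_spectrum(segments$segments[i, , , drop = TRUE],
      sampling_rate = segments$sampling_rate, bins = bins
    )
    mean(sp[chs, , drop = FALSE])
  }, numeric(1))
  vals
}
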