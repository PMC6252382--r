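#' Configuration of a synthetic motor-imagery EEG study
#'
#' Describes a complete event-related study: seven task conditions (move
#' foot/hand `MF`/`MH`, imagine foot/hand `IF`/`IH`, observe foot/hand
#' `OF`/`OH`, rest `RS`), 25 trials per condition of 6 s at 250 Hz, and a
#' cohort of control-profile and patient-profile recordings (defaults mirror
#' a 22-control, 7-patient/14-recording cohort).
#'
#' The signal model is, per channel, 1/f-shaped Gaussian background noise
#' plus condition-dependent narrow-band oscillators (mu around 10 Hz, beta
#' around 20 Hz) over the sensorimotor channel groups, mixed across
#' channels by a distance-decaying matrix emulating volume conduction.
#' Condition effects are multiplicative band-power factors < 1
#' (desynchronisation) applied to the oscillator of a channel group. By
#' default movement desynchronises strongly and somatotopically (foot
#' effects on midline channels, hand effects on lateral C3/C4 neighbours),
#' imagery desynchronises weakly and diffusely (so `IF` vs `IH` is at
#' chance), and observation carries no motor-band effect (so `OF` vs `OH`
#' is a negative control). Patient profiles shift the reactive mu peak down
#' by `patient_peak_shift` Hz (10 -> 8 Hz by default).
#'
#' Generated data is declared already Cz-referenced; no re-referencing stage
#' exists anywhere in the pipeline.
#'
#' @param n_control_recordings control-profile recordings (default 22).
#' @param n_patient_recordings patient-profile recordings (default 14).
#' @param patient_sessions integer vector of recordings per patient, summing
#'   to `n_patient_recordings` (default `c(2, 4, 2, 3, 1, 1, 1)`).
#' @param n_channels channels to synthesise (default 64; up to 256).
#' @param sampling_rate Hz (default 250).
#' @param n_trials_per_condition default 25.
#' @param epoch_duration seconds per trial epoch (default 6).
#' @param effect_map nested list: condition -> channel-group -> named power
#'   factors `c(mu = , beta = )`. Missing entries mean factor 1 (no effect).
#' @param channel_groups named list of channel-label vectors the effects act
#'   on.
#' @param osc_amplitude named amplitudes (a.u., background sd = 1) of the
#'   baseline mu and beta oscillators.
#' @param patient_peak_shift Hz downshift of the mu peak in patient
#'   profiles (default 2).
#' @param noise_exponent 1/f spectral slope of the background (default 1).
#' @param line_noise_amplitude amplitude of 50 Hz mains contamination
#'   (default 0 = off).
#' @param coupling_spec optional ground-truth directed coupling: a list with
#'   `coefficients` (list of square matrices), `innovation_cov`, `channels`
#'   (labels the latent sources are injected at) and `scale`.
#' @param inter_trial_gap seconds between trials (default 1).
#' @param seed base seed for the study (default 1).
#' @return a validated `study_config` list.
#' @export
study_config <- function(n_control_recordings = 22,
                         n_patient_recordings = 14,
                         patient_sessions = NULL,
                         n_channels = 64,
                         sampling_rate = 250,
                         n_trials_per_condition = 25,
                         epoch_duration = 6,
                         effect_map = default_effect_map(),
                         channel_groups = default_channel_groups(),
                         osc_amplitude = c(mu = 2, beta = 1.2),
                         patient_peak_shift = 2,
                         noise_exponent = 1,
                         line_noise_amplitude = 0,
                         coupling_spec = NULL,
                         inter_trial_gap = 1,
                         seed = 1) {
  conditions <- c("MF", "MH", "IF", "IH", "OF", "OH", "RS")
  if (is.null(patient_sessions)) {
    patient_sessions <- if (n_patient_recordings == 14) {
      c(2L, 4L, 2L, 3L, 1L, 1L, 1L)
    } else {
      rep(1L, n_patient_recordings)
    }
  }
  stopifnot(
    sum(patient_sessions) == n_patient_recordings,
    n_channels >= 1, n_channels <= 256,
    sampling_rate * epoch_duration == round(sampling_rate * epoch_duration),
    n_trials_per_condition >= 1,
    all(unlist(effect_map) > 0),
    all(osc_amplitude >= 0)
  )
  structure(
    list(
      n_control_recordings = as.integer(n_control_recordings),
      n_patient_recordings = as.integer(n_patient_recordings),
      patient_sessions = as.integer(patient_sessions),
      n_channels = as.integer(n_channels),
      sampling_rate = sampling_rate,
      n_trials_per_condition = as.integer(n_trials_per_condition),
      epoch_duration = epoch_duration,
      conditions = conditions,
      effect_map = effect_map,
      channel_groups = channel_groups,
      osc_amplitude = osc_amplitude,
      patient_peak_shift = patient_peak_shift,
      noise_exponent = noise_exponent,
      line_noise_amplitude = line_noise_amplitude,
      coupling_spec = coupling_spec,
      inter_trial_gap = inter_trial_gap,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Default condition-effect map
#'
#' Multiplicative band-power factors by condition and channel group.
#' Movement: strong somatotopic desynchronisation. Imagery: weaker, diffuse
#' (identical for foot and hand, so that pair classifies at chance).
#' Observation and rest: no motor-band effect.
#'
#' @return nested list usable as `effect_map` in [study_config()].
#' @export
default_effect_map <- function() {
  list(
    MF = list(foot = c(mu = 0.5, beta = 0.6)),
    MH = list(hand = c(mu = 0.5, beta = 0.6)),
    IF = list(
      foot = c(mu = 0.75, beta = 0.85),
      hand = c(mu = 0.75, beta = 0.85)
    ),
    IH = list(
      foot = c(mu = 0.75, beta = 0.85),
      hand = c(mu = 0.75, beta = 0.85)
    )
  )
}

#' Default sensorimotor channel groups
#' @return named list with `hand` (lateral central) and `foot` (midline
#'   central) label sets.
#' @export
default_channel_groups <- function() {
  list(
    hand = c("C3", "C4", "FC3", "FC4", "CP3", "CP4"),
    foot = c("Cz", "FCz", "CPz", "C1", "C2")
  )
}

# Approximate 2-D scalp coordinates (x: left -1 .. right 1, y: back -1 ..
# front 1) for the named 10-10 labels used by the montages; generic E<k>
# fillers are laid out on a deterministic sunflower spiral.
channel_positions <- function(labels) {
  named <- list(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F3 = c(-0.55, 0.48), Fz = c(0, 0.5),
    F4 = c(0.55, 0.48), F8 = c(0.81, 0.59),
    T3 = c(-1, 0), T4 = c(1, 0),
    T5 = c(-0.81, -0.59), T6 = c(0.81, -0.59),
    P3 = c(-0.55, -0.48), Pz = c(0, -0.5), P4 = c(0.55, -0.48),
    O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95),
    FT7 = c(-0.9, 0.3), FC5 = c(-0.73, 0.27), FC3 = c(-0.5, 0.25),
    FC1 = c(-0.25, 0.25), FCz = c(0, 0.25), FC2 = c(0.25, 0.25),
    FC4 = c(0.5, 0.25), FC6 = c(0.73, 0.27), FT8 = c(0.9, 0.3),
    T7 = c(-0.98, -0.02), C5 = c(-0.75, 0), C3 = c(-0.5, 0),
    C1 = c(-0.25, 0), Cz = c(0, 0), C2 = c(0.25, 0), C4 = c(0.5, 0),
    C6 = c(0.75, 0), T8 = c(0.98, -0.02),
    TP7 = c(-0.9, -0.3), CP5 = c(-0.73, -0.27), CP3 = c(-0.5, -0.25),
    CP1 = c(-0.25, -0.25), CPz = c(0, -0.25), CP2 = c(0.25, -0.25),
    CP4 = c(0.5, -0.25), CP6 = c(0.73, -0.27), TP8 = c(0.9, -0.3)
  )
  pos <- matrix(NA_real_, length(labels), 2,
    dimnames = list(labels, c("x", "y"))
  )
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (!is.null(named[[lab]])) {
      pos[i, ] <- named[[lab]]
    } else {
      k <- suppressWarnings(as.integer(sub("^E", "", lab)))
      if (is.na(k)) k <- i
      r <- 0.95 * sqrt(k / 256)
      th <- k * 2.399963
      pos[i, ] <- c(r * cos(th), r * sin(th))
    }
  }
  pos
}

# Ordered channel label list: the named montage labels first, then E<k>
# fillers so that the face/neck exclusion labels E198..E256 are the last of
# a full 256-channel net.
make_channel_labels <- function(n_channels) {
  named <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4",
    "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C1", "C2", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"
  )
  stopifnot(!anyDuplicated(named))
  if (n_channels <= length(named)) {
    named[seq_len(n_channels)]
  } else {
    c(named, paste0("E", (length(named) + 1):n_channels))
  }
}

# 1/f^a shaped Gaussian noise, unit variance, by spectral shaping of white
# noise. n x m matrix of independent channels (columns).
pink_noise <- function(n, m, exponent) {
  w <- matrix(stats::rnorm(n * m), n, m)
  f <- c(0, seq_len(floor(n / 2)), -rev(seq_len(ceiling(n / 2) - 1)))
  shape <- c(0, abs(f[-1])^(-exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n
  scale(x, center = TRUE, scale = apply(x, 2, stats::sd))
}

#' Generate one synthetic EEG recording
#'
#' Produces a continuous multichannel recording for one session of one
#' subject profile: a randomised sequence of 7 x `n_trials_per_condition`
#' trial epochs separated by inter-trial gaps, with the configured
#' band-power structure (see [study_config()]) and full ground truth
#' attached.
#'
#' @param config a [study_config()].
#' @param profile `"control"` or `"patient"`.
#' @param session session index (default 1).
#' @param seed recording seed; same inputs give bit-identical output.
#' @return an `eeg_recording`: list with `data` (channels x samples),
#'   `channel_labels`, `sampling_rate`, `events` (tibble: onset, condition,
#'   trial_id), `profile`, `session`, `ground_truth`.
#' @export
generate_recording <- function(config, profile = c("control", "patient"),
                               session = 1, seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  profile <- match.arg(profile)
  fs <- config$sampling_rate
  labels <- make_channel_labels(config$n_channels)
  groups <- lapply(config$channel_groups, function(g) intersect(g, labels))
  if (any(lengths(config$channel_groups) > 0 & lengths(groups) == 0)) {
    stop("channel count too small for the configured channel groups")
  }
  epoch_len <- as.integer(round(config$epoch_duration * fs))
  gap_len <- as.integer(round(config$inter_trial_gap * fs))
  n_ev <- length(config$conditions) * config$n_trials_per_condition
  lead <- fs # 1 s lead-in
  total <- lead + n_ev * (epoch_len + gap_len) + fs

  mu_centre <- if (profile == "patient") 10 - config$patient_peak_shift else 10
  beta_centre <- 20

  with_seed(seed, {
    cond_seq <- sample(rep(config$conditions, config$n_trials_per_condition))
    onsets <- lead + (seq_len(n_ev) - 1L) * (epoch_len + gap_len) + 1L
    events <- tibble::tibble(
      onset = as.integer(onsets),
      condition = cond_seq,
      trial_id = seq_len(n_ev)
    )

    # independent 1/f background per channel (channels in rows)
    x <- t(pink_noise(total, config$n_channels, config$noise_exponent))

    # optional ground-truth MVAR sources injected at named channels
    if (!is.null(config$coupling_spec)) {
      cs <- config$coupling_spec
      idx <- match(cs$channels, labels)
      if (anyNA(idx)) stop("coupling_spec channels not present in recording")
      z <- simulate_mvar(cs$coefficients, cs$innovation_cov, total,
        seed = derive_seed(seed, 7701)
      )
      x[idx, ] <- x[idx, ] + (cs$scale %||% 1) * z
    }

    # condition-dependent narrow-band oscillators on the group channels
    tt <- seq_len(epoch_len) / fs
    bands <- list(
      mu = list(centre = mu_centre, amp = config$osc_amplitude[["mu"]]),
      beta = list(centre = beta_centre, amp = config$osc_amplitude[["beta"]])
    )
    for (ev in seq_len(n_ev)) {
      span <- onsets[ev]:(onsets[ev] + epoch_len - 1L)
      cond <- cond_seq[ev]
      for (gname in names(groups)) {
        gidx <- match(groups[[gname]], labels)
        if (length(gidx) == 0) next
        for (bname in names(bands)) {
          b <- bands[[bname]]
          if (b$amp <= 0) next
          fac <- 1
          emap <- config$effect_map[[cond]]
          if (!is.null(emap[[gname]]) && !is.na(emap[[gname]][bname])) {
            fac <- emap[[gname]][[bname]]
          }
          freq <- b$centre + stats::runif(1, -0.5, 0.5)
          phase <- stats::runif(1, 0, 2 * pi)
          gain <- exp(stats::rnorm(1, 0, 0.05))
          # waxing-and-waning rhythm: lognormal amplitude envelope
          # resampled every second within the epoch
          env <- rep(
            exp(stats::rnorm(config$epoch_duration, 0, 0.15)),
            each = fs
          )[seq_len(epoch_len)]
          wave <- b$amp * sqrt(fac) * gain * env *
            sin(2 * pi * freq * tt + phase)
          x[gidx, span] <- x[gidx, span] + rep(wave, each = length(gidx))
        }
      }
    }

    if (config$line_noise_amplitude > 0) {
      mains <- config$line_noise_amplitude *
        sin(2 * pi * 50 * seq_len(total) / fs + stats::runif(1, 0, 2 * pi))
      x <- x + rep(mains, each = config$n_channels)
    }

    # volume conduction: distance-decaying, row-normalised mixing
    pos <- channel_positions(labels)
    d2 <- as.matrix(stats::dist(pos))^2
    mix <- exp(-d2 / (2 * 0.25^2))
    mix <- mix / rowSums(mix)
    x <- mix %*% x
    dimnames(x) <- NULL

    structure(
      list(
        data = x,
        channel_labels = labels,
        sampling_rate = fs,
        events = events,
        profile = profile,
        session = as.integer(session),
        ground_truth = list(
          config = config, profile = profile, session = session,
          seed = seed, mu_centre = mu_centre, beta_centre = beta_centre
        )
      ),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s session %d: %d channels x %d samples @ %g Hz, %d events\n",
    x$profile, x$session, nrow(x$data), ncol(x$data), x$sampling_rate,
    nrow(x$events)
  ))
  invisible(x)
}

#' Enumerate the recordings of a study without generating data
#'
#' @param config a [study_config()].
#' @return tibble with one row per recording: `recording_id`, `subject`,
#'   `profile`, `session`, `seed` (derived deterministically from the study
#'   seed).
#' @export
study_plan <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  rid <- 0L
  for (s in seq_len(config$n_control_recordings)) {
    rid <- rid + 1L
    rows[[rid]] <- tibble::tibble(
      recording_id = rid, subject = sprintf("C%02d", s),
      profile = "control", session = 1L
    )
  }
  for (p in seq_along(config$patient_sessions)) {
    for (sess in seq_len(config$patient_sessions[p])) {
      rid <- rid + 1L
      rows[[rid]] <- tibble::tibble(
        recording_id = rid, subject = sprintf("P%02d", p),
        profile = "patient", session = sess
      )
    }
  }
  plan <- dplyr::bind_rows(rows)
  plan$seed <- vapply(
    plan$recording_id,
    function(i) derive_seed(config$seed, i), integer(1)
  )
  plan
}

#' Generate every recording of a synthetic study
#'
#' Calls [generate_recording()] for each row of [study_plan()]; per-recording
#' seeds are derived from the study seed, so no two recordings share data.
#'
#' @param config a [study_config()].
#' @return named list of `eeg_recording` objects (names `C01`..`P07.2` style
#'   `subject.session`).
#' @export
generate_study <- function(config) {
  plan <- study_plan(config)
  recs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    recs[[i]] <- generate_recording(
      config,
      profile = plan$profile[i],
      session = plan$session[i],
      seed = plan$seed[i]
    )
  }
  names(recs) <- paste0(plan$subject, ".", plan$session)
  recs
}

#' Simulate a stationary MVAR process
#'
#' Ground-truth generator for connectivity parameter-recovery checks:
#' draws a realisation of `x(t) = sum_k A_k x(t-k) + e(t)` with Gaussian
#' innovations, discarding a burn-in prefix.
#'
#' @param coefficients list of p square coefficient matrices.
#' @param innovation_cov positive-definite innovation covariance.
#' @param n_samples samples to return after burn-in.
#' @param seed RNG seed.
#' @param burn_in samples discarded at the start (default 500).
#' @return numeric matrix channels x `n_samples`.
#' @export
simulate_mvar <- function(coefficients, innovation_cov, n_samples,
                          seed = 1, burn_in = 500) {
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  coefficients <- lapply(coefficients, as.matrix)
  m <- nrow(coefficients[[1]])
  p <- length(coefficients)
  if (mvar_spectral_radius(coefficients) >= 1) {
    stop("unstable model: companion spectral radius must be < 1")
  }
  L <- tryCatch(t(chol(innovation_cov)), error = function(e) {
    stop("innovation covariance must be positive definite")
  })
  with_seed(seed, {
    total <- n_samples + burn_in
    e <- L %*% matrix(stats::rnorm(m * total), m, total)
    x <- matrix(0, m, total)
    for (t in (p + 1):total) {
      acc <- e[, t]
      for (k in seq_len(p)) acc <- acc + coefficients[[k]] %*% x[, t - k]
      x[, t] <- acc
    }
    x[, (burn_in + 1):total, drop = FALSE]
  })
}
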