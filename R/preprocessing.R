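#' High-pass filter a multichannel recording
#'
#' Causal 4th-order Butterworth IIR high-pass, applied independently to each
#' channel (row) of the data matrix. Used with the default 1 Hz cutoff to
#' remove drift and DC before epoching.
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate Hz.
#' @param cutoff high-pass edge in Hz; must be below Nyquist.
#' @param order filter order (default 4).
#' @return filtered matrix, same shape.
#' @export
highpass_filter <- function(data, sampling_rate, cutoff = 1, order = 4) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (cutoff >= sampling_rate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "high")
  t(apply(data, 1, function(x) as.numeric(signal::filter(bf, x))))
}

#' Notch filter for line-noise removal
#'
#' Second-order IIR notch (biquad) with the standard constant-Q design:
#' zeros on the unit circle at the notch frequency, poles pulled inside by
#' the quality factor. Narrow rejection at `freq`, near-unity gain elsewhere.
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate Hz.
#' @param freq notch centre in Hz (default 50, European mains); below Nyquist.
#' @param q quality factor; bandwidth is roughly `freq / q` (default 30).
#' @return filtered matrix, same shape.
#' @export
notch_filter <- function(data, sampling_rate, freq = 50, q = 30) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (freq >= sampling_rate / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / sampling_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  t(apply(data, 1, function(x) as.numeric(signal::filter(b, a, x))))
}

#' Cut condition epochs from a continuous recording
#'
#' One epoch per trial-onset event, starting at the onset sample and lasting
#' `epoch_duration` seconds (6 s at 250 Hz = 1500 samples), labelled with the
#' event's condition and trial id.
#'
#' @param recording an `eeg_recording` (see [generate_recording()] or
#'   [read_recording()]).
#' @param epoch_duration seconds per epoch (default 6).
#' @return an `epoch_set`: list with `epochs` array
#'   (n_epochs x channels x samples), `condition`, `trial_id`,
#'   `channel_labels`, `sampling_rate`.
#' @export
segment_trials <- function(recording, epoch_duration = 6) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  len <- as.integer(round(epoch_duration * fs))
  ev <- recording$events
  n_samp <- ncol(recording$data)
  if (any(ev$onset + len - 1 > n_samp)) {
    stop("an event epoch exceeds the recording bounds")
  }
  n_ev <- nrow(ev)
  m <- nrow(recording$data)
  epochs <- array(NA_real_, c(n_ev, m, len))
  for (i in seq_len(n_ev)) {
    epochs[i, , ] <- recording$data[, ev$onset[i]:(ev$onset[i] + len - 1)]
  }
  structure(
    list(
      epochs = epochs,
      condition = ev$condition,
      trial_id = ev$trial_id,
      channel_labels = recording$channel_labels,
      sampling_rate = fs
    ),
    class = "epoch_set"
  )
}

#' Split epochs into 1-second classification segments
#'
#' Each 6 s epoch is divided into 6 consecutive non-overlapping 1 s segments
#' that inherit the epoch's condition and trial id and carry a sub-segment
#' index 1..6. This enlarges the sample available to the classifier; the
#' sub-segments of one trial are not independent, which is why all
#' cross-validation in this package groups folds by trial.
#'
#' @param epochs an `epoch_set` from [segment_trials()].
#' @param segment_duration seconds per sub-segment (default 1).
#' @return a `segment_set`: list with `segments` array
#'   (n_segments x channels x samples), `condition`, `trial_id`,
#'   `subsegment_index`, `channel_labels`, `sampling_rate`.
#' @export
subsegment <- function(epochs, segment_duration = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sampling_rate
  seg_len <- as.integer(round(segment_duration * fs))
  epoch_len <- dim(epochs$epochs)[3]
  if (epoch_len %% seg_len != 0) {
    stop("epoch length is not divisible by the segment length")
  }
  k <- epoch_len %/% seg_len
  n_ep <- dim(epochs$epochs)[1]
  m <- dim(epochs$epochs)[2]
  segs <- array(NA_real_, c(n_ep * k, m, seg_len))
  for (i in seq_len(n_ep)) {
    for (j in seq_len(k)) {
      segs[(i - 1) * k + j, , ] <-
        epochs$epochs[i, , ((j - 1) * seg_len + 1):(j * seg_len)]
    }
  }
  structure(
    list(
      segments = segs,
      condition = rep(epochs$condition, each = k),
      trial_id = rep(epochs$trial_id, each = k),
      subsegment_index = rep(seq_len(k), times = n_ep),
      channel_labels = epochs$channel_labels,
      sampling_rate = fs
    ),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments x %d channels x %d samples (%d conditions)\n",
    dim(x$segments)[1], dim(x$segments)[2], dim(x$segments)[3],
    length(unique(x$condition))
  ))
  invisible(x)
}

#' Load the montage definitions
#'
#' Montages are shipped as an editable YAML resource. Four spatial
#' configurations are defined: `LD-SM` (the two sensorimotor electrodes C3
#' and C4), `LD-whole` (the 19 standard 10-20 positions), `HD-SM` (27
#' labels over the central strip of a high-density net) and `HD-whole` (all
#' channels of the recording minus a declared face/neck exclusion list sized
#' to leave 197 of 256). The high-density label sets are declared
#' approximations of a geodesic sensor layout and can be overridden by
#' editing the file or passing a different `path`. Each montage also carries
#' the autoregressive `model_order` used for its connectivity features.
#'
#' @param path YAML file; defaults to the packaged resource.
#' @return named list of `montage_config` objects with fields `name`,
#'   `channels` (NULL for exclusion-based montages), `exclude`,
#'   `model_order`.
#' @export
load_montages <- function(path = system.file("extdata", "montages.yaml",
                            package = "midecode"
                          )) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    m <- raw[[nm]]
    structure(
      list(
        name = nm,
        channels = if (!is.null(m$channels)) as.character(m$channels) else NULL,
        exclude = if (!is.null(m$exclude)) as.character(m$exclude) else character(),
        model_order = as.integer(m$model_order)
      ),
      class = "montage_config"
    )
  })
  names(out) <- names(raw)
  out
}

#' Restrict a segment set to a montage's channels
#'
#' Selects the montage's channel list (order as listed) from the segment
#' set. Exclusion-based montages (`HD-whole`) keep every channel of the
#' recording except the declared exclusion labels, preserving recording
#' order.
#'
#' @param segments a `segment_set`.
#' @param montage a `montage_config` from [load_montages()].
#' @return a `segment_set` with the reduced channel dimension.
#' @export
apply_montage <- function(segments, montage) {
  stopifnot(inherits(segments, "segment_set"), inherits(montage, "montage_config"))
  labels <- segments$channel_labels
  if (is.null(montage$channels)) {
    keep <- setdiff(labels, montage$exclude)
  } else {
    missing <- setdiff(montage$channels, labels)
    if (length(missing) > 0) {
      stop(
        "montage '", montage$name, "' references absent channel(s): ",
        paste(missing, collapse = ", ")
      )
    }
    keep <- montage$channels
  }
  idx <- match(keep, labels)
  out <- segments
  out$segments <- segments$segments[, idx, , drop = FALSE]
  out$channel_labels <- labels[idx]
  out
}
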