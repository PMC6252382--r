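#' Write a recording to the internal array container
#'
#' The container is a raw little-endian float64 array file (`<stem>.dat`,
#' channel-major: all samples of channel 1, then channel 2, ...) plus a JSON
#' sidecar (`<stem>.json`) holding channel labels, sampling rate, events,
#' profile, session and — for synthetic recordings — the generating seed.
#'
#' @param recording an `eeg_recording`.
#' @param stem path without extension.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 8, endian = "little")
  meta <- list(
    n_channels = nrow(recording$data),
    n_samples = ncol(recording$data),
    channel_labels = recording$channel_labels,
    sampling_rate = recording$sampling_rate,
    events = as.data.frame(recording$events),
    profile = recording$profile,
    session = recording$session,
    seed = recording$ground_truth$seed
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Read a recording from the internal array container
#'
#' @param stem path without extension, as written by [write_recording()].
#' @return an `eeg_recording` (without ground-truth generator parameters
#'   beyond the seed).
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  data <- t(matrix(raw, nrow = meta$n_samples, ncol = meta$n_channels))
  structure(
    list(
      data = data,
      channel_labels = meta$channel_labels,
      sampling_rate = as.numeric(meta$sampling_rate),
      events = tibble::as_tibble(meta$events),
      profile = meta$profile,
      session = as.integer(meta$session),
      ground_truth = list(seed = meta$seed)
    ),
    class = "eeg_recording"
  )
}

#' Write a feature table as tab-separated text
#'
#' One row per segment; the header names each feature from its index map
#' (`channel|band` for FFT, `source>sink|band` for ffDTF).
#'
#' @param features a `feature_table`.
#' @param path output file.
#' @export
write_feature_table <- function(features, path) {
  im <- features$index_map
  hdr <- if (features$kind == "FFT") {
    paste0(im$channel, "|", im$band)
  } else {
    paste0(im$source, ">", im$sink, "|", im$band)
  }
  df <- as.data.frame(features$values)
  names(df) <- hdr
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
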