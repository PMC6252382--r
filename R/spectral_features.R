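#' Default 13-band averaging scheme over 1-48 Hz
#'
#' Band power is averaged in 2 Hz bands from 1 Hz up to 20 Hz (ten bands),
#' then in three broad bands covering 21-30, 31-40 and 41-48 Hz. With 1 Hz
#' spectral resolution the bins partition the integers 1..48, so every bin
#' belongs to exactly one band and the scheme is well defined for averaging.
#'
#' @return object of class `band_scheme`: a named list of integer bin vectors
#'   (frequencies in Hz), 13 bands in ascending order.
#' @export
band_scheme <- function() {
  low <- lapply(seq(1, 19, by = 2), function(f) c(f, f + 1L))
  names(low) <- vapply(low, function(b) sprintf("%d-%d Hz", b[1], b[2]), "")
  high <- list(
    "21-30 Hz" = 21:30,
    "31-40 Hz" = 31:40,
    "41-48 Hz" = 41:48
  )
  scheme <- c(low, high)
  scheme <- lapply(scheme, as.integer)
  stopifnot(
    length(scheme) == 13,
    identical(sort(unlist(scheme, use.names = FALSE)), 1:48)
  )
  structure(scheme, class = "band_scheme")
}

#' One-sided FFT power spectrum at 1 Hz resolution
#'
#' Computes the magnitude-squared one-sided spectrum of each channel of a
#' 1-second segment. At 250 samples and 250 Hz the DFT bins fall exactly on
#' integer frequencies. Scaling is such that the sum over the full one-sided
#' spectrum (DC through Nyquist, `bins = 0:125`) equals the time-domain mean
#' square power (Parseval). No taper is applied: the segments are already
#' high-passed and the rectangular window keeps tone power in its own bin.
#'
#' @param segment numeric matrix, channels x samples.
#' @param sampling_rate sampling rate in Hz; must equal the sample count so
#'   that bins are 1 Hz apart.
#' @param bins integer frequencies (Hz) to return; default 1:48.
#' @return matrix channels x length(bins) with column names the frequencies.
#' @export
power_spectrum <- function(segment, sampling_rate = 250, bins = 1:48) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n != sampling_rate) {
    stop("segment length must equal the sampling rate (1 Hz bin resolution)")
  }
  if (any(!is.finite(segment))) stop("non-finite values in segment")
  stopifnot(all(bins >= 0), all(bins <= n / 2))
  X <- t(apply(segment, 1, stats::fft))
  if (nrow(segment) == 1) X <- matrix(X, nrow = 1)
  p <- Mod(X)^2 / n^2
  # fold negative frequencies onto 1..(n/2 - 1); DC and Nyquist unpaired
  k <- bins + 1L
  scale <- ifelse(bins == 0 | bins == n / 2, 1, 2)
  out <- sweep(p[, k, drop = FALSE], 2, scale, "*")
  dimnames(out) <- list(rownames(segment), as.character(bins))
  out
}

#' Average per-frequency values into bands
#'
#' @param spectrum numeric matrix channels x 48 (columns named with integer
#'   frequencies 1..48), or a vector over 1..48 Hz.
#' @param scheme a [band_scheme()].
#' @return matrix channels x 13, columns named by band label; each entry the
#'   arithmetic mean over the band's bins.
#' @export
band_average <- function(spectrum, scheme = band_scheme()) {
  if (is.vector(spectrum)) spectrum <- matrix(spectrum, nrow = 1)
  freqs <- as.integer(colnames(spectrum) %||% seq_len(ncol(spectrum)))
  need <- sort(unique(unlist(scheme, use.names = FALSE)))
  if (!all(need %in% freqs)) {
    stop("spectrum does not cover bins: ", paste(setdiff(need, freqs), collapse = ", "))
  }
  out <- vapply(
    scheme,
    function(b) rowMeans(spectrum[, match(b, freqs), drop = FALSE]),
    numeric(nrow(spectrum))
  )
  if (nrow(spectrum) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(scheme)))
  out
}

# Construct a feature table object; values is n_segments x n_features,
# index_map a tibble with one row per feature.
feature_table <- function(values, index_map, kind) {
  stopifnot(ncol(values) == nrow(index_map), kind %in% c("FFT", "ffDTF"))
  if (any(!is.finite(values))) stop("non-finite feature values")
  structure(
    list(values = values, index_map = index_map, kind = kind),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %s: %d segments x %d features\n",
    x$kind, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Band-averaged FFT power features for every segment
#'
#' One row per 1-second segment; features are ordered channel-major, then
#' band, giving `M x 13` features for `M` channels. Values are raw band
#' power by default; `log_power = TRUE` applies `log10`.
#'
#' @param segments a `segment_set` (see [subsegment()]), montage already
#'   applied.
#' @param scheme a [band_scheme()].
#' @param log_power return `log10` power instead of raw power.
#' @return a `feature_table` with `index_map` columns `feature`, `channel`,
#'   `band`.
#' @export
build_fft_features <- function(segments, scheme = band_scheme(), log_power = FALSE) {
  stopifnot(inherits(segments, "segment_set"))
  n_seg <- dim(segments$segments)[1]
  labels <- segments$channel_labels
  m <- length(labels)
  vals <- matrix(NA_real_, n_seg, m * length(scheme))
  for (i in seq_len(n_seg)) {
    sp <- power_spectrum(segments$segments[i, , , drop = TRUE],
      sampling_rate = segments$sampling_rate
    )
    if (m == 1) sp <- matrix(sp, nrow = 1)
    ba <- band_average(sp, scheme)
    vals[i, ] <- as.vector(t(ba)) # channel-major: ch1 bands, ch2 bands, ...
  }
  if (log_power) vals <- log10(vals)
  index_map <- tibble::tibble(
    feature = seq_len(m * length(scheme)),
    channel = rep(labels, each = length(scheme)),
    band = rep(names(scheme), times = m)
  )
  feature_table(vals, index_map, "FFT")
}
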