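#' Largest admissible MVAR model order for a segment
#'
#' The number of autoregressive coefficients (`M^2 p`) must stay below the
#' number of data points (`M N`), i.e. `N / (M p) > 1`. This returns the
#' largest integer order satisfying that bound: with 250 samples it gives
#' p = 9 at 27 channels and p = 1 at 197 channels.
#'
#' @param n_samples samples per segment (N).
#' @param n_channels channels (M).
#' @return largest integer `p` with `n_samples / (n_channels * p) > 1`.
#' @export
max_model_order <- function(n_samples, n_channels) {
  stopifnot(n_samples >= 1, n_channels >= 1)
  p <- floor((n_samples - 1) / n_channels)
  if (p < 1) stop("no valid model order: n_samples must exceed n_channels")
  as.integer(p)
}

#' Fit a multivariate autoregressive model by the Vieira-Morf recursion
#'
#' Estimates the MVAR model `x(t) = sum_k A_k x(t-k) + e(t)` with the
#' Vieira-Morf lattice (forward/backward prediction-error partial
#' correlation) recursion. Reflection matrices are obtained from the
#' geometric-mean normalisation of the forward/backward cross-covariance;
#' all covariances are normalised by the actual number of lagged products
#' (unbiased estimates). Channels are demeaned before fitting.
#'
#' @param segment numeric matrix, channels (M) x samples (N).
#' @param order model order p; must satisfy `N / (M * p) > 1`.
#' @return an `mvar_model`: list with `order`, `coefficients` (list of p
#'   M x M matrices A_1..A_p), `innovation_cov` (M x M), `sampling_rate`
#'   (attached by callers that know it; NA here), `channel_labels`.
#' @export
fit_mvar <- function(segment, order) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  m <- nrow(segment)
  n <- ncol(segment)
  stopifnot(order >= 1)
  if (n / (m * order) <= 1) {
    stop("model order too large: need N/(M*p) > 1")
  }
  if (any(!is.finite(segment))) stop("non-finite values in segment")
  x <- segment - rowMeans(segment)

  chol_lower <- function(P) {
    L <- tryCatch(t(chol(P)), error = function(e) {
      stop("rank-deficient residual covariance (singular lattice update)")
    })
    L
  }

  f <- x # forward error f_{k-1}(t), valid columns k..n
  b <- x # backward error b_{k-1}(t), valid columns k..n
  A <- list() # A_i^{(k)}
  Bc <- list() # backward coefficients
  for (k in seq_len(order)) {
    tf <- (k + 1):n # indices of f_{k-1}(t)
    tb <- k:(n - 1) # indices of b_{k-1}(t-1)
    nk <- n - k
    D <- f[, tf, drop = FALSE] %*% t(b[, tb, drop = FALSE]) / nk
    Pf <- f[, tf, drop = FALSE] %*% t(f[, tf, drop = FALSE]) / nk
    Pb <- b[, tb, drop = FALSE] %*% t(b[, tb, drop = FALSE]) / nk
    Lf <- chol_lower(Pf)
    Lb <- chol_lower(Pb)
    rho <- solve(Lf, t(solve(Lb, t(D)))) # Lf^-1 D Lb^-T
    Kf <- Lf %*% rho %*% solve(Lb)
    Kb <- Lb %*% t(rho) %*% solve(Lf)

    f_new <- f[, tf, drop = FALSE] - Kf %*% b[, tb, drop = FALSE]
    b_new <- b[, tb, drop = FALSE] - Kb %*% f[, tf, drop = FALSE]

    A_new <- vector("list", k)
    B_new <- vector("list", k)
    A_new[[k]] <- Kf
    B_new[[k]] <- Kb
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        A_new[[i]] <- A[[i]] - Kf %*% Bc[[k - i]]
        B_new[[i]] <- Bc[[i]] - Kb %*% A[[k - i]]
      }
    }
    A <- A_new
    Bc <- B_new
    # re-align error series so that column t again corresponds to time t
    f <- cbind(matrix(0, m, k), f_new)
    b <- cbind(matrix(0, m, k), b_new)
  }
  resid <- f[, (order + 1):n, drop = FALSE]
  sigma <- resid %*% t(resid) / (n - order)
  structure(
    list(
      order = as.integer(order),
      coefficients = A,
      innovation_cov = sigma,
      sampling_rate = NA_real_,
      channel_labels = rownames(segment)
    ),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  m <- nrow(x$innovation_cov)
  cat(sprintf("<mvar_model> M = %d channels, order p = %d\n", m, x$order))
  invisible(x)
}

#' Spectral radius of the companion matrix of an MVAR model
#'
#' The model is stable (stationary) iff this is below 1.
#'
#' @param coefficients list of p M x M coefficient matrices.
#' @return largest eigenvalue modulus of the companion form.
#' @export
mvar_spectral_radius <- function(coefficients) {
  p <- length(coefficients)
  m <- nrow(coefficients[[1]])
  comp <- matrix(0, m * p, m * p)
  comp[1:m, ] <- do.call(cbind, coefficients)
  if (p > 1) {
    comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Frequency-domain transfer function of an MVAR model
#'
#' Evaluates `H(f) = (I - sum_k A_k exp(-i 2 pi f k / fs))^-1` on a
#' frequency grid.
#'
#' @param model an `mvar_model`.
#' @param frequencies numeric vector of frequencies in Hz (default 1..48).
#' @param sampling_rate Hz (default 250; overrides any rate in the model).
#' @return complex array `[n_freq, M, M]`, `H[f, i, j]` the transfer from
#'   source j to sink i.
#' @export
transfer_function <- function(model, frequencies = 1:48, sampling_rate = 250) {
  stopifnot(inherits(model, "mvar_model"))
  m <- nrow(model$innovation_cov)
  H <- array(NA_complex_, c(length(frequencies), m, m))
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    Abar <- diag(m) + 0i
    for (k in seq_len(model$order)) {
      Abar <- Abar - model$coefficients[[k]] * exp(-2i * pi * f * k / sampling_rate)
    }
    Hf <- tryCatch(solve(Abar), error = function(e) {
      stop(sprintf("transfer matrix is singular at f = %g Hz", f))
    })
    H[fi, , ] <- Hf
  }
  dimnames(H) <- list(as.character(frequencies), NULL, NULL)
  H
}

#' Full-frequency Directed Transfer Function
#'
#' Normalises the squared transfer magnitudes over sources *and* the entire
#' frequency grid, per sink row:
#' \deqn{\eta^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_{f'} \sum_m |H_{im}(f')|^2}
#' so that for every sink i the values over all sources and frequencies sum
#' to 1, emphasising the frequencies that carry most inflow power. With
#' `squared = FALSE` the magnitude variant
#' `|H_ij(f)| / sqrt(sum |H_im(f')|^2)` is returned instead.
#'
#' @param transfer complex array `[n_freq, M, M]` from [transfer_function()]
#'   covering the full 1..48 Hz grid.
#' @param squared use squared magnitudes (default TRUE).
#' @return real array of the same shape with values in `[0, 1]`.
#' @export
ffdtf <- function(transfer, squared = TRUE) {
  h2 <- Mod(transfer)^2
  m <- dim(h2)[2]
  denom <- apply(h2, 2, sum) # per sink row i: sum over f and sources
  if (any(denom <= 0)) stop("zero denominator row in ffDTF normalisation")
  out <- h2
  for (i in seq_len(m)) out[, i, ] <- h2[, i, ] / denom[i]
  if (!squared) out <- sqrt(out)
  out
}

#' Band-averaged ffDTF connectivity features for every segment
#'
#' Per segment: fit the MVAR model at the montage's configured order,
#' evaluate the transfer function on the 1..48 Hz grid, form the ffDTF and
#' aggregate each ordered channel pair (self-flows included) over the 13
#' frequency bands, yielding `M * M * 13` features per segment. Segments
#' whose lattice fit fails (rank-deficient residual covariance) are dropped
#' with a warning naming the segment.
#'
#' @param segments a `segment_set` with the montage already applied.
#' @param montage the `montage_config` (provides `model_order`).
#' @param scheme a [band_scheme()].
#' @param squared squared-magnitude ffDTF (default) or magnitude variant.
#' @param band_stat aggregate band bins by `"mean"` (default) or `"sum"`.
#' @return a `feature_table` with `index_map` columns `feature`, `source`,
#'   `sink`, `band`; the table keeps `condition`/`trial_id` alignment of the
#'   retained segments in attribute `kept`.
#' @export
build_ffdtf_features <- function(segments, montage, scheme = band_scheme(),
                                 squared = TRUE, band_stat = c("mean", "sum")) {
  stopifnot(inherits(segments, "segment_set"))
  band_stat <- match.arg(band_stat)
  labels <- segments$channel_labels
  m <- length(labels)
  p <- montage$model_order
  n_seg <- dim(segments$segments)[1]
  nb <- length(scheme)
  vals <- matrix(NA_real_, n_seg, m * m * nb)
  ok <- rep(TRUE, n_seg)
  for (s in seq_len(n_seg)) {
    res <- tryCatch(
      {
        mod <- fit_mvar(segments$segments[s, , , drop = TRUE], order = p)
        H <- transfer_function(mod, 1:48, sampling_rate = segments$sampling_rate)
        eta <- ffdtf(H, squared = squared)
        feats <- numeric(m * m * nb)
        idx <- 1L
        for (i in seq_len(m)) { # sink
          for (j in seq_len(m)) { # source
            series <- eta[, i, j]
            for (b in seq_len(nb)) {
              bins <- scheme[[b]]
              feats[idx] <- if (band_stat == "mean") {
                mean(series[bins])
              } else {
                sum(series[bins])
              }
              idx <- idx + 1L
            }
          }
        }
        feats
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      ok[s] <- FALSE
      warning(sprintf("segment %d rejected: %s", s, conditionMessage(res)))
    } else {
      vals[s, ] <- res
    }
  }
  index_map <- tibble::tibble(
    feature = seq_len(m * m * nb),
    sink = rep(labels, each = m * nb),
    source = rep(rep(labels, each = nb), times = m),
    band = rep(names(scheme), times = m * m)
  )
  ft <- feature_table(vals[ok, , drop = FALSE], index_map, "ffDTF")
  attr(ft, "kept") <- which(ok)
  ft
}
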