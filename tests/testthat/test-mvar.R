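# Ordinary least-squares MVAR fit: independent oracle for the lattice
# estimator on small systems.
ols_mvar <- function(x, p) {
  x <- x - rowMeans(x)
  m <- nrow(x)
  n <- ncol(x)
  Y <- t(x[, (p + 1):n, drop = FALSE])
  Z <- do.call(cbind, lapply(seq_len(p), function(k) {
    t(x[, (p + 1 - k):(n - k), drop = FALSE])
  }))
  B <- solve(crossprod(Z), crossprod(Z, Y)) # (m*p) x m
  lapply(seq_len(p), function(k) t(B[((k - 1) * m + 1):(k * m), , drop = FALSE]))
}

test_that("the model-order rule reproduces the configured orders", {
  expect_identical(max_model_order(250, 27), 9L)
  expect_identical(max_model_order(250, 197), 1L)
  expect_identical(max_model_order(250, 19), 13L)
  expect_identical(max_model_order(250, 2), 124L)
  expect_error(max_model_order(250, 300), "exceed")
})

test_that("the lattice estimator recovers known autoregressive structure", {
  # independent white noise: all coefficients near zero
  w <- simulate_mvar(list(matrix(0, 2, 2)), diag(2), 10000, seed = 21)
  fw <- fit_mvar(w, 1)
  expect_true(all(abs(fw$coefficients[[1]]) < 0.05))
  # AR(1), a = 0.5
  x <- simulate_mvar(list(matrix(0.5)), matrix(1), 10000, seed = 22)
  fx <- fit_mvar(x, 1)
  expect_lt(abs(fx$coefficients[[1]][1, 1] - 0.5), 0.02)
  expect_lt(abs(fx$innovation_cov[1, 1] - 1), 0.05)
  # unidirectional coupling: a21 recovered, a12 stays at zero
  A <- matrix(c(0.3, 0.4, 0, 0.3), 2, 2)
  y <- simulate_mvar(list(A), diag(2), 10000, seed = 23)
  fy <- fit_mvar(y, 1)
  expect_lt(abs(fy$coefficients[[1]][2, 1] - 0.4), 0.05)
  expect_lt(abs(fy$coefficients[[1]][1, 2]), 0.05)
})

test_that("lattice and least-squares estimates agree on well-conditioned data", {
  A1 <- matrix(c(0.5, 0.2, -0.1, 0.3), 2, 2)
  A2 <- matrix(c(-0.2, 0, 0.1, -0.1), 2, 2)
  y <- simulate_mvar(list(A1, A2), diag(2), 5000, seed = 24)
  vm <- fit_mvar(y, 2)$coefficients
  ols <- ols_mvar(y, 2)
  for (k in 1:2) expect_lt(max(abs(vm[[k]] - ols[[k]])), 0.02)
})

test_that("order bounds and degenerate inputs are rejected", {
  x <- matrix(rnorm(2 * 100), 2, 100)
  expect_error(fit_mvar(x, 50), "N/\\(M\\*p\\)")
  xdup <- rbind(x[1, ], x[1, ]) # perfectly collinear channels
  expect_error(fit_mvar(xdup, 2), "rank-deficient")
})

test_that("the transfer function matches analytic forms", {
  null_model <- structure(
    list(
      order = 1L, coefficients = list(matrix(0, 3, 3)),
      innovation_cov = diag(3)
    ),
    class = "mvar_model"
  )
  H <- transfer_function(null_model, 1:48, 250)
  for (f in c(1, 25, 48)) {
    expect_equal(H[as.character(f), , ], diag(3) + 0i, tolerance = 1e-12)
  }
  ar1 <- structure(
    list(
      order = 1L, coefficients = list(matrix(0.5)),
      innovation_cov = matrix(1)
    ),
    class = "mvar_model"
  )
  H1 <- transfer_function(ar1, 1:48, 250)
  analytic <- 1 / Mod(1 - 0.5 * exp(-2i * pi * (1:48) / 250))^2
  expect_lt(max(abs(Mod(H1[, 1, 1])^2 - analytic)), 1e-9)
  expect_true(all(is.finite(Mod(H1))))
})

test_that("ffDTF is normalized per sink over sources and frequencies", {
  ident <- array(0 + 0i, c(48, 2, 2))
  ident[, 1, 1] <- 1 + 0i
  ident[, 2, 2] <- 1 + 0i
  eta <- ffdtf(ident)
  expect_equal(eta[, 1, 2], rep(0, 48))
  expect_equal(eta[, 1, 1], rep(1 / 48, 48), tolerance = 1e-12)

  y <- simulate_mvar(
    list(matrix(c(0.4, 0.3, -0.2, 0.5), 2, 2)), diag(2),
    2500,
    seed = 31
  )
  H <- transfer_function(fit_mvar(y, 3), 1:48, 250)
  eta2 <- ffdtf(H)
  expect_true(all(eta2 >= 0 & eta2 <= 1))
  for (i in 1:2) expect_equal(sum(eta2[, i, ]), 1, tolerance = 1e-9)
  # magnitude variant squares back to the squared form
  expect_equal(ffdtf(H, squared = FALSE)^2, eta2, tolerance = 1e-12)
})

test_that("ffDTF recovers directionality of a unidirectional system", {
  A <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2) # only 1 -> 2
  y <- simulate_mvar(list(A), diag(2), 2500, seed = 32)
  H <- transfer_function(fit_mvar(y, 2), 1:48, 250)
  eta <- ffdtf(H)
  inflow_21 <- sum(eta[, 2, 1]) # source 1 -> sink 2
  inflow_12 <- sum(eta[, 1, 2])
  expect_gt(inflow_21, 10 * inflow_12)
})

test_that("ffDTF feature tables have pair-by-band layout and carry the
           normalization through band sums", {
  cfg <- tiny_config(n_trials = 2)
  rec <- generate_recording(cfg, "control", 1, seed = 13)
  mont <- tiny_montage(order = 5L)
  segs <- apply_montage(subsegment(segment_trials(rec)), mont)
  ft <- build_ffdtf_features(segs, mont)
  expect_identical(ncol(ft$values), 52L) # 2 x 2 x 13
  expect_identical(nrow(ft$values), 84L)
  expect_true(all(ft$values >= 0 & ft$values <= 1))
  expect_identical(ft$index_map$sink[1:26], rep("C3", 26))
  expect_identical(ft$index_map$source[c(1, 14)], c("C3", "C4"))

  # with bin sums instead of means, each sink row sums to 1 per segment
  ft_sum <- build_ffdtf_features(segs, mont, band_stat = "sum")
  for (sink in c("C3", "C4")) {
    cols <- which(ft_sum$index_map$sink == sink)
    expect_equal(rowSums(ft_sum$values[, cols]), rep(1, 84),
      tolerance = 1e-6
    )
  }
})

test_that("models fitted to stationary EEG-like segments are stable", {
  cfg <- tiny_config(n_trials = 4)
  rec <- generate_recording(cfg, "control", 1, seed = 14)
  mont <- tiny_montage(order = 8L)
  segs <- apply_montage(subsegment(segment_trials(rec)), mont)
  n <- dim(segs$segments)[1]
  radii <- vapply(seq_len(n), function(i) {
    mvar_spectral_radius(fit_mvar(segs$segments[i, , ], 8)$coefficients)
  }, numeric(1))
  expect_gte(mean(radii < 1), 0.99)
})
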