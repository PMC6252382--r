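test_that("identical seeds reproduce recordings bit-identically; study seeds differ", {
  cfg <- tiny_config(n_trials = 3)
  r1 <- generate_recording(cfg, "control", 1, seed = 42)
  r2 <- generate_recording(cfg, "control", 1, seed = 42)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- generate_recording(cfg, "control", 1, seed = 43)
  expect_false(identical(r1$data, r3$data))

  plan <- study_plan(study_config())
  expect_identical(nrow(plan), 36L)
  expect_identical(sum(plan$profile == "control"), 22L)
  expect_identical(sum(plan$profile == "patient"), 14L)
  expect_false(anyDuplicated(plan$seed) > 0)

  plan1 <- study_plan(study_config(
    n_control_recordings = 0,
    n_patient_recordings = 1, patient_sessions = 1L
  ))
  expect_identical(nrow(plan1), 1L)

  cfg2 <- study_config(
    n_control_recordings = 2, n_patient_recordings = 0,
    patient_sessions = integer(0), n_channels = 12,
    n_trials_per_condition = 2
  )
  recs <- generate_study(cfg2)
  expect_length(recs, 2)
  expect_false(identical(recs[[1]]$data, recs[[2]]$data))
})

test_that("event schedule has randomized order, full epochs and >= 1 s gaps", {
  cfg <- tiny_config(n_trials = 5)
  rec <- generate_recording(cfg, "control", 1, seed = 3)
  ev <- rec$events
  expect_identical(nrow(ev), 35L)
  expect_true(all(table(ev$condition) == 5))
  expect_true(all(diff(ev$onset) >= 6 * 250 + 250)) # epoch + 1 s gap
  expect_true(all(ev$onset + 6 * 250 - 1 <= ncol(rec$data)))
  expect_true(all(diff(ev$onset) > 0))
  # randomly intermixed: not blocked by condition
  expect_false(all(ev$condition == sort(ev$condition)))
  expect_false(anyDuplicated(rec$channel_labels) > 0)
})

test_that("null effect map leaves MF and RS mu-band power indistinguishable", {
  cfg <- study_config(
    n_control_recordings = 1, n_patient_recordings = 0,
    patient_sessions = integer(0), n_channels = 12,
    n_trials_per_condition = 100, effect_map = list()
  )
  rec <- generate_recording(cfg, "control", 1, seed = 5)
  segs <- subsegment(segment_trials(rec))
  mf <- mean_band_power(segs, "MF", c("C3", "C4"), 8:12)
  rs <- mean_band_power(segs, "RS", c("C3", "C4"), 8:12)
  se <- sqrt(var(mf) / length(mf) + var(rs) / length(rs))
  expect_lt(abs(mean(mf) - mean(rs)), 3 * se)
})

test_that("a planted 40% mu-power reduction is recovered from generated epochs", {
  em <- list(MF = list(
    hand = c(mu = 0.6, beta = 1),
    foot = c(mu = 0.6, beta = 1)
  ))
  ratios <- vapply(1:3, function(s) {
    cfg <- tiny_config(n_trials = 25, effect_map = em)
    rec <- generate_recording(cfg, "control", 1, seed = s)
    segs <- subsegment(segment_trials(rec))
    mean(mean_band_power(segs, "MF", c("C3", "C4"), 8:12)) /
      mean(mean_band_power(segs, "RS", c("C3", "C4"), 8:12))
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 0.6 - 1), 0.1)
})

test_that("patient profiles shift the reactive mu peak down", {
  cfg <- tiny_config(n_trials = 15)
  ctrl <- generate_recording(cfg, "control", 1, seed = 8)
  pat <- generate_recording(cfg, "patient", 1, seed = 8)
  peak_at <- function(rec) {
    segs <- subsegment(segment_trials(rec))
    sp <- vapply(
      6:14,
      function(f) mean(mean_band_power(segs, "RS", c("C3", "C4"), f)),
      numeric(1)
    )
    (6:14)[which.max(sp)]
  }
  expect_identical(peak_at(ctrl), 10L)
  expect_identical(peak_at(pat), 8L)
})

test_that("line noise is generated on demand and removed by the notch", {
  cfg <- tiny_config(n_trials = 2, line_noise_amplitude = 2)
  rec <- generate_recording(cfg, "control", 1, seed = 2)
  segs <- subsegment(segment_trials(rec))
  raw50 <- mean(mean_band_power(segs, "RS", "C3", 50:50))
  raw10 <- mean(mean_band_power(segs, "RS", "C3", 10:10))
  expect_gt(raw50, raw10) # mains dominates
  rec$data <- notch_filter(rec$data, 250, freq = 50)
  segs2 <- subsegment(segment_trials(rec))
  filt50 <- mean(mean_band_power(segs2, "RS", "C3", 50:50))
  expect_lt(filt50, raw50 / 100)
})

test_that("simulate_mvar matches closed-form autocorrelation structure", {
  # white noise: no lag-1 correlation
  w <- simulate_mvar(list(matrix(0, 2, 2)), diag(2), 10000, seed = 1)
  r <- cor(w[1, -1], w[1, -10000])
  expect_lt(abs(r), 0.05)
  # AR(1) with a = 0.5: rho(1) = 0.5
  x <- simulate_mvar(list(matrix(0.5)), matrix(1), 10000, seed = 2)
  expect_lt(abs(cor(x[1, -1], x[1, -10000]) - 0.5), 0.03)
  # unidirectional coupling 1 -> 2 shows up in lagged cross-correlation
  A <- matrix(c(0.3, 0.5, 0, 0.3), 2, 2) # A[2,1] = 0.5
  y <- simulate_mvar(list(A), diag(2), 10000, seed = 3)
  fwd <- cor(y[1, -10000], y[2, -1]) # x1(t) -> x2(t+1)
  bwd <- cor(y[2, -10000], y[1, -1])
  expect_gt(fwd, bwd + 0.2)
})

test_that("simulate_mvar rejects unstable or degenerate models", {
  expect_error(
    simulate_mvar(list(matrix(1.1)), matrix(1), 100),
    "unstable"
  )
  expect_error(
    simulate_mvar(
      list(matrix(0.2, 2, 2) * diag(2)),
      matrix(c(1, 1, 1, 1), 2), 100
    ),
    "positive definite"
  )
})

test_that("ground-truth coupling injected into recordings is detectable", {
  A <- matrix(c(0.4, 0.5, 0, 0.4), 2, 2)
  cfg <- tiny_config(
    n_trials = 2,
    coupling_spec = list(
      coefficients = list(A), innovation_cov = diag(2),
      channels = c("C3", "C4"), scale = 1.5
    )
  )
  rec <- generate_recording(cfg, "control", 1, seed = 4)
  expect_identical(rec$ground_truth$seed, 4)
  i <- match(c("C3", "C4"), rec$channel_labels)
  fwd <- cor(rec$data[i[1], -ncol(rec$data)], rec$data[i[2], -1])
  bwd <- cor(rec$data[i[2], -ncol(rec$data)], rec$data[i[1], -1])
  expect_gt(fwd, bwd)
})
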