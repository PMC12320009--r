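mk_rec <- function(data, fs = 100) {
  nch <- nrow(data)
  arr <- tiny_array()[seq_len(nch), ]
  new_recording(data, arr, fs)
}

test_that("artifact interpolation draws the bridging line and is idempotent", {
  # hand case: [0, 9, 0, 0] with the window covering sample 2 -> [0, 0, 0, 0]
  rec <- mk_rec(matrix(c(0, 9, 0, 0), 1), fs = 1)
  m <- artifact_mask(cbind(1, 2), 4)
  out <- interpolate_artifacts(rec, m)
  expect_equal(as.vector(out$data), c(0, 0, 0, 0))

  # a ramp is its own bridging line; flat channel unchanged
  ramp <- mk_rec(rbind(seq(0, 1, length.out = 50), rep(2, 50)), fs = 10)
  m2 <- artifact_mask(cbind(1.5, 3.0), 5)
  out2 <- interpolate_artifacts(ramp, m2)
  expect_equal(out2$data, ramp$data, tolerance = 1e-12)

  # idempotence
  rec3 <- mk_rec(matrix(rnorm(200), 2), fs = 10)
  o1 <- interpolate_artifacts(rec3, m2)
  expect_identical(interpolate_artifacts(o1, m2)$data, o1$data)

  # edge-touching window holds the nearest valid value
  rec4 <- mk_rec(matrix(1:10, 1), fs = 1)
  o4 <- interpolate_artifacts(rec4, artifact_mask(cbind(0, 3), 10))
  expect_equal(as.vector(o4$data)[1:3], c(4, 4, 4))
})

test_that("band-pass is zero-phase, preserves in-band amplitude, kills DC and 50 Hz", {
  fs <- 1200
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mid <- seq(5 * fs, 15 * fs)
  rec <- mk_rec(rbind(sin(2 * pi * 3 * t), 1, sin(2 * pi * 50 * t)), fs = fs)
  out <- filter_bandpass(rec, 1, 40)
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.01)        # 3 Hz within 1%
  expect_lt(max(abs(out$data[2, mid])), 10^(-40 / 20))        # DC > 40 dB down
  wide <- filter_bandpass(rec, 0.2, 40)
  expect_lt(max(abs(wide$data[3, mid])), 10^(-40 / 20))       # 50 Hz > 40 dB down

  # impulse keeps its latency (zero phase), +/- 1 sample
  imp <- matrix(0, 1, fs * 4); imp[1, 2 * fs] <- 1
  fi <- filter_bandpass(mk_rec(imp, fs = fs), 1, 40)
  expect_lte(abs(which.max(fi$data[1, ]) - 2 * fs), 1)

  # linearity
  x <- matrix(rnorm(fs * 2), 1); y <- matrix(rnorm(fs * 2), 1)
  fa <- filter_bandpass(mk_rec(2 * x + 3 * y, fs), 1, 40)$data
  fb <- 2 * filter_bandpass(mk_rec(x, fs), 1, 40)$data +
    3 * filter_bandpass(mk_rec(y, fs), 1, 40)$data
  expect_lt(max(abs(fa - fb)) / max(abs(fb)), 1e-9)
})

test_that("notch removes the line and leaves neighbours intact", {
  fs <- 600
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- mk_rec(rbind(sin(2 * pi * 25 * t) + sin(2 * pi * 20 * t)), fs = fs)
  out <- filter_notch(rec, 25)
  mid <- seq(2 * fs, 8 * fs)
  resid <- out$data[1, mid] - sin(2 * pi * 20 * t)[mid]
  expect_lt(max(abs(resid)), 0.02)
})

test_that("noise-peak detection flags injected lines inside the band only", {
  fs <- 600
  n <- fs * 60
  t <- (seq_len(n) - 1) / fs
  base <- matrix(rnorm(4 * n), 4)
  expect_length(detect_noise_peaks(mk_rec(base, fs)), 0)

  amp <- sd(base) * 2    # line clearly above the white floor in a 4 s window
  with_line <- base + matrix(rep(amp * sin(2 * pi * 25 * t), each = 4), 4)
  pk <- detect_noise_peaks(mk_rec(with_line, fs))
  expect_true(any(abs(pk - 25) <= 0.5))

  outside <- base + matrix(rep(amp * sin(2 * pi * 50 * t), each = 4), 4)
  expect_length(detect_noise_peaks(mk_rec(outside, fs)), 0)
})

test_that("robust z-score rejection masks bursts, not Gaussian noise, monotonically", {
  fs <- 100
  n <- fs * 120
  set.seed(11)
  clean <- mk_rec(matrix(rnorm(2 * n), 2), fs)
  m <- robust_zscore_reject(clean, threshold = 5)
  masked <- sum(mask_samples(m, fs, n))
  expect_lt(masked / n, 0.001)
  expect_equal(nrow(robust_zscore_reject(clean, threshold = Inf)$windows), 0)

  burst <- clean
  i <- seq(60 * fs, 60.2 * fs)
  burst$data[1, i] <- burst$data[1, i] + 50
  mb <- robust_zscore_reject(burst, threshold = 5)
  bs <- mask_samples(mb, fs, n)
  expect_true(all(bs[i]))

  # lowering the threshold never shrinks the mask
  m3 <- robust_zscore_reject(burst, threshold = 3)
  expect_true(all(bs | !bs))  # trivially typed
  expect_true(all(mask_samples(mb, fs, n) <= mask_samples(m3, fs, n)))

  # all-constant channel contributes nothing
  const <- mk_rec(rbind(rep(1, n)), fs)
  expect_equal(nrow(robust_zscore_reject(const)$windows), 0)
})

test_that("window extension pads, clips and merges", {
  m <- artifact_mask(cbind(10, 11), 100)
  e <- extend_windows(m, 1.5)
  expect_equal(as.numeric(e$windows[1, ]), c(8.5, 12.5))

  m2 <- artifact_mask(rbind(c(0, 1), c(2, 3)), 100)
  e2 <- extend_windows(m2, 1.5)
  expect_equal(nrow(e2$windows), 1)
  expect_equal(as.numeric(e2$windows[1, ]), c(0, 4.5))

  empty <- artifact_mask(matrix(numeric(0), ncol = 2), 100)
  expect_equal(nrow(extend_windows(empty)$windows), 0)
})

test_that("principal-component projection removes exactly the fitted subspace", {
  fs <- 50
  n <- fs * 20
  set.seed(3)
  pattern <- rnorm(6)
  rank1 <- mk_rec(tcrossprod(pattern, sin(2 * pi * 1 * (1:n) / fs)), fs)
  out <- project_out_pcs(rank1, n = 1)
  expect_lt(max(abs(out$data)), max(abs(rank1$data)) * 1e-10)

  noisy <- mk_rec(matrix(rnorm(6 * n), 6), fs)
  expect_identical(project_out_pcs(noisy, n = 0)$data, noisy$data)
  expect_error(project_out_pcs(noisy, n = 6), "components")

  o3 <- project_out_pcs(noisy, n = 3)
  U <- o3$meta$pc_projector
  expect_lt(max(abs(t(U) %*% o3$data)) / max(abs(noisy$data)), 1e-10)
  # idempotent for the same subspace
  again <- o3
  again$data <- o3$data - U %*% (t(U) %*% o3$data)
  expect_equal(again$data, o3$data, tolerance = 1e-12)
})

test_that("ICA flags and removes an injected rank-1 heartbeat; clean data untouched", {
  arr <- tiny_array(6, 3, seed = 2)
  cfg <- fast_sim(duration = 60, sampling_rate = 300, evoked_amplitude = 0,
                  infant_heart_amplitude = 5e-12, parent_heart_amplitude = 0,
                  movement_rate = 0, drift = 0, pink_noise = 0, seed = 21)
  rec <- add_artifacts(generate_evoked_recording(cfg, arr), cfg)
  res <- suppressWarnings(remove_heartbeat_components(rec, seed = 5))
  expect_gte(length(res$decomposition$removed_components), 1)
  # residual heart-band SNR under the flag threshold
  filt <- filter_bandpass(res$recording, 1, 40)
  worst <- 0
  for (ch in seq_len(nrow(filt$data))) {
    ps <- opmpipe:::segment_power_spectrum(filt$data[ch, ], 300)
    snr <- snr_from_power(matrix(ps$power, 1), ps$freq)[1, ]
    i <- which(ps$freq >= 2.2 & ps$freq <= 2.5)
    worst <- max(worst, max(snr[i], na.rm = TRUE))
  }
  expect_lt(worst, 7.5)

  # reconstruction identity on the fitted data
  dec <- res$decomposition
  X <- filter_bandpass(rec, 1, 40)$data
  X <- X - rowMeans(X)
  recon <- dec$mixing %*% dec$unmixing %*% X
  expect_lt(max(abs(recon - X)) / max(abs(X)), 1e-6)

  # threshold Inf removes nothing
  res_inf <- suppressWarnings(remove_heartbeat_components(rec, snr_threshold = Inf, seed = 5))
  expect_identical(res_inf$recording$data, rec$data)

  # heartbeat-free noise: no component removed for several seeds
  removed <- vapply(1:5, function(s) {
    cfg0 <- fast_sim(duration = 40, sampling_rate = 300, evoked_amplitude = 0,
                     infant_heart_amplitude = 0, parent_heart_amplitude = 0,
                     movement_rate = 0, drift = 0, pink_noise = 0, seed = 100 + s)
    r0 <- generate_evoked_recording(cfg0, arr)
    length(suppressWarnings(remove_heartbeat_components(r0, seed = s))$decomposition$removed_components)
  }, numeric(1))
  expect_gte(mean(removed == 0), 0.8)
})

test_that("heart-rate ranges recover the component's dominant frequency", {
  arr <- tiny_array(6, 3, seed = 2)
  cfg <- fast_sim(duration = 60, sampling_rate = 300, evoked_amplitude = 0,
                  infant_heart_amplitude = 5e-12, parent_heart_amplitude = 2e-12,
                  movement_rate = 0, drift = 0, pink_noise = 0, seed = 22)
  rec <- add_artifacts(generate_evoked_recording(cfg, arr), cfg)
  res <- suppressWarnings(remove_heartbeat_components(rec, seed = 5))
  rng <- estimate_heart_rate_ranges(res$decomposition)
  expect_gte(length(rng), 1)
  truth <- rec$meta$artifact_truth$infant_rate
  hit <- vapply(rng, function(r) truth >= r[1] - 0.2 && truth <= r[2] + 0.2,
                logical(1))
  expect_true(any(hit))
  for (r in rng) expect_equal(r[2] - r[1], 0.3, tolerance = 1e-9)

  # nothing flagged -> empty list
  dec0 <- res$decomposition
  dec0$removed_components <- integer(0)
  expect_length(estimate_heart_rate_ranges(dec0), 0)
})
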