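# Shared fixtures: small arrays and fast simulation configs so that each
# test file stays inside a few seconds. All randomness is seeded.

tiny_array <- function(n_sensors = 8, triaxial = 5, seed = 1L) {
  make_sensor_array(n_sensors, head_radius = 0.065, triaxial_count = triaxial,
                    seed = seed)
}

fast_sim <- function(..., sampling_rate = 300, duration = 40, seed = 7L) {
  sim_config(sampling_rate = sampling_rate, duration = duration, seed = seed, ...)
}

# noise-free configs isolate the deterministic signal path
silent_sim <- function(...) {
  fast_sim(white_noise = 0, pink_noise = 0, drift = 0, movement_rate = 0,
           ambient_field = 0,
           infant_heart_amplitude = 0, parent_heart_amplitude = 0, ...)
}

# brute-force sign-flip null: exact p-value of max |mean| over all 2^n flips
enumerate_signflip_p <- function(arr) {
  n <- dim(arr)[1]
  M <- matrix(arr, nrow = n)
  obs <- abs(colMeans(M))
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  mx <- apply(abs(flips %*% M) / n, 1, max)
  vapply(obs, function(o) mean(mx >= o), numeric(1))
}

expect_tibble_row <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_equal(nrow(x), 1L)
}
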