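#' Simulation configuration for synthetic OPM-MEG recordings
#'
#' Defaults emulate the study conditions of a newborn auditory OPM-MEG
#' session: 5-minute sequences sampled at 1200 Hz; 100 ms tones (15 ms
#' fade-in/out) presented either with a 500-600 ms random SOA (evoked
#' paradigm) or at a steady 3 Hz with every fourth tone an oddball
#' (0.75 Hz); an evoked response peaking 260 ms post-stimulus at bilateral
#' temporal dipoles; infant (2.2-2.5 Hz) and parent (1.0-1.5 Hz) heartbeat
#' artifacts; sensor white noise, 1/f noise, drift and movement bursts.
#'
#' Amplitudes are in tesla at the most strongly coupled channel. The sensor
#' noise floor (25 fT/sqrt(Hz)) is typical of alkali OPMs; evoked amplitude
#' 2 pT and heartbeat amplitudes of a few pT reflect close-to-scalp infant
#' recordings.
#'
#' @param ... overrides for any of the defaults listed below.
#' @return A validated list of class `opm_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    sampling_rate = 1200,
    duration = 300,
    soa_range = c(0.5, 0.6),
    tone_dur = 0.1,
    fade = 0.015,
    base_rate = 3.0,
    oddball_every = 4L,
    evoked_peak_latency = 0.26,
    evoked_amplitude = 2e-12,
    oddball_base_amplitude = 1.5e-12,
    oddball_amplitude = 6e-13,
    # bilateral temporal dipoles (m, head frame: x anterior, y left, z up)
    dipole_pos = rbind(left = c(0, 0.045, 0.015), right = c(0, -0.045, 0.015)),
    # tangential moments (anterior-pointing) so they produce external field
    dipole_ori = rbind(left = c(1, 0, 0), right = c(1, 0, 0)),
    infant_heart_rate = c(2.2, 2.5),
    parent_heart_rate = c(1.0, 1.5),
    infant_heart_amplitude = 3e-12,
    parent_heart_amplitude = 1e-12,
    white_noise = 25e-15,       # T/sqrt(Hz), flat sensor noise density
    pink_noise = 25e-15,        # T/sqrt(Hz) at 1 Hz, density ~ 1/f
    ambient_field = 2e-11,      # T rms per axis: homogeneous field fluctuations
    drift = 2e-14,              # T/s, sd of per-channel linear drift slope
    movement_rate = 2 / 60,     # bursts per second
    movement_amplitude = 2e-11, # T at the strongest channel
    movement_duration = c(0.5, 2),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown sim_config fields:", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "opm_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0, cfg$duration > 0, cfg$base_rate > 0,
            cfg$soa_range[1] <= cfg$soa_range[2], cfg$soa_range[1] > 0,
            cfg$evoked_amplitude >= 0, cfg$oddball_base_amplitude >= 0,
            cfg$oddball_amplitude >= 0, cfg$ambient_field >= 0,
            cfg$infant_heart_amplitude >= 0,
            cfg$parent_heart_amplitude >= 0, cfg$white_noise >= 0,
            cfg$pink_noise >= 0, cfg$drift >= 0, cfg$movement_rate >= 0,
            all(cfg$infant_heart_rate > 0), all(cfg$parent_heart_rate > 0))
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @param cfg an `opm_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("dipole_pos", "dipole_ori"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- do.call(rbind, raw[[nm]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (nm in c("dipole_pos", "dipole_ori"))
    out[[nm]] <- lapply(seq_len(nrow(out[[nm]])), function(i) as.numeric(out[[nm]][i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

# biphasic source waveform: difference of two gamma-shaped bumps, unit peak
# at `peak` seconds. Shape parameter 12 gives a physiologically plausible
# ~150 ms wide main deflection. The rising second bump pulls the combined
# maximum slightly earlier, so the waveform is time-shifted so that its true
# maximum (located on a 0.1 ms grid) sits exactly at `peak`.
evoked_waveform <- function(t, peak, undershoot_frac = 0.35, shape = 12) {
  g <- function(t, p) ifelse(t <= 0, 0, (t / p)^shape * exp(shape * (1 - t / p)))
  w_raw <- function(t) g(t, peak) - undershoot_frac * g(t, peak + 0.18)
  tf <- seq(0, peak + 0.1, by = 1e-4)
  delta <- peak - tf[which.max(w_raw(tf))]
  w <- w_raw(t - delta)
  w / max(w)
}

# field pattern (channels vector) of the configured bilateral dipole pair,
# scaled so its largest absolute channel value is 1
dipole_pattern <- function(cfg, channels, centre = c(0, 0, 0)) {
  pos <- channel_positions(channels)
  ori <- channel_orientations(channels)
  f <- numeric(nrow(pos))
  for (d in seq_len(nrow(cfg$dipole_pos))) {
    B <- sarvas_field(pos, cfg$dipole_pos[d, ], cfg$dipole_ori[d, ], centre)
    f <- f + rowSums(B * ori)
  }
  if (max(abs(f)) == 0) abort("configured dipoles produce no field at this array")
  f / max(abs(f))
}

white_noise_matrix <- function(nch, n, fs, density) {
  if (density <= 0) return(matrix(0, nch, n))
  matrix(rnorm(nch * n, sd = density * sqrt(fs / 2)), nch, n)
}

# 1/f ("pink") noise by spectral shaping of white noise; `density` is the
# one-sided amplitude spectral density at 1 Hz in T/sqrt(Hz)
pink_noise_matrix <- function(nch, n, fs, density) {
  if (density <= 0) return(matrix(0, nch, n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # two-sided |f|
  h <- density * sqrt(fs / 2) / sqrt(pmax(f, fs / n))
  h[1] <- 0
  out <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    w <- rnorm(n)
    out[ch, ] <- Re(fft(fft(w) * h, inverse = TRUE)) / n
  }
  out
}

#' Generate a synthetic evoked-paradigm recording
#'
#' Tone events are laid down with stimulus onset asynchronies drawn uniformly
#' from `soa_range`. Each event injects a biphasic source time course peaking
#' at `evoked_peak_latency` through the spherical-conductor forward field of
#' the configured bilateral dipoles, scaled so the per-event average peaks at
#' `evoked_amplitude` on the best channel. Sensor white noise is added per
#' the config; environmental components are added by [add_artifacts()].
#' Ground truth (event times, waveform, spatial pattern) is stored in `meta`.
#'
#' @param config an [sim_config()] object.
#' @param array channel tibble from [make_sensor_array()].
#' @return An `opm_recording`.
#' @export
generate_evoked_recording <- function(config, array) {
  stopifnot(inherits(config, "opm_sim_config"), nrow(array) > 0)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  lead_out <- 0.6                       # room for the response after the last tone
  if (config$duration < config$soa_range[1] + lead_out)
    abort("duration too short for at least one event")
  events <- with_seed(derive_seed(config$seed, "events"), {
    t <- config$soa_range[1]
    out <- numeric(0)
    repeat {
      if (t > config$duration - lead_out) break
      out <- c(out, t)
      t <- t + runif(1, config$soa_range[1], config$soa_range[2])
    }
    out
  })
  pattern <- dipole_pattern(config, array)
  trel <- seq(0, lead_out, by = 1 / fs)
  bump <- evoked_waveform(trel, config$evoked_peak_latency)
  sig <- numeric(n)
  idx0 <- round(events * fs)            # sample index of each onset (0-based)
  for (i0 in idx0) {
    j <- i0 + seq_along(trel)
    keep <- j <= n
    sig[j[keep]] <- sig[j[keep]] + bump[keep]
  }
  data <- tcrossprod(pattern * config$evoked_amplitude, sig)
  data <- data + with_seed(derive_seed(config$seed, "white"),
                           white_noise_matrix(nrow(array), n, fs, config$white_noise))
  new_recording(data, array, fs,
                events = tibble(time = events, label = "tone"),
                meta = list(paradigm = "evoked", seed = config$seed,
                            ground_truth = list(
                              event_times = events,
                              peak_latency = config$evoked_peak_latency,
                              waveform_times = trel, waveform = bump,
                              pattern = pattern,
                              amplitude = config$evoked_amplitude)))
}

#' Generate a synthetic oddball (frequency-tagging) recording
#'
#' Tone events are exactly periodic at `base_rate`; every `oddball_every`-th
#' tone is labelled `oddball`. The neural signal is a steady-state component
#' at the base frequency plus an oddball-locked component whose spectrum has
#' lines at the oddball frequency and its harmonics, both projected through
#' the bilateral dipole field pattern. Line amplitudes (tesla at the best
#' channel) are recorded as ground truth in `meta`.
#'
#' @inheritParams generate_evoked_recording
#' @return An `opm_recording`.
#' @export
generate_oddball_recording <- function(config, array) {
  stopifnot(inherits(config, "opm_sim_config"), nrow(array) > 0)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  fb <- config$base_rate
  fo <- fb / config$oddball_every
  n_ev <- floor(config$duration * fb)
  ev_t <- (seq_len(n_ev) - 1L) / fb
  # the cycle starts on an oddball so fixed-length oddball-locked epochs can
  # tile the recording from t = 0
  lab <- ifelse((seq_len(n_ev) - 1L) %% config$oddball_every == 0L,
                "oddball", "base")
  t <- (seq_len(n) - 1L) / fs
  # base line at fb; oddball-locked lines at fo and its first harmonic (the
  # next harmonic, 3 fo, falls into the infant heart-rate band and is not
  # part of the simulated neural response)
  lines <- rbind(c(fb, config$oddball_base_amplitude),
                 c(fo, config$oddball_amplitude),
                 c(2 * fo, 0.6 * config$oddball_amplitude))
  sig <- numeric(n)
  for (i in seq_len(nrow(lines)))
    sig <- sig + lines[i, 2] * sin(2 * pi * lines[i, 1] * t)
  pattern <- dipole_pattern(config, array)
  data <- tcrossprod(pattern, sig)
  data <- data + with_seed(derive_seed(config$seed, "white"),
                           white_noise_matrix(nrow(array), n, fs, config$white_noise))
  new_recording(data, array, fs,
                events = tibble(time = ev_t, label = lab),
                meta = list(paradigm = "oddball", seed = config$seed,
                            ground_truth = list(
                              base_freq = fb, oddball_freq = fo,
                              line_freq = lines[, 1], line_amp = lines[, 2],
                              pattern = pattern)))
}

# quasi-periodic pseudo-ECG: sharp QRS spike plus a smaller, wider T wave,
# beat times jittered around the nominal rate
heartbeat_trace <- function(n, fs, rate, jitter = 0.03) {
  t <- (seq_len(n) - 1L) / fs
  out <- numeric(n)
  beat <- 0.05
  while (beat < n / fs) {
    qrs <- exp(-((t - beat) / 0.015)^2)
    tw <- 0.3 * exp(-((t - beat - 0.12) / 0.04)^2)
    out <- out + qrs + tw
    beat <- beat + (1 / rate) * (1 + rnorm(1, 0, jitter))
  }
  out
}

#' Add environmental artifacts to a recording
#'
#' Adds (i) quasi-periodic heartbeat artifacts of the infant and the parent,
#' each a rank-1 spatial pattern times a pseudo-ECG waveform with rate
#' jitter; (ii) homogeneous ambient-field fluctuations (a rank-3 component:
#' a slowly varying field vector projected onto every channel's orientation,
#' the dominant interference of wearable magnetometer arrays and the target
#' of the principal-component projection); (iii) 1/f noise and per-channel
#' linear drift; (iv) sparse high-amplitude movement bursts. Burst windows
#' and the drawn heart rates are recorded as ground truth in
#' `meta$artifact_truth`.
#'
#' @param recording an `opm_recording`.
#' @param config an [sim_config()] object.
#' @return The recording with artifacts added.
#' @export
add_artifacts <- function(recording, config) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  nch <- nrow(recording$data)
  dur <- n / fs
  data <- recording$data
  truth <- list(burst_windows = matrix(numeric(0), ncol = 2))
  with_seed(derive_seed(config$seed %||% 1L, "artifacts"), {
    for (who in c("infant", "parent")) {
      amp <- config[[paste0(who, "_heart_amplitude")]]
      if (amp > 0) {
        rr <- config[[paste0(who, "_heart_rate")]]
        rate <- runif(1, rr[1], rr[2])
        pat <- rnorm(nch)
        pat <- pat / max(abs(pat))
        ecg <- heartbeat_trace(n, fs, rate)
        data <- data + tcrossprod(pat * amp, ecg)
        truth[[paste0(who, "_rate")]] <- rate
        truth[[paste0(who, "_pattern")]] <- pat
      }
    }
    if (config$ambient_field > 0) {
      O <- channel_orientations(recording$channels)
      b <- pink_noise_matrix(3, n, fs, 1)
      b <- b / sqrt(mean(b^2)) * config$ambient_field
      data <- data + O %*% b
    }
    if (config$pink_noise > 0)
      data <- data + pink_noise_matrix(nch, n, fs, config$pink_noise)
    if (config$drift > 0) {
      slope <- rnorm(nch, 0, config$drift)
      tt <- (seq_len(n) - 1L) / fs
      data <- data + tcrossprod(slope, tt - dur / 2)
    }
    if (config$movement_rate > 0 && config$movement_amplitude > 0) {
      nb <- rpois(1, config$movement_rate * dur)
      if (nb > 0) for (b in seq_len(nb)) {
        bdur <- runif(1, config$movement_duration[1], config$movement_duration[2])
        bstart <- runif(1, 0, max(dur - bdur, 0))
        i <- (round(bstart * fs) + 1L):min(round((bstart + bdur) * fs), n)
        m <- length(i)
        env <- sin(pi * seq(0, 1, length.out = m))^2
        # low-frequency waveform: heavily smoothed white noise, unit peak
        w <- moving_average(rnorm(m), max(3L, round(fs / 8)))
        w <- w / max(abs(w), 1e-30)
        pat <- runif(nch, 0.3, 1) * sample(c(-1, 1), nch, replace = TRUE)
        data[, i] <- data[, i] + config$movement_amplitude *
          tcrossprod(pat, w * env)
        truth$burst_windows <- rbind(truth$burst_windows,
                                     c(bstart, bstart + bdur))
      }
    }
  })
  out <- recording
  out$data <- data
  out$meta$artifact_truth <- truth
  out
}
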