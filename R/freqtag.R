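#' Oddball-locked Fourier epochs
#'
#' Cuts the recording into fixed-length epochs that each start at an oddball
#' event (preserving the stimulus-locked temporal structure across epochs),
#' skipping epochs that intersect the artifact mask, selected greedily and
#' non-overlapping from the start of the recording. Each epoch is Fourier
#' transformed per channel; with the default 20 s length the frequency grid
#' has exactly 0.05 Hz spacing, so the base (3 Hz), oddball (0.75 Hz) and
#' harmonic frequencies fall on exact bins and need no taper.
#'
#' @param recording an `opm_recording` with `oddball` events.
#' @param mask optional `opm_mask`.
#' @param length epoch length in seconds (default 20).
#' @param max_freq discard bins above this frequency (Hz, default 45) to
#'   keep the coefficient array small.
#' @return An object of class `opm_fourier`: complex `coef` array
#'   (epoch x channel x frequency, unnormalized DFT convention), `freq`,
#'   `n_epochs`, `epoch_length`, `starts`, `channels`, and the count of
#'   candidate epochs skipped.
#' @export
oddball_epochs <- function(recording, mask = NULL, length = 20, max_freq = 45) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  cand <- recording$events$time[recording$events$label == "oddball"]
  starts <- numeric(0)
  skipped <- 0L
  last_end <- -Inf
  for (t0 in cand) {
    if (t0 < last_end) next                  # overlap with a selected epoch
    if (round(t0 * fs) + round(length * fs) > n) next
    if (!is.null(mask) && nrow(mask$windows) &&
        any(mask$windows$start < t0 + length & mask$windows$end > t0)) {
      skipped <- skipped + 1L
      next
    }
    starts <- c(starts, t0)
    last_end <- t0 + length
  }
  nchs <- nrow(recording$data)
  nsamp <- round(length * fs)
  df <- 1 / length
  nf_keep <- min(nsamp %/% 2, floor(max_freq / df) + 1L)
  freq <- (seq_len(nf_keep) - 1L) * df
  coef <- array(complex(real = 0), dim = c(base::length(starts), nchs, nf_keep))
  for (e in seq_along(starts)) {
    i0 <- round(starts[e] * fs)
    X <- stats::mvfft(t(recording$data[, (i0 + 1L):(i0 + nsamp), drop = FALSE]))
    coef[e, , ] <- t(X[seq_len(nf_keep), , drop = FALSE])
  }
  if (!base::length(starts))
    warn("no artifact-free oddball epochs available")
  structure(list(coef = coef, freq = freq, n_epochs = base::length(starts),
                 epoch_length = length, starts = starts,
                 channels = recording$channels, skipped = skipped,
                 convention = "unnormalized_dft"),
            class = "opm_fourier")
}

#' Average complex Fourier coefficients across epochs
#'
#' Stimulus-locked components add coherently while noise adds incoherently,
#' so the expected noise power in the average falls as `1/n_epochs`.
#'
#' @param fourier_set an `opm_fourier`.
#' @return class `opm_avgcoef`: `coef` (channel x frequency complex matrix),
#'   `freq`, `channels`, `n_epochs`, `epoch_length`.
#' @export
average_coefficients <- function(fourier_set) {
  stopifnot(fourier_set$n_epochs > 0)
  avg <- apply(fourier_set$coef, c(2, 3), mean)
  structure(list(coef = avg, freq = fourier_set$freq,
                 channels = fourier_set$channels,
                 n_epochs = fourier_set$n_epochs,
                 epoch_length = fourier_set$epoch_length),
            class = "opm_avgcoef")
}

#' Flanking-bin SNR of a power spectrum
#'
#' The SNR of bin `f` is its power divided by the mean power over the two
#' flanking intervals `excl <= |g - f| <= extent` (default 0.1-0.4 Hz on
#' both sides; at 0.05 Hz spacing that is 7 bins per side, 14 in total).
#' Bins without complete flanks get `NA` (not extrapolated); a bin whose
#' flank power is exactly zero gets `+Inf`.
#'
#' @param power numeric matrix, rows x frequency bins.
#' @param freq frequency grid (Hz, uniform spacing).
#' @param excl inner flank exclusion (Hz).
#' @param extent outer flank extent (Hz).
#' @return matrix of the same shape as `power`.
#' @export
snr_from_power <- function(power, freq, excl = 0.1, extent = 0.4) {
  power <- as.matrix(power)
  df <- freq[2] - freq[1]
  k1 <- as.integer(round(excl / df))
  k2 <- as.integer(round(extent / df))
  stopifnot(k1 >= 1, k2 >= k1)
  offs <- c(-(k2:k1), k1:k2)
  nf <- length(freq)
  flank_sum <- matrix(0, nrow(power), nf)
  valid <- rep(TRUE, nf)
  for (o in offs) {
    j <- seq_len(nf) + o
    ok <- j >= 1L & j <= nf
    valid <- valid & ok
    jj <- pmin(pmax(j, 1L), nf)
    flank_sum <- flank_sum + power[, jj, drop = FALSE]
  }
  snr <- power / (flank_sum / length(offs))
  snr[power == 0 & flank_sum == 0] <- NaN
  snr[, !valid] <- NA_real_
  snr
}

#' Power spectrum and SNR from averaged coefficients
#'
#' @param avg_coefficients an `opm_avgcoef` ([average_coefficients()]).
#' @param excl,extent flank definition in Hz (see [snr_from_power()]).
#' @param frequencies_of_interest bins reported by [tidy()] and tested by
#'   the inference stage (default 0.75, 1.5, 3 Hz).
#' @return class `opm_snr_spectrum`: `power` and `snr` (channel x frequency
#'   matrices), `freq`, `channels`, flank definition and the frequencies of
#'   interest.
#' @export
power_and_snr <- function(avg_coefficients, excl = 0.1, extent = 0.4,
                          frequencies_of_interest = c(0.75, 1.5, 3)) {
  pw <- Mod(avg_coefficients$coef)^2
  freq <- avg_coefficients$freq
  for (f in frequencies_of_interest)
    if (f - extent < min(freq) - 1e-9 || f + extent > max(freq) + 1e-9)
      abort("frequency grid does not cover the flanks of a frequency of interest")
  snr <- snr_from_power(pw, freq, excl, extent)
  structure(list(power = pw, snr = snr, freq = freq,
                 channels = avg_coefficients$channels,
                 flank = c(excl = excl, extent = extent),
                 frequencies_of_interest = frequencies_of_interest,
                 n_epochs = avg_coefficients$n_epochs),
            class = "opm_snr_spectrum")
}

#' Tangential-norm SNR spectrum
#'
#' For each triaxial sensor, combines the SNR spectra of its two tangential
#' channels as `sqrt(snr_t1^2 + snr_t2^2)` per frequency bin. Note this is a
#' norm of SNRs, not the SNR of a normed field; under flat noise (SNR 1 on
#' each axis) its baseline is `sqrt(2)`.
#'
#' @param spectrum an `opm_snr_spectrum` containing both tangential axes.
#' @return An `opm_snr_spectrum` with one row per triaxial sensor
#'   (axis label `tangential_norm`); `power` holds the summed tangential
#'   power for reference.
#' @export
tangential_snr <- function(spectrum) {
  ch <- spectrum$channels
  t1 <- which(ch$axis == "tangential_1")
  t2 <- which(ch$axis == "tangential_2")
  s2 <- ch$sensor_id[t2]
  t1 <- t1[match(s2, ch$sensor_id[t1])]
  if (!length(t2) || anyNA(t1)) abort("no sensors with both tangential axes")
  snr <- sqrt(spectrum$snr[t1, , drop = FALSE]^2 +
                spectrum$snr[t2, , drop = FALSE]^2)
  chans <- ch[t1, ]
  chans$axis <- "tangential_norm"
  chans$channel_id <- paste0(chans$sensor_id, "_tannorm")
  out <- spectrum
  out$snr <- snr
  out$power <- spectrum$power[t1, , drop = FALSE] +
    spectrum$power[t2, , drop = FALSE]
  out$channels <- chans
  out
}

#' Group-average SNR spectra across participants
#'
#' Channels are matched to a shared template layout by optimal assignment on
#' their 2D-projected positions (see [match_channels_to_template()]); the
#' group spectrum is the arithmetic mean of the individual SNRs (not of the
#' power, which would not commute with the SNR ratio).
#'
#' @param spectra list of `opm_snr_spectrum`, one per participant.
#' @param template channel tibble used as the layout (default: channels of
#'   the first participant).
#' @return An `opm_snr_spectrum` on the template channels.
#' @export
group_average_snr <- function(spectra, template = NULL) {
  template <- template %||% spectra[[1]]$channels
  freq <- spectra[[1]]$freq
  acc_snr <- 0; acc_pow <- 0
  for (sp in spectra) {
    stopifnot(identical(sp$freq, freq))
    idx <- match_channels_to_template(template, sp$channels)
    acc_snr <- acc_snr + sp$snr[idx, , drop = FALSE]
    acc_pow <- acc_pow + sp$power[idx, , drop = FALSE]
  }
  out <- spectra[[1]]
  out$snr <- acc_snr / length(spectra)
  out$power <- acc_pow / length(spectra)
  out$channels <- template
  out$n_participants <- length(spectra)
  out
}
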