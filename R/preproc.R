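#' Artifact masks
#'
#' An artifact mask is a set of merged, non-overlapping half-open time
#' windows `[start, end)` in seconds, tied to a recording duration.
#'
#' @param windows two-column matrix / data frame of start, end times (s).
#' @param duration recording duration (s); windows are clipped to
#'   `[0, duration]`.
#' @return An object of class `opm_mask` (tibble of windows + duration).
#' @export
artifact_mask <- function(windows, duration) {
  win <- as.matrix(windows)
  if (length(win)) {
    win[, 1] <- pmax(win[, 1], 0)
    win[, 2] <- pmin(win[, 2], duration)
    win <- win[win[, 2] > win[, 1], , drop = FALSE]
  }
  structure(list(windows = windows_tbl(win), duration = duration),
            class = "opm_mask")
}

#' @export
print.opm_mask <- function(x, ...) {
  cat(sprintf("<opm_mask> %d windows, %.2f of %.2f s masked\n",
              nrow(x$windows), sum(x$windows$end - x$windows$start), x$duration))
  invisible(x)
}

#' Per-sample logical mask aligned to a recording
#' @param mask an `opm_mask`.
#' @param sampling_rate Hz.
#' @param n_samples number of samples.
#' @return logical vector, TRUE inside some window.
#' @export
mask_samples <- function(mask, sampling_rate, n_samples) {
  out <- logical(n_samples)
  t <- (seq_len(n_samples) - 1L) / sampling_rate
  for (i in seq_len(nrow(mask$windows)))
    out <- out | (t >= mask$windows$start[i] & t < mask$windows$end[i])
  out
}

#' Union of artifact masks
#' @param ... `opm_mask` objects with a common duration.
#' @export
union_masks <- function(...) {
  ms <- list(...)
  dur <- ms[[1]]$duration
  artifact_mask(do.call(rbind, lapply(ms, function(m) as.matrix(m$windows))), dur)
}

#' Extend artifact windows
#'
#' Grows each window by `pad` seconds on both sides (clipped to the
#' recording), then merges overlaps. Mirrors the practice of padding marked
#' artifact periods before epoch rejection.
#'
#' @param mask an `opm_mask`.
#' @param pad seconds (default 1.5).
#' @export
extend_windows <- function(mask, pad = 1.5) {
  w <- as.matrix(mask$windows)
  if (nrow(w)) w <- cbind(w[, 1] - pad, w[, 2] + pad)
  artifact_mask(w, mask$duration)
}

#' Replace artifact windows by linear interpolation
#'
#' Within each masked window every channel is replaced by the straight line
#' joining the last sample before and the first sample after the window, so
#' that subsequent filtering does not smear high-amplitude artifacts. A
#' window touching a recording edge is held at the nearest valid value.
#'
#' @param recording an `opm_recording`.
#' @param mask an `opm_mask`.
#' @return The interpolated recording.
#' @export
interpolate_artifacts <- function(recording, mask) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  bad <- mask_samples(mask, fs, n)
  if (!any(bad)) return(recording)
  data <- recording$data
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    pre <- i0 - 1L; post <- i1 + 1L
    if (pre < 1L && post > n) next
    if (pre < 1L) {
      data[, i0:i1] <- data[, post]
    } else if (post > n) {
      data[, i0:i1] <- data[, pre]
    } else {
      w <- (seq(i0, i1) - pre) / (post - pre)
      data[, i0:i1] <- data[, pre] %o% (1 - w) + data[, post] %o% w
    }
  }
  recording$data <- data
  recording
}

# Zero-phase FFT filtering with raised-cosine transitions and reflect
# padding. gain_fn maps frequency (Hz, >= 0) to a real gain; applied
# symmetrically so the phase response is identically zero (an impulse keeps
# its latency, which matters because latencies are headline outputs).
fft_apply_gain <- function(data, fs, gain_fn) {
  n <- ncol(data)
  pad <- min(n, as.integer(round(10 * fs)))
  idx <- c(pmin(pad:1, n), seq_len(n), pmax(n - (1:pad) + 1L, 1L))
  xe <- data[, idx, drop = FALSE]
  m <- ncol(xe)
  f <- (seq_len(m) - 1L) * fs / m
  f <- pmin(f, fs - f)
  g <- gain_fn(f)
  out <- t(Re(stats::mvfft(stats::mvfft(t(xe)) * g, inverse = TRUE))) / m
  out[, pad + seq_len(n), drop = FALSE]
}

raised_cosine_edge <- function(f, lo, hi, rising = TRUE) {
  # 0 below lo, 1 above hi (rising) with half-cosine transition
  x <- pmin(pmax((f - lo) / max(hi - lo, 1e-12), 0), 1)
  g <- 0.5 - 0.5 * cos(pi * x)
  if (rising) g else 1 - g
}

#' Zero-phase band-pass filter
#'
#' FFT-domain filter with unit passband gain, zero stopband gain and
#' raised-cosine transitions; applied with reflect padding. Being exactly
#' zero-phase, a filtered impulse keeps its input latency. Default
#' transition widths: the low edge rolls off between `low/2` and `low`, the
#' high edge between `high` and `1.1 * high`.
#'
#' @param recording an `opm_recording`.
#' @param low,high band edges in Hz, `0 < low < high < ` Nyquist.
#' @return The filtered recording.
#' @export
filter_bandpass <- function(recording, low, high) {
  fs <- recording$sampling_rate
  stopifnot(low > 0, low < high, high < fs / 2)
  gain <- function(f)
    raised_cosine_edge(f, low / 2, low, TRUE) *
    raised_cosine_edge(f, high, min(1.1 * high, fs / 2), FALSE)
  recording$data <- fft_apply_gain(recording$data, fs, gain)
  recording
}

#' Zero-phase notch of narrow spectral lines
#'
#' Removes narrow lines (mains interference, mechanical resonances) by
#' segment-wise least-squares regression: within consecutive segments the
#' sine and cosine at each line frequency are fitted per channel and
#' subtracted. This removes the coherent line completely while leaving
#' neighbouring frequencies untouched and adding no phase distortion;
#' segmenting tracks slow amplitude or phase drift of the line.
#'
#' @param recording an `opm_recording`.
#' @param freqs numeric vector of line frequencies (Hz).
#' @param segment segment length in seconds (default 10; clipped to the
#'   recording length).
#' @return The filtered recording.
#' @export
filter_notch <- function(recording, freqs, segment = 10) {
  if (!length(freqs)) return(recording)
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  seg <- min(n, max(round(segment * fs), round(4 * fs / min(freqs))))
  starts <- seq(1L, n, by = seg)
  for (s0 in starts) {
    i <- s0:min(s0 + seg - 1L, n)
    t <- (i - 1) / fs
    X <- do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))))
    beta <- qr.solve(X, t(recording$data[, i, drop = FALSE]))
    recording$data[, i] <- recording$data[, i, drop = FALSE] - t(X %*% beta)
  }
  recording
}

#' Detect narrow noise peaks in the power spectrum
#'
#' Scans the channel-median Welch power spectrum for bins that exceed a
#' running-median baseline by `factor`, within `band`. Intended to automate
#' the choice of notch frequencies for environmental noise lines in the
#' 13-40 Hz range.
#'
#' @param recording an `opm_recording`.
#' @param band frequency band searched (Hz).
#' @param factor peak-over-baseline power ratio threshold (default 10).
#' @param segment_length Welch segment length in seconds (default 4).
#' @return Numeric vector of peak frequencies (possibly empty).
#' @export
detect_noise_peaks <- function(recording, band = c(13, 40), factor = 10,
                               segment_length = 4) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  seg <- max(16L, round(segment_length * fs))
  nseg <- n %/% seg
  if (nseg < 1) { seg <- n; nseg <- 1L }
  nf <- seg %/% 2
  pow <- matrix(0, nrow(recording$data), nf)
  for (s in seq_len(nseg)) {
    X <- stats::mvfft(t(recording$data[, ((s - 1L) * seg + 1L):(s * seg), drop = FALSE]))
    pow <- pow + t(Mod(X[seq_len(nf), , drop = FALSE])^2)
  }
  med <- apply(pow / nseg, 2, median)
  freq <- (seq_len(nf) - 1L) * fs / seg
  halfw <- max(3L, round(1 / (fs / seg)))   # ~1 Hz running-median half width
  base <- vapply(seq_len(nf), function(i)
    median(med[max(1L, i - halfw):min(nf, i + halfw)]), numeric(1))
  inband <- freq >= band[1] & freq <= band[2]
  cand <- which(inband & med > factor * pmax(base, .Machine$double.xmin))
  if (!length(cand)) return(numeric(0))
  # collapse runs of adjacent bins to their strongest bin
  grp <- cumsum(c(1L, diff(cand) > 1L))
  vapply(split(cand, grp), function(i) freq[i[which.max(med[i])]], numeric(1),
         USE.NAMES = FALSE)
}

#' Robust z-score sample rejection
#'
#' Per channel, the amplitude `|x|` is smoothed with a 1 s moving-average
#' box; the robust z-score `(a - median(a)) / (1.4826 * MAD(a))` is then
#' thresholded, and samples exceeding the threshold on any channel are
#' masked. An all-constant channel (zero MAD) contributes no rejections.
#'
#' @param recording an `opm_recording`.
#' @param threshold robust z threshold (default 5).
#' @param smooth_window smoothing window in seconds (default 1).
#' @return An `opm_mask` of rejected sample windows.
#' @export
robust_zscore_reject <- function(recording, threshold = 5, smooth_window = 1) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  w <- max(1L, round(smooth_window * fs))
  bad <- logical(n)
  for (ch in seq_len(nrow(recording$data))) {
    a <- moving_average(abs(recording$data[ch, ]), w)
    s <- mad(a)                 # 1.4826 * median absolute deviation
    if (s == 0) next
    bad <- bad | ((a - median(a)) / s > threshold)
  }
  if (!any(bad)) return(artifact_mask(matrix(numeric(0), ncol = 2), n / fs))
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  win <- cbind((starts[r$values] - 1L) / fs, ends[r$values] / fs)
  artifact_mask(win, n / fs)
}

#' Project out leading principal components
#'
#' The top `n` spatial principal components are estimated from the
#' artifact-free samples only, and the orthogonal projector `I - U U'` is
#' applied to every sample. Used to suppress spatially global interference
#' (movement in a remnant field, distant sources); the output has exactly
#' zero variance along the removed components.
#'
#' @param recording an `opm_recording`.
#' @param mask optional `opm_mask`; masked samples are excluded from the fit.
#' @param n number of components to remove (default 3; 0 is the identity).
#' @return The projected recording; the projector basis is stored in
#'   `meta$pc_projector`.
#' @export
project_out_pcs <- function(recording, mask = NULL, n = 3) {
  nch <- nrow(recording$data)
  if (n == 0) return(recording)
  if (n >= nch) abort("cannot remove as many components as channels")
  keep <- rep(TRUE, ncol(recording$data))
  if (!is.null(mask))
    keep <- !mask_samples(mask, recording$sampling_rate, ncol(recording$data))
  if (sum(keep) < n) abort("not enough artifact-free samples to fit components")
  X <- recording$data[, keep, drop = FALSE]
  X <- X - rowMeans(X)
  U <- svd(X, nu = n, nv = 0)$u
  recording$data <- recording$data - U %*% (t(U) %*% recording$data)
  recording$meta$pc_projector <- U
  recording
}

# Symmetric FastICA with tanh contrast on whitened data.
# X: channels x samples (already subsetted/filtered by caller).
# Returns list(unmixing = comps x channels, mixing = channels x comps).
fast_ica <- function(X, n_comp, seed = 1L, max_iter = 100, tol = 1e-5,
                     retries = 2) {
  nch <- nrow(X)
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(cv, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10)
  n_comp <- min(n_comp, length(keep))
  K <- t(e$vectors[, keep[seq_len(n_comp)], drop = FALSE]) /
    sqrt(e$values[keep[seq_len(n_comp)]])
  Z <- K %*% Xc
  sym_orth <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% (t(s$vectors) / sqrt(s$values)) %*% W
  }
  for (try in seq_len(retries)) {
    W <- with_seed(derive_seed(seed, paste0("ica", try)),
                   matrix(rnorm(n_comp^2), n_comp))
    W <- sym_orth(W)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      G <- tanh(W %*% Z)
      Wn <- G %*% t(Z) / ncol(Z) - diag(rowMeans(1 - G^2)) %*% W
      Wn <- sym_orth(Wn)
      delta <- max(abs(1 - abs(rowSums(Wn * W))))
      W <- Wn
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  if (!converged)
    # with mostly-Gaussian data the rotation within the noise subspace never
    # settles; the non-Gaussian (artifact) directions are still recovered, so
    # proceed with the final iterate rather than fail the pipeline
    warn(sprintf("ICA did not reach tol %.0e in %d iterations; using final iterate",
                 tol, max_iter))
  unmixing <- W %*% K
  if (!all(is.finite(unmixing))) abort("ICA diverged to non-finite unmixing")
  mixing <- pinv(unmixing)
  list(unmixing = unmixing, mixing = mixing, n_comp = n_comp,
       converged = converged, iterations = it)
}

# Welch power spectrum of a single time series on a fixed-resolution grid
# (segments of `seg_dur` seconds, averaged periodograms), for component
# screening with the flanking-bin SNR statistic.
segment_power_spectrum <- function(x, fs, seg_dur = 20) {
  seg <- round(seg_dur * fs)
  nseg <- length(x) %/% seg
  if (nseg < 1)
    abort(sprintf("need at least %g s of data for the component spectrum", seg_dur))
  nf <- seg %/% 2
  pow <- numeric(nf)
  for (s in seq_len(nseg)) {
    X <- fft(x[((s - 1L) * seg + 1L):(s * seg)])
    pow <- pow + Mod(X[seq_len(nf)])^2
  }
  list(power = pow / nseg, freq = (seq_len(nf) - 1L) * fs / seg)
}

#' Remove heartbeat components by ICA
#'
#' A linear unmixing (symmetric FastICA, tanh non-Gaussianity contrast) is
#' fitted on the artifact-free portion of the recording, band-pass filtered
#' 1-40 Hz. A component is flagged as cardiac if the maximum of its
#' power-spectrum SNR (flanking-bin definition, 0.05 Hz grid) within any of
#' the supplied heart-rate ranges exceeds `snr_threshold`; flagged
#' components' contributions are subtracted from the full, unfiltered
#' recording.
#'
#' @param recording an `opm_recording`.
#' @param mask optional `opm_mask` of artifact windows excluded from the fit.
#' @param heart_ranges list of `(lo, hi)` Hz ranges (infant and parent).
#' @param snr_threshold flag threshold on the component spectrum SNR
#'   (default 7.5).
#' @param n_comp number of components (default `min(channels, 40)`).
#' @param seed RNG seed for the ICA initialisation.
#' @param exclude_freqs frequencies (Hz) whose spectral bins must not count
#'   as heartbeat evidence — typically the stimulation-locked frequencies of
#'   a frequency-tagging paradigm, whose harmonics can fall inside a
#'   heart-rate range.
#' @param exclude_halfwidth half-width (Hz) of each exclusion (default 0.1).
#' @return list with `recording` (cleaned) and `decomposition`, a
#'   `opm_ica` object carrying `mixing`, `unmixing`, `sources` (fit data),
#'   `removed` (tibble of flagged components with reasons) and the per-
#'   component spectra.
#' @export
remove_heartbeat_components <- function(recording, mask = NULL,
                                        heart_ranges = list(c(1.0, 1.5), c(2.2, 2.5)),
                                        snr_threshold = 7.5,
                                        n_comp = NULL, seed = 1L,
                                        exclude_freqs = numeric(0),
                                        exclude_halfwidth = 0.1) {
  fs <- recording$sampling_rate
  nch <- nrow(recording$data)
  n_comp <- n_comp %||% min(nch, 40L)
  filt <- filter_bandpass(recording, 1, min(40, fs / 2.2 - 1e-9))
  keep <- rep(TRUE, ncol(filt$data))
  if (!is.null(mask)) keep <- !mask_samples(mask, fs, ncol(filt$data))
  Xfit <- filt$data[, keep, drop = FALSE]
  # the unmixing is estimated on a decimated copy (sufficient statistics for
  # the contrast converge fast); spectra are screened on the full sources
  stride <- max(1L, ncol(Xfit) %/% 12000L)
  ica <- fast_ica(Xfit[, seq(1L, ncol(Xfit), by = stride), drop = FALSE],
                  n_comp, seed = seed)
  S_fit <- ica$unmixing %*% Xfit
  flagged <- integer(0)
  info <- list()
  for (k in seq_len(nrow(S_fit))) {
    ps <- segment_power_spectrum(S_fit[k, ], fs)
    snr <- snr_from_power(matrix(ps$power, 1), ps$freq)[1, ]
    excl <- rep(FALSE, length(ps$freq))
    for (f0 in exclude_freqs)
      excl <- excl | abs(ps$freq - f0) <= exclude_halfwidth
    peak <- NA_real_; best <- -Inf
    for (rg in heart_ranges) {
      i <- which(ps$freq >= rg[1] & ps$freq <= rg[2] & is.finite(snr) & !excl)
      if (length(i)) {
        m <- i[which.max(snr[i])]
        if (snr[m] > best) { best <- snr[m]; peak <- ps$freq[m] }
      }
    }
    hit <- is.finite(best) && best > snr_threshold
    if (hit) flagged <- c(flagged, k)
    info[[k]] <- tibble(component = k, max_heart_snr = ifelse(is.finite(best), best, NA_real_),
                        peak_freq = peak, removed = hit)
  }
  cleaned <- recording
  if (length(flagged)) {
    S_full <- ica$unmixing[flagged, , drop = FALSE] %*% recording$data
    cleaned$data <- recording$data -
      ica$mixing[, flagged, drop = FALSE] %*% S_full
  }
  removed <- dplyr::bind_rows(info)
  removed$reason <- ifelse(removed$removed,
                           sprintf("heart-range SNR %.2f > %.2f at %.2f Hz",
                                   removed$max_heart_snr, snr_threshold,
                                   removed$peak_freq), NA_character_)
  dec <- structure(list(mixing = ica$mixing, unmixing = ica$unmixing,
                        sources = S_fit, sampling_rate = fs,
                        removed_components = flagged,
                        screening = removed, method = "fastica-tanh"),
                   class = "opm_ica")
  list(recording = cleaned, decomposition = dec)
}

#' Heart-rate ranges from flagged cardiac components
#'
#' For each component flagged during heartbeat removal, returns the
#' frequency of its dominant spectral peak in the physiological band
#' (0.8-3.5 Hz) plus/minus `half_width`.
#'
#' @param decomposition an `opm_ica` from [remove_heartbeat_components()].
#' @param half_width half-width of the returned range (Hz, default 0.15).
#' @param search band searched for the dominant peak (Hz).
#' @return list of `c(lo, hi)` ranges (possibly empty).
#' @export
estimate_heart_rate_ranges <- function(decomposition, half_width = 0.15,
                                       search = c(0.8, 3.5)) {
  out <- list()
  for (k in decomposition$removed_components) {
    ps <- segment_power_spectrum(decomposition$sources[k, ],
                                 decomposition$sampling_rate)
    i <- which(ps$freq >= search[1] & ps$freq <= search[2])
    f0 <- ps$freq[i[which.max(ps$power[i])]]
    out[[length(out) + 1L]] <- c(f0 - half_width, f0 + half_width)
  }
  out
}
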