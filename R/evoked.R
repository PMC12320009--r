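#' Epoch a recording around stimulus events
#'
#' One epoch per event whose window lies fully inside the recording; epochs
#' overlapping the (extended) artifact mask are rejected, with counts kept.
#'
#' @param recording an `opm_recording`.
#' @param mask optional `opm_mask`.
#' @param window epoch window relative to the event, seconds
#'   (default `c(-0.070, 0.500)`).
#' @param baseline baseline interval, seconds (default `c(-0.070, 0)`);
#'   must lie inside the window.
#' @param event_label restrict to events with this label (default: all).
#' @return class `opm_epochs`: `epochs` array (trial x channel x time),
#'   `times` (s, relative to event), `channels`, `baseline`, and kept /
#'   rejected bookkeeping.
#' @export
make_epochs <- function(recording, mask = NULL, window = c(-0.070, 0.500),
                        baseline = c(-0.070, 0), event_label = NULL) {
  stopifnot(baseline[1] >= window[1], baseline[2] <= window[2])
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  ev <- recording$events
  if (!is.null(event_label)) ev <- ev[ev$label %in% event_label, ]
  i_rel <- round(window[1] * fs):round(window[2] * fs)
  times <- i_rel / fs
  kept <- logical(nrow(ev))
  rejected_artifact <- 0L
  epochs <- list()
  for (e in seq_len(nrow(ev))) {
    i0 <- round(ev$time[e] * fs)
    idx <- i0 + i_rel + 1L
    if (idx[1] < 1L || idx[length(idx)] > n) next
    t0 <- ev$time[e] + window[1]; t1 <- ev$time[e] + window[2]
    if (!is.null(mask) && nrow(mask$windows) &&
        any(mask$windows$start < t1 & mask$windows$end > t0)) {
      rejected_artifact <- rejected_artifact + 1L
      next
    }
    kept[e] <- TRUE
    epochs[[length(epochs) + 1L]] <- recording$data[, idx, drop = FALSE]
  }
  arr <- array(0, dim = c(length(epochs), nrow(recording$data), length(times)))
  for (e in seq_along(epochs)) arr[e, , ] <- epochs[[e]]
  if (!length(epochs)) warn("no epochs survived artifact rejection")
  structure(list(epochs = arr, times = times, channels = recording$channels,
                 window = window, baseline = baseline,
                 n_kept = length(epochs), n_rejected = rejected_artifact,
                 event_times = ev$time[kept]),
            class = "opm_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the prestimulus baseline.
#'
#' @param epochs an `opm_epochs`.
#' @export
baseline_correct <- function(epochs) {
  b <- epochs$times >= epochs$baseline[1] & epochs$times < epochs$baseline[2]
  stopifnot(any(b))
  bl <- apply(epochs$epochs[, , b, drop = FALSE], c(1, 2), mean)
  epochs$epochs <- epochs$epochs - as.vector(bl)   # recycles over time (3rd dim)
  epochs
}

#' Average epochs into an evoked response
#'
#' @param epochs an `opm_epochs`.
#' @return class `opm_evoked`: `mean` (channel x time, tesla), `times`,
#'   `channels`, `n_epochs`, `axis_mode`.
#' @export
average_epochs <- function(epochs) {
  stopifnot(epochs$n_kept > 0)
  m <- apply(epochs$epochs, c(2, 3), mean)
  structure(list(mean = m, times = epochs$times, channels = epochs$channels,
                 baseline = epochs$baseline, n_epochs = epochs$n_kept,
                 axis_mode = "field"),
            class = "opm_evoked")
}

# 2D azimuthal-equidistant projection of channel positions (for layout
# matching): radius = polar angle from +z, direction = azimuth.
project_layout_2d <- function(channels) {
  p <- channel_positions(channels)
  r <- sqrt(rowSums(p^2))
  theta <- acos(pmin(1, pmax(-1, p[, 3] / pmax(r, 1e-12))))
  phi <- atan2(p[, 2], p[, 1])
  cbind(theta * cos(phi), theta * sin(phi))
}

#' Match channels to a template layout
#'
#' Bijective nearest-position matching of a participant's channels onto a
#' shared 2D template layout (azimuthal equidistant projection), solved as an
#' optimal assignment per axis label so radial channels can only match radial
#' template slots, and so on.
#'
#' @param template template channel tibble.
#' @param channels participant channel tibble (same per-axis counts).
#' @return integer vector `idx` such that `channels[idx[i], ]` corresponds to
#'   `template[i, ]`.
#' @export
match_channels_to_template <- function(template, channels) {
  pt <- project_layout_2d(template)
  pc <- project_layout_2d(channels)
  idx <- integer(nrow(template))
  for (ax in unique(template$axis)) {
    ti <- which(template$axis == ax)
    ci <- which(channels$axis == ax)
    if (length(ci) != length(ti))
      abort(sprintf("axis '%s': %d channels cannot be matched bijectively to %d template slots",
                    ax, length(ci), length(ti)))
    cost <- outer(seq_along(ti), seq_along(ci),
                  Vectorize(function(i, j) sum((pt[ti[i], ] - pc[ci[j], ])^2)))
    idx[ti] <- ci[solve_assignment(cost)]
  }
  idx
}

#' Group-average evoked responses
#'
#' Arithmetic mean across participants after matching each participant's
#' channels to a shared template layout.
#'
#' @param evoked_list list of `opm_evoked`, one per participant.
#' @param template channel tibble (default: first participant's channels).
#' @return An `opm_evoked` on the template channels.
#' @export
group_average <- function(evoked_list, template = NULL) {
  template <- template %||% evoked_list[[1]]$channels
  times <- evoked_list[[1]]$times
  acc <- 0
  for (ev in evoked_list) {
    stopifnot(identical(ev$times, times))
    idx <- match_channels_to_template(template, ev$channels)
    acc <- acc + ev$mean[idx, , drop = FALSE]
  }
  out <- evoked_list[[1]]
  out$mean <- acc / length(evoked_list)
  out$channels <- template
  out$n_participants <- length(evoked_list)
  out
}

#' Tangential-norm response
#'
#' For each triaxial sensor and time point, `sqrt(t1^2 + t2^2)` over the two
#' tangential channels — invariant under rotation of the tangential frame.
#' Computed on the individual evoked response before group averaging.
#'
#' @param x an `opm_evoked` or `opm_epochs` containing both tangential axes.
#' @return The same type, with one `tangential_norm` channel per triaxial
#'   sensor; all values are non-negative.
#' @export
tangential_norm <- function(x) {
  ch <- x$channels
  t1 <- which(ch$axis == "tangential_1")
  t2 <- which(ch$axis == "tangential_2")
  s2 <- ch$sensor_id[t2]
  t1 <- t1[match(s2, ch$sensor_id[t1])]
  if (!length(t2) || anyNA(t1)) abort("no sensors with both tangential axes")
  chans <- ch[t1, ]
  chans$axis <- "tangential_norm"
  chans$channel_id <- paste0(chans$sensor_id, "_tannorm")
  if (inherits(x, "opm_evoked")) {
    x$mean <- sqrt(x$mean[t1, , drop = FALSE]^2 + x$mean[t2, , drop = FALSE]^2)
    x$axis_mode <- "tangential_norm"
  } else if (inherits(x, "opm_epochs")) {
    x$epochs <- sqrt(x$epochs[, t1, , drop = FALSE]^2 +
                       x$epochs[, t2, , drop = FALSE]^2)
  } else abort("tangential_norm expects opm_evoked or opm_epochs")
  x$channels <- chans
  x
}

#' Evoked-response metrics: latency, amplitude, SNR
#'
#' The across-channel root-mean-square time course peaks at the response
#' latency (search restricted to poststimulus times). The response amplitude
#' is the largest absolute channel value at the time `t*` where the score of
#' the first spatial principal component of the evoked matrix peaks (set
#' `pc_method = "rms"` to use the RMS peak instead), and the SNR is that
#' amplitude divided by the baseline standard deviation of the same channel.
#'
#' @param evoked an `opm_evoked`.
#' @param pc_method `"spatial_pc"` (default) or `"rms"`: how `t*` is defined.
#' @return One-row tibble: `latency_s`, `t_star_s`, `amplitude`, `channel`,
#'   `snr`, `n_epochs`, `axis_mode`. All-zero input yields an explicit
#'   all-`NA` row.
#' @export
evoked_metrics <- function(evoked, pc_method = c("spatial_pc", "rms")) {
  pc_method <- match.arg(pc_method)
  M <- evoked$mean
  if (all(M == 0))
    return(tibble(latency_s = NA_real_, t_star_s = NA_real_,
                  amplitude = NA_real_, channel = NA_character_,
                  snr = NA_real_, n_epochs = evoked$n_epochs %||% NA_integer_,
                  axis_mode = evoked$axis_mode))
  post <- evoked$times > 0
  rms <- sqrt(colMeans(M^2))
  latency <- evoked$times[post][which.max(rms[post])]
  if (pc_method == "spatial_pc") {
    u1 <- svd(M, nu = 1, nv = 0)$u[, 1]
    score <- as.vector(crossprod(u1, M))
    t_star <- evoked$times[post][which.max(abs(score[post]))]
  } else t_star <- latency
  j <- which.min(abs(evoked$times - t_star))
  ch_i <- which.max(abs(M[, j]))
  amplitude <- abs(M[ch_i, j])
  b <- evoked$times >= evoked$baseline[1] & evoked$times < evoked$baseline[2]
  bsd <- sd(M[ch_i, b])
  tibble(latency_s = latency, t_star_s = t_star, amplitude = amplitude,
         channel = evoked$channels$channel_id[ch_i],
         snr = if (bsd > 0) amplitude / bsd else NA_real_,
         n_epochs = evoked$n_epochs %||% NA_integer_,
         axis_mode = evoked$axis_mode)
}
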