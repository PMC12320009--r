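#' Construct a multichannel magnetometer recording
#'
#' The recording is the single currency passed between pipeline stages:
#' a channels-by-samples matrix in tesla plus channel geometry, stimulus
#' events, artifact-window annotations and free-form provenance metadata.
#'
#' @param data numeric matrix, channels x samples, tesla.
#' @param channels channel tibble as returned by [make_sensor_array()].
#' @param sampling_rate sampling frequency in Hz.
#' @param events tibble with columns `time` (s) and `label`
#'   (`"tone"`, `"base"` or `"oddball"`), sorted ascending.
#' @param artifact_windows tibble with `start`, `end` columns, seconds,
#'   half-open intervals `[start, end)` inside the recording.
#' @param meta named list of provenance (seed, generator parameters,
#'   ground truth for synthetic data).
#' @return An object of class `opm_recording`.
#' @export
new_recording <- function(data, channels, sampling_rate,
                          events = tibble(time = numeric(0), label = character(0)),
                          artifact_windows = tibble(start = numeric(0), end = numeric(0)),
                          meta = list()) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == nrow(channels), sampling_rate > 0)
  if (!all(is.finite(data))) abort("recording data contains non-finite values")
  dur <- ncol(data) / sampling_rate
  if (nrow(events)) {
    events <- events[order(events$time), ]
    stopifnot(all(events$time >= 0), all(events$time <= dur))
  }
  if (nrow(artifact_windows)) {
    stopifnot(all(artifact_windows$start >= 0), all(artifact_windows$end <= dur),
              all(artifact_windows$start <= artifact_windows$end))
  }
  structure(list(data = data, channels = channels, sampling_rate = sampling_rate,
                 events = as_tibble(events),
                 artifact_windows = as_tibble(artifact_windows), meta = meta),
            class = "opm_recording")
}

#' @export
print.opm_recording <- function(x, ...) {
  cat(sprintf("<opm_recording> %d channels x %d samples (%.1f s @ %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), rec_duration(x), x$sampling_rate,
              nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `opm_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

rec_times <- function(rec) (seq_len(ncol(rec$data)) - 1L) / rec$sampling_rate

#' Write / read a recording container
#'
#' The container is a pair of files: `<path>.dat` holding the raw data matrix
#' as little-endian float64 (channel-major), and `<path>.json` holding the
#' sampling rate, channel table, events, artifact windows and metadata.
#'
#' @param rec an `opm_recording`.
#' @param path file path without extension.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `opm_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  side <- list(format = "opmpipe-recording-v1",
               sampling_rate = rec$sampling_rate,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               channels = as.data.frame(rec$channels),
               head_radius = attr(rec$channels, "head_radius"),
               standoff = attr(rec$channels, "standoff"),
               events = as.data.frame(rec$events),
               artifact_windows = as.data.frame(rec$artifact_windows),
               meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = side$n_channels * side$n_samples,
               size = 8, endian = "little")
  channels <- as_tibble(side$channels)
  attr(channels, "head_radius") <- side$head_radius
  attr(channels, "standoff") <- side$standoff
  ev <- if (length(side$events)) as_tibble(side$events) else
    tibble(time = numeric(0), label = character(0))
  aw <- if (length(side$artifact_windows)) as_tibble(side$artifact_windows) else
    tibble(start = numeric(0), end = numeric(0))
  new_recording(matrix(v, nrow = side$n_channels), channels, side$sampling_rate,
                events = ev, artifact_windows = aw,
                meta = if (is.null(side$meta)) list() else side$meta)
}
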