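#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evoked response into a long tibble
#'
#' @param x an `opm_evoked`.
#' @param ... unused.
#' @return tibble with `channel`, `sensor`, `axis`, `time_s`, `value`.
#' @method tidy opm_evoked
#' @export
tidy.opm_evoked <- function(x, ...) {
  tibble(channel = rep(x$channels$channel_id, times = length(x$times)),
         sensor = rep(x$channels$sensor_id, times = length(x$times)),
         axis = rep(x$channels$axis, times = length(x$times)),
         time_s = rep(x$times, each = nrow(x$mean)),
         value = as.vector(x$mean))
}

#' Tidy an SNR spectrum into a long tibble
#'
#' @param x an `opm_snr_spectrum`.
#' @param ... unused.
#' @return tibble with `channel`, `sensor`, `axis`, `freq_hz`, `power`, `snr`.
#' @method tidy opm_snr_spectrum
#' @export
tidy.opm_snr_spectrum <- function(x, ...) {
  tibble(channel = rep(x$channels$channel_id, times = length(x$freq)),
         sensor = rep(x$channels$sensor_id, times = length(x$freq)),
         axis = rep(x$channels$axis, times = length(x$freq)),
         freq_hz = rep(x$freq, each = nrow(x$snr)),
         power = as.vector(x$power),
         snr = as.vector(x$snr))
}

#' Tidy a step-down maximum-statistics result
#'
#' @param x an `opm_maxstat`.
#' @param ... unused.
#' @return tibble with one row per tested element: `channel`, `element`
#'   (time or frequency), `observed`, `p_value`, `significant`.
#' @method tidy opm_maxstat
#' @export
tidy.opm_maxstat <- function(x, ...) {
  dn <- dimnames(x$observed)
  tibble(channel = rep(dn[[1]], times = ncol(x$observed)),
         element = rep(dn[[2]], each = nrow(x$observed)),
         observed = as.vector(x$observed),
         p_value = as.vector(x$p_values),
         significant = as.vector(x$significant))
}

#' One-row summary of a step-down maximum-statistics result
#'
#' @param x an `opm_maxstat`.
#' @param ... unused.
#' @method glance opm_maxstat
#' @export
glance.opm_maxstat <- function(x, ...) {
  tibble(n_elements = length(x$observed),
         n_significant = sum(x$significant),
         min_p = min(x$p_values, na.rm = TRUE),
         iterations = x$iterations,
         n_surrogates = x$n_surrogates,
         alpha = x$alpha,
         kind = x$kind)
}

#' Tidy a source estimate into an (x, y, z, value) tibble
#'
#' @param x an `opm_source_estimate`.
#' @param ... unused.
#' @method tidy opm_source_estimate
#' @export
tidy.opm_source_estimate <- function(x, ...) as_tibble(x$sources)

#' Butterfly plot of an evoked response
#'
#' One trace per channel against peristimulus time, with the across-channel
#' RMS overlaid.
#'
#' @param object an `opm_evoked`.
#' @param ... unused.
#' @method autoplot opm_evoked
#' @export
autoplot.opm_evoked <- function(object, ...) {
  d <- tidy(object)
  rms <- tibble(time_s = object$times,
                value = sqrt(colMeans(object$mean^2)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value,
                                  group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_line(data = rms, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "field (T)",
                  title = sprintf("Evoked response (%s)", object$axis_mode))
}

#' Plot SNR spectra per channel
#'
#' @param object an `opm_snr_spectrum`.
#' @param fmax upper frequency limit of the display (Hz).
#' @param ... unused.
#' @method autoplot opm_snr_spectrum
#' @export
autoplot.opm_snr_spectrum <- function(object, fmax = 4, ...) {
  d <- tidy(object)
  d <- d[d$freq_hz <= fmax & !is.na(d$snr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_hz, y = .data$snr,
                                  group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$frequencies_of_interest,
                        linetype = 3, colour = "blue") +
    ggplot2::labs(x = "frequency (Hz)", y = "power-spectrum SNR")
}

#' @importFrom rlang .data
NULL
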