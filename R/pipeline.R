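#' Pipeline configuration
#'
#' One configuration object drives simulation, preprocessing, analysis,
#' inference and source localization. Defaults mirror a newborn OPM-MEG
#' study session: 13 participants, ~27-sensor arrays (20 triaxial), 5-minute
#' recordings at 1200 Hz, 10000 surrogates at alpha 0.05. Tests and examples
#' typically scale `duration`, `n_participants` and `n_surrogates` down.
#'
#' @param ... overrides; `sim` takes a list of [sim_config()] overrides.
#' @return list of class `opm_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_participants = 13L,
    n_sensors = 27L,
    triaxial_count = 20L,
    head_radius = 0.065,
    sim = list(),
    evoked_band = c(1, 40),
    oddball_band = c(0.2, 40),
    notch_band = c(13, 40),
    notch_factor = 10,
    z_threshold = 5,
    mask_pad = 1.5,
    n_pcs = 3L,
    do_ica = TRUE,
    heart_ranges = list(c(1.0, 1.5), c(2.2, 2.5)),
    heart_snr_threshold = 7.5,
    epoch_window = c(-0.070, 0.500),
    epoch_baseline = c(-0.070, 0),
    oddball_epoch_length = 20,
    frequencies_of_interest = c(0.75, 1.5, 3),
    pool_frequencies = FALSE,
    n_surrogates = 10000L,
    alpha = 0.05,
    grid_spacing = 0.0075,
    lambda2 = 1 / 9,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown pipeline_config fields:",
                               paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "opm_pipeline_config")
}

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

new_manifest <- function(config) {
  list(config = unclass(config), seed = config$seed,
       package = "opmpipe", version = as.character(utils::packageVersion("opmpipe")),
       stages = tibble(stage = character(0), seconds = numeric(0),
                       hash = character(0)))
}

log_stage <- function(manifest, stage, t0, value) {
  manifest$stages <- dplyr::bind_rows(
    manifest$stages,
    tibble(stage = stage, seconds = as.numeric(proc.time()[3] - t0),
           hash = obj_hash(value)))
  manifest
}

simulate_participants <- function(config, paradigm) {
  gen <- if (paradigm == "evoked") generate_evoked_recording else
    generate_oddball_recording
  lapply(seq_len(config$n_participants), function(p) {
    ps <- derive_seed(config$seed, paste0(paradigm, "-participant-", p))
    array <- make_sensor_array(config$n_sensors, config$head_radius,
                               config$triaxial_count, seed = ps)
    sc <- do.call(sim_config, c(config$sim, list(seed = ps)))
    add_artifacts(gen(sc, array), sc)
  })
}

#' Preprocess one recording
#'
#' The chain: robust z-score artifact detection (unioned with any annotated
#' windows), ICA heartbeat removal fitted on the artifact-free data, linear
#' interpolation of artifact windows, zero-phase band-pass, automatic notch
#' of detected noise lines, artifact-window extension plus a second robust
#' z-score pass on the filtered data, and projection of the leading
#' principal components.
#'
#' @param recording an `opm_recording`.
#' @param band band-pass edges (Hz).
#' @param config an [pipeline_config()].
#' @param second_heart_pass re-screen components within heart-rate ranges
#'   estimated from the first pass (used in the oddball path where the
#'   low-frequency band retains heartbeat energy).
#' @param seed seed for the ICA.
#' @return list: `recording` (cleaned), `mask` (`opm_mask`),
#'   `decomposition`, `heart_ranges_estimated`, `notch_freqs`, `log`.
#' @export
preprocess_recording <- function(recording, band, config = pipeline_config(),
                                 second_heart_pass = FALSE, seed = 1L,
                                 stim_freqs = numeric(0)) {
  # initial movement-artifact detection runs on a band-limited copy so that
  # slow ambient-field excursions (huge in raw wearable-magnetometer data)
  # do not swamp the amplitude statistic
  mask0 <- robust_zscore_reject(filter_bandpass(recording, 1,
                                                min(40, recording$sampling_rate / 2.2)),
                                config$z_threshold)
  if (nrow(recording$artifact_windows))
    mask0 <- union_masks(mask0, artifact_mask(recording$artifact_windows,
                                              rec_duration(recording)))
  dec <- NULL; est_ranges <- list()
  rec <- recording
  if (config$do_ica) {
    hb <- remove_heartbeat_components(rec, mask0,
                                      heart_ranges = config$heart_ranges,
                                      snr_threshold = config$heart_snr_threshold,
                                      seed = derive_seed(seed, "ica1"),
                                      exclude_freqs = stim_freqs)
    rec <- hb$recording
    dec <- hb$decomposition
    est_ranges <- estimate_heart_rate_ranges(dec)
    if (second_heart_pass && length(est_ranges)) {
      hb2 <- remove_heartbeat_components(rec, mask0,
                                         heart_ranges = est_ranges,
                                         snr_threshold = config$heart_snr_threshold,
                                         seed = derive_seed(seed, "ica2"),
                                         exclude_freqs = stim_freqs)
      rec <- hb2$recording
    }
  }
  rec <- interpolate_artifacts(rec, mask0)
  rec <- filter_bandpass(rec, band[1], band[2])
  notch_freqs <- detect_noise_peaks(rec, config$notch_band, config$notch_factor)
  if (length(notch_freqs)) rec <- filter_notch(rec, notch_freqs)
  mask1 <- union_masks(extend_windows(mask0, config$mask_pad),
                       extend_windows(robust_zscore_reject(rec, config$z_threshold),
                                      config$mask_pad))
  rec <- project_out_pcs(rec, mask1, config$n_pcs)
  list(recording = rec, mask = mask1, decomposition = dec,
       heart_ranges_estimated = est_ranges, notch_freqs = notch_freqs,
       log = tibble(
         stage = c("mask", "notch"),
         detail = c(sprintf("%d artifact windows, %.1f s masked",
                            nrow(mask1$windows),
                            sum(mask1$windows$end - mask1$windows$start)),
                    paste(round(notch_freqs, 2), collapse = ","))))
}

pick_axis <- function(obj, axes) {
  i <- which(obj$channels$axis %in% axes)
  if (inherits(obj, "opm_evoked")) obj$mean <- obj$mean[i, , drop = FALSE]
  else if (inherits(obj, "opm_fourier")) obj$coef <- obj$coef[, i, , drop = FALSE]
  else if (inherits(obj, "opm_snr_spectrum")) {
    obj$snr <- obj$snr[i, , drop = FALSE]
    obj$power <- obj$power[i, , drop = FALSE]
  } else abort("unsupported object for pick_axis")
  obj$channels <- obj$channels[i, ]
  obj
}

#' Run the evoked-response pipeline end to end
#'
#' Simulates (or takes) one recording per participant, preprocesses each,
#' epochs around tone onsets, builds individual and group evoked responses
#' (radial axes, plus the tangential norm where triaxial sensors exist),
#' tests the group response with sign-flip step-down maximum statistics, and
#' localizes the group peak with the noise-normalized minimum-norm inverse.
#'
#' @param config an [pipeline_config()].
#' @param recordings optional list of `opm_recording` (one per participant);
#'   simulated from `config` when omitted.
#' @return class `opm_report`: per-participant `metrics` tibble,
#'   `group_evoked`, `group_metrics`, `maxstat`, `sources`, `hemispheres`,
#'   `manifest`.
#' @export
run_evoked_pipeline <- function(config = pipeline_config(), recordings = NULL) {
  manifest <- new_manifest(config)
  t0 <- proc.time()[3]
  recordings <- recordings %||% simulate_participants(config, "evoked")
  manifest <- log_stage(manifest, "simulate", t0, lapply(recordings, `[[`, "data"))
  evokeds_rad <- list(); evokeds_tan <- list(); metrics <- list()
  for (p in seq_along(recordings)) {
    pp <- preprocess_recording(recordings[[p]], config$evoked_band, config,
                               seed = derive_seed(config$seed, paste0("pre", p)))
    ep <- make_epochs(pp$recording, pp$mask, config$epoch_window,
                      config$epoch_baseline, event_label = "tone")
    ep <- baseline_correct(ep)
    ev <- average_epochs(ep)
    ev_rad <- pick_axis(ev, "radial")
    evokeds_rad[[p]] <- ev_rad
    m <- evoked_metrics(ev_rad)
    m$participant <- p; m$axis_mode <- "radial"
    metrics[[length(metrics) + 1L]] <- m
    if (sum(ev$channels$axis == "tangential_2") > 0) {
      ev_tan <- tangential_norm(ev)
      evokeds_tan[[length(evokeds_tan) + 1L]] <- ev_tan
      mt <- evoked_metrics(ev_tan)
      mt$participant <- p; mt$axis_mode <- "tangential_norm"
      metrics[[length(metrics) + 1L]] <- mt
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  manifest <- log_stage(manifest, "evoked", t0, metrics)
  group <- group_average(evokeds_rad)
  group_metrics <- evoked_metrics(group)
  stream <- signflip_surrogates(evokeds_rad, config$n_surrogates,
                                seed = derive_seed(config$seed, "signflip"))
  ms <- stepdown_maxstat(stream, config$alpha)
  manifest <- log_stage(manifest, "stats", t0, ms$p_values)
  grid <- make_source_grid(config$head_radius, config$grid_spacing)
  fwd <- sphere_lead_field(group$channels, grid)
  j <- which.min(abs(group$times - group_metrics$latency_s))
  src <- minimum_norm_inverse(fwd, group$mean[, j], lambda2 = config$lambda2)
  hemi <- hemispheric_sources(src)
  manifest <- log_stage(manifest, "sources", t0, src$sources$value)
  structure(list(kind = "evoked", metrics = metrics, group_evoked = group,
                 group_tangential = if (length(evokeds_tan))
                   group_average(evokeds_tan) else NULL,
                 group_metrics = group_metrics, maxstat = ms, sources = src,
                 hemispheres = hemi, manifest = manifest, config = config),
            class = "opm_report")
}

#' Run the oddball frequency-tagging pipeline end to end
#'
#' Preprocessing uses the wide 0.2-40 Hz band (to keep the oddball frequency)
#' and a second ICA screening pass within heart-rate ranges estimated from
#' the first. Oddball-locked 20 s epochs are Fourier transformed; power and
#' flanking-bin SNR are computed per participant and group-averaged; the SNR
#' at the frequencies of interest is tested with phase-randomization
#' step-down maximum statistics; source spectra are reconstructed per
#' participant and group-averaged.
#'
#' @inheritParams run_evoked_pipeline
#' @return class `opm_report` with `snr_foi` (per-participant peak SNR at
#'   each frequency of interest), `group_snr`, `maxstat`, `source_spectrum`,
#'   `hemispheres`, `manifest`.
#' @export
run_oddball_pipeline <- function(config = pipeline_config(), recordings = NULL) {
  manifest <- new_manifest(config)
  t0 <- proc.time()[3]
  recordings <- recordings %||% simulate_participants(config, "oddball")
  manifest <- log_stage(manifest, "simulate", t0, lapply(recordings, `[[`, "data"))
  fsets_rad <- list(); spectra_rad <- list(); spectra_tan <- list()
  avgcoefs_rad <- list(); snr_foi <- list()
  for (p in seq_along(recordings)) {
    fo <- min(config$frequencies_of_interest)
    pp <- preprocess_recording(recordings[[p]], config$oddball_band, config,
                               second_heart_pass = TRUE,
                               seed = derive_seed(config$seed, paste0("pre", p)),
                               stim_freqs = seq(fo, 3.5, by = fo))
    fe <- oddball_epochs(pp$recording, pp$mask, config$oddball_epoch_length)
    fe_rad <- pick_axis(fe, "radial")
    fsets_rad[[p]] <- fe_rad
    ac <- average_coefficients(fe_rad)
    avgcoefs_rad[[p]] <- ac
    sp <- power_and_snr(ac, frequencies_of_interest = config$frequencies_of_interest)
    spectra_rad[[p]] <- sp
    for (f in config$frequencies_of_interest) {
      b <- which.min(abs(sp$freq - f))
      snr_foi[[length(snr_foi) + 1L]] <-
        tibble(participant = p, axis_mode = "radial", freq_hz = f,
               snr = max(sp$snr[, b], na.rm = TRUE))
    }
    if (sum(fe$channels$axis == "tangential_2") > 0) {
      ac_all <- average_coefficients(fe)
      sp_all <- power_and_snr(ac_all,
                              frequencies_of_interest = config$frequencies_of_interest)
      spt <- tangential_snr(sp_all)
      spectra_tan[[length(spectra_tan) + 1L]] <- spt
      for (f in config$frequencies_of_interest) {
        b <- which.min(abs(spt$freq - f))
        snr_foi[[length(snr_foi) + 1L]] <-
          tibble(participant = p, axis_mode = "tangential_norm", freq_hz = f,
                 snr = max(spt$snr[, b], na.rm = TRUE))
      }
    }
  }
  snr_foi <- dplyr::bind_rows(snr_foi)
  group_snr <- group_average_snr(spectra_rad)
  manifest <- log_stage(manifest, "freqtag", t0, group_snr$snr)
  # each tagged frequency is tested as its own family (the strong base-rate
  # line would otherwise dominate the surrogate maxima of the weaker oddball
  # bins); pooling across frequencies is available as a config switch
  if (config$pool_frequencies) {
    stream <- phase_surrogates(fsets_rad, config$n_surrogates,
                               seed = derive_seed(config$seed, "phase"),
                               frequencies_of_interest = config$frequencies_of_interest)
    ms <- stepdown_maxstat(stream, config$alpha)
  } else {
    parts <- lapply(config$frequencies_of_interest, function(f) {
      st <- phase_surrogates(fsets_rad, config$n_surrogates,
                             seed = derive_seed(config$seed, paste0("phase", f)),
                             frequencies_of_interest = f)
      stepdown_maxstat(st, config$alpha)
    })
    ms <- parts[[1]]
    ms$observed <- do.call(cbind, lapply(parts, `[[`, "observed"))
    ms$significant <- do.call(cbind, lapply(parts, `[[`, "significant"))
    ms$p_values <- do.call(cbind, lapply(parts, `[[`, "p_values"))
    colnames(ms$observed) <- colnames(ms$significant) <-
      colnames(ms$p_values) <- as.character(config$frequencies_of_interest)
    ms$thresholds <- lapply(parts, `[[`, "thresholds")
    ms$iterations <- max(vapply(parts, `[[`, integer(1), "iterations"))
  }
  manifest <- log_stage(manifest, "stats", t0, ms$p_values)
  grid <- make_source_grid(config$head_radius, config$grid_spacing)
  fwd <- sphere_lead_field(spectra_rad[[1]]$channels, grid)
  # match every participant's averaged coefficients onto the forward's channels
  coefs <- lapply(seq_along(avgcoefs_rad), function(p) {
    ac <- avgcoefs_rad[[p]]
    idx <- match_channels_to_template(fwd$channels, ac$channels)
    ac$coef <- ac$coef[idx, , drop = FALSE]
    ac$channels <- fwd$channels
    ac
  })
  srcspec <- localize_oddball(coefs, fwd, lambda2 = config$lambda2)
  hemi <- dplyr::bind_rows(lapply(config$frequencies_of_interest, function(f) {
    h <- hemispheric_sources(srcspec, freq_hz = f)
    h$freq_hz <- f
    h
  }))
  manifest <- log_stage(manifest, "sources", t0, srcspec$snr)
  structure(list(kind = "oddball", snr_foi = snr_foi, group_snr = group_snr,
                 group_tangential = if (length(spectra_tan))
                   group_average_snr(spectra_tan) else NULL,
                 maxstat = ms, source_spectrum = srcspec, hemispheres = hemi,
                 manifest = manifest, config = config),
            class = "opm_report")
}

#' @export
print.opm_report <- function(x, ...) {
  cat(sprintf("<opm_report> %s pipeline, %d participants, %d surrogates\n",
              x$kind, x$config$n_participants, x$maxstat$n_surrogates))
  print(x$maxstat)
  invisible(x)
}

#' Compare two pipeline reports
#'
#' Tabulates the per-participant metrics of two runs (for example radial vs
#' tangential axes, or two sensor systems) and applies the normality-gated
#' paired or unpaired comparisons plus the amplitude correlation.
#'
#' @param report_a,report_b `opm_report` objects of the same kind.
#' @param paired compare participant-by-participant (requires identical
#'   participant sets).
#' @return tibble with one row per compared quantity: the chosen test, its
#'   statistic, p-value, and for amplitudes the Pearson r.
#' @export
run_comparison <- function(report_a, report_b, paired = TRUE) {
  stopifnot(report_a$kind == report_b$kind)
  out <- list()
  if (report_a$kind == "evoked") {
    ma <- report_a$metrics[report_a$metrics$axis_mode == "radial", ]
    mb <- report_b$metrics[report_b$metrics$axis_mode == "radial", ]
    if (paired && !identical(ma$participant, mb$participant))
      abort("paired comparison requires identical participant sets")
    for (q in c("latency_s", "amplitude", "snr")) {
      cmp <- compare_samples(ma[[q]], mb[[q]], paired = paired)
      cmp$quantity <- q
      out[[length(out) + 1L]] <- cmp
    }
    cr <- correlate_samples(ma$amplitude, mb$amplitude)
    cr$quantity <- "amplitude_correlation"
    out[[length(out) + 1L]] <- cr
  } else {
    for (f in report_a$config$frequencies_of_interest) {
      sa <- report_a$snr_foi
      sb <- report_b$snr_foi
      sa <- sa[sa$axis_mode == "radial" & sa$freq_hz == f, ]
      sb <- sb[sb$axis_mode == "radial" & sb$freq_hz == f, ]
      if (paired && !identical(sa$participant, sb$participant))
        abort("paired comparison requires identical participant sets")
      cmp <- compare_samples(sa$snr, sb$snr, paired = paired)
      cmp$quantity <- sprintf("snr_%g_hz", f)
      out[[length(out) + 1L]] <- cmp
    }
  }
  dplyr::bind_rows(out)
}
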