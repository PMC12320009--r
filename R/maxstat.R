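#' Sign-flip surrogate stream for evoked statistics
#'
#' Builds the null distribution for stimulus-locked evoked activity: each
#' surrogate draws one random sign per unit (epoch at the individual level,
#' participant evoked response at the group level), applies it to all
#' channels and time points of that unit, and re-averages into the statistic
#' map `|mean|`. The same flips apply to every channel, preserving the
#' spatial structure of the data under the null.
#'
#' @param x an `opm_epochs` (units = epochs), a list of `opm_evoked`
#'   (units = participants; channels matched to the first), or a numeric
#'   array units x channels x time.
#' @param n_surrogates number of surrogates (default 10000).
#' @param seed RNG seed; the stream is replayable.
#' @return class `opm_surrogates`, for [stepdown_maxstat()]: carries the
#'   observed map, `n_surrogates`, and a replayable `max_stat(idx)` that
#'   returns the per-surrogate maximum over the elements `idx`.
#' @export
signflip_surrogates <- function(x, n_surrogates = 10000, seed = 1L) {
  if (inherits(x, "opm_epochs")) {
    arr <- x$epochs
    dn <- list(channel = x$channels$channel_id, time = x$times)
  } else if (is.list(x) && inherits(x[[1]], "opm_evoked")) {
    template <- x[[1]]$channels
    arr <- array(0, dim = c(length(x), nrow(template), length(x[[1]]$times)))
    for (p in seq_along(x)) {
      idx <- match_channels_to_template(template, x[[p]]$channels)
      arr[p, , ] <- x[[p]]$mean[idx, , drop = FALSE]
    }
    dn <- list(channel = template$channel_id, time = x[[1]]$times)
  } else {
    arr <- x
    dn <- list(channel = seq_len(dim(arr)[2]), time = seq_len(dim(arr)[3]))
  }
  n_units <- dim(arr)[1]
  map_dim <- dim(arr)[c(2, 3)]
  M <- matrix(arr, nrow = n_units)          # units x (ch*time)
  observed <- abs(colMeans(M))
  flips <- with_seed(derive_seed(seed, "signflip"),
                     matrix(sample(c(-1, 1), n_surrogates * n_units,
                                   replace = TRUE), n_surrogates, n_units))
  max_stat <- function(idx) {
    out <- numeric(n_surrogates)
    Mi <- M[, idx, drop = FALSE]
    block <- max(1L, floor(2e7 / max(length(idx), 1L)))
    s0 <- 1L
    while (s0 <= n_surrogates) {
      s1 <- min(s0 + block - 1L, n_surrogates)
      S <- abs(flips[s0:s1, , drop = FALSE] %*% Mi) / n_units
      out[s0:s1] <- apply(S, 1, max)
      s0 <- s1 + 1L
    }
    out
  }
  structure(list(observed = observed, map_dim = map_dim, dimnames = dn,
                 n_surrogates = n_surrogates, n_units = n_units,
                 max_stat = max_stat, kind = "signflip", seed = seed),
            class = "opm_surrogates")
}

# per-surrogate x per-epoch phase factors for one frequency bin (replayable)
phase_factors <- function(n_surrogates, n_epochs, seed, tag) {
  with_seed(derive_seed(seed, tag), {
    th <- matrix(runif(n_surrogates * n_epochs, 0, 2 * pi),
                 n_surrogates, n_epochs)
    exp(1i * th)
  })
}

#' Phase-randomization surrogate stream for frequency-tagged statistics
#'
#' For each surrogate, every epoch's Fourier coefficient at every involved
#' frequency bin is multiplied by a random unit phase, identically across
#' channels (the magnitude spectrum of every epoch and channel is exactly
#' preserved). The epoch-averaged coefficients, power, and flanking-bin SNR
#' at the frequencies of interest are then recomputed, giving the null
#' distribution of the SNR map. With `granularity = "epoch"` a single phase
#' per epoch is shared across bins instead.
#'
#' @param x an `opm_fourier`, or a list of them (one per participant): the
#'   statistic is then the group-mean SNR, with independent phase draws per
#'   participant and channels matched to the first participant's layout.
#' @param n_surrogates number of surrogates.
#' @param seed RNG seed; the stream is replayable.
#' @param frequencies_of_interest tested bins (Hz).
#' @param excl,extent flank definition ([snr_from_power()]).
#' @param granularity `"bin"` (default: independent phase per epoch and bin)
#'   or `"epoch"` (one phase per epoch, all bins).
#' @return class `opm_surrogates` (see [signflip_surrogates()]).
#' @export
phase_surrogates <- function(x, n_surrogates = 10000, seed = 1L,
                             frequencies_of_interest = c(0.75, 1.5, 3),
                             excl = 0.1, extent = 0.4,
                             granularity = c("bin", "epoch")) {
  granularity <- match.arg(granularity)
  sets <- if (inherits(x, "opm_fourier")) list(x) else x
  template <- sets[[1]]$channels
  freq <- sets[[1]]$freq
  df <- freq[2] - freq[1]
  k1 <- as.integer(round(excl / df)); k2 <- as.integer(round(extent / df))
  offs <- c(-(k2:k1), k1:k2)
  foi_bins <- vapply(frequencies_of_interest,
                     function(f) which.min(abs(freq - f)), integer(1))
  nch <- nrow(template)
  nfoi <- length(foi_bins)
  acc_obs <- 0
  acc_maps <- 0
  for (p in seq_along(sets)) {
    fs_p <- sets[[p]]
    stopifnot(identical(fs_p$freq, freq))
    idx <- match_channels_to_template(template, fs_p$channels)
    n_ep <- fs_p$n_epochs
    pow_bin <- function(b, phased) {
      Cb <- matrix(fs_p$coef[, idx, b], nrow = n_ep)    # epochs x ch
      if (is.null(phased)) {
        matrix(Mod(colMeans(Cb))^2, 1, nch)
      } else {
        Mod(phased %*% Cb / n_ep)^2                     # n_surr x ch
      }
    }
    surr_pow <- function(b) {
      tag <- if (granularity == "bin") paste0("p", p, "b", b) else paste0("p", p, "e")
      pow_bin(b, phase_factors(n_surrogates, n_ep, seed, tag))
    }
    obs_map <- matrix(0, nch, nfoi)
    maps <- matrix(0, n_surrogates, nch * nfoi)
    for (fi in seq_len(nfoi)) {
      b <- foi_bins[fi]
      op <- pow_bin(b, NULL)
      ofl <- 0; sfl <- 0
      for (o in offs) {
        ofl <- ofl + pow_bin(b + o, NULL)
        sfl <- sfl + surr_pow(b + o)
      }
      obs_map[, fi] <- op[1, ] / (ofl[1, ] / length(offs))
      sp <- surr_pow(b)
      maps[, (fi - 1L) * nch + seq_len(nch)] <- sp / (sfl / length(offs))
    }
    acc_obs <- acc_obs + obs_map
    acc_maps <- acc_maps + maps
  }
  np <- length(sets)
  observed <- as.vector(acc_obs / np)
  maps <- acc_maps / np
  max_stat <- function(idx2) apply(maps[, idx2, drop = FALSE], 1, max)
  structure(list(observed = observed, map_dim = c(nch, nfoi),
                 dimnames = list(channel = template$channel_id,
                                 freq = frequencies_of_interest),
                 n_surrogates = n_surrogates, max_stat = max_stat,
                 kind = "phase", granularity = granularity, seed = seed),
            class = "opm_surrogates")
}

#' Step-down maximum-statistics inference
#'
#' Iteration k compares the observed statistic of every not-yet-significant
#' element against the null distribution of the maximum statistic over those
#' elements; elements whose empirical p-value `(1 + #\{max >= observed\}) /`
#' `(1 + n_surrogates)` is at most `alpha` are declared significant, masked
#' off, and the next iteration re-tests the remainder with its own null.
#' Iteration stops when no new element is added. This step-down refinement
#' controls the family-wise error rate at `alpha` while gaining power over
#' the single-step maximum test.
#'
#' @param stream an `opm_surrogates` ([signflip_surrogates()],
#'   [phase_surrogates()]).
#' @param alpha significance level (default 0.05).
#' @return class `opm_maxstat`: `observed`, `significant` and `p_values`
#'   maps (matrices of the stream's map dimension), per-iteration
#'   `thresholds` (the empirical `1 - alpha` quantile of each null),
#'   `iterations`, `n_surrogates`, `alpha`.
#' @export
stepdown_maxstat <- function(stream, alpha = 0.05) {
  obs <- stream$observed
  n_el <- length(obs)
  n <- stream$n_surrogates
  significant <- rep(FALSE, n_el)
  p_values <- rep(NA_real_, n_el)
  thresholds <- numeric(0)
  repeat {
    idx <- which(!significant)
    if (!length(idx)) break
    mx <- sort(stream$max_stat(idx))
    thresholds <- c(thresholds, unname(quantile(mx, 1 - alpha, type = 7)))
    # a surrogate equal to the observed statistic (e.g. the identity sign
    # flip) must count as an exceedance even if floating-point evaluation
    # orders differ by an ulp, so ties are compared with relative slack
    cnt_ge <- n - findInterval(obs[idx] - 1e-9 * abs(obs[idx]), mx,
                               left.open = TRUE)
    p <- (1 + cnt_ge) / (1 + n)
    p_values[idx] <- p
    new_sig <- p <= alpha
    if (!any(new_sig)) break
    significant[idx[new_sig]] <- TRUE
  }
  shape <- function(v) {
    m <- matrix(v, stream$map_dim[1], stream$map_dim[2])
    dimnames(m) <- stream$dimnames[1:2]
    m
  }
  structure(list(observed = shape(obs), significant = shape(significant),
                 p_values = shape(p_values), thresholds = thresholds,
                 iterations = length(thresholds), n_surrogates = n,
                 alpha = alpha, kind = stream$kind, seed = stream$seed),
            class = "opm_maxstat")
}

#' @export
print.opm_maxstat <- function(x, ...) {
  cat(sprintf("<opm_maxstat> %s surrogates: %d; %d/%d elements significant at alpha = %g (%d iterations)\n",
              x$kind, x$n_surrogates, sum(x$significant), length(x$significant),
              x$alpha, x$iterations))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Two-tailed paired (or unpaired) t-test unless a Shapiro-Wilk test
#' indicates non-normality (of the paired differences, or of either sample),
#' in which case the Wilcoxon signed-rank (or rank-sum) test is used.
#'
#' @param a,b numeric samples (equal length if paired).
#' @param paired logical.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return One-row tibble of class `opm_comparison`: `test`, `statistic`,
#'   `z` (normal-approximation deviate for rank tests), `p_value`, `n`,
#'   `normality_p`, `direction` (sign of the mean difference).
#' @export
compare_samples <- function(a, b, paired = TRUE, alpha_normality = 0.05) {
  if (paired) stopifnot(length(a) == length(b))
  d <- if (paired) a - b else NULL
  shap <- function(x) {
    if (length(unique(x)) < 3 || length(x) < 3) return(NA_real_)
    shapiro.test(x)$p.value
  }
  norm_p <- if (paired) shap(d) else min(shap(a), shap(b))
  degenerate <- paired && sd(d) == 0
  use_t <- degenerate || is.na(norm_p) || norm_p >= alpha_normality
  if (degenerate) {
    res <- list(test = "paired-t", statistic = 0, p_value = 1)
  } else if (use_t) {
    tt <- t.test(a, b, paired = paired)
    res <- list(test = if (paired) "paired-t" else "unpaired-t",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE,
                                       correct = TRUE))
    res <- list(test = if (paired) "wilcoxon-signed-rank" else "rank-sum",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  z <- if (res$test %in% c("wilcoxon-signed-rank", "rank-sum"))
    sign(mean(a) - mean(b)) * abs(stats::qnorm(res$p_value / 2)) else NA_real_
  out <- tibble(test = res$test, statistic = res$statistic, z = z,
                p_value = res$p_value, n = if (paired) length(d) else
                  min(length(a), length(b)),
                normality_p = norm_p,
                direction = sign(mean(a) - mean(b)))
  class(out) <- c("opm_comparison", class(out))
  out
}

#' Pearson correlation with two-tailed p-value
#'
#' @param a,b numeric vectors of equal length.
#' @return One-row tibble of class `opm_comparison` with `r` and `p_value`.
#' @export
correlate_samples <- function(a, b) {
  ct <- cor.test(a, b, method = "pearson")
  out <- tibble(test = "pearson-r", statistic = unname(ct$statistic),
                r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
  class(out) <- c("opm_comparison", class(out))
  out
}
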