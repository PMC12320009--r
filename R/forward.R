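#' Magnetic field of a current dipole in a homogeneous spherical conductor
#'
#' Analytic external solution (Sarvas formula). The field is independent of
#' the conductivity profile as long as it is spherically symmetric, and the
#' radially oriented part of any dipole produces no external field at all.
#'
#' @param sensors n x 3 matrix of sensor positions (m), relative to any origin.
#' @param r0 dipole position (3-vector, m).
#' @param q dipole moment (3-vector, A m).
#' @param centre sphere centre (3-vector, m).
#' @return n x 3 matrix of the magnetic field vector (T) at each sensor.
#' @keywords internal
sarvas_field <- function(sensors, r0, q, centre = c(0, 0, 0)) {
  rr <- sweep(as.matrix(sensors), 2, centre)
  r0 <- as.numeric(r0) - centre
  q <- as.numeric(q)
  a_v <- sweep(rr, 2, r0)                    # r - r0
  a <- sqrt(rowSums(a_v^2))
  r <- sqrt(rowSums(rr^2))
  ar <- rowSums(a_v * rr)                    # a . r
  r0r <- as.vector(rr %*% r0)                # r0 . r
  FF <- a * (r * a + r^2 - r0r)
  gF_r <- a^2 / r + ar / a + 2 * a + 2 * r   # coefficient of r in grad F
  gF_r0 <- a + 2 * r + ar / a                # coefficient of r0 in grad F
  gradF <- rr * gF_r - tcrossprod(gF_r0, r0)
  qxr0 <- cross3(q, r0)
  B <- (matrix(qxr0, nrow(rr), 3, byrow = TRUE) * FF -
          gradF * as.vector(rr %*% qxr0)) * (1e-7 / FF^2)
  bad <- !is.finite(FF) | abs(FF) < 1e-30
  if (any(bad)) B[bad, ] <- 0
  B
}

#' Regular source grid inside a sphere
#'
#' @param radius sphere (scalp) radius in metres.
#' @param spacing grid spacing in metres (default 7.5 mm).
#' @param fraction sources are kept within `fraction * radius` of the centre.
#' @param centre sphere centre.
#' @return n x 3 matrix of source positions.
#' @export
make_source_grid <- function(radius, spacing = 0.0075, fraction = 0.85,
                             centre = c(0, 0, 0)) {
  rmax <- radius * fraction
  g <- seq(-rmax, rmax, by = spacing)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  grid <- grid[sqrt(rowSums(grid^2)) <= rmax, , drop = FALSE]
  grid <- sweep(grid, 2, -as.numeric(centre))
  attr(grid, "spacing") <- spacing
  grid
}

#' Spherical-conductor lead field for a channel set
#'
#' Projects the analytic dipole field onto each channel's measurement axis,
#' for unit moments along x, y and z at every grid source. Radially oriented
#' dipoles produce exactly zero field, so the effective source space is
#' two-dimensional; the inverse operators treat sources as free-orientation
#' triplets regardless.
#'
#' @param channels channel tibble ([make_sensor_array()]).
#' @param source_grid n x 3 matrix of source positions ([make_source_grid()]).
#' @param centre sphere centre.
#' @return An object of class `opm_forward` with elements `lead_field`
#'   (channels x 3*n_sources, T per A m), `grid`, `centre`, `channels`.
#' @export
sphere_lead_field <- function(channels, source_grid, centre = c(0, 0, 0)) {
  pos <- channel_positions(channels)
  ori <- channel_orientations(channels)
  grid <- as.matrix(source_grid)
  rad <- min(sqrt(rowSums(sweep(pos, 2, centre)^2)))
  src_r <- sqrt(rowSums(sweep(grid, 2, centre)^2))
  if (any(src_r >= rad))
    abort("all sources must lie strictly inside the sensor sphere")
  L <- matrix(0, nrow(pos), 3L * nrow(grid))
  for (s in seq_len(nrow(grid))) {
    for (k in 1:3) {
      q <- c(0, 0, 0); q[k] <- 1
      B <- sarvas_field(pos, grid[s, ], q, centre)
      L[, 3L * (s - 1L) + k] <- rowSums(B * ori)
    }
  }
  structure(list(lead_field = L, grid = grid, centre = as.numeric(centre),
                 channels = channels, conductor = "homogeneous_sphere"),
            class = "opm_forward")
}

#' Noise-normalized minimum-norm inverse
#'
#' Linear inverse `W = L' (L L' + lambda2 * g * C)^-1` with identity source
#' covariance, where `g = trace(L L') / trace(C)` puts the regularizer on the
#' scale of the data term and `lambda2` is the usual inverse squared
#' amplitude-SNR (default SNR 3). Depth-bias correction by noise
#' normalization comes in two standard flavours: `"sloreta"` (default)
#' standardizes each source's free-orientation estimate by the corresponding
#' 3x3 diagonal block of the resolution matrix `W L` (zero localization
#' error for a noiseless point source; the silent radial orientation of the
#' spherical conductor is handled by a block pseudo-inverse), while `"dspm"`
#' divides each source component by its projected noise standard deviation
#' `sqrt(diag(W C W'))`. Both give dimensionless maps; `"none"` returns the
#' raw minimum-norm amplitude (units of the dipole moment).
#' Free-orientation sources are reported as a non-negative per-source norm.
#'
#' @param forward an `opm_forward`.
#' @param data numeric (or complex) vector of per-channel values at one
#'   time point / frequency bin, or a channels x k matrix for several.
#' @param noise_cov channels x channels noise covariance; defaults to the
#'   identity.
#' @param lambda2 regularization (1/SNR^2; default SNR 3).
#' @param method `"sloreta"`, `"dspm"` or `"none"`.
#' @return An object of class `opm_source_estimate`: tibble `sources`
#'   (x, y, z, value) for the first column of `data`, the full `values`
#'   matrix (sources x k), the operator and settings. For complex input the
#'   norms use complex magnitudes.
#' @export
minimum_norm_inverse <- function(forward, data, noise_cov = NULL, lambda2 = 1 / 9,
                                 method = c("sloreta", "dspm", "none")) {
  method <- match.arg(method)
  L <- forward$lead_field
  nch <- nrow(L)
  data <- if (is.null(dim(data))) matrix(data, ncol = 1) else as.matrix(data)
  stopifnot(nrow(data) == nch)
  C <- noise_cov %||% diag(nch)
  stopifnot(nrow(C) == nch, ncol(C) == nch)
  G <- tcrossprod(L)
  g <- sum(diag(G)) / sum(diag(C))
  if (lambda2 <= 0 && nch < ncol(L))
    abort("singular system: fewer channels than sources; use lambda2 > 0")
  M <- G + lambda2 * g * C
  W <- t(L) %*% solve(M)                  # (3 n_src) x nch
  ns <- nrow(forward$grid)
  est <- W %*% data                       # complex-safe
  if (method == "dspm") {
    nsd <- sqrt(rowSums((W %*% C) * W))
    nsd[nsd == 0] <- 1
    est <- est / nsd
  }
  blocks <- NULL
  if (method == "sloreta") {
    # 3x3 diagonal blocks of the resolution matrix W L, pseudo-inverted so
    # the silent (radial) orientation does not blow up
    blocks <- vector("list", ns)
    for (s in seq_len(ns)) {
      i <- 3L * (s - 1L) + 1:3
      Rjj <- W[i, , drop = FALSE] %*% L[, i, drop = FALSE]
      Rjj <- (Rjj + t(Rjj)) / 2
      e <- eigen(Rjj, symmetric = TRUE)
      keep <- e$values > max(e$values, 0) * 1e-8
      blocks[[s]] <- if (any(keep))
        e$vectors[, keep, drop = FALSE] %*%
          (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
      else matrix(0, 3, 3)
    }
  }
  val <- vapply(seq_len(ncol(est)), function(j) {
    m <- matrix(est[, j], nrow = 3)       # 3 x n_src
    if (method == "sloreta") {
      vapply(seq_len(ns), function(s) {
        v <- m[, s]
        sqrt(max(Re(Conj(v) %*% blocks[[s]] %*% v), 0))
      }, numeric(1))
    } else sqrt(colSums(Mod(m)^2))
  }, numeric(ns))
  src <- tibble(x = forward$grid[, 1], y = forward$grid[, 2],
                z = forward$grid[, 3])
  src$value <- if (is.matrix(val)) val[, 1] else val
  structure(list(sources = src, values = val, operator = W, forward = forward,
                 lambda2 = lambda2, method = method),
            class = "opm_source_estimate")
}

#' Source-level spectra for the oddball paradigm
#'
#' Group-averaged sensor SNR is not linear in the field, so source spectra are
#' reconstructed per participant from the epoch-averaged complex Fourier
#' coefficients at each frequency bin; source power and its flanking-bin SNR
#' are then computed along the source spectrum, and the group average of the
#' SNRs is taken.
#'
#' @param coef_list list (one per participant) of averaged-coefficient
#'   objects as returned by [average_coefficients()]; all participants must
#'   share the forward model's channel set.
#' @param forward an `opm_forward`.
#' @param lambda2,noise_cov passed to [minimum_norm_inverse()].
#' @param flank_excl,flank_extent flanking-bin SNR definition (Hz).
#' @return class `opm_source_spectrum`: `snr` (sources x frequency group-mean
#'   SNR), `power` (group-mean source power), `freq`, `grid`.
#' @export
localize_oddball <- function(coef_list, forward, lambda2 = 1 / 9,
                             noise_cov = NULL, flank_excl = 0.1,
                             flank_extent = 0.4) {
  if (!is.list(coef_list) || inherits(coef_list, "opm_avgcoef"))
    coef_list <- list(coef_list)
  freq <- coef_list[[1]]$freq
  snr_sum <- NULL; pow_sum <- NULL
  for (ac in coef_list) {
    stopifnot(identical(ac$freq, freq))
    se <- minimum_norm_inverse(forward, ac$coef, noise_cov = noise_cov,
                               lambda2 = lambda2)
    pow <- se$values^2                      # sources x freq
    snr <- snr_from_power(pow, freq, excl = flank_excl, extent = flank_extent)
    snr_sum <- if (is.null(snr_sum)) snr else snr_sum + snr
    pow_sum <- if (is.null(pow_sum)) pow else pow_sum + pow
  }
  n <- length(coef_list)
  structure(list(snr = snr_sum / n, power = pow_sum / n, freq = freq,
                 grid = forward$grid, n_participants = n),
            class = "opm_source_spectrum")
}

#' Lateral auditory regions of interest on the source grid
#'
#' ROIs are lateral wedges around the left (+y) and right (-y) axes: sources
#' within `half_angle` of the axis and beyond `min_radius_frac` of the
#' outermost source radius.
#'
#' @param grid source grid matrix.
#' @param half_angle wedge half-angle in radians.
#' @param min_radius_frac minimum eccentricity as a fraction of the maximum
#'   source radius.
#' @return list with integer index vectors `left` and `right`.
#' @export
auditory_rois <- function(grid, half_angle = pi / 3.2, min_radius_frac = 0.45) {
  r <- sqrt(rowSums(grid^2))
  rmax <- max(r)
  cosang <- grid[, 2] / pmax(r, 1e-12)
  list(left = which(cosang > cos(half_angle) & r >= min_radius_frac * rmax),
       right = which(-cosang > cos(half_angle) & r >= min_radius_frac * rmax))
}

#' Maximally activated source per hemisphere
#'
#' @param source_estimate an `opm_source_estimate`, or an
#'   `opm_source_spectrum` together with `freq_hz`.
#' @param rois list of `left` / `right` grid indices ([auditory_rois()]).
#' @param freq_hz for source spectra, the frequency bin at which to take the
#'   activation.
#' @return tibble with one row per hemisphere: `hemisphere`, grid `index`,
#'   `x`, `y`, `z`, `value`.
#' @export
hemispheric_sources <- function(source_estimate, rois = NULL, freq_hz = NULL) {
  if (inherits(source_estimate, "opm_source_spectrum")) {
    grid <- source_estimate$grid
    stopifnot(!is.null(freq_hz))
    b <- which.min(abs(source_estimate$freq - freq_hz))
    act <- source_estimate$snr[, b]
  } else {
    grid <- source_estimate$forward$grid
    act <- source_estimate$sources$value
  }
  rois <- rois %||% auditory_rois(grid)
  if (!length(rois$left) || !length(rois$right))
    abort("empty hemisphere ROI on this source grid")
  pick <- function(idx, hemi) {
    i <- idx[which.max(act[idx])]
    tibble(hemisphere = hemi, index = i, x = grid[i, 1], y = grid[i, 2],
           z = grid[i, 3], value = act[i])
  }
  dplyr::bind_rows(pick(rois$left, "left"), pick(rois$right, "right"))
}
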