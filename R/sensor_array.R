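#' Build a wearable magnetometer array on a spherical head model
#'
#' Places `n_sensors` optically pumped magnetometers on the upper part of a
#' sphere of radius `head_radius`, with a 4 mm standoff (the gap left between
#' scalp and sensor housing for heat dissipation). No sensors are placed in
#' the occipital patch, mirroring a cap design for newborns who rest on their
#' back. Each physical sensor contributes two (radial + one tangential) or
#' three (radial + two tangential) orthogonal measurement channels; triaxial
#' housings are assigned preferentially to lateral (temporal) positions where
#' auditory responses are strongest.
#'
#' Head coordinate frame: x anterior, y left, z superior, origin at the
#' sphere centre. Candidate positions come from a Fibonacci lattice restricted
#' to the allowed region (upper three quarters of the sphere by area, minus
#' the occipital patch), thinned by farthest-point sampling so sensors are
#' evenly spread.
#'
#' @param n_sensors number of physical sensor housings (study arrays carried
#'   19 to 30, mean 27).
#' @param head_radius scalp sphere radius in metres.
#' @param triaxial_count how many housings measure along all three axes; the
#'   rest are biaxial (radial + first tangential).
#' @param seed integer; rotates the lattice azimuthally so different
#'   participants get slightly different caps. Placement is deterministic
#'   given the seed.
#' @param standoff sensor-to-scalp gap in metres (default 4 mm).
#' @param min_spacing minimum angular spacing between housings in radians;
#'   requesting more sensors than can be packed at this spacing is an error.
#'
#' @return A tibble with one row per channel: `channel_id`, `sensor_id`,
#'   `axis` (`"radial"`, `"tangential_1"`, `"tangential_2"`), position
#'   columns `x, y, z` (m) and unit orientation columns `ox, oy, oz`.
#'   Attributes: `head_radius`, `standoff`, `centre`.
#' @export
make_sensor_array <- function(n_sensors = 27, head_radius = 0.065,
                              triaxial_count = 20, seed = 1L,
                              standoff = 0.004, min_spacing = 0.15) {
  stopifnot(head_radius > 0, n_sensors >= 1,
            triaxial_count >= 1, triaxial_count <= n_sensors)
  r <- head_radius + standoff
  # Fibonacci lattice over the sphere, azimuth offset derived from the seed
  m <- 4000L
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi0 <- 2 * pi * ((derive_seed(seed, "array") %% 997L) / 997) / 20
  phi <- i * pi * (3 - sqrt(5)) + phi0
  pts <- cbind(x = sqrt(1 - z^2) * cos(phi), y = sqrt(1 - z^2) * sin(phi), z = z)
  # allowed region: upper 3/4 of the sphere by area, occipital patch excluded
  allowed <- pts[, "z"] > -0.5 & !(pts[, "x"] < -0.4 & pts[, "z"] < 0.4)
  pts <- pts[allowed, , drop = FALSE]
  # farthest-point sampling, seeded from the point nearest the vertex
  sel <- integer(n_sensors)
  sel[1] <- which.max(pts[, "z"])
  mind <- acos(pmin(1, pmax(-1, pts %*% pts[sel[1], ])))
  if (n_sensors > 1) for (k in 2:n_sensors) {
    sel[k] <- which.max(mind)
    if (mind[sel[k]] < min_spacing)
      abort(sprintf(
        "cannot place %d sensors at minimum angular spacing %.3g rad", n_sensors,
        min_spacing))
    mind <- pmin(mind, acos(pmin(1, pmax(-1, pts %*% pts[sel[k], ]))))
  }
  u <- pts[sel, , drop = FALSE]
  # triaxial housings go to the most lateral positions (largest |y|)
  tri <- rank(-abs(u[, "y"]), ties.method = "first") <= triaxial_count
  rows <- list()
  for (s in seq_len(n_sensors)) {
    us <- u[s, ]
    g <- if (abs(us[3]) < 0.95) c(0, 0, 1) else c(1, 0, 0)
    t1 <- normalize3(cross3(g, us))
    t2 <- cross3(us, t1)
    axes <- list(radial = us, tangential_1 = t1)
    if (tri[s]) axes$tangential_2 <- t2
    for (ax in names(axes)) {
      rows[[length(rows) + 1L]] <- tibble(
        channel_id = sprintf("S%02d_%s", s,
                             c(radial = "rad", tangential_1 = "tan1",
                               tangential_2 = "tan2")[[ax]]),
        sensor_id = sprintf("S%02d", s), axis = ax,
        x = us[1] * r, y = us[2] * r, z = us[3] * r,
        ox = axes[[ax]][1], oy = axes[[ax]][2], oz = axes[[ax]][3])
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "head_radius") <- head_radius
  attr(out, "standoff") <- standoff
  attr(out, "centre") <- c(0, 0, 0)
  class(out) <- c("opm_array", class(out))
  out
}

#' Channel position / orientation matrices
#'
#' @param channels a channel tibble ([make_sensor_array()]).
#' @return n x 3 numeric matrix of positions (m) or unit measurement axes.
#' @export
channel_positions <- function(channels) {
  as.matrix(channels[, c("x", "y", "z")])
}

#' @rdname channel_positions
#' @export
channel_orientations <- function(channels) {
  as.matrix(channels[, c("ox", "oy", "oz")])
}
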