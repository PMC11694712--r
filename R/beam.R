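# Analytic broad-beam model: separable Gaussian-beam (paraxial)
# approximation per lateral axis. Reproduces the focused-vs-diverging
# trade-off (a focused beam is narrower with stronger on-axis two-way
# amplitude at typical imaging depth; lowering the transmit frequency pulls
# the diffraction-shifted effective focus toward the transducer) and
# provides the lateral-elevation point-spread function used for jet
# cross-section segmentation.

#' Broad-beam configuration
#'
#' @param transmit_frequency transmit frequency (MHz); the transmit sequence
#'   uses the highest frequency in 1.5-2 MHz that the jet depth and maximum
#'   velocity allow.
#' @param aperture_width full aperture width per lateral axis (mm); scalar or
#'   length-2 `(x, y)`.
#' @param focus_depth geometric focus depth (mm). Positive = focused
#'   (default 300 mm, a slightly focused broad transmit); negative = virtual
#'   focus behind the transducer face, i.e. a slightly diverging beam.
#' @param sound_speed speed of sound (m/s).
#' @return an object of class `beam_config`.
#' @export
beam_config <- function(transmit_frequency = 2, aperture_width = c(20, 20),
                        focus_depth = 300, sound_speed = 1540) {
  if (any(aperture_width <= 0))
    stop_hprfd("aperture_width must be positive", "hprfd_parameter_error")
  if (transmit_frequency <= 0)
    stop_hprfd("transmit_frequency must be positive", "hprfd_parameter_error")
  if (length(aperture_width) == 1L) aperture_width <- rep(aperture_width, 2)
  structure(list(
    transmit_frequency = transmit_frequency,
    aperture_width = aperture_width,
    focus_depth = focus_depth,
    sound_speed = sound_speed
  ), class = "beam_config")
}

# Gaussian-beam parameters for one axis: given the 1/e field radius at the
# transducer (aperture_width/2) and the geometric focus F, propagate the
# complex beam parameter to find the waist position z_w (the effective,
# diffraction-shifted focus), Rayleigh range z_R and waist radius w0 (mm).
# z_w = F / (1 + (lambda F / (pi w_a^2))^2) <= F, and decreases as the
# wavelength grows.
gaussian_beam_axis <- function(aperture_mm, focus_mm, f0_mhz, c_ms) {
  wa <- aperture_mm / 2
  lambda <- c_ms / (f0_mhz * 1e3)  # mm
  v <- lambda / (pi * wa^2)
  if (is.infinite(focus_mm) || focus_mm == 0) {
    u <- 0
  } else {
    u <- 1 / focus_mm
  }
  zw <- u / (u^2 + v^2)
  zR <- v / (u^2 + v^2)
  w0 <- sqrt(lambda * zR / pi)
  list(w0 = w0, zw = zw, zR = zR, lambda = lambda)
}

beam_axes <- function(config) {
  list(
    x = gaussian_beam_axis(config$aperture_width[1], config$focus_depth,
                           config$transmit_frequency, config$sound_speed),
    y = gaussian_beam_axis(config$aperture_width[2], config$focus_depth,
                           config$transmit_frequency, config$sound_speed)
  )
}

# 1/e field radius at depth z for one axis
beam_w_at <- function(ax, z) ax$w0 * sqrt(1 + ((z - ax$zw) / ax$zR)^2)

#' Beam amplitude at a position
#'
#' Separable Gaussian-beam amplitude, normalized to 1 on axis at the waist.
#' The one-way field per axis is `sqrt(w0/w(z)) * exp(-x^2 / w(z)^2)`; the
#' two-way (transmit times receive) amplitude is the square of the one-way
#' product.
#'
#' @param config a [beam_config()].
#' @param position length-3 `(x, y, z)` (mm) or n-by-3 matrix; depth `z > 0`.
#' @param two_way if `TRUE` return the transmit-receive (squared) amplitude.
#' @return relative amplitude(s), in `(0, 1]`.
#' @export
beam_amplitude <- function(config, position, two_way = FALSE) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  if (any(p[, 3] <= 0))
    stop_hprfd("depth must be positive", "hprfd_parameter_error")
  ax <- beam_axes(config)
  wx <- beam_w_at(ax$x, p[, 3])
  wy <- beam_w_at(ax$y, p[, 3])
  a <- sqrt(ax$x$w0 / wx) * exp(-p[, 1]^2 / wx^2) *
       sqrt(ax$y$w0 / wy) * exp(-p[, 2]^2 / wy^2)
  if (two_way) a^2 else a
}

#' Two-way beam width at depth
#'
#' Full width of the two-way lateral profile at `level_db` below the on-axis
#' value at that depth, along one lateral axis.
#'
#' @param config a [beam_config()].
#' @param depth depth (mm), > 0.
#' @param level_db level below on-axis (dB, negative; default -6).
#' @param axis `"lateral"` (x) or `"elevation"` (y).
#' @return full width (mm).
#' @export
beam_width_at_depth <- function(config, depth, level_db = -6,
                                axis = c("lateral", "elevation")) {
  axis <- match.arg(axis)
  if (any(depth <= 0)) stop_hprfd("depth must be positive", "hprfd_parameter_error")
  if (any(level_db >= 0)) stop_hprfd("level_db must be negative", "hprfd_parameter_error")
  ax <- beam_axes(config)[[if (axis == "lateral") "x" else "y"]]
  w <- beam_w_at(ax, depth)
  # two-way amplitude profile exp(-2 x^2 / w^2) = 10^(level_db/20):
  # full width 2x = w sqrt(2 ln 10^(-level_db/20))
  w * sqrt(-2 * log(10^(level_db / 20)))
}

#' Effective (diffraction-shifted) focus depth
#'
#' @param config a [beam_config()].
#' @return named vector of effective focus depths (mm) for the x and y axes.
#' @export
effective_focus <- function(config) {
  ax <- beam_axes(config)
  c(x = ax$x$zw, y = ax$y$zw)
}

# 1/e radius (mm) of the dynamically focused receive profile per axis at
# depth z: diffraction-limited, w_rx = z * lambda / (pi * w_a) with w_a the
# aperture radius.
receive_w <- function(config, depth) {
  lambda <- config$sound_speed / (config$transmit_frequency * 1e3)  # mm
  c(x = depth * lambda / (pi * config$aperture_width[1] / 2),
    y = depth * lambda / (pi * config$aperture_width[2] / 2))
}

# Gaussian sigma (mm) of the power point-spread function per axis at a
# given depth, as a function of the receive beamforming position for a
# fixed broad transmit: receive power ~ exp(-2 x^2 / w_rx^2) =
# exp(-x^2 / (2 sigma^2)), sigma = w_rx / 2. Used by the cross-section
# segmentation; the slowly varying transmit power envelope
# exp(-2 x^2 / w_tx^2) at absolute position is applied separately.
beam_psf_sigma <- function(config, depth) {
  receive_w(config, depth) / 2
}

# 1/e one-way beam radii (mm) per axis at depth, for the transmit envelope
beam_w_pair <- function(config, depth) {
  ax <- beam_axes(config)
  c(x = beam_w_at(ax$x, depth), y = beam_w_at(ax$y, depth))
}

#' Export a beam-width profile
#'
#' Two-way -6 dB beam width as a function of depth, for plotting or CSV
#' export.
#'
#' @param config a [beam_config()].
#' @param depths depths (mm).
#' @param level_db profile level (dB).
#' @return data.frame with `depth_mm` and `width_mm`.
#' @export
beam_profile <- function(config, depths = seq(20, 160, by = 5),
                         level_db = -6) {
  data.frame(depth_mm = depths,
             width_mm = beam_width_at_depth(config, depths, level_db))
}
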