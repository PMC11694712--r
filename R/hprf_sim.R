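# HPRF pulsed-Doppler acquisition simulation: range gating with spatial
# (range) ambiguity, slow-time phase progression, aliasing, receiver noise
# and saturation. The ensemble is produced directly on a beamformed
# lateral x elevation x gate-depth grid with the two-way beam amplitude as
# the spatial sensitivity; channel data and beamforming are not simulated.

#' HPRF acquisition configuration
#'
#' @param transmit_frequency transmit frequency f0 (MHz, default 2; the
#'   sequence uses the highest frequency in 1.5-2 MHz the jet allows).
#' @param prf pulse repetition frequency (kHz; typical 12-18).
#' @param gate_depth centre depth of the primary sample volume (mm).
#' @param gate_length axial length of the sample volume (mm, default 20).
#' @param n_frames number of slow-time samples (default 24000, at least one
#'   cardiac cycle at typical PRF).
#' @param sound_speed speed of sound (m/s).
#' @param n_lateral,n_elevation lateral/elevation grid points.
#' @param lateral_spacing,elevation_spacing grid spacing (mm).
#' @param depth_spacing receive gate sampling within the sample volume (mm,
#'   default 0.5).
#' @param noise_level_db complex white-noise power relative to the signal
#'   power of a unit-RMS blood scatterer at the beam centre of the primary
#'   sample volume (dB; `-Inf` disables noise).
#' @param clip_level receiver dynamic-range bound (linear amplitude applied
#'   to real and imaginary parts; `Inf` disables saturation).
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(transmit_frequency = 2, prf = 12,
                               gate_depth = 90, gate_length = 20,
                               n_frames = 24000, sound_speed = 1540,
                               n_lateral = 13, n_elevation = 13,
                               lateral_spacing = 2, elevation_spacing = 2,
                               depth_spacing = 0.5,
                               noise_level_db = -Inf, clip_level = Inf) {
  if (transmit_frequency <= 0 || prf <= 0)
    stop_hprfd("transmit_frequency and prf must be positive",
               "hprfd_parameter_error")
  if (gate_depth <= 0) stop_hprfd("gate_depth must be positive",
                                  "hprfd_parameter_error")
  if (clip_level <= 0) stop_hprfd("clip_level must be positive",
                                  "hprfd_parameter_error")
  structure(list(
    transmit_frequency = transmit_frequency, prf = prf,
    gate_depth = gate_depth, gate_length = gate_length,
    n_frames = as.integer(n_frames), sound_speed = sound_speed,
    n_lateral = as.integer(n_lateral), n_elevation = as.integer(n_elevation),
    lateral_spacing = lateral_spacing, elevation_spacing = elevation_spacing,
    depth_spacing = depth_spacing,
    noise_level_db = noise_level_db, clip_level = clip_level
  ), class = "acquisition_config")
}

#' Nyquist velocity
#'
#' Maximum unambiguous Doppler velocity `v_nyq = c * PRF / (4 * f0)`. Faster
#' flow wraps (aliases). Reducing the transmit frequency or raising the PRF
#' increases the maximum detectable velocity.
#'
#' @param config an [acquisition_config()].
#' @return Nyquist velocity (m/s).
#' @export
nyquist_velocity <- function(config) {
  config$sound_speed * (config$prf * 1e3) /
    (4 * config$transmit_frequency * 1e6)
}

#' Ambiguous sample-volume depths
#'
#' With HPRF, echoes from depths separated by `c / (2 PRF)` arrive in the
#' same receive gate: the primary sample volume at `gate_depth` is
#' accompanied by additional volumes `gate_depth - k c / (2 PRF)` for all
#' positive depths. Increasing the PRF brings an additional sample volume
#' close to the transducer.
#'
#' @param config an [acquisition_config()].
#' @param gate_depth depth of the primary sample volume (mm); defaults to
#'   the configured value.
#' @return depths (mm), sorted descending, the primary gate first.
#' @export
ambiguous_depths <- function(config, gate_depth = config$gate_depth) {
  spacing <- config$sound_speed * 1e3 / (2 * config$prf * 1e3)  # mm
  k <- 0:floor((gate_depth - 1e-9) / spacing)
  gate_depth - k * spacing
}

# grid axes of the beamformed ensemble
acquisition_grid <- function(config) {
  ax <- function(n, d) (seq_len(n) - (n + 1) / 2) * d
  nz <- max(2L, round(config$gate_length / config$depth_spacing))
  list(x = ax(config$n_lateral, config$lateral_spacing),
       y = ax(config$n_elevation, config$elevation_spacing),
       z = config$gate_depth + ax(nz, config$depth_spacing))
}

# -6 dB range-gate resolution (mm): 1 mm at 2 MHz, scaled by 2.0/f0
gate_resolution <- function(config) 1 * (2.0 / config$transmit_frequency)

#' Simulate an HPRF Doppler IQ ensemble
#'
#' Produces complex baseband slow-time samples for a scatterer cloud moving
#' in a jet phantom's velocity field. Each pulse, every scatterer inside any
#' ambiguous sample volume contributes
#' `amplitude * two-way beam amplitude * range-gate window * exp(i 4 pi f0 r / c)`
#' to the gate-depth bin congruent to its depth modulo `c / (2 PRF)`;
#' circular complex white noise is added at the configured level and the
#' receiver clip applied. Reproducible under a fixed seed.
#'
#' @param cloud a [make_scatterers()] cloud (carries its phantom).
#' @param beam a [beam_config()].
#' @param config an [acquisition_config()].
#' @param seed RNG seed for the noise realization.
#' @param add_noise,apply_clip set `FALSE` to obtain the raw superposition
#'   (used by linearity/superposition checks).
#' @param ramp_mm axial taper length (mm) of the blood scattering amplitude
#'   at the core entrance/exit, so scatterers recycle at zero amplitude
#'   instead of producing broadband amplitude steps; 0 disables.
#' @param coherence_time blood speckle coherence period (s): each blood
#'   scatterer's amplitude is modulated by a unit-power cosine with a
#'   random phase and this period, emulating the echo decorrelation of real
#'   blood that purely laminar advection lacks; 0 disables.
#' @return an object of class `iq_ensemble`: `samples` (complex array
#'   `gate_depth_bin x lateral x elevation x slow_time`), `saturation_mask`
#'   (`lateral x elevation x slow_time`), `config`, `beam`, `grid`,
#'   `frame_times` and the source `phantom`.
#' @export
simulate_iq <- function(cloud, beam, config, seed = 1,
                        add_noise = TRUE, apply_clip = TRUE, ramp_mm = 3,
                        coherence_time = 0.04) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(beam, "beam_config"))
  phantom <- cloud$phantom
  grid <- acquisition_grid(config)
  nt <- config$n_frames
  tt <- (seq_len(nt) - 1L) / (config$prf * 1e3)
  if (nrow(cloud$positions) == 0L) {
    warning("empty scatterer cloud: noise-only ensemble")
    samples <- array(complex(real = 0, imaginary = 0),
                     dim = c(length(grid$z), length(grid$x),
                             length(grid$y), nt))
  } else {
    wf_q <- waveform_flow_rate(phantom$waveform, tt)
    g <- orifice_modulation(phantom, tt)
    area0 <- pi * phantom$orifice$semi_axis_a * phantom$orifice$semi_axis_b
    speed <- wf_q / (area0 * g^2)             # mean core speed m/s
    exc <- phantom$lateral_excursion *
      sin(2 * pi * (tt %% phantom$waveform$cycle_length) /
            phantom$waveform$cycle_length)
    bas <- jet_basis(phantom$orifice$orientation)
    axs <- beam_axes(beam)
    sigma_g <- gate_resolution(config) / (2 * sqrt(2 * log(2)))
    # fresh radial coordinates (uniform in the unit ellipse) for scatterers
    # recycling through the core: deterministic pool drawn from the seed
    n_blood <- sum(cloud$class == "blood")
    travel_mm <- sum(abs(speed)) / (config$prf * 1e3) * 1000
    n_pool <- max(16L, min(2e6, ceiling(1.6 * n_blood * travel_mm /
                                          phantom$core_length)))
    respawn <- with_seed(seed + 1L, {
      r <- sqrt(runif(n_pool)); th <- runif(n_pool, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    })
    samples <- cpp_simulate_iq(
      cloud$positions, cloud$amplitudes, as.integer(cloud$class) - 1L,
      cloud$drift,
      phantom$orifice$orientation, bas$e1, bas$e2,
      phantom$orifice$center,
      phantom$core_length,
      phantom$orifice$semi_axis_a, phantom$orifice$semi_axis_b,
      as.integer(phantom$profile == "parabolic"),
      speed, g, exc,
      grid$x, grid$y, grid$z,
      axs$x$w0, axs$x$zw, axs$x$zR, axs$y$w0, axs$y$zw, axs$y$zR,
      axs$x$lambda / (pi * beam$aperture_width[1] / 2),
      axs$y$lambda / (pi * beam$aperture_width[2] / 2),
      config$transmit_frequency * 1e6, config$prf * 1e3,
      config$sound_speed, sigma_g, nt, ramp_mm, respawn,
      cloud$coherence_phase %||% rep(0, nrow(cloud$positions)),
      if (coherence_time > 0) 2 * pi / coherence_time else 0)
  }
  if (add_noise && is.finite(config$noise_level_db)) {
    # reference: unit-RMS blood scatterer at the beam centre of the primary
    # gate (one-way transmit x unit-gain focused receive)
    a_ref <- beam_amplitude(beam, c(0, 0, config$gate_depth))
    sigma <- db_to_amp(config$noise_level_db) * a_ref / sqrt(2)
    n <- length(samples)
    noise <- with_seed(seed, complex(real = rnorm(n, 0, sigma),
                                     imaginary = rnorm(n, 0, sigma)))
    samples <- samples + array(noise, dim = dim(samples))
  }
  sat <- NULL
  if (apply_clip && is.finite(config$clip_level)) {
    cl <- apply_saturation(samples, config$clip_level)
    samples <- cl$samples
    sat <- cl$saturation_mask
  }
  if (is.null(sat))
    sat <- array(FALSE, dim = dim(samples)[c(2, 3, 4)])
  structure(list(
    samples = samples, saturation_mask = sat,
    config = config, beam = beam, grid = grid,
    frame_times = tt, phantom = phantom
  ), class = "iq_ensemble")
}

#' Apply receiver saturation
#'
#' Hard-clips the real and imaginary parts to `[-clip_level, clip_level]`,
#' the simplest mechanism by which a strong reflector inside an ambiguous
#' sample volume destroys weaker signal content arriving in the same gate.
#'
#' @param samples complex array (`gate_depth_bin x lateral x elevation x
#'   slow_time`) or any complex vector/array.
#' @param clip_level positive linear amplitude bound.
#' @return list with clipped `samples` and a logical `saturation_mask`; for
#'   4-D input the mask is per `(lateral, elevation, slow_time)` (TRUE where
#'   any gate bin clipped), otherwise it matches the input shape.
#' @export
apply_saturation <- function(samples, clip_level) {
  if (clip_level <= 0)
    stop_hprfd("clip_level must be positive", "hprfd_parameter_error")
  re <- Re(samples); im <- Im(samples)
  hit <- abs(re) > clip_level | abs(im) > clip_level
  if (any(hit)) {
    re <- pmin(pmax(re, -clip_level), clip_level)
    im <- pmin(pmax(im, -clip_level), clip_level)
  }
  out <- complex(real = re, imaginary = im)
  dm <- dim(samples)
  if (!is.null(dm)) dim(out) <- dm
  mask <- if (!is.null(dm) && length(dm) == 4L) {
    dim(hit) <- dm
    colSums(hit, dims = 1) > 0
  }
  else {
    m <- hit
    if (!is.null(dm)) dim(m) <- dm
    m
  }
  list(samples = out, saturation_mask = mask)
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "HPRF IQ ensemble: %d gate bins x %d x %d beams x %d frames\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  f0 %.2f MHz, PRF %.1f kHz, gate %.0f mm, v_nyq %.2f m/s\n",
              x$config$transmit_frequency, x$config$prf,
              x$config$gate_depth, nyquist_velocity(x$config)))
  cat(sprintf("  ambiguous sample volumes at %s mm\n",
              paste(sprintf("%.1f", ambiguous_depths(x$config)),
                    collapse = ", ")))
  invisible(x)
}
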