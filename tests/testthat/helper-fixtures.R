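# Shared fixtures: small phantoms and acquisition settings sized for fast
# simulation, plus hand-built scatterer clouds for single-target tests.

# compact jet phantom: short cycle, ~76 mm^2 orifice, 20 mL default;
# peak core speed stays near 0.65 v_nyq at PRF 12 so the broadened
# envelope clears the Nyquist boundary
tiny_phantom <- function(rvol_ml = 20, jet_angle = 0,
                         lateral_excursion = 0, profile = "top_hat",
                         direction = "toward") {
  standard_phantom(rvol_ml, jet_angle = jet_angle,
                   lateral_excursion = lateral_excursion,
                   semi_axis_a = 5.5, semi_axis_b = 4.4,
                   duration = 0.2, cycle_length = 0.26,
                   direction = direction, profile = profile,
                   orifice_depth = 94)
}

# compact acquisition grid matched to tiny_phantom (one 0.26 s cycle)
tiny_acquisition <- function(prf = 12, noise_level_db = -Inf,
                             clip_level = Inf, n_frames = NULL, ...) {
  standard_acquisition(
    n_frames = n_frames %||% ceiling(0.26 * prf * 1e3),
    prf = prf, noise_level_db = noise_level_db, clip_level = clip_level,
    gate_length = 12, n_lateral = 9, n_elevation = 9,
    lateral_spacing = 2.25, elevation_spacing = 2.25, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built cloud: targets advected only by their constant drift velocity
manual_cloud <- function(positions, amplitudes = NULL, drift = NULL,
                         class = "tissue_clutter", phantom = tiny_phantom()) {
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3)
  n <- nrow(p)
  structure(list(
    positions = p,
    velocities = drift %||% matrix(0, n, 3),
    amplitudes = amplitudes %||% rep(1, n),
    class = factor(rep(class, length.out = n),
                   levels = c("blood", "tissue_clutter", "apical_reflector")),
    drift = drift %||% matrix(0, n, 3),
    phantom = phantom, seed = 0
  ), class = "scatterer_cloud")
}

# slow-time phase-progression frequency (Hz) at the strongest voxel,
# weighted by local signal amplitude so gaps in target presence drop out
dominant_doppler_hz <- function(ensemble) {
  dm <- dim(ensemble$samples)
  m <- matrix(ensemble$samples, nrow = prod(dm[1:3]))
  i <- which.max(rowSums(abs(m)^2))
  sig <- m[i, ]
  prod_t <- sig[-1] * Conj(sig[-length(sig)])
  w <- abs(prod_t)
  sum(Arg(prod_t) * w) / sum(w) * ensemble$config$prf * 1e3 / (2 * pi)
}

# steady jet: constant flow rate chosen to give a fixed core speed (m/s)
steady_phantom <- function(speed = 1, a = 5, b = 4) {
  orif <- orifice_geometry(a, b, center = c(0, 0, 94))
  q <- speed * pi * a * b   # Q (mL/s) for core speed Q/A
  wf <- make_waveform("diastolic", 0.26, q, "constant", cycle_length = 0.26)
  jet_phantom(orif, wf, jet_angle = 0, direction = "toward")
}

# synthetic single-tone ensemble at a given toward-positive velocity (m/s),
# for exact spectral-mapping checks independent of the simulator
synth_tone_ensemble <- function(v, acq, amp = 1) {
  grid <- hprfdoppler:::acquisition_grid(acq)
  nt <- acq$n_frames
  f <- -2 * v * acq$transmit_frequency * 1e6 / acq$sound_speed
  tone <- amp * exp(2i * pi * f * (seq_len(nt) - 1) / (acq$prf * 1e3))
  nz <- length(grid$z); nx <- length(grid$x); ny <- length(grid$y)
  samples <- array(rep(tone, each = nz * nx * ny),
                   dim = c(nz, nx, ny, nt))
  structure(list(samples = samples,
                 saturation_mask = array(FALSE, dim = c(nx, ny, nt)),
                 config = acq, beam = standard_beam(), grid = grid,
                 frame_times = (seq_len(nt) - 1) / (acq$prf * 1e3),
                 phantom = NULL), class = "iq_ensemble")
}
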