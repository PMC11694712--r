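# Slow-time spectral processing: polynomial-regression clutter filtering,
# Hann-window periodograms, power-Doppler maps and maximum-velocity maps.
#
# Velocity sign convention: motion toward the transducer is positive, as on
# a clinical spectral display. Velocities wrap to [-v_nyq, v_nyq).

#' Spectral processing configuration
#'
#' @param window_length slow-time samples per spectral window (>= 16,
#'   default 128: at PRF 12-18 kHz with 50% overlap this yields roughly
#'   90-140 map frames per second, and a velocity resolution of
#'   `2 v_nyq / 128`).
#' @param window_overlap fractional overlap of consecutive windows, `[0, 1)`.
#' @param clutter_filter_order polynomial order of the slow-time clutter
#'   (wall) filter; polynomials of degree <= order are removed exactly.
#' @param envelope_threshold_db spectral envelope threshold (dB below the
#'   per-spectrum peak, negative; default -20).
#' @param noise_floor_percentile percentile of all periodogram bins used as
#'   the noise-floor estimate.
#' @param noise_margin_db detection margin above the noise floor (dB).
#' @param min_velocity smallest |velocity| (m/s) reported as detectable
#'   flow; velocities below it sit in the clutter-filter stop band and are
#'   flagged undetectable. `NULL` uses 1.5 spectral bins.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(window_length = 128, window_overlap = 0.5,
                            clutter_filter_order = 4,
                            envelope_threshold_db = -20,
                            noise_floor_percentile = 25,
                            noise_margin_db = 6,
                            min_velocity = NULL) {
  if (window_length < 16) stop_hprfd("window_length must be >= 16",
                                     "hprfd_parameter_error")
  if (window_overlap < 0 || window_overlap >= 1)
    stop_hprfd("window_overlap must be in [0, 1)", "hprfd_parameter_error")
  if (envelope_threshold_db >= 0)
    stop_hprfd("envelope_threshold_db must be negative",
               "hprfd_parameter_error")
  structure(list(
    window_length = as.integer(window_length),
    window_overlap = window_overlap,
    clutter_filter_order = as.integer(clutter_filter_order),
    envelope_threshold_db = envelope_threshold_db,
    noise_floor_percentile = noise_floor_percentile,
    noise_margin_db = noise_margin_db,
    min_velocity = min_velocity
  ), class = "spectral_config")
}

# orthonormal polynomial basis (time along rows), degree <= order
poly_basis <- function(n, order) {
  B <- outer(seq_len(n) - (n + 1) / 2, 0:order, `^`)
  qr.Q(qr(B))
}

#' Polynomial-regression clutter filter
#'
#' High-pass filtering along slow time: a least-squares polynomial of degree
#' <= `order` is fitted to each slow-time signal and removed. Strong echoes
#' from stationary or slowly moving tissue concentrate near DC and are
#' annihilated exactly if they are polynomial in time.
#'
#' @param x complex (or numeric) vector, or matrix with slow time along rows.
#' @param order polynomial order, >= 0.
#' @return filtered signal, same shape.
#' @export
clutter_filter <- function(x, order) {
  if (order < 0) stop_hprfd("order must be >= 0", "hprfd_parameter_error")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  if (n < order + 2) stop_hprfd("signal shorter than order + 2",
                                "hprfd_clutter_error")
  Q <- poly_basis(n, order)
  out <- m - Q %*% (t(Q) %*% m)
  if (vec) out[, 1] else out
}

# window start indices
window_starts <- function(n_frames, wl, overlap) {
  step <- max(1L, as.integer(round(wl * (1 - overlap))))
  seq(1L, n_frames - wl + 1L, by = step)
}

#' Power-Doppler and maximum-velocity maps
#'
#' For every grid point and spectral window: the slow-time segment is
#' clutter-filtered, Hann-windowed and transformed to a periodogram with
#' the frequency axis mapped to velocity (`v = f c / (2 f0)`, wrapped to
#' `[-v_nyq, v_nyq)`, positive toward the transducer). The power map is the
#' total post-filter power; the maximum-velocity map is the largest
#' `|velocity|` bin whose power exceeds both the noise floor plus a margin
#' and the per-spectrum peak plus the envelope threshold. Points where no
#' bin clears the noise criterion are flagged undetectable (`NA`).
#'
#' @param ensemble an [simulate_iq()] ensemble.
#' @param config a [spectral_config()].
#' @return an object of class `velocity_maps`: `power_map` (dB),
#'   `max_velocity_map` and `mean_velocity_map` (m/s) arrays
#'   `gate_depth_bin x lateral x elevation x frame`, `frame_times` (s,
#'   window centres), `noise_floor` (dB), `v_axis`, `v_nyq`, `grid`, and
#'   `jet_depth_trace` (filled by [jet_depth_trace()]).
#' @export
spectral_maps <- function(ensemble, config = spectral_config()) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  wl <- config$window_length
  dm <- dim(ensemble$samples)
  nz <- dm[1]; nx <- dm[2]; ny <- dm[3]; nt <- dm[4]
  if (nt < wl) stop_hprfd("n_frames < window_length", "hprfd_parameter_error")
  starts <- window_starts(nt, wl, config$window_overlap)
  nw <- length(starts)
  nvox <- nz * nx * ny
  acq <- ensemble$config
  vnyq <- nyquist_velocity(acq)
  # velocity axis (wrapped), toward-transducer positive: v = -f c / (2 f0)
  f <- (seq_len(wl) - 1) / wl * (acq$prf * 1e3)
  f <- ifelse(f >= acq$prf * 1e3 / 2, f - acq$prf * 1e3, f)
  v_axis <- -f * acq$sound_speed / (2 * acq$transmit_frequency * 1e6)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)))
  Q <- poly_basis(wl, config$clutter_filter_order)

  power <- array(NA_real_, dim = c(nz, nx, ny, nw))
  maxv <- array(NA_real_, dim = c(nz, nx, ny, nw))
  meanv <- array(NA_real_, dim = c(nz, nx, ny, nw))
  m <- matrix(ensemble$samples, nrow = nvox, ncol = nt)
  pool <- numeric(0)   # subsampled bins for the pooled noise-floor estimate
  P_list <- vector("list", nw)
  absv <- abs(v_axis)
  for (w in seq_len(nw)) {
    seg <- m[, starts[w]:(starts[w] + wl - 1L), drop = FALSE]
    seg <- seg - (seg %*% Q) %*% t(Q)               # clutter filter
    seg <- sweep(seg, 2, hann, `*`)
    X <- mvfft(t(seg))                               # wl x nvox
    P <- (Re(X)^2 + Im(X)^2) / wl                    # periodogram
    P_list[[w]] <- P
    power[, , , w] <- colSums(P)
    pool <- c(pool, P[seq(1, length(P), by = 17L)])
  }
  noise_floor_lin <- max(stats::quantile(pool,
                                         config$noise_floor_percentile / 100,
                                         names = FALSE), 1e-300)
  # detection threshold calibrated to the maximum statistic of wl
  # exponential noise bins: the per-spectrum peak of pure noise sits near
  # mean * ln(wl), so the margin is applied on top of that, not on the
  # percentile floor (which would flag noise-only spectra as flow)
  noise_mean <- noise_floor_lin /
    (-log(1 - config$noise_floor_percentile / 100))
  det_thr <- noise_mean * log(wl) * db_to_pow(config$noise_margin_db)
  env_fac <- db_to_pow(config$envelope_threshold_db)
  min_v <- config$min_velocity %||% (1.5 * 2 * vnyq / wl)
  for (w in seq_len(nw)) {
    P <- P_list[[w]]
    peak <- P[cbind(max.col(t(P), ties.method = "first"), seq_len(nvox))]
    thr <- pmax(det_thr, peak * env_fac)
    cand <- P > rep(thr, each = wl)
    vm <- absv * cand                                # |v| of qualifying bins
    idx <- max.col(t(vm), ties.method = "first")
    vmax <- v_axis[idx]
    vmax[peak < det_thr] <- NA_real_                 # undetectable
    vmax[abs(vmax) < min_v] <- NA_real_              # clutter stop band
    maxv[, , , w] <- vmax
    # power-weighted mean velocity of the qualifying bins: symmetric
    # spectral broadening (transit time, acceleration) cancels, so this is
    # the unbiased flux-density estimator
    Pq <- P * cand
    vme <- colSums(Pq * v_axis) / pmax(colSums(Pq), 1e-300)
    vme[is.na(vmax)] <- NA_real_
    meanv[, , , w] <- vme
  }
  structure(list(
    frame_times = ensemble$frame_times[starts + (wl %/% 2)],
    power_map = pow_to_db(power + 1e-300),
    max_velocity_map = maxv,
    mean_velocity_map = meanv,
    noise_floor = pow_to_db(noise_floor_lin),
    # expected total power of a noise-only spectrum, on the power_map scale
    noise_power = pow_to_db(noise_mean * wl + 1e-300),
    v_axis = v_axis, v_nyq = vnyq,
    grid = ensemble$grid, spectral_config = config,
    acquisition_config = acq, beam = ensemble$beam,
    jet_depth_trace = NULL
  ), class = "velocity_maps")
}

#' Pulsed-wave Doppler spectrogram
#'
#' Time-velocity spectrogram for one spatial beam position, mirroring the
#' pulsed-wave display used for acquisition guidance.
#'
#' @param ensemble an [simulate_iq()] ensemble.
#' @param gate_bin gate-depth bin (default: all bins summed).
#' @param lateral_index,elevation_index beam position (defaults: centre).
#' @param config a [spectral_config()].
#' @return object of class `pw_spectrogram`: `power_db` (velocity x time),
#'   `v_axis` (m/s), `times` (s).
#' @export
pulsed_wave_display <- function(ensemble, gate_bin = NULL,
                                lateral_index = NULL, elevation_index = NULL,
                                config = spectral_config()) {
  dm <- dim(ensemble$samples)
  li <- lateral_index %||% ((dm[2] + 1) %/% 2)
  ei <- elevation_index %||% ((dm[3] + 1) %/% 2)
  if (li < 1 || li > dm[2] || ei < 1 || ei > dm[3])
    stop_hprfd("invalid beam position", "hprfd_parameter_error")
  sig <- if (is.null(gate_bin)) {
    sl <- ensemble$samples[, li, ei, , drop = FALSE]
    dim(sl) <- c(dm[1], dm[4])
    colSums(sl)
  } else {
    if (gate_bin < 1 || gate_bin > dm[1])
      stop_hprfd("invalid gate_bin", "hprfd_parameter_error")
    ensemble$samples[gate_bin, li, ei, ]
  }
  wl <- config$window_length
  starts <- window_starts(length(sig), wl, config$window_overlap)
  acq <- ensemble$config
  f <- (seq_len(wl) - 1) / wl * (acq$prf * 1e3)
  f <- ifelse(f >= acq$prf * 1e3 / 2, f - acq$prf * 1e3, f)
  v_axis <- -f * acq$sound_speed / (2 * acq$transmit_frequency * 1e6)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)))
  Q <- poly_basis(wl, config$clutter_filter_order)
  S <- sapply(starts, function(s) {
    x <- sig[s:(s + wl - 1L)]
    x <- x - Q %*% (t(Q) %*% x)
    X <- fft(as.vector(x) * hann)
    (Re(X)^2 + Im(X)^2) / wl
  })
  ord <- order(v_axis)
  structure(list(
    power_db = pow_to_db(S[ord, , drop = FALSE] + 1e-300),
    v_axis = v_axis[ord],
    times = ensemble$frame_times[starts + (wl %/% 2)]
  ), class = "pw_spectrogram")
}

#' @export
plot.pw_spectrogram <- function(x, ...) {
  graphics::image(x$times, x$v_axis, t(x$power_db),
                  xlab = "time (s)", ylab = "velocity (m/s)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}
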