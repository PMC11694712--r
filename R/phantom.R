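# Synthetic regurgitant-jet phantoms: orifice geometry, flow waveforms,
# jet velocity fields, hemispheric flow-convergence fields and scatterer
# clouds with known ground-truth regurgitant volume.
#
# Coordinates are beam coordinates: z = depth from the transducer
# (mm, positive away), x lateral, y elevation. Velocities are in m/s.

#' Orifice geometry of a regurgitant lesion
#'
#' Describes an elliptical regurgitant orifice, its position in beam
#' coordinates and the jet axis. Within-beat orifice-area variation is
#' modelled by modulating both semi-axes with the same time factor so the
#' instantaneous area stays analytic.
#'
#' @param semi_axis_a,semi_axis_b semi-axes of the orifice ellipse (mm),
#'   `semi_axis_a >= semi_axis_b > 0`.
#' @param center orifice centre, length-3 (mm, beam coordinates).
#' @param orientation jet axis as a length-3 vector (normalized internally);
#'   points in the direction of flow. The default points straight toward the
#'   transducer, as for aortic regurgitation imaged from the apex.
#' @param area_variation_fraction peak-to-trough fractional modulation of the
#'   orifice area within the regurgitant phase, in `[0, 1)`.
#' @return an object of class `orifice_geometry`.
#' @export
orifice_geometry <- function(semi_axis_a, semi_axis_b,
                             center = c(0, 0, 90),
                             orientation = c(0, 0, -1),
                             area_variation_fraction = 0) {
  if (!is.numeric(semi_axis_a) || !is.numeric(semi_axis_b) ||
      semi_axis_b <= 0 || semi_axis_a < semi_axis_b)
    stop_hprfd("require semi_axis_a >= semi_axis_b > 0", "hprfd_parameter_error")
  if (area_variation_fraction < 0 || area_variation_fraction >= 1)
    stop_hprfd("area_variation_fraction must be in [0, 1)", "hprfd_parameter_error")
  structure(list(
    semi_axis_a = semi_axis_a,
    semi_axis_b = semi_axis_b,
    center = as.numeric(center),
    orientation = unit_vec(as.numeric(orientation)),
    area_variation_fraction = area_variation_fraction
  ), class = "orifice_geometry")
}

#' Regurgitant flow-rate waveform
#'
#' Builds a single-phase regurgitant flow waveform Q(t) (mL/s) on a uniform
#' time grid. Aortic regurgitation is holodiastolic, mitral regurgitation
#' holosystolic; here the regurgitant phase occupies `[0, duration]` of the
#' cycle and the flow rate is zero elsewhere.
#'
#' @param phase `"diastolic"` (AR) or `"systolic"` (MR).
#' @param duration duration of the regurgitant phase (s).
#' @param peak_flow_rate peak flow rate (mL/s).
#' @param shape `"half_sine"`, `"decaying_exponential"`, `"biphasic"` or
#'   `"constant"`.
#' @param cycle_length cardiac cycle length (s).
#' @param n_samples samples on the uniform grid spanning the phase (>= 200).
#' @param tau decay constant (s) for the decaying-exponential shape.
#' @return an object of class `flow_waveform` with elements `times` (s, from
#'   phase onset), `samples` (mL/s), `phase`, `duration`, `cycle_length` and
#'   `true_rvol` (mL, trapezoidal integral of the samples).
#' @export
make_waveform <- function(phase = c("diastolic", "systolic"),
                          duration, peak_flow_rate,
                          shape = c("half_sine", "decaying_exponential",
                                    "biphasic", "constant"),
                          cycle_length = 0.8, n_samples = 256,
                          tau = duration / 3) {
  phase <- match.arg(phase)
  shape <- match.arg(shape)
  if (!is.numeric(duration) || duration <= 0)
    stop_hprfd("duration must be positive", "hprfd_parameter_error")
  if (!is.numeric(peak_flow_rate) || peak_flow_rate <= 0)
    stop_hprfd("peak_flow_rate must be positive", "hprfd_parameter_error")
  if (cycle_length < duration)
    stop_hprfd("cycle_length must be >= duration", "hprfd_parameter_error")
  n_samples <- max(200L, as.integer(n_samples))
  t <- seq(0, duration, length.out = n_samples)
  q <- switch(shape,
    half_sine = peak_flow_rate * sin(pi * t / duration),
    constant = rep(peak_flow_rate, n_samples),
    decaying_exponential = peak_flow_rate * exp(-t / tau),
    biphasic = {
      # two half-sine lobes (early filling + late lobe), non-negative
      h <- duration / 2
      q1 <- ifelse(t < h, sin(pi * t / h), 0)
      q2 <- ifelse(t >= h, 0.6 * sin(pi * (t - h) / h), 0)
      peak_flow_rate * (q1 + q2)
    })
  wf <- structure(list(
    phase = phase, duration = duration, cycle_length = cycle_length,
    times = t, samples = q,
    true_rvol = trapz(t, q)
  ), class = "flow_waveform")
  wf
}

#' Instantaneous flow rate of a waveform
#'
#' Linear interpolation of the waveform samples; zero outside the regurgitant
#' phase; time is wrapped modulo the cycle length.
#'
#' @param waveform a [make_waveform()] object.
#' @param time times (s).
#' @return flow rate (mL/s) at `time`.
#' @export
waveform_flow_rate <- function(waveform, time) {
  tc <- time %% waveform$cycle_length
  q <- rep(0, length(tc))
  inside <- tc <= waveform$duration
  if (any(inside))
    q[inside] <- approx(waveform$times, waveform$samples, xout = tc[inside],
                        rule = 2)$y
  q
}

#' Regurgitant-jet phantom
#'
#' Combines an orifice, a flow waveform and jet kinematics into a phantom
#' with known ground-truth regurgitant volume. The jet core is a
#' non-spreading elliptical cylinder of length `core_length` along the jet
#' axis (the near-orifice high-velocity core that the 3D HPRF Doppler method
#' samples); entrainment and spreading are not modelled. Valve-plane
#' excursion displaces the jet laterally (along +x) as a sinusoid at the
#' cycle frequency.
#'
#' @param orifice an [orifice_geometry()]; its `orientation` is overridden
#'   when `jet_angle` is given (the default) to a tilt of `jet_angle` degrees
#'   from the beam axis in the x-z plane.
#' @param waveform a [make_waveform()] object.
#' @param jet_angle beam-to-jet angle (degrees, in `[0, 90]`); `NULL` keeps
#'   the orientation stored in `orifice`.
#' @param direction `"toward"` (aortic regurgitation seen from the apex) or
#'   `"away"` (mitral regurgitation): sign of the axial flow component.
#' @param lateral_excursion amplitude (mm) of the sinusoidal lateral jet
#'   displacement over the cycle.
#' @param core_length length of the jet core (mm); default 20 mm, the sample
#'   volume length.
#' @param profile `"top_hat"` (plug flow, core speed Q/A) or `"parabolic"`
#'   (centreline speed 2 Q/A).
#' @return an object of class `jet_phantom`.
#' @export
jet_phantom <- function(orifice, waveform, jet_angle = 0,
                        direction = c("toward", "away"),
                        lateral_excursion = 0, core_length = 20,
                        profile = c("top_hat", "parabolic")) {
  direction <- match.arg(direction)
  profile <- match.arg(profile)
  stopifnot(inherits(orifice, "orifice_geometry"),
            inherits(waveform, "flow_waveform"))
  if (!is.null(jet_angle)) {
    if (jet_angle < 0 || jet_angle > 90)
      stop_hprfd("jet_angle must be in [0, 90] degrees", "hprfd_parameter_error")
    th <- jet_angle * pi / 180
    zsgn <- if (direction == "toward") -1 else 1
    orifice$orientation <- c(sin(th), 0, zsgn * cos(th))
  }
  structure(list(
    orifice = orifice, waveform = waveform,
    jet_angle = jet_angle %||% NA_real_,
    direction = direction,
    lateral_excursion = lateral_excursion,
    core_length = core_length,
    profile = profile,
    true_rvol = waveform$true_rvol
  ), class = "jet_phantom")
}

#' Ground-truth regurgitant volume of a phantom
#'
#' Trapezoidal integral of the flow waveform over the regurgitant phase.
#'
#' @param phantom a [jet_phantom()] (or a bare [make_waveform()]).
#' @return regurgitant volume (mL).
#' @export
true_rvol <- function(phantom) {
  wf <- if (inherits(phantom, "flow_waveform")) phantom else phantom$waveform
  trapz(wf$times, wf$samples)
}

# Orthonormal cross-section basis (e1, e2) perpendicular to the jet axis u.
jet_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Semi-axis modulation factor g(t) (both axes scaled by g, area by g^2):
# area(t) = A0 * (1 - f * h(t)) with h a raised cosine in the regurgitant
# phase, giving peak-to-trough area modulation f.
orifice_modulation <- function(phantom, time) {
  f <- phantom$orifice$area_variation_fraction
  if (f <= 0) return(rep(1, length(time)))
  tc <- time %% phantom$waveform$cycle_length
  h <- ifelse(tc <= phantom$waveform$duration,
              (1 - cos(2 * pi * tc / phantom$waveform$duration)) / 2, 0)
  sqrt(pmax(1 - f * h, 1e-6))
}

#' Jet velocity field
#'
#' Evaluates the phantom's 3D velocity field. Inside the displaced elliptical
#' core the velocity is directed along the jet axis with speed set by the
#' instantaneous flow rate and orifice area (top-hat: Q/A everywhere;
#' parabolic: 2 Q/A (1 - r^2) with r the normalized elliptical radius);
#' outside the core the velocity is zero. Time wraps modulo the cycle length.
#'
#' @param phantom a [jet_phantom()].
#' @param position length-3 vector or n-by-3 matrix of positions (mm).
#' @param time scalar time (s).
#' @return n-by-3 matrix of velocities (m/s).
#' @export
jet_velocity <- function(phantom, position, time) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  n <- nrow(p)
  v <- matrix(0, n, 3)
  q <- waveform_flow_rate(phantom$waveform, time)
  if (q <= 0) return(v)
  g <- orifice_modulation(phantom, time)
  a <- phantom$orifice$semi_axis_a * g
  b <- phantom$orifice$semi_axis_b * g
  area_mm2 <- pi * a * b
  u <- phantom$orifice$orientation
  bas <- jet_basis(u)
  exc <- phantom$lateral_excursion *
    sin(2 * pi * (time %% phantom$waveform$cycle_length) /
          phantom$waveform$cycle_length)
  ctr <- phantom$orifice$center + c(exc, 0, 0)
  d <- sweep(p, 2, ctr)
  s <- as.vector(d %*% u)
  rad <- d - s %*% t(u)
  r2 <- as.vector((rad %*% bas$e1 / a)^2 + (rad %*% bas$e2 / b)^2)
  inside <- s >= 0 & s <= phantom$core_length & r2 <= 1
  if (!any(inside)) return(v)
  # Q mL/s over area mm^2: mean speed in m/s equals Q/A numerically
  mean_speed <- q / area_mm2
  sp <- if (phantom$profile == "top_hat") rep(mean_speed, n)
        else 2 * mean_speed * (1 - r2)
  v[inside, ] <- sp[inside] %o% u
  v
}

#' Hemispheric flow-convergence (PISA) velocity field
#'
#' Radial inflow speed on the upstream side of the orifice under the
#' hemispheric convergence assumption: all of the flow rate Q passes through
#' a hemisphere of radius r, so the speed is Q / (2 pi r^2), directed toward
#' the orifice centre.
#'
#' @param flow_rate instantaneous flow rate Q (mL/s), >= 0.
#' @param orifice_center unused placeholder for the field origin (mm).
#' @param radius distance(s) from the orifice centre (mm), > 0.
#' @return radial speed(s) (cm/s), directed toward `orifice_center`.
#' @export
pisa_velocity_field <- function(flow_rate, orifice_center = c(0, 0, 90),
                                radius) {
  if (any(radius <= 0))
    stop_hprfd("radius must be positive", "hprfd_parameter_error")
  if (any(flow_rate < 0))
    stop_hprfd("flow_rate must be non-negative", "hprfd_parameter_error")
  # Q mL/s = 1000 mm^3/s; speed mm/s = 1000*Q/(2 pi r^2); cm/s = /10
  100 * flow_rate / (2 * pi * radius^2)
}

#' Scatterer cloud for a jet phantom
#'
#' Seeds blood scatterers in the swept jet-core region, quasi-static tissue
#' clutter through the surrounding volume, and (optionally) strong discrete
#' reflectors in the near field, as found in the LV apical area. Blood
#' scatterer counts are Poisson with mean `density * volume`; amplitudes are
#' Gaussian (fully developed speckle). Clutter amplitudes are
#' `clutter_level` dB above blood RMS, reflector amplitudes
#' `apical_reflector_gain` dB above blood RMS (>= 40 dB).
#'
#' @param phantom a [jet_phantom()].
#' @param density blood scatterer density (per mm^3).
#' @param clutter_level clutter amplitude above blood (dB).
#' @param clutter_density clutter scatterer density (per mm^3).
#' @param apical_reflector_gain reflector amplitude above blood (dB, >= 40).
#' @param n_reflectors number of discrete near-field reflectors.
#' @param reflector_depth depth (mm) at which reflectors sit.
#' @param reflector_spread lateral half-extent (mm) of the reflector patch.
#' @param reflector_depth_spread axial half-extent (mm) of the reflector
#'   patch.
#' @param margin padding (mm) added around the swept core for blood seeding.
#' @param seed RNG seed (required; the cloud is reproducible given the seed).
#' @return an object of class `scatterer_cloud` with fields `positions`
#'   (n x 3 mm), `velocities` (n x 3 m/s, the field at seeding time),
#'   `amplitudes`, `class` (`blood`, `tissue_clutter`, `apical_reflector`)
#'   and `drift` (n x 3 m/s clutter drift, |drift| <= 2 cm/s).
#' @export
make_scatterers <- function(phantom, density = 0.5, clutter_level = 40,
                            clutter_density = 0.02,
                            apical_reflector_gain = 60,
                            n_reflectors = 0, reflector_depth = 20,
                            reflector_spread = 4,
                            reflector_depth_spread = 2,
                            margin = 3, seed) {
  if (missing(seed)) stop_hprfd("seed is required", "hprfd_parameter_error")
  if (density <= 0) stop_hprfd("density must be positive", "hprfd_parameter_error")
  if (apical_reflector_gain < 40)
    stop_hprfd("apical_reflector_gain must be >= 40 dB", "hprfd_parameter_error")
  orif <- phantom$orifice
  u <- orif$orientation
  L <- phantom$core_length
  # bounding box of the swept core: endpoints +- the core's radial extent
  # projected on each axis, plus excursion (x) and a small margin
  ends <- rbind(orif$center, orif$center + L * u)
  bas <- jet_basis(u)
  radial <- sqrt((orif$semi_axis_a * bas$e1)^2 +
                 (orif$semi_axis_b * bas$e2)^2) + margin
  exc <- abs(phantom$lateral_excursion)
  lo <- apply(ends, 2, min) - radial - c(exc, 0, 0)
  hi <- apply(ends, 2, max) + radial + c(exc, 0, 0)
  lo[3] <- max(lo[3], 1)
  vol <- prod(hi - lo)
  if (vol <= 0) stop_hprfd("empty seeding volume", "hprfd_parameter_error")
  with_seed(seed, {
    nb <- rpois(1, density * vol)
    pb <- cbind(runif(nb, lo[1], hi[1]), runif(nb, lo[2], hi[2]),
                runif(nb, lo[3], hi[3]))
    # clutter occupies a larger shell around the gate region
    clo <- lo - 10; chi <- hi + 10; clo[3] <- max(clo[3], 1)
    nc <- rpois(1, clutter_density * prod(chi - clo))
    pc <- cbind(runif(nc, clo[1], chi[1]), runif(nc, clo[2], chi[2]),
                runif(nc, clo[3], chi[3]))
    nr <- n_reflectors
    pr <- if (nr > 0)
      cbind(runif(nr, -reflector_spread, reflector_spread),
            runif(nr, -reflector_spread, reflector_spread),
            reflector_depth + runif(nr, -reflector_depth_spread,
                                    reflector_depth_spread))
      else matrix(0, 0, 3)
    pos <- rbind(pb, pc, pr)
    cls <- c(rep("blood", nb), rep("tissue_clutter", nc),
             rep("apical_reflector", nr))
    amp <- c(rnorm(nb), db_to_amp(clutter_level) * rnorm(nc),
             db_to_amp(apical_reflector_gain) * rep(1, nr))
    # quasi-static clutter drift, <= 2 cm/s
    drift <- matrix(0, nrow(pos), 3)
    if (nc > 0) {
      dv <- matrix(rnorm(3 * nc), nc, 3)
      dv <- dv / pmax(sqrt(rowSums(dv^2)), 1e-12) *
        runif(nc, 0, 0.02)
      drift[nb + seq_len(nc), ] <- dv
    }
    vel <- jet_velocity(phantom, pos, 0) + drift
    structure(list(
      positions = pos, velocities = vel, amplitudes = amp,
      class = factor(cls, levels = c("blood", "tissue_clutter",
                                     "apical_reflector")),
      drift = drift,
      coherence_phase = runif(nrow(pos), 0, 2 * pi),
      phantom = phantom, seed = seed
    ), class = "scatterer_cloud")
  })
}

#' @export
print.jet_phantom <- function(x, ...) {
  cat("Regurgitant-jet phantom\n")
  cat(sprintf("  orifice: %.1f x %.1f mm semi-axes at depth %.1f mm\n",
              x$orifice$semi_axis_a, x$orifice$semi_axis_b,
              x$orifice$center[3]))
  cat(sprintf("  waveform: %s %s, %.0f ms, true RVol %.2f mL\n",
              x$waveform$phase,
              if (x$direction == "toward") "(toward transducer)" else "(away)",
              1000 * x$waveform$duration, x$true_rvol))
  cat(sprintf("  jet angle %.0f deg, excursion %.1f mm, %s profile\n",
              x$jet_angle, x$lateral_excursion, x$profile))
  invisible(x)
}
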