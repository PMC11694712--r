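# Comparator quantifications: 2D PISA regurgitant volume with temporal
# averaging and multi-jet summation, phase-contrast flow quantification
# with second-degree polynomial background correction, indirect mitral
# RVol, disc-summation ventricular volume, and severity categorization.

#' 2D PISA regurgitant volume
#'
#' Per measurement the flow rate is `Q = 2 pi r^2 Va` (hemispheric
#' isovelocity shell at aliasing velocity `Va`); with temporal averaging the
#' flow rate is averaged over the time points of each jet (holosystolic
#' regurgitation with markedly varying flow rate should supply at least
#' three time points). The effective regurgitant orifice area is
#' `EROA = Q / Vmax` and `RVol = EROA * VTI` from the continuous-wave
#' Doppler envelope. With two clearly separated jets, PISA is performed on
#' both and the RVols added together.
#'
#' @param measurements data.frame with columns `r_mm` (PISA radius, mm),
#'   `va_cm_s` (aliasing velocity, cm/s) and optionally `jet_id` and
#'   `time_s`.
#' @param vmax_m_s peak jet velocity from the CW envelope (m/s).
#' @param vti_cm velocity-time integral of the CW envelope (cm).
#' @param average_over_time average the per-jet flow rate over time points.
#' @return list: `flow_rate` (mL/s, summed over jets), `eroa` (mm^2),
#'   `rvol` (mL), and the per-jet breakdown `per_jet`.
#' @export
pisa_rvol <- function(measurements, vmax_m_s, vti_cm,
                      average_over_time = FALSE) {
  if (!nrow(measurements))
    stop_hprfd("at least one PISA measurement required",
               "hprfd_parameter_error")
  if (missing(vmax_m_s) || missing(vti_cm) ||
      is.null(vmax_m_s) || is.null(vti_cm) ||
      is.na(vmax_m_s) || is.na(vti_cm))
    stop_hprfd("missing continuous-wave Doppler envelope (Vmax/VTI)",
               "hprfd_infeasible")
  if (any(measurements$r_mm <= 0) || any(measurements$va_cm_s <= 0))
    stop_hprfd("PISA radius and aliasing velocity must be positive",
               "hprfd_parameter_error")
  if (vmax_m_s <= 0 || vti_cm <= 0)
    stop_hprfd("Vmax and VTI must be positive", "hprfd_parameter_error")
  jet <- as.character(measurements$jet_id %||% rep("jet1",
                                                   nrow(measurements)))
  # Q mL/s from r in mm and Va in cm/s: 2*pi*r^2*Va * 10 mm^3/s / 1000
  q <- 2 * pi * measurements$r_mm^2 * measurements$va_cm_s / 100
  per_jet <- lapply(split(q, jet), function(qj) {
    if (average_over_time) {
      if (length(qj) < 3)
        warning("temporal averaging requested with fewer than 3 time points")
      qe <- mean(qj)
    } else qe <- qj[length(qj)]
    eroa <- qe / vmax_m_s                 # mL/s over m/s gives mm^2
    list(flow_rate = qe, eroa = eroa, rvol = eroa * vti_cm / 100)
  })
  list(flow_rate = sum(vapply(per_jet, `[[`, 0, "flow_rate")),
       eroa = sum(vapply(per_jet, `[[`, 0, "eroa")),
       rvol = sum(vapply(per_jet, `[[`, 0, "rvol")),
       per_jet = per_jet)
}

#' PISA flow rate measured on a convergence field
#'
#' Samples a radial-speed profile, finds the isovelocity radius where the
#' speed equals the chosen aliasing velocity (linear interpolation between
#' samples), and applies `Q = 2 pi r^2 Va`. On an exact hemispheric field
#' the recovered flow rate is independent of the chosen `Va`; on a
#' funnel-shaped (non-hemispheric) convergence it is biased.
#'
#' @param field function of radius (mm) returning radial speed (cm/s), e.g.
#'   built on [pisa_velocity_field()].
#' @param va_cm_s chosen aliasing velocity (cm/s).
#' @param r_max largest radius sampled (mm).
#' @param dr radial sampling (mm).
#' @return recovered flow rate (mL/s).
#' @export
pisa_on_phantom <- function(field, va_cm_s, r_max = 40, dr = 0.1) {
  r <- seq(dr, r_max, by = dr)
  sp <- field(r)
  if (all(sp < va_cm_s))
    stop_hprfd("aliasing velocity above the field maximum: no isosurface",
               "hprfd_infeasible")
  # outermost radius where speed still exceeds Va (speed decays outward)
  i <- max(which(sp >= va_cm_s))
  if (i == length(r)) {
    r_iso <- r[i]
  } else {
    r_iso <- r[i] + (sp[i] - va_cm_s) / (sp[i] - sp[i + 1]) * dr
  }
  2 * pi * r_iso^2 * va_cm_s / 100
}

#' Second-degree polynomial background correction
#'
#' Least-squares fit of a full second-degree 2D polynomial (6 coefficients:
#' 1, x, y, x^2, xy, y^2) to a reference phase image (a stationary phantom
#' recording, or stationary tissue), subtracted from the target phase image
#' to remove background phase offsets from magnetic field inaccuracies.
#'
#' @param phase_image phase image (radians, matrix).
#' @param reference_phase reference phase image, same shape.
#' @param mask optional logical matrix marking reference pixels (default:
#'   all); at least 6 pixels are required.
#' @return corrected phase image.
#' @export
pc_background_correct <- function(phase_image, reference_phase,
                                  mask = NULL) {
  stopifnot(all(dim(phase_image) == dim(reference_phase)))
  nx <- nrow(phase_image); ny <- ncol(phase_image)
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  if (sum(mask) < 6)
    stop_hprfd("reference mask must contain at least 6 pixels",
               "hprfd_underdetermined")
  x <- rep(seq_len(nx), times = ny); y <- rep(seq_len(ny), each = nx)
  x <- (x - mean(x)) / nx; y <- (y - mean(y)) / ny
  B <- cbind(1, x, y, x^2, x * y, y^2)
  m <- as.vector(mask)
  coef <- qr.solve(B[m, , drop = FALSE], as.vector(reference_phase)[m])
  phase_image - matrix(B %*% coef, nx, ny)
}

#' Phase-contrast through-plane flow quantification
#'
#' Converts pixel phase to velocity (`v = VENC * phase / pi`), integrates
#' over the region of interest per frame and over the cycle: the forward
#' stroke volume is the integral of positive flow, the regurgitant volume
#' the magnitude of the integral of negative flow. Any ROI pixel at phase
#' wrap (`|phase| >= pi`) raises an aliasing error; such recordings are
#' discarded rather than unwrapped.
#'
#' @param phase_images array (`nx x ny x n_frames`) of corrected phase
#'   (radians).
#' @param venc_cm_s velocity encoding limit (cm/s); phase +-pi corresponds
#'   to +-VENC.
#' @param pixel_area_mm2 pixel area (mm^2).
#' @param roi_mask logical matrix (`nx x ny`).
#' @param frame_times frame times (s).
#' @return list: `forward_sv` (mL), `rvol` (mL), `q_ml_s` per frame.
#' @export
pc_flow_quantify <- function(phase_images, venc_cm_s, pixel_area_mm2,
                             roi_mask, frame_times) {
  if (venc_cm_s <= 0) stop_hprfd("venc must be positive",
                                 "hprfd_parameter_error")
  dm <- dim(phase_images)
  nf <- dm[3]
  m <- as.vector(roi_mask)
  q <- numeric(nf)
  for (k in seq_len(nf)) {
    ph <- phase_images[, , k][m]
    if (any(abs(ph) >= pi - 1e-12))
      stop_hprfd("phase aliasing inside ROI: recording discarded",
                 "hprfd_aliasing_error")
    v <- venc_cm_s * ph / pi                       # cm/s
    q[k] <- sum(v * 10 * pixel_area_mm2) / 1000    # mL/s
  }
  list(forward_sv = trapz(frame_times, pmax(q, 0)),
       rvol = abs(trapz(frame_times, pmin(q, 0))),
       q_ml_s = q)
}

#' Indirect mitral regurgitant volume
#'
#' `RVol = LV stroke volume - aortic stroke volume`. A negative result is
#' returned with a quality flag rather than clamped.
#'
#' @param lv_sv_ml left-ventricular stroke volume (mL, disc summation).
#' @param aortic_sv_ml aortic forward stroke volume (mL, phase contrast).
#' @return list: `rvol` (mL, possibly negative), `quality_flag`.
#' @export
mitral_rvol_indirect <- function(lv_sv_ml, aortic_sv_ml) {
  if (lv_sv_ml < 0 || aortic_sv_ml < 0)
    stop_hprfd("stroke volumes must be non-negative",
               "hprfd_parameter_error")
  rv <- lv_sv_ml - aortic_sv_ml
  list(rvol = rv, quality_flag = if (rv < 0) "negative_rvol" else "ok")
}

#' Disc-summation ventricular volume
#'
#' Volume of a short-axis stack as the sum of slice areas times the slice
#' thickness (8 mm without gaps in the imaging protocol emulated here).
#'
#' @param slice_areas_mm2 per-slice cavity areas (mm^2).
#' @param slice_thickness_mm slice thickness (mm), > 0.
#' @return volume (mL).
#' @export
lv_volume_disc_summation <- function(slice_areas_mm2, slice_thickness_mm = 8) {
  if (!length(slice_areas_mm2))
    stop_hprfd("empty slice stack", "hprfd_parameter_error")
  if (slice_thickness_mm <= 0)
    stop_hprfd("slice thickness must be positive", "hprfd_parameter_error")
  sum(slice_areas_mm2) * slice_thickness_mm / 1000
}

#' Severity grade from regurgitant volume
#'
#' Categorizes RVol into mild (< 30 mL), moderate (30-59 mL) and severe
#' (>= 60 mL); the bins are exhaustive and non-overlapping and apply to
#' both aortic and mitral regurgitation.
#'
#' @param rvol_ml regurgitant volume(s) (mL, >= 0).
#' @return ordered factor with levels `mild < moderate < severe`.
#' @export
grade_severity <- function(rvol_ml) {
  if (any(is.na(rvol_ml)) || any(rvol_ml < 0))
    stop_hprfd("rvol must be non-negative", "hprfd_parameter_error")
  cut(rvol_ml, breaks = c(-Inf, 30, 60, Inf), right = FALSE,
      labels = c("mild", "moderate", "severe"), ordered_result = TRUE)
}
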