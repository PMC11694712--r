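# Reference quantifications: PISA, phase-contrast flow, indirect mitral
# RVol, disc summation, severity grading.

test_that("PISA RVol reproduces the hand-worked example and sums jets", {
  # r = 10 mm, Va = 40 cm/s, Vmax = 5 m/s, VTI = 150 cm
  res <- pisa_rvol(data.frame(r_mm = 10, va_cm_s = 40), 5, 150)
  expect_equal(res$flow_rate, 2 * pi * 100 * 40 / 100, tolerance = 1e-6)
  expect_equal(res$flow_rate, 251.327, tolerance = 1e-3)
  expect_equal(res$eroa, 50.265, tolerance = 1e-3)
  expect_equal(res$rvol, 75.398, tolerance = 1e-3)

  # two identical jets double the RVol exactly
  two <- pisa_rvol(data.frame(r_mm = c(10, 10), va_cm_s = c(40, 40),
                              jet_id = c("a", "b")), 5, 150)
  expect_equal(two$rvol, 2 * res$rvol, tolerance = 1e-12)

  # temporal average of a constant flow equals the single-time value
  avg <- pisa_rvol(data.frame(r_mm = rep(10, 3), va_cm_s = rep(40, 3),
                              time_s = c(0.1, 0.2, 0.3)), 5, 150,
                   average_over_time = TRUE)
  expect_equal(avg$rvol, res$rvol, tolerance = 1e-12)
  expect_warning(pisa_rvol(data.frame(r_mm = c(10, 10),
                                      va_cm_s = c(40, 40)), 5, 150,
                           average_over_time = TRUE), "fewer than 3")

  # a missing CW envelope is an infeasibility, not a number
  expect_error(pisa_rvol(data.frame(r_mm = 10, va_cm_s = 40), NA, 150),
               class = "hprfd_infeasible")
})

test_that("PISA on an exact hemispheric field is unbiased and Va-invariant", {
  q_true <- 200
  field <- function(r) pisa_velocity_field(q_true, radius = r)
  q40 <- pisa_on_phantom(field, 40)
  expect_equal(q40, q_true, tolerance = 0.03 * q_true)
  # invariance across a decade of aliasing velocities
  qs <- vapply(c(10, 20, 40, 80, 100), function(va)
    pisa_on_phantom(field, va), numeric(1))
  expect_lt(max(abs(qs / q_true - 1)), 0.03)
  # Va above the field maximum: no isosurface
  expect_error(pisa_on_phantom(field, 1e6), class = "hprfd_infeasible")
  # funnel-shaped convergence (flow constrained to a partial cone with
  # solid angle < hemisphere) biases the hemispheric formula upward
  funnel <- function(r) 100 * q_true / (pi * r^2)   # half the hemisphere
  q_fun <- pisa_on_phantom(funnel, 40)
  expect_gt(q_fun / q_true, 1.5)
})

test_that("quadratic background correction is exact and idempotent", {
  nx <- 24; ny <- 20
  xg <- (seq_len(nx) - (nx + 1) / 2) / nx
  yg <- (seq_len(ny) - (ny + 1) / 2) / ny
  X <- outer(xg, rep(1, ny)); Y <- outer(rep(1, nx), yg)
  bg <- 0.05 + 0.01 * X - 0.02 * Y^2 + 0.03 * X * Y + 0.015 * X^2
  # reference exactly quadratic: residual at machine precision
  corr <- pc_background_correct(bg, bg)
  expect_lt(max(abs(corr)), 1e-10)
  # zero reference: identity
  expect_equal(pc_background_correct(bg, matrix(0, nx, ny)), bg)
  # flow + quadratic background: flow recovered to machine precision
  flow <- matrix(0, nx, ny); flow[8:16, 6:14] <- 0.8
  rec <- pc_background_correct(flow + bg, bg)
  expect_equal(rec, flow, tolerance = 1e-12)
  # idempotent: correcting an already-corrected image changes nothing
  expect_equal(pc_background_correct(rec, bg * 0), rec)
  expect_error(pc_background_correct(bg, bg, mask = matrix(FALSE, nx, ny)),
               class = "hprfd_underdetermined")
})

test_that("phase-contrast flow separates forward and regurgitant volumes", {
  # uniform 1 m/s over a circular ROI of radius 10 mm: Q = 314.16 mL/s
  nx <- 30; pix <- 1
  rr <- sqrt(outer((seq_len(nx) - 15.5)^2, (seq_len(nx) - 15.5)^2, `+`))
  roi <- rr * pix <= 10
  area <- sum(roi) * pix^2
  venc <- 170
  ph1 <- array(pi * (100 / venc) * roi, dim = c(nx, nx, 1))  # 1 m/s
  res1 <- pc_flow_quantify(ph1, venc, pix^2, roi, 0)
  expect_equal(res1$q_ml_s, 100 * 10 * area / 1000, tolerance = 1e-10)
  expect_equal(res1$q_ml_s, 314.159, tolerance = 0.03 * 314)

  # biphasic waveform with known forward 100 mL and reverse 20 mL
  nt <- 60; tt <- seq(0, 1, length.out = nt)
  qf <- ifelse(tt < 0.4, sin(pi * tt / 0.4), 0)
  qf <- qf * 100 / hprfdoppler:::trapz(tt, qf)
  qr <- ifelse(tt >= 0.5, sin(pi * (tt - 0.5) / 0.5), 0)
  qr <- qr * 20 / hprfdoppler:::trapz(tt, qr)
  q <- qf - qr                                    # mL/s
  ph <- array(0, dim = c(nx, nx, nt))
  for (k in seq_len(nt)) {
    v_cm <- q[k] * 1000 / area / 10
    ph[, , k] <- pi * v_cm / venc * roi
  }
  res <- pc_flow_quantify(ph, venc, pix^2, roi, tt)
  expect_equal(res$forward_sv, 100, tolerance = 0.01 * 100)
  expect_equal(res$rvol, 20, tolerance = 0.01 * 20)

  # 180 cm/s against VENC 170 cm/s wraps: recording discarded
  ph_alias <- array(pi * (180 / 170) * roi, dim = c(nx, nx, 1))
  ph_alias <- pmin(ph_alias, pi)   # wrap bound
  expect_error(pc_flow_quantify(ph_alias, venc, pix^2, roi, 0),
               class = "hprfd_aliasing_error")
})

test_that("indirect mitral RVol subtracts aortic from LV stroke volume", {
  expect_equal(mitral_rvol_indirect(120, 95)$rvol, 25)
  expect_equal(mitral_rvol_indirect(100, 100)$rvol, 0)
  neg <- mitral_rvol_indirect(90, 100)
  expect_equal(neg$rvol, -10)
  expect_equal(neg$quality_flag, "negative_rvol")
  expect_error(mitral_rvol_indirect(-5, 10),
               class = "hprfd_parameter_error")
})

test_that("disc summation integrates slice areas, matching a sphere", {
  expect_equal(lv_volume_disc_summation(rep(2000, 10), 8), 160)
  expect_equal(lv_volume_disc_summation(rep(0, 5), 8), 0)
  # sphere of radius 40 mm discretized at 8 mm slices
  R <- 40; th <- 8
  centers <- seq(-R + th / 2, R - th / 2, by = th)
  areas <- pi * (R^2 - centers^2)
  vol <- lv_volume_disc_summation(areas, th)
  expect_equal(vol, 4 / 3 * pi * R^3 / 1000, tolerance = 0.05)
  expect_error(lv_volume_disc_summation(numeric(0), 8),
               class = "hprfd_parameter_error")
})

test_that("severity grading uses the 30/60 mL bins, right-open", {
  expect_equal(as.character(grade_severity(c(15, 45, 60))),
               c("mild", "moderate", "severe"))
  expect_equal(as.character(grade_severity(c(0, 29.99, 30, 59.99, 200))),
               c("mild", "mild", "moderate", "moderate", "severe"))
  # monotone non-decreasing in RVol
  g <- grade_severity(seq(0, 100, by = 0.5))
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_error(grade_severity(-1), class = "hprfd_parameter_error")
})
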