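# Estimation chain components: segmentation, flow integration, feasibility.

make_fake_maps <- function(maxv, power = NULL, grid_x, grid_y, grid_z,
                           frame_times, v_nyq = 2.31, wl = 128,
                           noise_floor = -60) {
  structure(list(
    frame_times = frame_times,
    power_map = power %||% array(0, dim = dim(maxv)),
    max_velocity_map = maxv,
    mean_velocity_map = maxv,
    noise_floor = noise_floor,
    noise_power = noise_floor,
    v_axis = seq(-v_nyq, v_nyq, length.out = wl),
    v_nyq = v_nyq,
    grid = list(x = grid_x, y = grid_y, z = grid_z),
    beam = standard_beam(), jet_depth_trace = NULL
  ), class = "velocity_maps")
}

test_that("ellipse segmentation round-trips a known ellipse", {
  beam <- standard_beam()
  gx <- seq(-12, 12, by = 2); gy <- seq(-12, 12, by = 2)
  truth <- list(cx = 1, cy = -0.5, a = 5, b = 3, rot = 20)
  obs <- hprfdoppler:::cpp_ellipse_model_image(
    truth$cx, truth$cy, truth$a, truth$b, truth$rot, gx, gy,
    hprfdoppler:::beam_psf_sigma(beam, 90)[1],
    hprfdoppler:::beam_psf_sigma(beam, 90)[2], 0.5,
    hprfdoppler:::beam_w_pair(beam, 90)[1],
    hprfdoppler:::beam_w_pair(beam, 90)[2])
  img_db <- 10 * log10(obs / max(obs) + 1e-300)
  fit <- segment_cross_section(img_db, beam, 90, gx, gy)
  expect_equal(fit$area, pi * 5 * 3, tolerance = 0.05)
  expect_equal(fit$center, c(1, -0.5), tolerance = 0.3)
  expect_lt(fit$fit_residual, 0.01)
  expect_gte(fit$semi_axes[1], fit$semi_axes[2])
})

test_that("circularly symmetric images give a nearly circular fit", {
  beam <- standard_beam()
  gx <- seq(-12, 12, by = 2)
  obs <- hprfdoppler:::cpp_ellipse_model_image(
    0, 0, 4, 4, 0, gx, gx,
    hprfdoppler:::beam_psf_sigma(beam, 90)[1],
    hprfdoppler:::beam_psf_sigma(beam, 90)[2], 0.5,
    hprfdoppler:::beam_w_pair(beam, 90)[1],
    hprfdoppler:::beam_w_pair(beam, 90)[2])
  fit <- segment_cross_section(10 * log10(obs / max(obs)), beam, 90, gx, gx)
  expect_equal(unname(fit$semi_axes[1] / fit$semi_axes[2]), 1,
               tolerance = 0.1)
})

test_that("segmentation tolerates 20 dB image noise (median over seeds)", {
  beam <- standard_beam()
  gx <- seq(-12, 12, by = 2)
  psf <- hprfdoppler:::beam_psf_sigma(beam, 90)
  env <- hprfdoppler:::beam_w_pair(beam, 90)
  clean <- hprfdoppler:::cpp_ellipse_model_image(0, 0, 5, 3.5, 10, gx, gx,
                                                 psf[1], psf[2], 0.5,
                                                 env[1], env[2])
  clean <- clean / max(clean)
  # multiplicative (speckle-like) 20 dB noise; the pipeline subtracts the
  # additive noise pedestal before segmentation, so the residual noise on
  # the image is multiplicative
  areas <- vapply(1:100, function(s) {
    noisy <- pmax(clean * (1 + hprfdoppler:::with_seed(s,
      matrix(rnorm(length(clean), 0, 0.1), nrow(clean)))), 1e-9)
    segment_cross_section(10 * log10(noisy), beam, 90, gx, gx)$area
  }, numeric(1))
  expect_lt(abs(stats::median(areas) / (pi * 5 * 3.5) - 1), 0.15)
})

test_that("segmentation refuses images below the noise floor", {
  img <- matrix(-100, 9, 9)
  expect_error(segment_cross_section(img, standard_beam(), 90,
                                     seq(-8, 8, 2), seq(-8, 8, 2),
                                     noise_floor_db = -60),
               class = "hprfd_no_flow_error")
})

test_that("flow rate integrates |v| * area over the fitted ellipse", {
  # uniform 4 m/s over a 0.4 cm^2 = 40 mm^2 cross-section on a fine grid
  gx <- seq(-8, 8, by = 0.25); gy <- gx
  a <- 4; b <- 40 / (4 * pi)
  inside <- outer(gx^2 / a^2, gy^2 / b^2, `+`) <= 1
  maxv <- array(NA_real_, dim = c(1, length(gx), length(gy), 1))
  maxv[1, , , 1] <- ifelse(inside, 4, NA)
  maps <- make_fake_maps(maxv, grid_x = gx, grid_y = gy, grid_z = 90,
                         frame_times = 0)
  fit <- structure(list(center = c(0, 0), semi_axes = c(a = a, b = b),
                        rotation = 0, area = pi * a * b, fit_residual = 0),
                   class = "ellipse_fit")
  q <- flow_rate_curve(maps, list(fit), trace = 90)
  expect_equal(q, 160, tolerance = 0.02)
  # zero-velocity frame contributes zero
  maxv[1, , , 1] <- NA
  maps0 <- make_fake_maps(maxv, grid_x = gx, grid_y = gy, grid_z = 90,
                          frame_times = 0)
  expect_equal(flow_rate_curve(maps0, list(fit), trace = 90), 0)
})

test_that("temporal integration recovers volumes and converges", {
  t1 <- seq(0, 0.3, length.out = 40)
  r1 <- integrate_rvol(rep(100, 40), t1)
  expect_equal(r1$rvol, 30, tolerance = 1e-10)
  # doubling the frame rate changes a smooth integral by < 1%
  t2 <- seq(0, 0.3, length.out = 80)
  q1 <- 150 * sin(pi * t1 / 0.3); q2 <- 150 * sin(pi * t2 / 0.3)
  v1 <- integrate_rvol(q1, t1)$rvol; v2 <- integrate_rvol(q2, t2)$rvol
  expect_lt(abs(v2 - v1) / v1, 0.01)
  expect_error(integrate_rvol(c(0, 0, 5), c(0, 0.1, 0.2)),
               class = "hprfd_insufficient_data")
})

test_that("feasibility rules fire for the three failure modes", {
  gx <- seq(-8, 8, 2); gz <- seq(85, 95, 2)
  nt <- 30; tt <- seq(0, 0.3, length.out = nt)
  nz <- length(gz); nx <- length(gx)
  # alias pile-up: envelope folded to the wrong sign at high |v|
  maxv <- array(NA_real_, dim = c(nz, nx, nx, nt))
  maxv[3, 4:6, 4:6, ] <- -1.62          # toward jet reading away
  pw <- array(-30, dim = dim(maxv)); pw[3, 4:6, 4:6, ] <- 0
  maps <- make_fake_maps(maxv, pw, gx, gx, gz, tt, noise_floor = -30)
  trace <- rep(89, nt)
  f <- assess_feasibility(maps, trace, expected_direction = "toward")
  expect_false(f$feasible)
  expect_equal(f$reason, "insufficient_prf")
  # envelope parked within one bin of +v_nyq is also alias pile-up
  maxv2 <- maxv; maxv2[3, 4:6, 4:6, ] <- 2.31
  f2 <- assess_feasibility(make_fake_maps(maxv2, pw, gx, gx, gz, tt,
                                          noise_floor = -30),
                           trace, expected_direction = "toward")
  expect_false(f2$feasible)
  expect_equal(f2$reason, "insufficient_prf")
  # no detectable flow anywhere
  f3 <- assess_feasibility(make_fake_maps(
    array(NA_real_, dim = dim(maxv)), pw, gx, gx, gz, tt),
    rep(NA_real_, nt))
  expect_false(f3$feasible)
  expect_equal(f3$reason, "no_detectable_flow")
  # detectable but weak: jet-core power < 10 dB above the noise floor
  maxv4 <- maxv; maxv4[3, 4:6, 4:6, ] <- 1.0
  pw4 <- array(-30, dim = dim(maxv)); pw4[3, 4:6, 4:6, ] <- -25
  f4 <- assess_feasibility(make_fake_maps(maxv4, pw4, gx, gx, gz, tt,
                                          noise_floor = -30),
                           trace, expected_direction = "toward")
  expect_false(f4$feasible)
  expect_equal(f4$reason, "low_snr")
  # healthy case
  pw5 <- array(-30, dim = dim(maxv)); pw5[3, 4:6, 4:6, ] <- 0
  maxv5 <- maxv; maxv5[3, 4:6, 4:6, ] <- 1.0
  f5 <- assess_feasibility(make_fake_maps(maxv5, pw5, gx, gx, gz, tt,
                                          noise_floor = -30),
                           trace, expected_direction = "toward")
  expect_true(f5$feasible)
  expect_equal(f5$reason, "none")
})

test_that("the depth trace finds a constant jet depth and smooths it", {
  gx <- seq(-8, 8, 2); gz <- seq(85, 95, 2)
  nt <- 20
  maxv <- array(NA_real_, dim = c(length(gz), length(gx), length(gx), nt))
  pw <- array(-40, dim = dim(maxv))
  maxv[4, 3:7, 3:7, ] <- 1.5
  pw[4, 3:7, 3:7, ] <- 0
  maps <- make_fake_maps(maxv, pw, gx, gx, gz, seq_len(nt))
  tr <- jet_depth_trace(maps)
  expect_true(all(tr == gz[4]))
})
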