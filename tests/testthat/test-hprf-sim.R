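# HPRF acquisition physics: Nyquist velocity, range ambiguity, slow-time
# phase progression, aliasing, superposition, saturation.

test_that("Nyquist velocity follows c PRF / (4 f0)", {
  cfg <- acquisition_config(transmit_frequency = 2, prf = 12)
  expect_equal(nyquist_velocity(cfg), 1540 * 12e3 / (4 * 2e6))
  expect_equal(nyquist_velocity(cfg), 2.31)
  cfg2 <- acquisition_config(transmit_frequency = 1.5, prf = 18)
  expect_equal(nyquist_velocity(cfg2), 4.62)
  # linear in PRF
  cfg3 <- acquisition_config(transmit_frequency = 2, prf = 24)
  expect_equal(nyquist_velocity(cfg3), 2 * nyquist_velocity(cfg))
})

test_that("ambiguous sample volumes sit c/(2 PRF) apart", {
  cfg <- acquisition_config(prf = 12, gate_depth = 90)
  d <- ambiguous_depths(cfg)
  expect_equal(d, c(90, 90 - 1540e3 / (2 * 12e3)), tolerance = 1e-6)
  expect_equal(d[1] - d[2], 64.1667, tolerance = 1e-4)

  # higher PRF brings an additional volume close to the transducer
  cfg18 <- acquisition_config(prf = 18, gate_depth = 90)
  d18 <- ambiguous_depths(cfg18)
  expect_equal(length(d18), 3)
  expect_equal(d18, c(90, 47.2222, 4.4444), tolerance = 1e-4)
  expect_lt(min(d18), 10)

  # low PRF: single unambiguous volume
  cfg_lo <- acquisition_config(prf = 6, gate_depth = 90)
  expect_equal(ambiguous_depths(cfg_lo), 90)
})

test_that("stationary and moving point targets produce the right phase", {
  acq <- tiny_acquisition(n_frames = 512)
  beam <- standard_beam()
  # stationary: slow-time phase constant
  cl0 <- manual_cloud(c(0, 0, 90))
  iq0 <- simulate_iq(cl0, beam, acq, add_noise = FALSE)
  sig <- iq0$samples[3, 5, 5, ]
  expect_lt(diff(range(Arg(sig))), 1e-10)

  # axial 1.0 m/s toward the transducer, f0 2 MHz: f_d = 2 v f0 / c and
  # the slow-time phase retards (range shrinking)
  acq2 <- tiny_acquisition(n_frames = 256, transmit_frequency = 2)
  cl1 <- manual_cloud(c(0, 0, 93), drift = matrix(c(0, 0, -1), 1))
  iq1 <- simulate_iq(cl1, beam, acq2, add_noise = FALSE)
  fd <- dominant_doppler_hz(iq1)
  expect_equal(fd, -2 * 1 * 2e6 / 1540, tolerance = 0.02)
  expect_equal(abs(fd), 2597.4, tolerance = 0.01)
})

test_that("a steady jet reads its core speed, aliased jets wrap by 2 v_nyq", {
  beam <- standard_beam()
  sc <- spectral_config(window_length = 128)
  acq <- tiny_acquisition(n_frames = 1024, transmit_frequency = 2, prf = 12)
  expect_equal(nyquist_velocity(acq), 2.31)
  vbin <- 2 * 2.31 / 128

  ridge_velocity <- function(iq) {
    # spectral-peak ridge at the jet-core gate bin of the central beam
    pw <- pulsed_wave_display(iq, gate_bin = 3, config = sc)
    stats::median(pw$v_axis[apply(pw$power_db, 2, which.max)])
  }
  # 1.0 m/s steady top-hat jet: spectral peak at +1.0 (toward positive)
  cl <- make_scatterers(steady_phantom(1.0), density = 0.3, seed = 21)
  iq <- simulate_iq(cl, beam, acq, add_noise = FALSE)
  expect_lt(abs(ridge_velocity(iq) - 1.0), 3 * vbin)
  # and the unbiased mean-velocity map agrees
  maps <- spectral_maps(iq, sc)
  vs <- maps$mean_velocity_map[3, 5, 5, ]
  expect_lt(abs(stats::median(vs, na.rm = TRUE) - 1.0), 3 * vbin)

  # 3.0 m/s with v_nyq 2.31 -> spectral peak wrapped to -1.62 m/s
  cl3 <- make_scatterers(steady_phantom(3.0), density = 0.3, seed = 22)
  iq3 <- simulate_iq(cl3, beam, acq, add_noise = FALSE)
  expect_lt(abs(ridge_velocity(iq3) - (3.0 - 2 * 2.31)), 3 * vbin)
})

test_that("range-ambiguous echoes superpose linearly into the same gate", {
  acq <- tiny_acquisition(n_frames = 64, prf = 12)
  beam <- standard_beam()
  spacing <- 1540e3 / (2 * 12e3)
  # one target in the primary volume, one in the near-field ambiguous volume
  pA <- c(1, 0, 90)
  pB <- c(1, 0, 90 - spacing)
  clA <- manual_cloud(pA, drift = matrix(c(0, 0, -0.4), 1))
  clB <- manual_cloud(pB, drift = matrix(c(0, 0, 0.2), 1))
  clAB <- manual_cloud(rbind(pA, pB),
                       drift = rbind(c(0, 0, -0.4), c(0, 0, 0.2)))
  iqA <- simulate_iq(clA, beam, acq, add_noise = FALSE, apply_clip = FALSE)
  iqB <- simulate_iq(clB, beam, acq, add_noise = FALSE, apply_clip = FALSE)
  iqAB <- simulate_iq(clAB, beam, acq, add_noise = FALSE,
                      apply_clip = FALSE)
  # the near-field target lands in the same gate bins as the deep target
  expect_gt(max(abs(iqB$samples)), 0)
  expect_equal(iqAB$samples, iqA$samples + iqB$samples, tolerance = 1e-12)

  # linearity in scatterer amplitude (pre-clip)
  cl2 <- manual_cloud(pA, amplitudes = 2, drift = matrix(c(0, 0, -0.4), 1))
  iq2 <- simulate_iq(cl2, beam, acq, add_noise = FALSE, apply_clip = FALSE)
  expect_equal(iq2$samples, 2 * iqA$samples, tolerance = 1e-12)
})

test_that("noise is reproducible under a fixed seed", {
  acq <- tiny_acquisition(n_frames = 64, noise_level_db = -20)
  cl <- manual_cloud(c(0, 0, 90))
  iq1 <- simulate_iq(cl, standard_beam(), acq, seed = 3)
  iq2 <- simulate_iq(cl, standard_beam(), acq, seed = 3)
  iq3 <- simulate_iq(cl, standard_beam(), acq, seed = 4)
  expect_identical(iq1$samples, iq2$samples)
  expect_false(identical(iq1$samples, iq3$samples))
})

test_that("saturation clips hard and flags the mask", {
  x <- array(complex(real = c(0.5, 3, -4, 0.1),
                     imaginary = c(0.2, -5, 0.3, 0)), dim = c(1, 2, 2, 1))
  # all below clip: identity, empty mask
  r1 <- apply_saturation(x, 10)
  expect_identical(r1$samples, x)
  expect_false(any(r1$saturation_mask))
  # clip at 1: real and imaginary parts bounded, mask marks hit beams
  r2 <- apply_saturation(x, 1)
  expect_true(all(abs(Re(r2$samples)) <= 1, abs(Im(r2$samples)) <= 1))
  expect_equal(as.vector(r2$saturation_mask), c(FALSE, TRUE, TRUE, FALSE))
  # infinite clip level reproduces the input bit-exactly
  expect_identical(apply_saturation(x, Inf)$samples, x)
  expect_error(apply_saturation(x, 0), class = "hprfd_parameter_error")
})

test_that("an empty cloud yields a warning and noise-only ensemble", {
  cl <- manual_cloud(matrix(numeric(0), 0, 3))
  acq <- tiny_acquisition(n_frames = 32, noise_level_db = -20)
  expect_warning(iq <- simulate_iq(cl, standard_beam(), acq, seed = 1),
                 "empty")
  expect_gt(stats::sd(Re(iq$samples)), 0)
})
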