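# Jet phantoms: waveforms, velocity fields, convergence fields, scatterers.

test_that("waveform integrals match analytic and quadrature oracles", {
  # half-sine: integral = (2/pi) * peak * duration
  wf <- make_waveform("diastolic", 0.3, 200, "half_sine")
  expect_equal(wf$true_rvol, 2 / pi * 200 * 0.3, tolerance = 1e-4)
  expect_equal(true_rvol(wf), 38.1972, tolerance = 1e-3)

  wf2 <- make_waveform("systolic", 0.3, 100, "constant")
  expect_equal(wf2$true_rvol, 30, tolerance = 1e-12)

  # decaying exponential against a 10x-density quadrature oracle
  wf3 <- make_waveform("diastolic", 0.6, 150, "decaying_exponential",
                       tau = 0.2)
  tfine <- seq(0, 0.6, length.out = 10 * length(wf3$times))
  oracle <- sum(diff(tfine) *
                (head(150 * exp(-tfine / 0.2), -1) +
                 tail(150 * exp(-tfine / 0.2), -1)) / 2)
  expect_equal(wf3$true_rvol, oracle, tolerance = 1e-3)

  # biphasic stays non-negative and integrates consistently
  wf4 <- make_waveform("systolic", 0.3, 120, "biphasic")
  expect_true(all(wf4$samples >= 0))
  expect_equal(true_rvol(wf4), wf4$true_rvol)

  expect_error(make_waveform("systolic", -0.1, 100, "half_sine"),
               class = "hprfd_parameter_error")
  expect_error(make_waveform("systolic", 0.3, 0, "half_sine"),
               class = "hprfd_parameter_error")
})

test_that("jet velocity field gives Q/A core speed and zero outside", {
  # 0.4 cm^2 = 40 mm^2 orifice, Q = 160 mL/s -> 4.0 m/s top-hat speed
  orif <- orifice_geometry(4, 40 / (4 * pi), center = c(0, 0, 90))
  wf <- make_waveform("diastolic", 0.3, 160, "constant")
  ph <- jet_phantom(orif, wf, jet_angle = 0, direction = "toward")
  v <- jet_velocity(ph, c(0, 0, 85), time = 0.1)
  expect_equal(as.vector(v), c(0, 0, -4), tolerance = 1e-6)

  expect_equal(as.vector(jet_velocity(ph, c(15, 0, 85), 0.1)), c(0, 0, 0))
  # outside the regurgitant phase the field is zero; time wraps mod cycle
  expect_equal(max(abs(jet_velocity(ph, c(0, 0, 85), 0.5))), 0)
  expect_equal(jet_velocity(ph, c(0, 0, 85), 0.1 + wf$cycle_length),
               jet_velocity(ph, c(0, 0, 85), 0.1))
})

test_that("parabolic profile has 2 Q/A centreline speed and flux Q", {
  orif <- orifice_geometry(5, 4, center = c(0, 0, 90))
  wf <- make_waveform("diastolic", 0.3, 100, "constant")
  ph <- jet_phantom(orif, wf, jet_angle = 0, profile = "parabolic")
  area <- pi * 5 * 4
  vc <- jet_velocity(ph, c(0, 0, 85), 0.1)
  expect_equal(vc[3], -2 * 100 / area, tolerance = 1e-6)
  # profile normalization: integral of v over the cross-section equals Q
  g <- expand.grid(x = seq(-6, 6, by = 0.1), y = seq(-5, 5, by = 0.1))
  vz <- jet_velocity(ph, cbind(g$x, g$y, 85), 0.1)[, 3]
  flux <- sum(abs(vz)) * 0.1 * 0.1    # m/s * mm^2 = mL/s
  expect_equal(flux, 100, tolerance = 0.01)
})

test_that("plane-integrated flux equals Q within 1% and is angle-invariant", {
  h <- 0.125
  g <- expand.grid(x = seq(-22, 22, by = h), y = seq(-8, 8, by = h))
  for (profile in c("top_hat", "parabolic")) {
    flux <- sapply(c(0, 25, 50), function(ang) {
      ph <- standard_phantom(30, jet_angle = ang, semi_axis_a = 5,
                             semi_axis_b = 4, orifice_depth = 90,
                             profile = profile)
      q_t <- waveform_flow_rate(ph$waveform, 0.15)
      vz <- jet_velocity(ph, cbind(g$x, g$y, 85), 0.15)[, 3]
      sum(abs(vz)) * h^2 / q_t
    })
    expect_true(all(abs(flux - 1) < 0.01))
    # angle invariance of the plane-integrated axial flux, 0 to 50 degrees
    expect_lt(max(flux) / min(flux) - 1, 0.02)
  }
})

test_that("hemispheric convergence field follows Q / (2 pi r^2)", {
  # Q = 251.33 mL/s at r = 10 mm -> 40 cm/s
  expect_equal(pisa_velocity_field(251.327412, radius = 10), 40,
               tolerance = 1e-6)
  expect_equal(pisa_velocity_field(0, radius = c(5, 10, 20)), rep(0, 3))
  # halving the radius quadruples the speed
  expect_equal(pisa_velocity_field(200, radius = 5) /
               pisa_velocity_field(200, radius = 10), 4)
  expect_error(pisa_velocity_field(100, radius = 0),
               class = "hprfd_parameter_error")
})

test_that("scatterer clouds are reproducible, Poisson-sized and classed", {
  ph <- tiny_phantom()
  c1 <- make_scatterers(ph, density = 0.5, seed = 11)
  c2 <- make_scatterers(ph, density = 0.5, seed = 11)
  expect_identical(c1$positions, c2$positions)
  expect_identical(c1$amplitudes, c2$amplitudes)
  c3 <- make_scatterers(ph, density = 0.5, seed = 12)
  expect_false(identical(c1$positions, c3$positions))

  # blood count ~ Poisson(density * box volume): mean over seeds within 4 sd
  nb <- vapply(1:20, function(s)
    sum(make_scatterers(ph, density = 0.5, seed = s)$class == "blood"),
    numeric(1))
  # box: core 20 mm + radial extent (semi-axes + margin) per axis
  vol <- (2 * (5.5 + 3)) * (2 * (4.4 + 3)) * (20 + 2 * 3)
  lam <- 0.5 * vol
  expect_lt(abs(mean(nb) - lam), 4 * sqrt(lam / 20))

  # reflector amplitude 60 dB -> 1000x blood RMS
  c4 <- make_scatterers(ph, density = 0.5, seed = 5, n_reflectors = 3,
                        apical_reflector_gain = 60)
  refl <- abs(c4$amplitudes[c4$class == "apical_reflector"])
  expect_equal(unique(refl), 1000)
  expect_error(make_scatterers(ph, density = 0.5, seed = 1,
                               apical_reflector_gain = 20),
               class = "hprfd_parameter_error")
  # clutter drift is quasi-static
  expect_lte(max(abs(c1$drift)), 0.02)
})

test_that("orifice geometry enforces its invariants", {
  expect_error(orifice_geometry(3, 5), class = "hprfd_parameter_error")
  expect_error(orifice_geometry(5, 0), class = "hprfd_parameter_error")
  expect_error(orifice_geometry(5, 3, area_variation_fraction = 1),
               class = "hprfd_parameter_error")
  o <- orifice_geometry(5, 3, orientation = c(0, 0, -2))
  expect_equal(sqrt(sum(o$orientation^2)), 1)
  expect_error(jet_phantom(o, make_waveform("systolic", 0.3, 10,
                                            "half_sine"), jet_angle = 120),
               class = "hprfd_parameter_error")
})

test_that("within-beat orifice-area variation preserves the RVol integral", {
  ph <- standard_phantom(30, area_variation_fraction = 0.4)
  expect_equal(true_rvol(ph), 30, tolerance = 1e-3)
  # core speed rises when the orifice narrows: Q/A(t) with A modulated
  t_mid <- 0.15
  v_mod <- abs(jet_velocity(ph, c(0, 0, 90), t_mid)[3])
  ph0 <- standard_phantom(30)
  v_plain <- abs(jet_velocity(ph0, c(0, 0, 90), t_mid)[3])
  expect_gt(v_mod, v_plain)
})
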