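test_that("Stokes density reproduces the printed reference densities", {
  # zero settling speed: exactly the fluid density (neutral buoyancy)
  expect_identical(stokes_density(0), 1000)
  # sinking at 5.224 cm/s: the heaviest particle used in vivo
  expect_equal(suppressWarnings(stokes_density(0.05224)), 1049.0,
               tolerance = 0.05)
  # rising at 0.64 cm/s: the production test-sample mean
  expect_equal(suppressWarnings(stokes_density(-0.0064)), 994.0,
               tolerance = 0.05)
  expect_error(stokes_density(0.01, d = -1), "diameter")
})

test_that("Stokes density is affine in settling speed and inverts exactly", {
  fl <- fluid_properties()
  slope <- 18 * fl$dynamic_viscosity / (fl$gravity * 1.4e-3^2)
  v <- c(-0.02, 0, 0.01, 0.05)
  expect_equal(suppressWarnings(stokes_density(v)), 1000 + slope * v)
  rho <- c(950, 1000, 1031, 1049, 1200)
  back <- suppressWarnings(stokes_density(stokes_settling_velocity(rho)))
  expect_identical(back, rho)
})

test_that("terminal velocity is the steady tail slope", {
  fr <- 50
  t <- seq(0, 2, by = 1 / fr)
  # exactly linear descent
  r <- terminal_velocity(-0.05 * t, fr)
  expect_equal(r$v_terminal, -0.05, tolerance = 1e-12)
  expect_lt(r$fit_quality, 1e-12)
  # exponential relaxation toward v_t
  vt <- -0.052
  tau <- 0.01
  y <- vt * (t - tau * (1 - exp(-t / tau)))
  expect_equal(terminal_velocity(y, fr)$v_terminal, vt, tolerance = 0.01 * 0.052)
  # a record that is all transient fails the drift check
  tau_slow <- 0.8
  y_slow <- vt * (t - tau_slow * (1 - exp(-t / tau_slow)))
  expect_error(terminal_velocity(y_slow[t <= 1], fr), "not reached")
})

test_that("noisy 50 fps drop tests recover density within 5%", {
  errs <- vapply(1:50, function(seed) {
    dt <- generate_drop_test(tracer_spec(density = 1049), duration = 2,
                             frame_rate = 50, noise_sd = 0.1, seed = seed)
    v <- terminal_velocity(dt$y, 50)$v_terminal
    est <- suppressWarnings(stokes_density(-v))
    abs(est - 1049) / 1049
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("a neutrally buoyant particle rides the fluid pathline", {
  m <- suction_model()
  sim <- simulate_suction(m, tracer_spec(1.4e-3, 1000), c(0.005, 0.002, 0),
                          gravity = FALSE)
  n <- min(nrow(sim$particle), nrow(sim$fluid_pathline))
  sep <- sqrt(rowSums((sim$particle[1:n, ] - sim$fluid_pathline[1:n, ])^2))
  expect_lt(max(sep), 1e-6)
})

test_that("quiescent settling reaches the Stokes terminal velocity", {
  mq <- suction_model(pressure_amplitude = 0, total_time = 2,
                      time_step = 1e-3)
  sim <- simulate_suction(mq, tracer_spec(1.4e-3, 1049), c(0.005, 0, 0),
                          drag_correction = FALSE)
  v_end <- sim$particle_velocity[nrow(sim$particle_velocity), 2]
  expect_equal(v_end, -stokes_settling_velocity(1049), tolerance = 0.01 * 0.0522)
  expect_error(simulate_suction(mq, tracer_spec(1.4e-3, 1000), c(-0.01, 0, 0)),
               "half-space")
})

test_that("halving the time step moves the endpoint by under 1% of the path", {
  m1 <- suction_model()
  m2 <- suction_model(time_step = 6.25e-5)
  s1 <- simulate_suction(m1, tracer_spec(1.4e-3, 1050), c(0.005, 0, 0))
  s2 <- simulate_suction(m2, tracer_spec(1.4e-3, 1050), c(0.005, 0, 0))
  end1 <- s1$particle[nrow(s1$particle), ]
  end2 <- s2$particle[nrow(s2$particle), ]
  path_len <- sum(sqrt(rowSums(diff(s1$particle)^2)))
  expect_lt(sqrt(sum((end1 - end2)^2)), 0.01 * path_len)
})

test_that("fidelity metrics are zero for identical paths and read off shifts", {
  p <- cbind(seq(0, 0.04, length.out = 50), 0, 0)
  fm <- fidelity_metrics(p, p)
  expect_equal(fm$gravity_deviation, 0)
  expect_equal(fm$path_separation, 0)
  shifted <- p
  shifted[, 2] <- shifted[, 2] - 5e-4  # 0.5 mm along gravity (-y)
  fm <- fidelity_metrics(shifted, p)
  expect_equal(fm$gravity_deviation, 5e-4, tolerance = 1e-12)
  expect_equal(fm$path_separation, 5e-4, tolerance = 1e-12)
  expect_error(fidelity_metrics(p[0, ], p), "empty")
})

test_that("metrics are invariant to co-rotating the scene and gravity", {
  # the flow is axisymmetric about x, so rotating the release point and the
  # gravity vector about x must leave every metric unchanged
  th <- pi / 2
  m1 <- suction_model()                               # gravity -y
  m2 <- suction_model(gravity_direction = c(0, 0, -1))  # rotated by 90 deg
  rp1 <- c(0.005, 0.003, 0)
  rp2 <- c(0.005, 0, 0.003)
  s1 <- simulate_suction(m1, tracer_spec(1.4e-3, 1100), rp1)
  s2 <- simulate_suction(m2, tracer_spec(1.4e-3, 1100), rp2)
  f1 <- fidelity_metrics(s1$particle, s1$fluid_pathline,
                         s1$particle_velocity, s1$fluid_velocity_at_particle,
                         m1$gravity_direction)
  f2 <- fidelity_metrics(s2$particle, s2$fluid_pathline,
                         s2$particle_velocity, s2$fluid_velocity_at_particle,
                         m2$gravity_direction)
  expect_equal(f1$gravity_deviation, f2$gravity_deviation, tolerance = 1e-9)
  expect_equal(f1$path_separation, f2$path_separation, tolerance = 1e-9)
  expect_equal(f1$max_lag, f2$max_lag, tolerance = 1e-9)
})

test_that("gravity deviation grows with particle density", {
  m <- suction_model()
  devs <- vapply(c(1000, 1050, 1100, 1200), function(rho) {
    f <- assess_tracer_fidelity(m, tracer_spec(1.4e-3, rho),
                                release_points = list(c(0.005, 0, 0)))
    f$gravity_deviation_mm
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})
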