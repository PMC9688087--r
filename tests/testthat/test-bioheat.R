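field_from <- function(x, pitch = 0.25, baseline = 26) {
  nanotherm:::new_temperature_field(x, pitch, -dim(x) * pitch / 2, baseline, 0)
}

test_that("conversion factor matches the voxel calorimetry", {
  m_kg <- 1040 * (0.25e-3)^3
  f <- conversion_factor(3554.6, m_kg)
  expect_equal(f, 2.77e-15, tolerance = 5e-3)
  expect_equal(f, 1.602e-19 / (m_kg * 1000 * 3554.6 / 1000), tolerance = 1e-12)
  expect_equal(conversion_factor(3554.6, 2 * m_kg), f / 2)
  expect_error(conversion_factor(3554.6, 0), "> 0")
})

test_that("energy map converts linearly to a temperature field", {
  em <- structure(list(energy = array(0, c(5, 5, 5)), pitch = 0.25,
                       origin = rep(-0.625, 3)), class = "energy_map")
  z <- energy_to_deltaT(em, 2.77e-15, 6e13)
  expect_true(all(z$delta_t == 0))
  em$energy[3, 3, 3] <- 1e12
  tf <- energy_to_deltaT(em, 2.77e-15, 6e13)
  expect_equal(tf$delta_t[3, 3, 3], 1e12 * 2.77e-15 * 6e13)
  expect_equal(tf$delta_t[3, 3, 3], 1.662e11, tolerance = 1e-3)
  tf2 <- energy_to_deltaT(em, 2.77e-15, 1.2e14)
  expect_equal(tf2$delta_t, 2 * tf$delta_t)
  expect_error(energy_to_deltaT(em, 2.77e-15, -1), "scaling")
})

test_that("voxel irradiance follows the eV-to-watt conversion", {
  a <- (0.25e-3)^2
  expect_equal(voxel_irradiance(0, 30, a), 0)
  expect_equal(voxel_irradiance(1e18, 30, a), 8.544e4, tolerance = 1e-3)
  expect_equal(voxel_irradiance(1e18, 60, a),
               voxel_irradiance(1e18, 30, a) / 2)
  expect_error(voxel_irradiance(1, 0, a), "> 0")
})

test_that("per-voxel nanoparticle heating term", {
  expect_equal(gnr_deltaT(0, 1.25e-4, 4.76e-16, 1e5, 0.59), 0)
  dt <- gnr_deltaT(2.2e17, 1.25e-4, 4.76e-16, 1e5, 0.59)
  expect_equal(dt, 2.2e17 * 1.25e-4^2 * 4.76e-16 * 1e5 / (2 * 0.59))
  expect_equal(dt, 0.139, tolerance = 0.01)
  expect_equal(gnr_deltaT(2.2e17, 1.25e-4, 4.76e-16, 2e5, 0.59), 2 * dt)
  expect_equal(gnr_deltaT(2.2e17, 1.25e-4, 9.52e-16, 1e5, 0.59), 2 * dt)
  expect_error(gnr_deltaT(1, 1, 1, 1, 0), "conductivity")
})

test_that("heat kernel is a normalized Gaussian of width sqrt(2 alpha t)", {
  k0 <- heat_kernel(0.14, 0, 0.25)
  expect_equal(sum(k0), 1)
  expect_equal(max(k0), 1)        # delta at t = 0
  k <- heat_kernel(0.14, 10, 0.25)
  expect_equal(sum(k), 1, tolerance = 1e-6)
  # empirical per-axis variance equals 2 alpha t (sigma = 1.673 mm)
  n <- dim(k)[1]
  x <- (seq_len(n) - (n + 1) / 2) * 0.25
  v <- sum(k * outer(outer(x^2, rep(1, n)), rep(1, n)))
  expect_equal(sqrt(v), 1.673, tolerance = 1e-2)
})

test_that("diffuse matches the closed-form Gaussian impulse response", {
  d <- c(41, 41, 41); pitch <- 0.25
  x <- array(0, d); x[21, 21, 21] <- 1
  f <- diffuse(field_from(x, pitch), thermal_model(0.14), 2)
  # closed form, sampled at voxel centers
  rr <- (seq_len(41) - 21) * pitch
  g1 <- exp(-rr^2 / (4 * 0.14 * 2))
  gauss <- outer(outer(g1, g1), g1) / (4 * pi * 0.14 * 2)^1.5 * pitch^3
  expect_lt(max(abs(f$delta_t - gauss)) / max(gauss), 0.01)
  expect_equal(f$time, 2)
  # t = 0 returns the input unchanged
  expect_identical(diffuse(field_from(x, pitch), thermal_model(0.14), 0)$delta_t, x)
})

test_that("diffuse agrees with an explicit finite-difference oracle", {
  set.seed(77)
  d <- c(64, 64, 64); pitch <- 0.25
  x <- array(0, d)
  # random localized sources away from the boundary
  idx <- cbind(sample(24:40, 30, TRUE), sample(24:40, 30, TRUE),
               sample(24:40, 30, TRUE))
  x[idx] <- stats::runif(30, 0.5, 2)
  x <- diffuse(field_from(x, pitch), thermal_model(0.14), 0.5)$delta_t # smooth
  ours <- diffuse(field_from(x, pitch), thermal_model(0.14), 2)$delta_t
  fd <- fd_diffuse(x, 0.14, pitch, 2)
  expect_lt(max(abs(ours - fd)) / max(fd), 0.02)
})

test_that("diffusion conserves heat without perfusion and decays with it", {
  # sources far from the boundary (> 6 sigma), so boundary flux is negligible
  set.seed(78)
  x <- array(0, c(48, 48, 48)); x[22:26, 22:26, 22:26] <- stats::runif(125)
  tot0 <- sum(x)
  f <- diffuse(field_from(x), thermal_model(0.16, qb = 0), 2)
  expect_equal(sum(f$delta_t), tot0, tolerance = 1e-4)
  fq <- diffuse(field_from(x), thermal_model(0.16, qb = 0.02), 2)
  expect_equal(sum(fq$delta_t), tot0 * exp(-0.02 * 2), tolerance = 1e-4)
})

test_that("time-step refinement converges for the probe curve", {
  ph <- build_world(2, 0.25, mat_pancreas())
  beam <- laser_beam(duration_s = 120)
  em <- run_transport(ph, beam, transport_settings(2e4, seed = 55))
  model <- thermal_model(0.14)
  p1 <- probe_curve(ph, beam, em, model, c(0, 2, 0), times = 120, dt = 1)
  p2 <- probe_curve(ph, beam, em, model, c(0, 2, 0), times = 120, dt = 0.5)
  expect_lt(abs(p1$delta_t_c - p2$delta_t_c) / p2$delta_t_c, 0.02)
})

test_that("irradiate is linear in injected power and respects the schedule", {
  ph <- build_world(1, 0.5, mat_pancreas())
  beam <- laser_beam(power_w = 2.1, duration_s = 10)
  em <- run_transport(ph, beam, transport_settings(5e3, seed = 66))
  model <- thermal_model(0.14)
  f1 <- irradiate(ph, beam, em, model, schedule = c(5, 10), baseline = 26)
  expect_equal(vapply(f1, `[[`, numeric(1), "time"), c(5, 10))
  beam2 <- laser_beam(power_w = 4.2, duration_s = 10)
  f2 <- irradiate(ph, beam2, em, model, schedule = c(5, 10), baseline = 26)
  r <- f2[[2]]$delta_t / f1[[2]]$delta_t
  expect_lt(max(abs(r[is.finite(r)] - 2)), 1e-9)
  # zero power heats nothing
  f0 <- irradiate(ph, laser_beam(power_w = 0, duration_s = 10), em, model,
                  schedule = c(5))
  expect_true(all(f0[[1]]$delta_t == 0))
  expect_error(irradiate(ph, beam, em, model, schedule = c(5, 5)),
               "config error")
})

test_that("probe curve agrees with the field solver at a probe point", {
  ph <- build_world(2, 0.25, mat_pancreas())
  beam <- laser_beam(duration_s = 60)
  em <- run_transport(ph, beam, transport_settings(2e4, seed = 57))
  model <- thermal_model(0.14)
  fields <- irradiate(ph, beam, em, model, schedule = c(30))
  direct <- probe_curve(ph, beam, em, model, c(0, 2, 0), times = 30)
  idx <- world_to_voxel(ph, c(0, 2, 0))
  expect_equal(direct$delta_t_c,
               fields[[1]]$delta_t[idx[1], idx[2], idx[3]], tolerance = 0.05)
})
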