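# independent oracle: depolarization factor of a prolate spheroid by
# numerical quadrature, P_a = (a b c / 2) Int dt / ((t+a^2)^(3/2) (t+b^2))
depol_quadrature <- function(diameter, length) {
  a <- length / 2; b <- diameter / 2
  f <- function(t) 1 / ((t + a^2)^1.5 * (t + b^2))
  a * b * b / 2 * stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# independent oracle: exact Mie dipole (n = 1) absorption cross section
mie_dipole_cabs <- function(r_nm, eps, eps_m, lambda_nm) {
  nm <- sqrt(Re(eps_m))
  k <- 2 * pi * nm / lambda_nm
  x <- k * r_nm
  m <- sqrt(eps) / nm
  psi  <- function(z) sin(z) / z - cos(z)
  psip <- function(z) cos(z) / z - sin(z) / z^2 + sin(z)
  chi  <- function(z) cos(z) / z + sin(z)
  chip <- function(z) -sin(z) / z - cos(z) / z^2 + cos(z)
  xi  <- function(z) psi(z) - 1i * chi(z)
  xip <- function(z) psip(z) - 1i * chip(z)
  a1 <- (m * psi(m * x) * psip(x) - psi(x) * psip(m * x)) /
    (m * psi(m * x) * xip(x) - xi(x) * psip(m * x))
  c_ext <- (2 * pi / k^2) * 3 * Re(a1)
  c_sca <- (2 * pi / k^2) * 3 * Mod(a1)^2
  c_ext - c_sca
}

test_that("depolarization factors match quadrature and behave at limits", {
  p <- depolarization_factors(10, 41)
  expect_equal(unname(p[1]), 0.0730, tolerance = 1e-3)
  expect_equal(unname(p[2]), 0.4635, tolerance = 1e-3)
  expect_equal(unname(p[1]), depol_quadrature(10, 41), tolerance = 1e-8)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(p[2]), unname(p[3]))

  # sphere limit is the continuous extension 1/3
  expect_equal(unname(depolarization_factors(10, 10)), rep(1 / 3, 3),
               tolerance = 1e-9)

  # P1 decreases with aspect ratio; P1 < 1/3 < P2 for a prolate rod
  ar <- c(1.5, 2, 4.1, 8)
  p1 <- vapply(ar, function(q) depolarization_factors(10, 10 * q)[1], numeric(1))
  expect_true(all(diff(p1) < 0))
  expect_true(all(p1 < 1 / 3))
  expect_error(depolarization_factors(41, 10), "prolate")
})

test_that("s-cylinder volume and equivalent radius", {
  v <- particle_volume(gnr_spec(10, 41))
  expect_equal(v, 2 * pi * 15.5 * 25 + 4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(v, 2958.3, tolerance = 1e-4)
  expect_equal(equivalent_radius(10, 41), 8.905, tolerance = 1e-3)
  # sphere case
  expect_equal(equivalent_radius(10, 10), 5)
  expect_equal(particle_volume(gnr_spec(10, 10)), 4 / 3 * pi * 125,
               tolerance = 1e-12)
  # bounded by the inscribed sphere and the full cylinder of the same length
  for (l in c(12, 20, 41, 80)) {
    r <- equivalent_radius(10, l)
    expect_gte(r, 5)
    expect_lte(r, (3 * pi * 25 * l / (4 * pi))^(1 / 3))
  }
  # volume monotone in length at fixed diameter
  vs <- vapply(c(10, 20, 41, 60), function(l) particle_volume(gnr_spec(10, l)),
               numeric(1))
  expect_true(all(diff(vs) > 0))
  expect_error(equivalent_radius(10, 8), "length >= diameter")
})

test_that("size-corrected permittivity adds surface-scattering loss only", {
  lam <- 808
  eb <- gold_permittivity(lam)
  # g = 0: no correction at all
  d0 <- drude_params(surface_scattering = 0)
  expect_identical(size_corrected_permittivity(8.9, lam, eb, d0), eb)
  # large particle: correction vanishes
  eps_big <- size_corrected_permittivity(1e9, lam, eb)
  expect_equal(eps_big, eb, tolerance = 1e-6)
  # independent evaluation of the two Drude terms at the rod radius
  a <- 8.905387
  dr <- drude_params()
  w <- 2 * pi * 2.99792458e8 / (lam * 1e-9)
  ga <- dr$bulk_damping + dr$fermi_velocity / (a * 1e-9)
  delta <- dr$plasma_frequency^2 / (w * (w + 1i * dr$bulk_damping)) -
    dr$plasma_frequency^2 / (w * (w + 1i * ga))
  eps_a <- size_corrected_permittivity(a, lam, eb)
  expect_equal(eps_a, eb + delta, tolerance = 1e-12)
  expect_gt(Im(eps_a), Im(eb))                    # only adds loss
  expect_lt(abs(Re(eps_a) - Re(eb)), 0.05 * abs(Re(eb)))
  expect_error(size_corrected_permittivity(-1, lam), "radius")
})

test_that("Gans polarizability reduces to the small-sphere form", {
  # index-matched particle has zero polarizability, zero cross section
  al0 <- gans_polarizability(host_eps, host_eps, 10, 41)
  expect_true(all(Mod(al0) == 0))
  expect_equal(absorption_cross_section(gnr_spec(), host_eps, host_eps, 808), 0)

  # sphere limit: Clausius-Mossotti, all axes equal
  eps <- table_eps
  al <- gans_polarizability(eps, host_eps, 10, 10)
  cm <- 4 * pi * 5^3 * (eps - host_eps) / (eps + 2 * host_eps)
  expect_equal(unname(al[1]), cm, tolerance = 1e-9)
  expect_lt(max(Mod(al - al[1])), 1e-9 * Mod(al[1]))

  # longitudinal plasmon dominance for the 4.1 aspect-ratio rod
  al41 <- gans_polarizability(eps, host_eps, 10, 41)
  expect_gt(Im(al41[1]) / Im(al41[2]), 100)
})

test_that("absorption cross section reproduces the published 476 nm^2", {
  cabs <- absorption_cross_section(gnr_spec(), table_eps, host_eps, 808)
  expect_lt(abs(cabs - 476) / 476, 0.05)
  expect_error(absorption_cross_section(gnr_spec(), table_eps,
                                        complex(real = 1.7, imaginary = 0.1), 808),
               "unsupported model")
})

test_that("sphere-limit chain agrees with the exact Mie dipole term", {
  lam <- 808
  eps <- size_corrected_permittivity(5, lam)
  ours <- absorption_cross_section(gnr_spec(10, 10), eps, host_eps, lam)
  mie <- mie_dipole_cabs(5, eps, host_eps, lam)
  expect_lt(abs(ours - mie) / mie, 0.01)
})

test_that("longitudinal resonance of the 4.1 rod lies near 808 nm in tissue", {
  spec <- gnr_spec()
  sp <- cross_section_spectrum(spec, seq(700, 920, by = 2),
                               eps_m = complex(real = 1.394^2))
  peak <- sp$wavelength_nm[which.max(sp$c_abs_nm2)]
  expect_lt(abs(peak - 808), 20)
})

test_that("resonant cross section grows with particle volume at fixed aspect ratio", {
  scale <- c(1, 1.25, 1.6)
  cs <- vapply(scale, function(s)
    absorption_cross_section(gnr_spec(10 * s, 41 * s), table_eps, host_eps, 808),
    numeric(1))
  expect_true(all(diff(cs) > 0))
  # quasi-static: proportional to volume
  expect_equal(cs[3] / cs[1], 1.6^3, tolerance = 1e-9)
})

test_that("volume fraction, number density and nano-absorption are unit-consistent", {
  vf <- volume_fraction(12.5, 19.3)
  expect_equal(vf, 6.5e-7, tolerance = 0.01)
  expect_equal(volume_fraction(0), 0)
  expect_equal(volume_fraction(25, 19.3), 2 * vf)

  n <- number_density(12.5, gnr_spec())
  expect_equal(n, 6.476684e-7 / 2.9583e-24, tolerance = 1e-3)
  expect_equal(n, 2.2e17, tolerance = 0.02)
  expect_equal(number_density(0, gnr_spec()), 0)
  # inverse scaling with particle volume at fixed concentration
  n2 <- number_density(12.5, gnr_spec(10, 82))
  expect_lt(n2, n)
  expect_equal(n2 * particle_volume(gnr_spec(10, 82)),
               n * particle_volume(gnr_spec()), tolerance = 1e-12)

  na <- nano_absorption(2.2e17, 476)
  expect_equal(na$mu_a_cm, 1.047, tolerance = 1e-3)
  expect_equal(na$length_cm, 0.955, tolerance = 1e-3)
  z <- nano_absorption(0, 476)
  expect_equal(z$mu_a_cm, 0)
  expect_identical(z$length_cm, Inf)
  expect_equal(nano_absorption(4.4e17, 476)$mu_a_cm, 2 * na$mu_a_cm)
})
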