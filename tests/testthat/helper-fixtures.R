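# shared fixtures, built in code

mat_absorber <- function(mu_a = 2, mu_s = 0, g = 0, mu_an = 0) {
  material("absorber", rho = 1000, cp = 4000, alpha_d = 0.1,
           mu_a = mu_a, mu_s = mu_s, g_hg = g, mu_a_nano = mu_an)
}

mat_pancreas <- function() load_material_table()$pancreas

# small slab phantom for transport oracles: 20 mm cube, 0.5 mm voxels
slab_phantom <- function(mat) build_world(8, 0.5, mat)

# pencil beam entering the slab from the low-z face
slab_beam <- function(d_mm = 0.3) {
  laser_beam(power_w = 2.1, tip_diameter_mm = d_mm,
             tip_position_mm = c(0, 0, -9.99), direction = c(0, 0, 1),
             emission_rate = 2e6)
}

table_eps <- complex(real = -24.718, imaginary = 3.6581)
host_eps <- complex(real = 1.767)

# independent oracle: explicit finite-difference heat equation with a
# stability-limited step on the same grid (Dirichlet far boundary)
fd_diffuse <- function(x, alpha, pitch, t) {
  dt <- 0.9 * pitch^2 / (6 * alpha)
  n <- ceiling(t / dt); dt <- t / n
  lam <- alpha * dt / pitch^2
  d <- dim(x)
  for (s in seq_len(n)) {
    xp <- array(0, d + 2)
    xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
    lap <- xp[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
      xp[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
      xp[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
      xp[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
      xp[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
      xp[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)] - 6 * x
    x <- x + lam * lap
  }
  x
}

# fitted attenuation coefficient (1/cm) from a depth profile of counts
fit_attenuation <- function(emap, min_counts = 50) {
  prof <- apply(emap$counts, 3, sum)
  z_cm <- (seq_along(prof) - 0.5) * emap$pitch / 10
  ok <- prof > min_counts
  -unname(stats::coef(stats::lm(log(prof[ok]) ~ z_cm[ok]))[2])
}
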