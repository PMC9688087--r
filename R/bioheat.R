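#' Thermal model for the bioheat solver
#'
#' The analytic Pennes solution uses a single thermal diffusivity for
#' the whole domain (chosen to represent the heated mixture) and a
#' uniform perfusion decay rate Qb = (rho_b c_b / rho c) wb.
#'
#' @param alpha_d Thermal diffusivity, mm^2/s.
#' @param k Thermal conductivity, W/(m K) (derived rho*cp*alpha when
#'   built from a material).
#' @param qb Perfusion decay rate, 1/s.
#' @param tb Baseline (blood/ambient) temperature, degC.
#' @return An object of class `thermal_model`.
#' @export
thermal_model <- function(alpha_d, k = NA_real_, qb = 0, tb = 26) {
  if (alpha_d < 0) stop("thermal diffusivity must be >= 0")
  if (qb < 0) stop("perfusion rate must be >= 0")
  structure(list(alpha_d = alpha_d, k = k, qb = qb, tb = tb),
            class = "thermal_model")
}

#' Thermal model derived from a material
#' @param mat A `material`.
#' @param tb Baseline temperature, degC.
#' @param perfusion Use the material's perfusion term?
#' @return A `thermal_model`.
#' @export
thermal_model_from_material <- function(mat, tb = 26, perfusion = FALSE) {
  qb <- if (perfusion && mat$wb > 0)
    mat$rho_b * mat$c_b / (mat$rho * mat$cp) * mat$wb else 0
  thermal_model(alpha_d = mat$alpha_d, k = thermal_conductivity(mat),
                qb = qb, tb = tb)
}

new_temperature_field <- function(delta_t, pitch, origin, baseline, time) {
  structure(list(delta_t = delta_t, shape = dim(delta_t), pitch = pitch,
                 origin = origin, baseline = baseline, time = time),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> t = %g s, baseline %g degC, max dT %.4g degC\n",
              x$time, x$baseline, max(x$delta_t)))
  invisible(x)
}

#' Energy-to-temperature conversion factor
#'
#' F = 1.602e-19 / (m[g] * Cp[J g^-1 degC^-1]), the temperature rise of
#' one voxel per deposited eV.
#'
#' @param cp Heat capacity, J/(kg K).
#' @param voxel_mass_kg Voxel mass, kg.
#' @return Conversion factor, degC/eV.
#' @export
conversion_factor <- function(cp, voxel_mass_kg) {
  if (cp <= 0 || voxel_mass_kg <= 0) stop("cp and voxel mass must be > 0")
  # m[g] * Cp[J/(g K)] == m[kg] * Cp[J/(kg K)]
  EV_TO_J / (voxel_mass_kg * cp)
}

#' Convert a deposited-energy map to a temperature-rise field
#'
#' deltaT = energy * F * scaling, voxelwise.
#'
#' @param emap An `energy_map`.
#' @param f Conversion factor, degC/eV (scalar or per-voxel array).
#' @param scaling Photon-flux scaling factor (dimensionless).
#' @param baseline Baseline temperature, degC.
#' @return A `temperature_field` at time 0.
#' @export
energy_to_deltaT <- function(emap, f, scaling = 1, baseline = 26) {
  if (any(scaling < 0)) stop("scaling must be >= 0")
  new_temperature_field(emap$energy * f * scaling, emap$pitch, emap$origin,
                        baseline, time = 0)
}

#' Per-voxel light irradiance
#'
#' I_voxel = E[eV] * 1.602e-19 / (t_laser * area_voxel).
#'
#' @param voxel_energy_ev Deposited energy, eV (scalar or array).
#' @param t_laser_s Illumination duration represented by the map, s.
#' @param voxel_area_m2 Voxel face area, m^2.
#' @return Irradiance, W/m^2.
#' @export
voxel_irradiance <- function(voxel_energy_ev, t_laser_s, voxel_area_m2) {
  if (t_laser_s <= 0 || voxel_area_m2 <= 0) stop("duration and area must be > 0")
  voxel_energy_ev * EV_TO_J / (t_laser_s * voxel_area_m2)
}

#' Nanoparticle-mediated temperature rise of a heated region
#'
#' deltaT = N R^2 C_abs I / (2 k), the quasi-steady excess temperature
#' at the center of a uniformly heated nanoparticle-loaded region of
#' radius R under irradiance I. Applied per voxel with R the voxel
#' half-size and I the voxel irradiance.
#'
#' @param n_density Particles per m^3.
#' @param r_m Region (voxel half-size) radius, m.
#' @param c_abs_m2 Absorption cross section, m^2.
#' @param i_wm2 Irradiance, W/m^2.
#' @param k Thermal conductivity, W/(m K).
#' @return Temperature rise, degC.
#' @export
gnr_deltaT <- function(n_density, r_m, c_abs_m2, i_wm2, k) {
  if (k <= 0) stop("thermal conductivity must be > 0")
  n_density * r_m^2 * c_abs_m2 * i_wm2 / (2 * k)
}

#' Discretized Gaussian heat kernel
#'
#' The Green's function of the heat equation,
#' (4 pi alpha t)^(-3/2) exp(-r^2 / (4 alpha t)), sampled on the voxel
#' grid and normalized to sum to one; per-axis standard deviation
#' sqrt(2 alpha t). At t = 0 a delta kernel (identity convolution) is
#' returned.
#'
#' @param alpha_d Thermal diffusivity, mm^2/s.
#' @param t Time, s.
#' @param pitch Voxel pitch, mm.
#' @param shape Kernel grid shape (odd counts recommended); default
#'   covers 4 standard deviations.
#' @return 3-D array summing to one.
#' @export
heat_kernel <- function(alpha_d, t, pitch, shape = NULL) {
  sigma <- sqrt(2 * alpha_d * t)
  if (is.null(shape)) {
    n <- max(1L, 2L * as.integer(ceiling(4 * sigma / pitch)) + 1L)
    shape <- c(n, n, n)
  }
  ker <- array(0, dim = shape)
  mid <- (shape + 1) / 2
  if (sigma == 0) {
    ker[mid[1], mid[2], mid[3]] <- 1
    return(ker)
  }
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - mid[a]) * pitch)^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  ker <- exp(-r2 / (4 * alpha_d * t))
  ker / sum(ker)
}

# squared angular frequency (rad/mm)^2 on a padded FFT grid, per axis
fft_wsq_axis <- function(n, pitch) {
  if (n == 1L) return(0)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * pitch)
  (2 * pi * f[seq_len(n)])^2
}

fft_wsq_grid <- function(np, pitch) {
  wx <- fft_wsq_axis(np[1], pitch)
  wy <- fft_wsq_axis(np[2], pitch)
  wz <- fft_wsq_axis(np[3], pitch)
  outer(outer(wx, wy, `+`), wz, `+`)
}

pad_shape <- function(shape, pad_vox) {
  vapply(shape + pad_vox, function(n) stats::nextn(n, c(2, 3)), numeric(1))
}

embed_padded <- function(x, np) {
  out <- array(0, dim = np)
  out[seq_len(dim(x)[1]), seq_len(dim(x)[2]), seq_len(dim(x)[3])] <- x
  out
}

#' Diffuse a temperature field for a time interval
#'
#' Convolves the field with the Gaussian heat kernel of width
#' sqrt(2 alpha t) per axis (spectrally, on a zero-padded grid covering
#' at least four standard deviations) and applies the perfusion decay
#' exp(-Qb t). With Qb = 0 the total temperature-weighted volume is
#' conserved.
#'
#' @param field A `temperature_field`.
#' @param model A `thermal_model`.
#' @param t Diffusion time, s.
#' @return A `temperature_field` at `field$time + t`.
#' @export
diffuse <- function(field, model, t) {
  stopifnot(inherits(field, "temperature_field"), inherits(model, "thermal_model"))
  if (t < 0) stop("diffusion time must be >= 0")
  if (t == 0) return(field)
  x <- field$delta_t
  if (model$alpha_d > 0) {
    sigma <- sqrt(2 * model$alpha_d * t)
    np <- pad_shape(dim(x), ceiling(4 * sigma / field$pitch))
    wsq <- fft_wsq_grid(np, field$pitch)
    xh <- stats::fft(embed_padded(x, np)) * exp(-model$alpha_d * t * wsq)
    x <- Re(stats::fft(xh, inverse = TRUE)) / prod(np)
    x <- x[seq_len(field$shape[1]), seq_len(field$shape[2]), seq_len(field$shape[3])]
  }
  new_temperature_field(x * exp(-model$qb * t), field$pitch, field$origin,
                        field$baseline, field$time + t)
}

#' Time-resolved heating of a phantom under continuous irradiation
#'
#' Approximates continuous-wave heating by superposition: the
#' per-second physical temperature-rise map (Monte Carlo energy map
#' converted voxelwise and multiplied by the photon-flux scaling
#' factor) is injected at sub-interval boundaries `dt` and each
#' injection diffuses for its remaining time (evaluated spectrally, so
#' injections compose exactly). Injection stops at the beam duration;
#' diffusion continues to later schedule points.
#'
#' Voxelwise conversion: plain-tissue voxels use the calorimetric
#' factor F of their material; nanorod-loaded voxels additionally (or,
#' with `heat_model = "gnr"`, instead) receive the per-voxel
#' nanoparticle term N R^2 C_abs I_voxel / (2 k).
#'
#' @param phantom The `phantom` that produced the energy map.
#' @param beam The `laser_beam`.
#' @param emap The `energy_map` from [run_transport()].
#' @param model A `thermal_model` (single alpha for the solve).
#' @param schedule Increasing vector of output times, s.
#' @param dt Injection sub-interval, s.
#' @param heat_model `"auto"` (calorimetric + nano term in loaded
#'   voxels), `"tissue"` (calorimetric everywhere) or `"gnr"`
#'   (nano term replaces the calorimetric one in loaded voxels).
#' @param gnr Optional result of [gnr_optics()]; required by the nano
#'   term (`n_density`, `c_abs_nm2`).
#' @param scaling Photon-flux scaling factor; default
#'   [flux_scaling_factor()] of the beam.
#' @param baseline Baseline temperature, degC.
#' @return List of `temperature_field`s, one per schedule time.
#' @export
irradiate <- function(phantom, beam, emap, model, schedule, dt = 1,
                      heat_model = c("auto", "tissue", "gnr"), gnr = NULL,
                      scaling = NULL, baseline = 26) {
  heat_model <- match.arg(heat_model)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("config error: schedule must be strictly increasing")
  if (any(schedule < 0)) stop("config error: schedule times must be >= 0")
  if (is.null(scaling)) scaling <- flux_scaling_factor(beam)

  s_map <- injection_rate_map(phantom, beam, emap, heat_model, gnr, scaling)

  tmax <- max(schedule)
  sigma_max <- sqrt(2 * model$alpha_d * tmax)
  np <- pad_shape(dim(s_map), ceiling(4 * sigma_max / phantom$pitch))
  wsq <- fft_wsq_grid(np, phantom$pitch)
  s_hat <- stats::fft(embed_padded(s_map, np))
  t_hat <- array(0i, dim = np)

  breaks <- sort(unique(c(seq(0, tmax, by = dt), schedule, beam$duration_s)))
  breaks <- breaks[breaks <= tmax & breaks >= 0]
  out <- vector("list", length(schedule))
  g_cache_delta <- -1; g_cache <- NULL
  t_cur <- 0
  for (t_next in breaks[-1]) {
    delta <- t_next - t_cur
    if (delta != g_cache_delta) {
      g_cache <- exp(-(model$alpha_d * delta) * wsq)
      g_cache_delta <- delta
    }
    inject <- t_cur < beam$duration_s
    if (inject) t_hat <- t_hat + s_hat * delta
    t_hat <- t_hat * g_cache
    if (model$qb > 0) t_hat <- t_hat * exp(-model$qb * delta)
    t_cur <- t_next
    hit <- which(abs(schedule - t_cur) < 1e-9)
    if (length(hit)) {
      x <- Re(stats::fft(t_hat, inverse = TRUE)) / prod(np)
      x <- x[seq_len(phantom$shape[1]), seq_len(phantom$shape[2]),
             seq_len(phantom$shape[3])]
      for (h in hit)
        out[[h]] <- new_temperature_field(x, phantom$pitch, phantom$origin,
                                          baseline, t_cur)
    }
  }
  # schedule time 0, if requested
  zero <- which(schedule == 0)
  for (h in zero)
    out[[h]] <- new_temperature_field(array(0, dim = phantom$shape),
                                      phantom$pitch, phantom$origin, baseline, 0)
  out
}

# per-second temperature-rise injection map, degC/s per voxel
injection_rate_map <- function(phantom, beam, emap, heat_model, gnr, scaling) {
  coef <- heating_coefficients(phantom, heat_model, gnr)          # degC per eV
  rate_ev <- emap$energy * (beam$emission_rate / emap$n_histories) # eV/s
  rate_ev * coef * scaling
}

#' Probe temperature curve by direct superposition
#'
#' Computes the temperature rise at one point, for many output times,
#' by summing the free-space Gaussian response of every injection
#' sub-interval directly (no field-sized transforms). Equivalent to
#' extracting the point from [irradiate()] fields up to spatial
#' discretization of the kernel; convenient for dense time curves.
#'
#' @inheritParams irradiate
#' @param position Probe world coordinate, mm.
#' @param times Output times, s (rounded to the `dt` grid).
#' @return A `probe` tibble (time, temperature rise, temperature).
#' @export
probe_curve <- function(phantom, beam, emap, model, position, times, dt = 1,
                        heat_model = c("auto", "tissue", "gnr"), gnr = NULL,
                        scaling = NULL, baseline = 26) {
  heat_model <- match.arg(heat_model)
  if (is.null(scaling)) scaling <- flux_scaling_factor(beam)
  s_map <- injection_rate_map(phantom, beam, emap, heat_model, gnr, scaling)
  nz <- which(s_map > 0)
  s <- s_map[nz]
  cc <- voxel_centers(phantom)
  ijk <- arrayInd(nz, phantom$shape)
  r2 <- (cc[[1]][ijk[, 1]] - position[1])^2 +
    (cc[[2]][ijk[, 2]] - position[2])^2 +
    (cc[[3]][ijk[, 3]] - position[3])^2
  vvox <- phantom$pitch^3
  alpha <- model$alpha_d
  times <- round(times / dt) * dt
  ages <- new.env(parent = emptyenv())
  q_of <- function(tau) {
    key <- format(tau, digits = 12)
    if (!is.null(ages[[key]])) return(ages[[key]])
    val <- if (alpha > 0)
      sum(s * exp(-r2 / (4 * alpha * tau))) * vvox / (4 * pi * alpha * tau)^1.5
    else {
      idx <- world_to_voxel(phantom, position)
      s_map[idx[1], idx[2], idx[3]]
    }
    ages[[key]] <- val
    val
  }
  dtv <- vapply(times, function(t) {
    tj <- seq(0, by = dt, length.out = ceiling(min(t, beam$duration_s) / dt))
    tj <- tj[tj < min(t, beam$duration_s)]
    if (!length(tj)) return(0)
    sum(vapply(tj, function(j) q_of(t - j) * exp(-model$qb * (t - j)),
               numeric(1))) * dt
  }, numeric(1))
  out <- tibble::tibble(time_s = times, delta_t_c = dtv,
                        temperature_c = baseline + dtv)
  attr(out, "position_mm") <- position
  attr(out, "mode") <- "hd"
  attr(out, "baseline_c") <- baseline
  class(out) <- c("probe", class(out))
  out
}

# per-voxel conversion coefficient, degC per deposited eV (per second map)
heating_coefficients <- function(phantom, heat_model, gnr) {
  pitch_m <- phantom$pitch / 1000
  voxel_vol_m3 <- pitch_m^3
  voxel_area_m2 <- pitch_m^2
  r_m <- pitch_m / 2
  coefs <- vapply(phantom$materials, function(m) {
    f <- conversion_factor(m$cp, m$rho * voxel_vol_m3)
    has_nano <- m$mu_a_nano > 0
    g <- 0
    if (has_nano) {
      if (is.null(gnr))
        stop("nanorod-loaded material '", m$name,
             "' requires gnr optics (see gnr_optics())")
      k <- thermal_conductivity(m)
      # I_voxel per deposited eV per second: EV_TO_J / area
      g <- gnr$n_density * r_m^2 * (gnr$c_abs_nm2 * 1e-18) *
        (EV_TO_J / voxel_area_m2) / (2 * k)
    }
    switch(heat_model,
           auto = f + g,
           tissue = f,
           gnr = if (has_nano) g else f)
  }, numeric(1))
  array(coefs[phantom$labels], dim = phantom$shape)
}
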