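HC_EV_NM <- 1239.842        # Planck constant x speed of light, eV nm
EV_TO_J <- 1.602e-19        # electronvolt in joule (value used throughout)

#' Define a laser beam
#'
#' @param wavelength_nm Wavelength, nm.
#' @param power_w Optical power, W.
#' @param tip_diameter_mm Applicator tip (core) diameter, mm.
#' @param tip_position_mm World coordinate of the tip, mm.
#' @param direction Beam direction (normalized internally).
#' @param emission_rate Simulated emission rate, photons/s (becquerel).
#' @param duration_s Irradiation duration, s.
#' @param area_unit Area convention for the photon-flux scaling factor:
#'   `"mm2"` (default, reproduces the printed worked example), `"cm2"`,
#'   `"m2"`, or `"photon"` for the energy-conserving photon-count ratio
#'   P / (E0 * emission_rate) that ignores the beam area.
#' @return An object of class `laser_beam`.
#' @export
laser_beam <- function(wavelength_nm = 808, power_w = 2.1,
                       tip_diameter_mm = 0.3, tip_position_mm = c(0, 0, 0),
                       direction = c(0, 0, 1), emission_rate = 2e6,
                       duration_s = 120, area_unit = c("mm2", "cm2", "m2", "photon")) {
  area_unit <- match.arg(area_unit)
  if (wavelength_nm <= 0) stop("wavelength must be > 0")
  if (power_w < 0) stop("power must be >= 0")
  if (tip_diameter_mm <= 0) stop("tip diameter must be > 0")
  if (duration_s < 0) stop("duration must be >= 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  structure(list(wavelength_nm = wavelength_nm, power_w = power_w,
                 tip_diameter_mm = tip_diameter_mm,
                 tip_position_mm = tip_position_mm,
                 direction = direction / nrm,
                 emission_rate = emission_rate, duration_s = duration_s,
                 area_unit = area_unit),
            class = "laser_beam")
}

#' Photon energy from wavelength
#'
#' E0 = hc / lambda with hc = 1239.842 eV nm.
#'
#' @param wavelength_nm Wavelength, nm.
#' @return Energy in eV.
#' @export
photon_energy <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be > 0")
  HC_EV_NM / wavelength_nm
}

beam_area <- function(tip_diameter_mm, area_unit) {
  r <- tip_diameter_mm / 2
  switch(area_unit,
         mm2 = pi * r^2,
         cm2 = pi * (r / 10)^2,
         m2  = pi * (r / 1000)^2,
         photon = 1)
}

#' Photon flux of the beam
#'
#' flux = P / (E0 * 1.602e-19 * area), with the beam cross-sectional
#' area evaluated in the chosen unit (default mm^2, the convention that
#' reproduces the printed worked example; `"photon"` drops the area and
#' returns the physical photon emission rate P / (E0 in J)).
#'
#' @param power_w Laser power, W.
#' @param e0_ev Photon energy, eV.
#' @param tip_diameter_mm Tip diameter, mm.
#' @param area_unit Area convention, see [laser_beam()].
#' @return Photons per second per area unit.
#' @export
photon_flux <- function(power_w, e0_ev, tip_diameter_mm,
                        area_unit = c("mm2", "cm2", "m2", "photon")) {
  area_unit <- match.arg(area_unit)
  if (e0_ev <= 0) stop("photon energy must be > 0")
  if (tip_diameter_mm <= 0) stop("tip diameter must be > 0")
  power_w / (e0_ev * EV_TO_J * beam_area(tip_diameter_mm, area_unit))
}

#' Photon-flux scaling factor
#'
#' Ratio of the physical photon flux to the simulated emission rate;
#' multiplying simulated per-voxel deposited energies by this factor
#' converts them to physical deposition in the post-processing heat
#' step.
#'
#' @param beam A `laser_beam`.
#' @return Dimensionless scaling factor.
#' @export
flux_scaling_factor <- function(beam) {
  if (beam$emission_rate <= 0) stop("emission rate must be > 0")
  flux <- photon_flux(beam$power_w, photon_energy(beam$wavelength_nm),
                      beam$tip_diameter_mm, beam$area_unit)
  flux / beam$emission_rate
}

#' Sample initial photons on the tip disc
#'
#' Positions are uniform on the disc of the tip diameter, centered at
#' the tip and perpendicular to the beam direction; initial directions
#' equal the beam direction (collimated model); energies are all
#' hc/lambda.
#'
#' @param beam A `laser_beam`.
#' @param n Number of photons.
#' @return A tibble with columns x, y, z (mm), dx, dy, dz, energy_ev.
#' @export
emit_photons <- function(beam, n) {
  u <- disc_basis(beam$direction)
  r <- (beam$tip_diameter_mm / 2) * sqrt(stats::runif(n))
  phi <- 2 * pi * stats::runif(n)
  pos <- matrix(beam$tip_position_mm, n, 3, byrow = TRUE) +
    outer(r * cos(phi), u$u1) + outer(r * sin(phi), u$u2)
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 dx = beam$direction[1], dy = beam$direction[2],
                 dz = beam$direction[3],
                 energy_ev = photon_energy(beam$wavelength_nm))
}

disc_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- c(d[2] * a[3] - d[3] * a[2],
          d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(d[2] * u1[3] - d[3] * u1[2],
          d[3] * u1[1] - d[1] * u1[3],
          d[1] * u1[2] - d[2] * u1[1])
  list(u1 = u1, u2 = u2)
}
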