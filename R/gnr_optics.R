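#' Gold nanorod specification
#'
#' @param diameter_nm Rod diameter D, nm.
#' @param length_nm Rod length l, nm (l >= D).
#' @param mass_concentration Mass concentration, ug/mL.
#' @param bulk_gold_density Bulk gold density, g/cm^3.
#' @param peak_wavelength_nm Nominal longitudinal resonance, nm.
#' @return An object of class `gnr_spec`.
#' @export
gnr_spec <- function(diameter_nm = 10, length_nm = 41,
                     mass_concentration = 12.5, bulk_gold_density = 19.3,
                     peak_wavelength_nm = 808) {
  if (!(diameter_nm > 0 && length_nm >= diameter_nm))
    stop("gnr_spec requires 0 < diameter <= length")
  if (mass_concentration < 0) stop("mass concentration must be >= 0")
  structure(list(diameter_nm = diameter_nm, length_nm = length_nm,
                 mass_concentration = mass_concentration,
                 bulk_gold_density = bulk_gold_density,
                 peak_wavelength_nm = peak_wavelength_nm),
            class = "gnr_spec")
}

#' Drude parameters for size-corrected gold permittivity
#'
#' Defaults describe gold: plasma frequency 1.37e16 rad/s, Fermi
#' velocity 1.40e6 m/s, electron mean free path 42 nm (hence bulk
#' damping vF / mfp), surface-scattering constant g = 1.
#'
#' @param plasma_frequency rad/s.
#' @param fermi_velocity m/s.
#' @param mean_free_path_nm Electron mean free path, nm.
#' @param surface_scattering Dimensionless surface-scattering constant.
#' @return An object of class `drude_params`.
#' @export
drude_params <- function(plasma_frequency = 1.37e16, fermi_velocity = 1.40e6,
                         mean_free_path_nm = 42, surface_scattering = 1) {
  if (mean_free_path_nm <= 0) stop("mean free path must be > 0")
  if (surface_scattering < 0) stop("surface-scattering constant must be >= 0")
  gb <- fermi_velocity / (mean_free_path_nm * 1e-9)
  structure(list(plasma_frequency = plasma_frequency,
                 fermi_velocity = fermi_velocity,
                 mean_free_path_nm = mean_free_path_nm,
                 surface_scattering = surface_scattering,
                 bulk_damping = gb),
            class = "drude_params")
}

#' Bulk gold permittivity from the packaged dispersion table
#'
#' Linear interpolation (separately on real and imaginary parts) of a
#' Johnson-Christy-type table of gold optical constants.
#'
#' @param wavelength_nm Wavelength(s), nm.
#' @param path Optional alternative two-column-pair table
#'   (wavelength_nm, eps_re, eps_im).
#' @return Complex permittivity, vectorized over wavelength.
#' @export
gold_permittivity <- function(wavelength_nm,
                              path = system.file("extdata", "gold_dielectric.tsv",
                                                 package = "nanotherm")) {
  tab <- utils::read.delim(path)
  if (any(wavelength_nm < min(tab$wavelength_nm) |
          wavelength_nm > max(tab$wavelength_nm)))
    stop("wavelength outside the tabulated range [",
         min(tab$wavelength_nm), ", ", max(tab$wavelength_nm), "] nm")
  complex(real = stats::approx(tab$wavelength_nm, tab$eps_re, wavelength_nm)$y,
          imaginary = stats::approx(tab$wavelength_nm, tab$eps_im, wavelength_nm)$y)
}

#' Depolarization factors of a prolate spheroid
#'
#' For a rod of diameter D and length l (prolate spheroid with
#' eccentricity x = sqrt(1 - (D/l)^2)), the longitudinal factor is
#' P1 = ((1 - x^2)/x^2) * (ln((1+x)/(1-x))/(2x) - 1) and the two
#' transverse factors are P2 = P3 = (1 - P1)/2. At D = l the continuous
#' extension P1 = 1/3 (sphere) is returned.
#'
#' @param diameter_nm Rod diameter, nm.
#' @param length_nm Rod length, nm.
#' @return Numeric vector `c(P1, P2, P3)`, summing to one.
#' @export
depolarization_factors <- function(diameter_nm, length_nm) {
  if (!(diameter_nm > 0)) stop("diameter must be > 0")
  if (diameter_nm > length_nm)
    stop("prolate-only model: requires diameter <= length")
  ratio <- diameter_nm / length_nm
  x2 <- 1 - ratio^2
  if (x2 < 1e-12) {
    p1 <- 1 / 3
  } else {
    x <- sqrt(x2)
    p1 <- (1 - x2) / x2 * (log((1 + x) / (1 - x)) / (2 * x) - 1)
  }
  c(P1 = p1, P2 = (1 - p1) / 2, P3 = (1 - p1) / 2)
}

#' Volume of an s-cylinder nanorod
#'
#' The rod is modeled as a cylinder of radius b = D/2 and section length
#' 2a capped by two hemispheres, total length 2(a + b) = l:
#' V = 2 pi a b^2 + (4/3) pi b^3.
#'
#' @param spec A `gnr_spec`.
#' @return Volume in nm^3.
#' @export
particle_volume <- function(spec) {
  b <- spec$diameter_nm / 2
  a <- spec$length_nm / 2 - b
  2 * pi * a * b^2 + 4 / 3 * pi * b^3
}

#' Volume-equivalent radius of an s-cylinder nanorod
#'
#' Radius of the sphere with the same volume as the s-cylinder,
#' (3 V / 4 pi)^(1/3); reduces to D/2 when l = D.
#'
#' @param diameter_nm Rod diameter, nm.
#' @param length_nm Rod length, nm.
#' @return Equivalent radius, nm.
#' @export
equivalent_radius <- function(diameter_nm, length_nm) {
  if (length_nm < diameter_nm) stop("requires length >= diameter")
  v <- particle_volume(gnr_spec(diameter_nm, length_nm))
  (3 * v / (4 * pi))^(1 / 3)
}

#' Size-corrected metal permittivity
#'
#' Adds to the bulk permittivity the difference of two Drude terms, the
#' second with damping increased by surface scattering:
#' gamma_a = gamma_bulk + g vF / a. The correction vanishes for large
#' particles or g = 0 and only adds loss (Im eps(a) >= Im eps_bulk).
#'
#' @param a_nm Equivalent particle radius, nm.
#' @param wavelength_nm Wavelength, nm.
#' @param eps_bulk Bulk complex permittivity at that wavelength
#'   (default: packaged gold table).
#' @param drude A `drude_params`.
#' @return Complex permittivity of the particle.
#' @export
size_corrected_permittivity <- function(a_nm, wavelength_nm,
                                        eps_bulk = gold_permittivity(wavelength_nm),
                                        drude = drude_params()) {
  if (!(a_nm > 0)) stop("particle radius must be > 0")
  w <- 2 * pi * 2.99792458e8 / (wavelength_nm * 1e-9)
  gb <- drude$bulk_damping
  ga <- gb + drude$surface_scattering * drude$fermi_velocity / (a_nm * 1e-9)
  wp2 <- drude$plasma_frequency^2
  eps_bulk + wp2 / (w * (w + 1i * gb)) - wp2 / (w * (w + 1i * ga))
}

#' Quasi-static polarizabilities of a prolate spheroid (Gans theory)
#'
#' alpha_i = 4 pi a b c (eps - eps_m) / (3 eps_m + 3 P_i (eps - eps_m))
#' with semi-axes a = l/2, b = c = D/2. At D = l this reduces to the
#' Clausius-Mossotti small-sphere polarizability
#' 4 pi r^3 (eps - eps_m)/(eps + 2 eps_m).
#'
#' @param eps Complex particle permittivity.
#' @param eps_m Complex host permittivity.
#' @param diameter_nm,length_nm Rod dimensions, nm.
#' @return Complex vector `c(alpha1, alpha2, alpha3)` in nm^3.
#' @export
gans_polarizability <- function(eps, eps_m, diameter_nm, length_nm) {
  p <- depolarization_factors(diameter_nm, length_nm)
  abc <- (length_nm / 2) * (diameter_nm / 2)^2
  den <- 3 * eps_m + 3 * p * (eps - eps_m)
  if (any(abs(den) == 0)) stop("singularity: resonance denominator is zero")
  4 * pi * abc * (eps - eps_m) / den
}

#' Orientation-averaged absorption cross section of a nanorod
#'
#' C_abs = k * Im[(alpha1 + alpha2 + alpha3)/3] with
#' k = 2 pi sqrt(Re eps_m) / lambda. The host must be transparent
#' (Im eps_m = 0).
#'
#' @param spec A `gnr_spec`.
#' @param eps Complex particle permittivity.
#' @param eps_m Host permittivity (transparent: real part > 0,
#'   imaginary part 0).
#' @param wavelength_nm Wavelength, nm.
#' @return Cross section in nm^2.
#' @export
absorption_cross_section <- function(spec, eps, eps_m, wavelength_nm) {
  if (Re(eps_m) <= 0) stop("host permittivity must have positive real part")
  if (abs(Im(eps_m)) > 1e-12)
    stop("unsupported model: absorptive host (Im eps_m != 0)")
  al <- gans_polarizability(eps, eps_m, spec$diameter_nm, spec$length_nm)
  k <- 2 * pi * sqrt(Re(eps_m)) / wavelength_nm
  k * Im(mean(al))
}

#' Absorption cross-section spectrum
#'
#' Sweeps [absorption_cross_section()] over wavelength using the
#' packaged gold dispersion with the size correction at the rod's
#' volume-equivalent radius.
#'
#' @param spec A `gnr_spec`.
#' @param wavelengths_nm Wavelengths to evaluate, nm.
#' @param eps_m Host permittivity.
#' @param drude A `drude_params`.
#' @return A tibble with `wavelength_nm` and `c_abs_nm2`.
#' @export
cross_section_spectrum <- function(spec, wavelengths_nm = seq(600, 1000, by = 2),
                                   eps_m = complex(real = 1.767),
                                   drude = drude_params()) {
  a_eq <- equivalent_radius(spec$diameter_nm, spec$length_nm)
  cs <- vapply(wavelengths_nm, function(l) {
    eps <- size_corrected_permittivity(a_eq, l, gold_permittivity(l), drude)
    absorption_cross_section(spec, eps, eps_m, l)
  }, numeric(1))
  tibble::tibble(wavelength_nm = wavelengths_nm, c_abs_nm2 = cs)
}

#' Nanoparticle volume fraction
#'
#' Mass concentration over bulk density, unit-consistent:
#' ug/mL over g/cm^3 gives 1e-6 * (ug/mL) / (g/cm^3).
#'
#' @param mass_concentration ug/mL.
#' @param bulk_gold_density g/cm^3.
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(mass_concentration, bulk_gold_density = 19.3) {
  if (mass_concentration < 0) stop("mass concentration must be >= 0")
  if (bulk_gold_density <= 0) stop("bulk density must be > 0")
  (mass_concentration * 1e-6) / bulk_gold_density
}

#' Nanoparticle number density
#'
#' Volume fraction divided by single-particle volume.
#'
#' @param mass_concentration ug/mL.
#' @param spec A `gnr_spec`.
#' @return Particles per m^3.
#' @export
number_density <- function(mass_concentration, spec) {
  v_m3 <- particle_volume(spec) * 1e-27
  if (v_m3 <= 0) stop("zero particle volume")
  volume_fraction(mass_concentration, spec$bulk_gold_density) / v_m3
}

#' Nano-absorption coefficient and length
#'
#' mu_a = N * C_abs; the nano-absorption length is its inverse (the mean
#' free path of a photon before absorption by the nanoparticle
#' population), infinite at N = 0.
#'
#' @param n_density Particles per m^3.
#' @param c_abs_nm2 Absorption cross section, nm^2.
#' @return A list with `mu_a_cm` (1/cm) and `length_cm` (cm).
#' @export
nano_absorption <- function(n_density, c_abs_nm2) {
  if (n_density < 0 || c_abs_nm2 < 0) stop("inputs must be >= 0")
  mu_m <- n_density * c_abs_nm2 * 1e-18   # 1/m
  mu_cm <- mu_m / 100
  list(mu_a_cm = mu_cm, length_cm = if (mu_cm > 0) 1 / mu_cm else Inf)
}

#' Full nanorod optics chain for a scenario
#'
#' Computes, from a rod spec and host/particle permittivities, the
#' orientation-averaged cross section, number density and
#' nano-absorption coefficient used by the transport and heating steps.
#'
#' @param spec A `gnr_spec`.
#' @param eps Particle permittivity; `NULL` means size-corrected gold
#'   from the packaged dispersion at the rod's equivalent radius.
#' @param eps_m Host permittivity.
#' @param wavelength_nm Wavelength, nm.
#' @return A list: `c_abs_nm2`, `n_density`, `mu_a_nano_cm`,
#'   `absorption_length_cm`, `volume_fraction`, `eps`, `eps_m`.
#' @export
gnr_optics <- function(spec, eps = NULL, eps_m = complex(real = 1.767),
                       wavelength_nm = 808) {
  if (is.null(eps)) {
    a_eq <- equivalent_radius(spec$diameter_nm, spec$length_nm)
    eps <- size_corrected_permittivity(a_eq, wavelength_nm)
  }
  c_abs <- absorption_cross_section(spec, eps, eps_m, wavelength_nm)
  n <- number_density(spec$mass_concentration, spec)
  na <- nano_absorption(n, c_abs)
  list(c_abs_nm2 = c_abs, n_density = n, mu_a_nano_cm = na$mu_a_cm,
       absorption_length_cm = na$length_cm,
       volume_fraction = volume_fraction(spec$mass_concentration,
                                         spec$bulk_gold_density),
       eps = eps, eps_m = eps_m)
}
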