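#' Define a material
#'
#' A material bundles the optical and thermal properties of one medium:
#' tissue absorption and scattering coefficients, scattering anisotropy,
#' refractive index and (host) permittivity on the optical side; density,
#' heat capacity, thermal diffusivity and blood perfusion on the thermal
#' side. Thermal conductivity is derived as k = rho * cp * alpha_d and is
#' not stored.
#'
#' @param name Material identifier.
#' @param rho Density, kg/m^3. Must be positive.
#' @param cp Heat capacity, J/(kg K). Must be positive.
#' @param alpha_d Thermal diffusivity, mm^2/s.
#' @param mu_a Tissue absorption coefficient, 1/cm.
#' @param mu_s Scattering coefficient, 1/cm.
#' @param g_hg Henyey-Greenstein anisotropy factor, in [-1, 1].
#' @param ri Refractive index (dimensionless).
#' @param eps Complex relative permittivity of the medium.
#' @param mu_a_nano Nanoparticle absorption coefficient, 1/cm. Zero for
#'   plain media; positive marks the material as nanoparticle-loaded.
#' @param wb Blood perfusion rate, 1/s.
#' @param rho_b,c_b,t_b Blood density (kg/m^3), heat capacity (J/(kg K))
#'   and temperature (degC) feeding the perfusion term.
#' @param composition Named numeric vector of element weight fractions;
#'   normalized to sum to one.
#' @return An object of class `material`.
#' @export
material <- function(name, rho, cp, alpha_d, mu_a = 0, mu_s = 0, g_hg = 0,
                     ri = 1, eps = complex(real = 1, imaginary = 0),
                     mu_a_nano = 0, wb = 0, rho_b = 1060, c_b = 3600,
                     t_b = 37, composition = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(rho) || rho <= 0) stop("material '", name, "': density must be > 0")
  if (!is.finite(cp) || cp <= 0) stop("material '", name, "': heat capacity must be > 0")
  if (alpha_d < 0) stop("material '", name, "': thermal diffusivity must be >= 0")
  if (mu_a < 0 || mu_s < 0 || mu_a_nano < 0)
    stop("material '", name, "': optical coefficients must be >= 0")
  if (abs(g_hg) > 1) stop("material '", name, "': |g_hg| must be <= 1")
  if (wb < 0) stop("material '", name, "': perfusion must be >= 0")
  if (!is.null(composition)) {
    composition <- unlist(composition)
    if (any(composition < 0)) stop("material '", name, "': negative composition weight")
    s <- sum(composition)
    if (s <= 0) stop("material '", name, "': composition sums to zero")
    composition <- composition / s
  }
  structure(
    list(name = name, rho = rho, cp = cp, alpha_d = alpha_d,
         mu_a = mu_a, mu_s = mu_s, g_hg = g_hg, ri = ri,
         eps = as.complex(eps), mu_a_nano = mu_a_nano, wb = wb,
         rho_b = rho_b, c_b = c_b, t_b = t_b, composition = composition),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, "\n",
      sprintf("  rho %.6g kg/m^3, cp %.6g J/(kg K), alpha %.4g mm^2/s\n",
              x$rho, x$cp, x$alpha_d),
      sprintf("  mu_a %.4g /cm, mu_s %.4g /cm, g %.3g, RI %.4g, nano mu_a %.4g /cm\n",
              x$mu_a, x$mu_s, x$g_hg, x$ri, x$mu_a_nano))
  invisible(x)
}

#' Thermal conductivity of a material
#'
#' k = rho * cp * alpha_d, in W/(m K) (alpha_d given in mm^2/s).
#' @param mat A `material`.
#' @return Conductivity in W/(m K).
#' @export
thermal_conductivity <- function(mat) {
  mat$rho * mat$cp * mat$alpha_d * 1e-6
}

parse_composition <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  vals <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

#' Load a material table
#'
#' Reads a delimited text table, one material per row, with columns
#' `name, rho, ri, mu_a, mu_s, g_hg, cp, alpha_d, wb, eps_re, eps_im`
#' plus an optional `mu_a_nano` column and a trailing `composition`
#' column of `element:weight` pairs (weights are normalized at load
#' time). Every row is validated against the material invariants.
#'
#' @param path Path to the table. Defaults to the packaged table of
#'   pancreas, nanorod-loaded tumor, water and air.
#' @return Named list of `material` objects.
#' @export
load_material_table <- function(path = system.file("extdata", "materials.tsv",
                                                   package = "nanotherm")) {
  if (!file.exists(path)) stop("material table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "rho", "ri", "mu_a", "mu_s", "g_hg", "cp",
                "alpha_d", "wb", "eps_re", "eps_im")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("material table is missing column(s): ", paste(missing, collapse = ", "))
  if (!"mu_a_nano" %in% names(df)) df$mu_a_nano <- 0
  mats <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    material(name = r$name, rho = r$rho, cp = r$cp, alpha_d = r$alpha_d,
             mu_a = r$mu_a, mu_s = r$mu_s, g_hg = r$g_hg, ri = r$ri,
             eps = complex(real = r$eps_re, imaginary = r$eps_im),
             mu_a_nano = r$mu_a_nano, wb = r$wb,
             composition = if ("composition" %in% names(df))
               parse_composition(r$composition) else NULL)
  })
  names(mats) <- df$name
  mats
}

#' Material table as a tibble
#'
#' @param materials Named list of `material` objects (default: packaged
#'   table).
#' @return A tibble, one row per material.
#' @export
material_table <- function(materials = load_material_table()) {
  purrr::map_dfr(materials, function(m)
    tibble::tibble(name = m$name, rho = m$rho, ri = m$ri, mu_a = m$mu_a,
                   mu_s = m$mu_s, g_hg = m$g_hg, cp = m$cp,
                   alpha_d = m$alpha_d, wb = m$wb,
                   eps_re = Re(m$eps), eps_im = Im(m$eps),
                   mu_a_nano = m$mu_a_nano,
                   k_w_mk = thermal_conductivity(m)))
}
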