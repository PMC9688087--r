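#' Transport settings
#'
#' @param n_histories Number of photon histories (>= 1).
#' @param seed RNG seed recorded with the run.
#' @param max_steps Safety cap on steps per photon.
#' @return An object of class `transport_settings`.
#' @export
transport_settings <- function(n_histories = 2e6, seed = 1L, max_steps = 1e6) {
  if (n_histories < 1) stop("n_histories must be >= 1")
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(n_histories = as.integer(n_histories), seed = as.integer(seed),
                 max_steps = as.integer(max_steps)),
            class = "transport_settings")
}

#' Sample an exponential free path
#'
#' s = -ln(u) / mu_t. A non-positive total attenuation means a
#' transparent medium: the photon travels to the boundary (infinite
#' path).
#'
#' @param mu_t Total attenuation coefficient, 1/cm.
#' @param u Uniform(0,1) variate(s).
#' @return Free path in cm.
#' @export
sample_free_path <- function(mu_t, u) {
  if (mu_t <= 0) return(rep(Inf, length(u)))
  if (any(u <= 0 | u >= 1)) stop("u must lie in (0,1)")
  -log(u) / mu_t
}

#' Choose the interaction type at a collision
#'
#' Events are drawn with probability proportional to their
#' coefficients. All-zero coefficients mean a ballistic (no-interaction)
#' contract.
#'
#' @param mu_a_tissue,mu_a_nano,mu_s Coefficients, 1/cm.
#' @param u Uniform(0,1) variate(s).
#' @return Character vector in
#'   `c("tissue_absorb", "nano_absorb", "scatter", "none")`.
#' @export
choose_interaction <- function(mu_a_tissue, mu_a_nano, mu_s, u) {
  mt <- mu_a_tissue + mu_a_nano + mu_s
  if (mt <= 0) return(rep("none", length(u)))
  e <- u * mt
  ifelse(e < mu_a_tissue, "tissue_absorb",
         ifelse(e < mu_a_tissue + mu_a_nano, "nano_absorb", "scatter"))
}

#' Sample a scattered direction (Henyey-Greenstein)
#'
#' The deflection cosine is drawn from the Henyey-Greenstein
#' distribution with anisotropy `g_hg` (isotropic at g = 0); the
#' azimuthal angle is uniform. The mean deflection cosine equals g.
#'
#' @param g_hg Anisotropy factor, |g| < 1.
#' @param incoming Unit direction vector.
#' @return Unit direction vector.
#' @export
scatter_direction <- function(g_hg, incoming) {
  if (abs(g_hg) >= 1) stop("|g_hg| must be < 1")
  if (abs(g_hg) < 1e-8) {
    ct <- 2 * stats::runif(1) - 1
  } else {
    f <- (1 - g_hg^2) / (1 - g_hg + 2 * g_hg * stats::runif(1))
    ct <- max(-1, min(1, (1 + g_hg^2 - f^2) / (2 * g_hg)))
  }
  st <- sqrt(1 - ct^2)
  ph <- 2 * pi * stats::runif(1)
  u <- incoming
  if (abs(u[3]) > 0.99999) {
    out <- c(st * cos(ph), st * sin(ph), sign(u[3]) * ct)
  } else {
    den <- sqrt(1 - u[3]^2)
    out <- c(st * (u[1] * u[3] * cos(ph) - u[2] * sin(ph)) / den + u[1] * ct,
             st * (u[2] * u[3] * cos(ph) + u[1] * sin(ph)) / den + u[2] * ct,
             -st * cos(ph) * den + u[3] * ct)
  }
  out / sqrt(sum(out^2))
}

#' Run Monte Carlo photon transport
#'
#' Launches photons from the beam tip disc and random-walks each one
#' through the voxelized phantom: free paths are sampled from the
#' current voxel's total attenuation (optical-depth tracking across
#' voxel boundaries), scattering redirects via Henyey-Greenstein,
#' absorption (tissue or nanoparticle channel) deposits the full photon
#' energy in the current voxel, and photons leaving the world escape.
#' Deterministic given the seed.
#'
#' @param phantom A `phantom`.
#' @param beam A `laser_beam` whose tip lies inside the world.
#' @param settings A `transport_settings`.
#' @return An `energy_map`: per-voxel deposited energy (eV), absorption
#'   counts (total and nano channel), geometry, history count and seed.
#' @export
run_transport <- function(phantom, beam, settings = transport_settings()) {
  stopifnot(inherits(phantom, "phantom"), inherits(beam, "laser_beam"),
            inherits(settings, "transport_settings"))
  lo <- phantom$origin
  hi <- phantom$origin + phantom$shape * phantom$pitch
  tip <- beam$tip_position_mm
  if (any(tip < lo) || any(tip > hi))
    stop("geometry error: beam tip lies outside the world")
  mats <- phantom$materials
  # 1/cm -> 1/mm
  mu_a <- vapply(mats, function(m) m$mu_a / 10, numeric(1))
  mu_an <- vapply(mats, function(m) m$mu_a_nano / 10, numeric(1))
  mu_s <- vapply(mats, function(m) m$mu_s / 10, numeric(1))
  g <- vapply(mats, function(m) m$g_hg, numeric(1))
  e0 <- photon_energy(beam$wavelength_nm)
  # single-medium fast path: every material present is optically identical
  present <- sort(unique(as.integer(phantom$labels)))
  props <- cbind(mu_a, mu_an, mu_s, g)[present, , drop = FALSE]
  homogeneous <- nrow(unique(props)) == 1L
  if (homogeneous) {
    mu_a <- props[1, 1]; mu_an <- props[1, 2]
    mu_s <- props[1, 3]; g <- props[1, 4]
  }
  res <- cpp_transport(phantom$shape, phantom$pitch, phantom$origin,
                       phantom$labels, mu_a, mu_an, mu_s, g,
                       tip, beam$direction, beam$tip_diameter_mm / 2,
                       as.numeric(settings$n_histories), settings$max_steps,
                       as.numeric(settings$seed), homogeneous)
  counts <- array(res$counts_tissue + res$counts_nano, dim = phantom$shape)
  structure(list(
    energy = counts * e0,
    counts = counts,
    counts_nano = array(res$counts_nano, dim = phantom$shape),
    shape = phantom$shape, pitch = phantom$pitch, origin = phantom$origin,
    n_histories = settings$n_histories, seed = settings$seed,
    e0_ev = e0, n_escaped = res$n_escaped, n_absorbed = res$n_absorbed,
    n_terminated = res$n_terminated),
    class = "energy_map")
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map> %d x %d x %d voxels, %g histories (seed %d)\n",
              x$shape[1], x$shape[2], x$shape[3], x$n_histories, x$seed),
      sprintf("  absorbed %g (%.1f%%), escaped %g, terminated %g; total %.4g eV\n",
              x$n_absorbed, 100 * x$n_absorbed / x$n_histories,
              x$n_escaped, x$n_terminated, sum(x$energy)))
  invisible(x)
}

#' Per-voxel relative statistical uncertainty
#'
#' 1 / sqrt(Np (Np - 1)) for voxels with at least two absorbed photons;
#' `NA` where the estimate is undefined (Np < 2).
#'
#' @param emap An `energy_map`.
#' @return Array of relative uncertainties (fractions, not %).
#' @export
uncertainty_map <- function(emap) {
  np <- emap$counts
  out <- array(NA_real_, dim = dim(np))
  ok <- np >= 2
  out[ok] <- 1 / sqrt(np[ok] * (np[ok] - 1))
  out
}
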