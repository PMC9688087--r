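#' Packaged pancreas photothermal-therapy scenario
#'
#' A cubic pancreas phantom (4 cm^3 world, 0.25 mm voxels) with a 3 cm^3
#' spherical tumor centered on the interstitial applicator tip at the
#' origin (truncated at the world faces, which the sphere slightly
#' exceeds), optionally loaded with 10 x 41 nm gold nanorods at
#' 12.5 ug/mL. The 808 nm source emits 2e6 simulated photons/s along +z.
#'
#' @param power_w Laser power, W.
#' @param tip_diameter_mm Applicator tip diameter, mm.
#' @param gnr Load the tumor with nanorods?
#' @param duration_s Irradiation duration, s.
#' @param schedule Output times, s.
#' @param n_histories Photon histories.
#' @param nano_mu_a `"computed"` (N x C_abs) or `"table"` (the packaged
#'   1.685 1/cm value).
#' @param area_unit Flux scaling convention, see [laser_beam()].
#' @param heat_model See [irradiate()].
#' @return A `scenario` list.
#' @export
scenario_pancreas_ptt <- function(power_w = 2.1, tip_diameter_mm = 0.3,
                                  gnr = TRUE, duration_s = 120,
                                  schedule = c(10, 20, 30, 40, 60, 85, 120),
                                  n_histories = 2e6,
                                  nano_mu_a = c("computed", "table"),
                                  area_unit = "mm2",
                                  heat_model = "auto") {
  nano_mu_a <- match.arg(nano_mu_a)
  structure(list(
    name = if (gnr) "pancreas_ptt" else "pancreas_plain",
    phantom = list(kind = "cube", world_volume_cm3 = 4, pitch_mm = 0.25,
                   base_material = "pancreas",
                   tumor = if (gnr) list(volume_cm3 = 3, center = c(0, 0, 0),
                                         material = "tumor_gnr", clip = TRUE)),
    materials = "default",
    gnr = if (gnr) list(diameter_nm = 10, length_nm = 41,
                        mass_concentration = 12.5, bulk_gold_density = 19.3,
                        particle_eps = "table", host_eps_re = 1.767,
                        host_eps_im = 0, nano_mu_a = nano_mu_a),
    laser = list(wavelength_nm = 808, power_w = power_w,
                 tip_diameter_mm = tip_diameter_mm,
                 tip_position_mm = c(0, 0, 0), direction = c(0, 0, 1),
                 emission_rate = 2e6, duration_s = duration_s,
                 area_unit = area_unit),
    transport = list(n_histories = n_histories, max_steps = 1e6),
    heat = list(model = heat_model, alpha_mm2_s = if (gnr) 0.16 else 0.14,
                dt_s = 1, baseline_c = 26, perfusion = FALSE),
    schedule = schedule,
    probes = list(list(position_mm = c(0, 2, 0), mode = "hd"),
                  list(position_mm = c(0, 0, 2), mode = "vd")),
    threshold_c = 155), class = "scenario")
}

#' Packaged water-drop benchmark scenario
#'
#' A 0.1 mL drop (cylinder of default radius 7.75 mm matching a 24-well
#' footprint) of water, plain or loaded with 0.625 mg/mL nanorods,
#' surface-illuminated for 30 s from above in air. The reported quantity
#' is the maximum surface temperature rise, mirroring an IR-camera
#' reading.
#'
#' @param power_w Laser power, W.
#' @param gnr Load the water with nanorods?
#' @param drop_radius_mm Drop (well) radius, mm.
#' @param beam_diameter_mm Collimated beam diameter at the surface, mm.
#' @param n_histories Photon histories.
#' @param schedule Output times, s.
#' @return A `scenario` list.
#' @export
scenario_water_drop <- function(power_w = 2.1, gnr = TRUE,
                                drop_radius_mm = 7.75, beam_diameter_mm = 3,
                                n_histories = 2e5, schedule = c(10, 20, 30)) {
  drop_height <- 100 / (pi * drop_radius_mm^2)   # 0.1 mL
  structure(list(
    name = if (gnr) "water_drop_gnr" else "water_drop",
    phantom = list(kind = "cylinder_drop", world_volume_cm3 = 4.096,
                   pitch_mm = 0.1, base_material = "air",
                   drop = list(material = "water", radius_mm = drop_radius_mm,
                               z_range = c(-drop_height, 0))),
    materials = "default",
    gnr = if (gnr) list(diameter_nm = 10, length_nm = 41,
                        mass_concentration = 625, bulk_gold_density = 19.3,
                        particle_eps = "drude", host_eps_re = 1.769,
                        host_eps_im = 0, nano_mu_a = "computed"),
    laser = list(wavelength_nm = 808, power_w = power_w,
                 tip_diameter_mm = beam_diameter_mm,
                 tip_position_mm = c(0, 0, -1e-6), direction = c(0, 0, -1),
                 emission_rate = 2e6, duration_s = 30, area_unit = "mm2"),
    transport = list(n_histories = n_histories, max_steps = 1e6),
    heat = list(model = "auto", alpha_mm2_s = 0.143, dt_s = 1,
                baseline_c = 26, perfusion = FALSE),
    schedule = schedule,
    probes = list(list(position_mm = c(0, 0, -0.05), mode = "vd")),
    threshold_c = 155), class = "scenario")
}

#' Read a scenario from a YAML config
#' @param path YAML file (see the packaged files under
#'   `system.file("scenarios", package = "nanotherm")`).
#' @return A `scenario` list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  for (fld in c("tip_position_mm", "direction"))
    if (!is.null(sc$laser[[fld]])) sc$laser[[fld]] <- as.numeric(sc$laser[[fld]])
  if (!is.null(sc$phantom$tumor$center))
    sc$phantom$tumor$center <- as.numeric(sc$phantom$tumor$center)
  sc$schedule <- as.numeric(unlist(sc$schedule))
  sc$probes <- lapply(sc$probes, function(p) {
    p$position_mm <- as.numeric(unlist(p$position_mm)); p
  })
  structure(sc, class = "scenario")
}

build_scenario_phantom <- function(sc, materials) {
  base <- materials[[sc$phantom$base_material]]
  ph <- build_world(sc$phantom$world_volume_cm3, sc$phantom$pitch_mm, base)
  if (!is.null(sc$phantom$tumor)) {
    tu <- sc$phantom$tumor
    ph <- embed_spherical_tumor(ph, tu$volume_cm3, tu$center,
                                materials[[tu$material]],
                                clip = isTRUE(tu$clip))
  }
  if (!is.null(sc$phantom$drop)) {
    dr <- sc$phantom$drop
    ph <- embed_cylinder(ph, dr$radius_mm, as.numeric(unlist(dr$z_range)),
                         material = materials[[dr$material]])
  }
  ph
}

scenario_gnr_optics <- function(sc, materials) {
  if (is.null(sc$gnr)) return(NULL)
  g <- sc$gnr
  spec <- gnr_spec(g$diameter_nm, g$length_nm, g$mass_concentration,
                   g$bulk_gold_density %||% 19.3)
  host <- complex(real = g$host_eps_re, imaginary = g$host_eps_im %||% 0)
  eps <- if (identical(g$particle_eps, "drude")) NULL else {
    # the nanorod-loaded material row stores the particle permittivity
    loaded <- Filter(function(m) m$mu_a_nano > 0 || Re(m$eps) < 0, materials)
    if (length(loaded)) loaded[[1]]$eps else NULL
  }
  out <- gnr_optics(spec, eps = eps, eps_m = host,
                    wavelength_nm = sc$laser$wavelength_nm)
  out$spec <- spec
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full scenario
#'
#' Executes the pipeline phantom build, nanorod optics (if present),
#' Monte Carlo transport, heat conversion and diffusion, and probe/map
#' extraction. With `out_dir`, writes the energy and count maps and the
#' temperature fields as `.img`/`.hdr` volumes, probe series as
#' tab-delimited text, and a JSON manifest of all resolved parameters.
#' Reruns with the same config and seed are bit-reproducible through
#' transport and deterministic thereafter.
#'
#' @param scenario A `scenario` (constructor or [read_scenario()]).
#' @param seed RNG seed.
#' @param out_dir Optional output directory.
#' @param n_histories Optional override of the configured history count.
#' @return A `ptt_run`: phantom, beam, optics, energy map, temperature
#'   fields, probes (one tibble, keyed by probe label) and a summary.
#' @export
run_scenario <- function(scenario, seed = 1L, out_dir = NULL,
                         n_histories = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  materials <- if (identical(scenario$materials, "default"))
    load_material_table() else load_material_table(scenario$materials)

  optics <- withCallingHandlers(
    scenario_gnr_optics(scenario, materials),
    error = function(e) stop("[gnr_optics] ", conditionMessage(e), call. = FALSE))

  # resolve the nano-absorption channel on the loaded material
  if (!is.null(optics)) {
    loaded_names <- names(Filter(function(m) m$mu_a_nano > 0, materials))
    target <- if (!is.null(scenario$phantom$tumor))
      scenario$phantom$tumor$material
    else scenario$phantom$drop$material
    mu <- if (identical(scenario$gnr$nano_mu_a, "table") && target %in% loaded_names)
      materials[[target]]$mu_a_nano else optics$mu_a_nano_cm
    materials[[target]]$mu_a_nano <- mu
  }

  phantom <- withCallingHandlers(
    build_scenario_phantom(scenario, materials),
    error = function(e) stop("[phantom] ", conditionMessage(e), call. = FALSE))

  beam <- do.call(laser_beam, scenario$laser)
  nh <- as.integer(n_histories %||% scenario$transport$n_histories)
  settings <- transport_settings(n_histories = nh, seed = seed,
                                 max_steps = scenario$transport$max_steps %||% 1e6)
  emap <- withCallingHandlers(
    run_transport(phantom, beam, settings),
    error = function(e) stop("[transport] ", conditionMessage(e), call. = FALSE))

  heat <- scenario$heat
  model <- thermal_model(alpha_d = heat$alpha_mm2_s, qb = 0,
                         tb = heat$baseline_c)
  fields <- withCallingHandlers(
    irradiate(phantom, beam, emap, model, schedule = scenario$schedule,
              dt = heat$dt_s %||% 1, heat_model = heat$model %||% "auto",
              gnr = optics, baseline = heat$baseline_c),
    error = function(e) stop("[bioheat] ", conditionMessage(e), call. = FALSE))

  probes <- purrr::imap_dfr(scenario$probes, function(p, i) {
    pr <- probe_series(fields, p$position_mm, p$mode)
    dplyr::mutate(pr,
                  probe = paste0(p$mode, "_",
                                 paste(p$position_mm, collapse = "_")),
                  .before = 1)
  })

  max_dt <- vapply(fields, function(f) max(f$delta_t), numeric(1))
  t_max <- max(scenario$schedule)
  scenario_name <- scenario$name
  summary <- tibble::tibble(
    scenario = scenario_name, seed = seed, n_histories = nh,
    power_w = beam$power_w, tip_diameter_mm = beam$tip_diameter_mm,
    scaling = flux_scaling_factor(beam),
    mu_a_nano_cm = if (is.null(optics)) 0 else
      max(vapply(phantom$materials, `[[`, numeric(1), "mu_a_nano")),
    absorbed_fraction = emap$n_absorbed / nh,
    peak_uncertainty_pct = 100 * min(uncertainty_map(emap), na.rm = TRUE),
    max_delta_t_c = max(max_dt), t_max_s = t_max)

  run <- structure(list(scenario = scenario, seed = seed, phantom = phantom,
                        beam = beam, optics = optics, emap = emap,
                        fields = fields, probes = probes, summary = summary),
                   class = "ptt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  em <- run$emap
  write_map(em$energy, file.path(out_dir, "energy_ev"), em$pitch, em$origin,
            datatype = "float64")
  write_map(em$counts + 0, file.path(out_dir, "counts"), em$pitch, em$origin,
            datatype = "float64")
  for (f in run$fields)
    write_map(f$delta_t, file.path(out_dir, sprintf("deltaT_t%03ds", round(f$time))),
              f$pitch, f$origin, datatype = "float32")
  utils::write.table(run$probes, file.path(out_dir, "probes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(scenario = run$scenario[setdiff(names(run$scenario), "probes")],
                   seed = run$seed, n_histories = em$n_histories,
                   e0_ev = em$e0_ev,
                   scaling = flux_scaling_factor(run$beam),
                   optics = if (!is.null(run$optics))
                     run$optics[c("c_abs_nm2", "n_density", "mu_a_nano_cm",
                                  "volume_fraction")],
                   n_absorbed = em$n_absorbed, n_escaped = em$n_escaped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.ptt_run <- function(x, ...) {
  cat("<ptt_run>", x$scenario$name, "\n")
  print(x$summary)
  invisible(x)
}
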