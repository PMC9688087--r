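#' Extract a virtual temperature probe
#'
#' Samples the voxel containing `position` (nearest-voxel sampling) in
#' each field of a time series, mirroring the simulated "detectors"
#' placed at a horizontal (hd, lateral) or vertical (vd, along-beam)
#' distance from the applicator tip.
#'
#' @param fields List of `temperature_field`s (increasing times).
#' @param position World coordinate, mm.
#' @param mode `"hd"` or `"vd"` (metadata only).
#' @return A `probe`: tibble with `time_s`, `delta_t_c`,
#'   `temperature_c`, carrying the position and mode as attributes.
#' @export
probe_series <- function(fields, position, mode = c("hd", "vd")) {
  mode <- match.arg(mode)
  f1 <- fields[[1]]
  phantom_like <- list(shape = f1$shape, pitch = f1$pitch, origin = f1$origin)
  idx <- world_to_voxel(structure(phantom_like, class = "phantom"), position)
  times <- vapply(fields, `[[`, numeric(1), "time")
  if (is.unsorted(times, strictly = TRUE))
    stop("field times must be strictly increasing")
  dt <- vapply(fields, function(f) f$delta_t[idx[1], idx[2], idx[3]], numeric(1))
  out <- tibble::tibble(time_s = times, delta_t_c = dt,
                        temperature_c = f1$baseline + dt)
  attr(out, "position_mm") <- position
  attr(out, "mode") <- mode
  attr(out, "baseline_c") <- f1$baseline
  class(out) <- c("probe", class(out))
  out
}

#' Relative error between experiment and simulation
#'
#' |(experiment - simulation) / experiment| x 100, in percent;
#' undefined (error) at experiment = 0. Scale-invariant.
#'
#' @param experiment Measured value(s), degC.
#' @param simulation Simulated value(s), degC.
#' @return Percent relative error.
#' @export
relative_error <- function(experiment, simulation) {
  if (any(experiment == 0)) stop("undefined metric: experiment value is zero")
  abs((experiment - simulation) / experiment) * 100
}

#' Truncate a probe series at a temperature threshold
#'
#' Keeps samples up to (excluding) the first one whose absolute
#' temperature exceeds the threshold; values above the threshold would
#' imply ablation/carbonization outside the model's validity.
#'
#' @param probe A `probe` from [probe_series()].
#' @param threshold Maximum temperature, degC.
#' @return The truncated `probe`.
#' @export
apply_threshold <- function(probe, threshold = 155) {
  if (threshold <= 0) stop("threshold must be > 0")
  over <- which(probe$temperature_c > threshold)
  out <- if (length(over)) probe[seq_len(over[1] - 1L), ] else probe
  attributes(out)[c("position_mm", "mode", "baseline_c")] <-
    attributes(probe)[c("position_mm", "mode", "baseline_c")]
  class(out) <- class(probe)
  out
}

#' Extract a 2-D plane from a temperature field
#'
#' Slices the temperature-rise field perpendicular to one axis at a
#' given world offset (e.g. the xy-plane at 2 mm from the tip).
#'
#' @param field A `temperature_field`.
#' @param axis `"x"`, `"y"` or `"z"` (the normal of the plane).
#' @param offset_mm World coordinate along `axis`.
#' @return A tibble with the two in-plane coordinates (mm) and
#'   `delta_t_c`.
#' @export
plane_map <- function(field, axis = c("z", "x", "y"), offset_mm = 0) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  lo <- field$origin[a]; hi <- field$origin[a] + field$shape[a] * field$pitch
  if (offset_mm < lo || offset_mm > hi)
    stop("geometry error: plane offset outside the world")
  i <- min(max(floor((offset_mm - lo) / field$pitch) + 1, 1), field$shape[a])
  cc <- lapply(1:3, function(ax)
    field$origin[ax] + (seq_len(field$shape[ax]) - 0.5) * field$pitch)
  others <- setdiff(1:3, a)
  sl <- switch(axis,
               x = field$delta_t[i, , ],
               y = field$delta_t[, i, ],
               z = field$delta_t[, , i])
  grid <- expand.grid(u = cc[[others[1]]], v = cc[[others[2]]])
  nm <- c("x_mm", "y_mm", "z_mm")[others]
  out <- tibble::tibble(grid$u, grid$v, delta_t_c = as.vector(sl))
  names(out)[1:2] <- nm
  attr(out, "axis") <- axis
  attr(out, "offset_mm") <- offset_mm
  out
}
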