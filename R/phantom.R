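#' Build a cubic world phantom
#'
#' Creates a voxelized cube of the requested volume, centered at the
#' world origin and uniformly filled with one material. The cube edge is
#' `side_volume^(1/3)` and the voxel count per axis is the edge divided
#' by the pitch, rounded to the nearest integer.
#'
#' @param side_volume World volume in cm^3.
#' @param pitch Voxel edge length in mm.
#' @param material A `material` filling the world.
#' @return A `phantom`: voxel label array plus geometry and material table.
#' @export
build_world <- function(side_volume, pitch, material) {
  if (!is.finite(side_volume) || side_volume <= 0)
    stop("invalid geometry: world volume must be > 0")
  if (!is.finite(pitch) || pitch <= 0)
    stop("invalid geometry: voxel pitch must be > 0")
  stopifnot(inherits(material, "material"))
  edge_mm <- 10 * side_volume^(1 / 3)
  n <- max(1L, as.integer(round(edge_mm / pitch)))
  shape <- c(n, n, n)
  origin <- -shape * pitch / 2
  new_phantom(shape = shape, pitch = pitch, origin = origin,
              labels = array(1L, dim = shape),
              materials = stats::setNames(list(material), material$name))
}

new_phantom <- function(shape, pitch, origin, labels, materials) {
  structure(list(shape = as.integer(shape), pitch = pitch,
                 origin = origin, labels = labels, materials = materials),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d voxels, pitch %.4g mm, extent %s mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$pitch,
              paste(sprintf("%.4g", x$shape * x$pitch), collapse = " x ")))
  tab <- table(factor(x$labels, levels = seq_along(x$materials),
                      labels = names(x$materials)))
  for (nm in names(tab))
    cat(sprintf("  %-12s %d voxels (%.3g cm^3)\n", nm, tab[[nm]],
                tab[[nm]] * (x$pitch / 10)^3))
  invisible(x)
}

#' World coordinates of voxel centers along each axis
#' @param phantom A `phantom`.
#' @return List of three numeric vectors (mm).
#' @export
voxel_centers <- function(phantom) {
  lapply(1:3, function(a)
    phantom$origin[a] + (seq_len(phantom$shape[a]) - 0.5) * phantom$pitch)
}

#' Voxel index containing a world coordinate
#' @param phantom A `phantom`.
#' @param position Length-3 world coordinate, mm.
#' @return Integer triple (1-based), or an error if outside the world.
#' @export
world_to_voxel <- function(phantom, position) {
  idx <- floor((position - phantom$origin) / phantom$pitch) + 1L
  idx <- as.integer(pmin(pmax(idx, 1L), phantom$shape))
  if (any(position < phantom$origin) ||
      any(position > phantom$origin + phantom$shape * phantom$pitch))
    stop("position ", paste(position, collapse = ","), " lies outside the world")
  idx
}

#' Embed a spherical tumor in a phantom
#'
#' Relabels every voxel whose center lies within the radius
#' r = (3 volume / 4 pi)^(1/3) of `center` to a new material. The
#' discretized volume converges to the requested one as the pitch
#' decreases.
#'
#' @param phantom A `phantom`.
#' @param volume Tumor volume, cm^3.
#' @param center World coordinate of the sphere center, mm.
#' @param material Tumor `material`.
#' @param clip If `TRUE`, a sphere extending beyond the world is
#'   truncated at the world bounds instead of raising an error. The
#'   packaged pancreas scenario needs this: a 3 cm^3 sphere does not fit
#'   inside a 4 cm^3 cube.
#' @return The modified `phantom`.
#' @export
embed_spherical_tumor <- function(phantom, volume, center = c(0, 0, 0),
                                  material, clip = FALSE) {
  stopifnot(inherits(phantom, "phantom"), inherits(material, "material"))
  if (!is.finite(volume) || volume <= 0)
    stop("invalid geometry: tumor volume must be > 0")
  r_mm <- 10 * (3 * volume / (4 * pi))^(1 / 3)
  lo <- phantom$origin
  hi <- phantom$origin + phantom$shape * phantom$pitch
  if (!clip && (any(center - r_mm < lo) || any(center + r_mm > hi)))
    stop("invalid geometry: sphere of radius ", signif(r_mm, 4),
         " mm exceeds the world bounds (use clip = TRUE to truncate)")
  cc <- voxel_centers(phantom)
  dx2 <- (cc[[1]] - center[1])^2
  dy2 <- (cc[[2]] - center[2])^2
  dz2 <- (cc[[3]] - center[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r_mm^2
  phantom$materials[[material$name]] <- material
  lbl <- match(material$name, names(phantom$materials))
  phantom$labels[inside] <- lbl
  phantom
}

#' Embed an axis-aligned cylinder (z-axis) in a phantom
#'
#' Used for the water-drop benchmark: a drop of given volume modeled as
#' a cylinder of given radius, voxels relabeled where centers fall
#' inside.
#'
#' @param phantom A `phantom`.
#' @param radius_mm Cylinder radius, mm.
#' @param z_range Length-2 vector, axial extent in mm.
#' @param center_xy Cylinder axis position in the xy-plane, mm.
#' @param material `material` to assign.
#' @return The modified `phantom`.
#' @export
embed_cylinder <- function(phantom, radius_mm, z_range, center_xy = c(0, 0),
                           material) {
  stopifnot(inherits(phantom, "phantom"), inherits(material, "material"),
            radius_mm > 0, length(z_range) == 2L)
  cc <- voxel_centers(phantom)
  r2 <- outer((cc[[1]] - center_xy[1])^2, (cc[[2]] - center_xy[2])^2, `+`)
  inz <- cc[[3]] >= min(z_range) & cc[[3]] <= max(z_range)
  inside <- outer(r2 <= radius_mm^2, inz, `&`)
  phantom$materials[[material$name]] <- material
  lbl <- match(material$name, names(phantom$materials))
  phantom$labels[inside] <- lbl
  phantom
}

#' Voxel counts and volumes per material
#' @param phantom A `phantom`.
#' @return A tibble with material name, voxel count and volume (cm^3).
#' @export
phantom_volumes <- function(phantom) {
  tab <- tabulate(phantom$labels, nbins = length(phantom$materials))
  tibble::tibble(name = names(phantom$materials), voxels = tab,
                 volume_cm3 = tab * (phantom$pitch / 10)^3)
}
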