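#' Default material catalog
#'
#' Materials known to the physics tables, with their default mass densities.
#' Densities can be overridden per phantom; the material name selects the
#' mass attenuation and stopping-power data.
#'
#' @return A data.frame with columns `name` and `density` (g/cm^3).
#' @export
default_materials <- function() {
  data.frame(name = c("water", "lung", "bone", "air"),
             density = c(1.0, 0.26, 1.85, 0.0012),
             stringsAsFactors = FALSE)
}

#' Voxel phantom
#'
#' A rectilinear density/material lattice. `origin` is the position (mm) of
#' the center of the first voxel; voxel centers are
#' `origin + (index - 1) * spacing`.
#'
#' @param density 3D numeric array of mass densities, g/cm^3 (finite, >= 0).
#' @param material 3D integer array of 1-based rows into `materials`
#'   (default: all water).
#' @param origin,spacing length-3 numeric, mm; spacing strictly positive.
#' @param materials material catalog data.frame (see [default_materials()]).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(density, material = NULL, origin, spacing,
                       materials = default_materials()) {
  dims <- dim(density)
  if (length(dims) != 3L || any(dims < 1L))
    stop("density must be a 3D array with positive dimensions")
  if (any(!is.finite(density)) || any(density < 0))
    stop("density values must be finite and non-negative")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (length(origin) != 3L) stop("origin must have three components")
  if (is.null(material)) {
    material <- array(match("water", materials$name), dim = dims)
  }
  material <- array(as.integer(material), dim = dims)
  if (any(is.na(material)) || any(material < 1L) ||
      any(material > nrow(materials)))
    stop("material ids must all resolve in the material catalog")
  structure(list(density = density, material = material,
                 origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims), materials = materials),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  density range [", signif(min(x$density), 4), ", ",
      signif(max(x$density), 4), "] g/cm3, materials: ",
      paste(x$materials$name[sort(unique(as.integer(x$material)))],
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: geometry list passed to the C++ kernels
grid_geom <- function(grid) {
  list(dims = grid$dims, origin = grid$origin, spacing = grid$spacing)
}

# internal: voxel center coordinates along one axis (1 = x, 2 = y, 3 = z)
grid_axis <- function(grid, a) {
  grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a]
}

#' Uniform water tank phantom
#'
#' Builds a uniform water phantom. The grid is centered on `x = y = 0` with
#' the beam-entry surface at `z = 0` (first voxel center at `spacing/2`).
#' Dimensions are `round(extent / spacing)` (round-half-to-even, R's `round`),
#' with a minimum of one voxel per axis.
#'
#' @param extent_mm,spacing_mm length-3 positive numerics, mm.
#' @return A [voxel_grid()] of water, density 1 g/cm^3.
#' @export
make_water_tank <- function(extent_mm, spacing_mm) {
  if (any(extent_mm <= 0) || any(spacing_mm <= 0))
    stop("extent and spacing must be strictly positive")
  extent_mm <- rep_len(as.numeric(extent_mm), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  dims <- pmax(1L, as.integer(round(extent_mm / spacing_mm)))
  density <- array(1.0, dim = dims)
  origin <- c(-extent_mm[1] / 2 + spacing_mm[1] / 2,
              -extent_mm[2] / 2 + spacing_mm[2] / 2,
              spacing_mm[3] / 2)
  voxel_grid(density, origin = origin, spacing = spacing_mm)
}

#' Layered slab phantom
#'
#' Builds a phantom whose density varies only along the beam (z) axis
#' according to a layer table. Layer boundaries are snapped to the nearest
#' voxel plane (`round(boundary / spacing_z)`); zero-thickness layers are
#' dropped. Layer thicknesses must sum to the axial extent.
#'
#' @param extent_mm,spacing_mm length-3 positive numerics, mm.
#' @param layers data.frame with columns `thickness` (mm), `density`
#'   (g/cm^3), `material` (catalog name).
#' @param materials material catalog.
#' @return A [voxel_grid()] with the same frame conventions as
#'   [make_water_tank()].
#' @export
make_slab_phantom <- function(extent_mm, spacing_mm, layers,
                              materials = default_materials()) {
  extent_mm <- rep_len(as.numeric(extent_mm), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(extent_mm <= 0) || any(spacing_mm <= 0))
    stop("extent and spacing must be strictly positive")
  layers <- layers[layers$thickness > 0, , drop = FALSE]
  if (abs(sum(layers$thickness) - extent_mm[3]) > 1e-6)
    stop("layer thicknesses must sum to the axial extent")
  tank <- make_water_tank(extent_mm, spacing_mm)
  nz <- tank$dims[3]
  planes <- pmin(nz, pmax(0L, as.integer(round(
    cumsum(layers$thickness) / spacing_mm[3]))))
  starts <- c(0L, planes[-length(planes)])
  mat_ids <- match(layers$material, materials$name)
  if (any(is.na(mat_ids))) stop("unknown material name in layer table")
  density <- tank$density
  material <- tank$material
  for (k in seq_len(nrow(layers))) {
    if (planes[k] > starts[k]) {
      zi <- (starts[k] + 1L):planes[k]
      density[, , zi] <- layers$density[k]
      material[, , zi] <- mat_ids[k]
    }
  }
  voxel_grid(density, material, tank$origin, spacing_mm, materials)
}

#' Structure mask
#'
#' Boolean voxel membership for a region of interest on an existing grid.
#'
#' @param grid a [voxel_grid()] (or `dose_grid`) whose geometry the mask uses.
#' @param mask logical 3D array matching the grid dims.
#' @param label text label.
#' @export
structure_mask <- function(grid, mask, label = "structure") {
  dims <- if (inherits(grid, "voxel_grid")) grid$dims else grid$dims
  if (!identical(dim(mask), as.integer(dims)))
    stop("mask dimensions must match the grid")
  structure(list(mask = array(as.logical(mask), dim = dims), label = label,
                 origin = grid$origin, spacing = grid$spacing,
                 dims = as.integer(dims)),
            class = "structure_mask")
}

#' Spherical structure mask
#'
#' @param grid a [voxel_grid()].
#' @param center length-3 numeric, mm.
#' @param radius mm.
#' @param label text label.
#' @export
sphere_mask <- function(grid, center, radius, label = "target") {
  cx <- grid_axis(grid, 1); cy <- grid_axis(grid, 2); cz <- grid_axis(grid, 3)
  d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
              (cz - center[3])^2, `+`)
  structure_mask(grid, d2 <= radius^2, label)
}

#' Water-equivalent path length along a segment
#'
#' Integrates mass density along the straight segment from `p0` to `p1` with
#' exact voxel-boundary traversal, returning the result in mm of water.
#' Portions of the segment outside the grid contribute zero; a degenerate
#' segment (`p0 == p1`) returns 0.
#'
#' @param grid a [voxel_grid()].
#' @param p0,p1 length-3 numerics, mm (world frame).
#' @return Water-equivalent length, mm.
#' @export
radiological_path <- function(grid, p0, p1) {
  .rad_path_cpp(grid_geom(grid), as.numeric(grid$density),
                as.integer(grid$material) - 1L,
                as.numeric(p0), as.numeric(p1))
}
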