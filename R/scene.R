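#' Scene configuration
#'
#' Describes the simulated volume: a cube of side `side_length` mm, voxelized
#' at `voxel_pitch` mm, with a surface layer (skin, or milk for the phantom)
#' of thickness `skin_thickness` over a homogeneous bulk. The coordinate
#' convention is z = depth from the tissue surface, y = along the transducer
#' array, x = lateral offset; the imaging plane of the array is the vertical
#' mid-plane x = side/2.
#'
#' @param side_length Cube side in mm (default 36).
#' @param voxel_pitch Cubic voxel edge in mm; `side_length/voxel_pitch` must be
#'   a whole number of voxels.
#' @param skin_thickness Surface-layer thickness in mm (0.3 for mouse skin,
#'   2.0 for human skin or the milk couplant). May be 0 for a homogeneous
#'   volume.
#' @param bulk A [tissue_spec()] for the bulk tissue.
#' @param surface_layer A [tissue_spec()] for the surface layer; ignored when
#'   `skin_thickness` is 0.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(side_length = 36, voxel_pitch = 0.15,
                         skin_thickness = 0.3,
                         bulk = tissue_spec("fibrous", 700),
                         surface_layer = tissue_spec("skin", bulk$wavelength_nm)) {
  nvox <- side_length / voxel_pitch
  if (abs(nvox - round(nvox)) > 1e-9)
    stop("side_length must be a whole number of voxels at pitch ", voxel_pitch)
  if (skin_thickness < 0) stop("skin_thickness must be >= 0")
  if (skin_thickness > 0) {
    if (skin_thickness < voxel_pitch - 1e-9)
      stop(sprintf(paste("surface layer of %.3g mm is thinner than one voxel at",
                         "pitch %.3g mm; use a finer voxel_pitch"),
                   skin_thickness, voxel_pitch))
  }
  structure(list(side_length = side_length, voxel_pitch = voxel_pitch,
                 skin_thickness = skin_thickness, bulk = bulk,
                 surface_layer = surface_layer),
            class = "scene_config")
}

new_scene <- function(config, layer_label, palette) {
  n <- round(config$side_length / config$voxel_pitch)
  stopifnot(length(layer_label) == n, all(layer_label %in% seq_len(nrow(palette))))
  structure(list(nx = n, ny = n, nz = n,
                 pitch = config$voxel_pitch,
                 side = config$side_length,
                 layer_label = as.integer(layer_label),
                 palette = palette,
                 config = config),
            class = "pa_scene")
}

palette_row <- function(tissue_name, props) {
  data.frame(tissue = tissue_name, mu_a = props$mu_a, mu_s = props$mu_s,
             g = props$g, n = props$n, stringsAsFactors = FALSE)
}

#' Build a layered skin-over-bulk scene
#'
#' Stacks `round(skin_thickness / voxel_pitch)` surface-tissue voxel layers on
#' top of a homogeneous bulk. The fiber bundle is taken to be pressed flush
#' with the skin, so there is no coupling medium above the surface.
#'
#' @param config A [scene_config()].
#' @return A `pa_scene`: label-per-depth-layer volume plus a palette mapping
#'   labels to optical properties. Use [as.array()][as.array.pa_scene] to
#'   materialize the full 3-D label grid.
#' @export
#' @examples
#' sc <- build_layered_scene(scene_config(voxel_pitch = 0.15,
#'   skin_thickness = 0.3, bulk = tissue_spec("fibrous", 700)))
#' sc
build_layered_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  bulk_props <- get_properties(config$bulk)
  n <- round(config$side_length / config$voxel_pitch)
  if (config$skin_thickness == 0) {
    palette <- palette_row(config$bulk$kind, bulk_props)
    return(new_scene(config, rep(1L, n), palette))
  }
  surf_props <- get_properties(config$surface_layer)
  nlay <- round(config$skin_thickness / config$voxel_pitch)
  palette <- rbind(palette_row(config$surface_layer$kind, surf_props),
                   palette_row(config$bulk$kind, bulk_props))
  labels <- c(rep(1L, nlay), rep(2L, n - nlay))
  new_scene(config, labels, palette)
}

#' Build the milk-over-gelatin phantom scene
#'
#' The validation phantom: a layer of milk (approximating skin optics at
#' 1064 nm) over a gelatin bulk whose absorption and scattering are those of
#' water. Defaults follow the physical phantom: 2 mm of milk, 36 mm cube.
#'
#' @param voxel_pitch Voxel edge in mm.
#' @param milk_thickness Milk layer thickness in mm (default 2).
#' @param side_length Cube side in mm.
#' @return A `pa_scene`.
#' @export
build_phantom_scene <- function(voxel_pitch = 0.15, milk_thickness = 2,
                                side_length = 36) {
  config <- scene_config(side_length = side_length, voxel_pitch = voxel_pitch,
                         skin_thickness = milk_thickness,
                         bulk = tissue_spec("gelatin", 1064),
                         surface_layer = tissue_spec("milk", 1064))
  build_layered_scene(config)
}

#' Scale the scattering coefficient of the surface layer
#'
#' Used for ballistic-versus-diffusive transport illustrations: reducing the
#' skin scattering coefficient (e.g. by 10x) preserves beam directionality
#' through the layer.
#'
#' @param scene A `pa_scene`.
#' @param factor Positive multiplier applied to the surface layer's mu_s.
#' @return The modified `pa_scene`.
#' @export
scale_surface_scattering <- function(scene, factor) {
  stopifnot(inherits(scene, "pa_scene"), factor > 0)
  if (scene$config$skin_thickness > 0)
    scene$palette$mu_s[1] <- scene$palette$mu_s[1] * factor
  scene
}

#' @export
print.pa_scene <- function(x, ...) {
  cat(sprintf("pa_scene: %d x %d x %d voxels @ %.3g mm (%g mm cube)\n",
              x$nx, x$ny, x$nz, x$pitch, x$side))
  nsurf <- sum(x$layer_label == 1L & nrow(x$palette) > 1L)
  if (nrow(x$palette) > 1L)
    cat(sprintf("  surface: %s, %d layer(s) (%.3g mm); bulk: %s\n",
                x$palette$tissue[1], nsurf, nsurf * x$pitch, x$palette$tissue[2]))
  else
    cat(sprintf("  homogeneous %s\n", x$palette$tissue[1]))
  invisible(x)
}

#' Materialize the 3-D label grid of a scene
#'
#' @param x A `pa_scene`.
#' @param ... Unused.
#' @return An integer array of dimension (nx, ny, nz) of palette indices.
#' @export
as.array.pa_scene <- function(x, ...) {
  arr <- array(0L, dim = c(x$nx, x$ny, x$nz))
  for (iz in seq_len(x$nz)) arr[, , iz] <- x$layer_label[iz]
  arr
}

#' Define the rectangular fiber-bundle source
#'
#' The distal fiber-bundle end is modelled as a collimated rectangular emitter
#' of uniform fluence, footprint `length_mm` (along the array, y) by
#' `width_mm` (across, x), centered `D` mm from the imaging plane, emitting at
#' a uniform angle `theta` tilted from the depth axis toward the imaging
#' plane. A ray from the footprint center crosses the imaging plane at depth
#' `D / tan(theta)`.
#'
#' @param D Offset from the imaging plane to the footprint center, mm.
#' @param theta Emission angle in degrees, 0 <= theta < 90; 0 is straight
#'   down.
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer RNG seed for the transport run.
#' @param length_mm Footprint extent along the array (default 25).
#' @param width_mm Footprint extent across the array (default 1.4).
#' @return An object of class `source_spec`.
#' @export
#' @examples
#' make_source(D = 7, theta = 45, n_photons = 1e5, seed = 1)
make_source <- function(D, theta, n_photons, seed,
                        length_mm = 25, width_mm = 1.4) {
  if (theta < 0 || theta >= 90)
    stop("theta must satisfy 0 <= theta < 90 degrees; got ", theta)
  if (D < width_mm / 2)
    stop(sprintf("offset D = %g mm puts the %g mm footprint across the imaging plane",
                 D, width_mm))
  if (n_photons < 1) stop("n_photons must be positive")
  structure(list(D = D, theta = theta, n_photons = as.numeric(n_photons),
                 seed = as.integer(seed), length_mm = length_mm,
                 width_mm = width_mm),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf("source: %g x %g mm footprint, D = %g mm, theta = %g deg, %g photons (seed %d)\n",
              x$length_mm, x$width_mm, x$D, x$theta, x$n_photons, x$seed))
  invisible(x)
}

#' Launch geometry of a source
#'
#' Returns the deterministic (collimated) launch direction and, for testing,
#' samples launch positions over the footprint.
#'
#' @param source A `source_spec`.
#' @param scene A `pa_scene` giving the volume frame.
#' @param n Number of positions to sample (0 for direction only).
#' @param seed RNG seed for the sampling.
#' @return A list with `direction` (unit 3-vector, components x, y, z) and
#'   `positions` (n x 3 matrix of launch points in mm).
#' @export
launch_geometry <- function(source, scene, n = 0, seed = 1L) {
  th <- source$theta * pi / 180
  dir <- c(-sin(th), 0, cos(th))
  cx <- scene$side / 2
  x0 <- cx + source$D
  pos <- NULL
  if (n > 0) {
    set.seed(seed)
    pos <- cbind(x = x0 + runif(n, -source$width_mm / 2, source$width_mm / 2),
                 y = scene$side / 2 + runif(n, -source$length_mm / 2, source$length_mm / 2),
                 z = 0)
  }
  list(direction = dir, positions = pos, center = c(x0, scene$side / 2, 0))
}
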