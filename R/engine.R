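#' Run the voxel Monte Carlo transport
#'
#' Launches `source$n_photons` photon packets from the rectangular collimated
#' emitter into the scene and tallies the fluence in every voxel, normalized
#' to the total launched energy (units 1/mm^2). Free paths between scattering
#' events are drawn from the local scattering coefficient; absorption
#' attenuates the packet weight continuously along the path (track-length
#' estimator), so thin layers are tallied without collision-count noise.
#' Henyey-Greenstein scattering uses the local anisotropy; Snell/Fresnel
#' refraction is applied at depth interfaces where the refractive index
#' changes. Photons crossing any outer face permanently escape. Low-weight
#' packets are terminated unbiasedly by Russian roulette (threshold 1e-4,
#' survival probability 0.1).
#'
#' Runs are deterministic given (scene, source, seed): each photon draws from
#' its own counter-derived random stream, so results do not depend on
#' execution order.
#'
#' @param scene A `pa_scene` from [build_layered_scene()] or
#'   [build_phantom_scene()].
#' @param source A `source_spec` from [make_source()].
#' @param boundary Outer-face treatment. `"escape"` (default): every face
#'   absorbs; photons crossing any outer face are lost permanently.
#'   `"reflect"`: unpolarized Fresnel reflection, including total internal
#'   reflection, against the exterior index n = 1 at every face before
#'   escape -- the convention of voxel Monte Carlo codes with
#'   index-mismatched boundaries; it retains substantially more diffuse
#'   light near the surface and rewards steeper emission angles, at several
#'   times the run time in weakly absorbing media. `"top"`: Fresnel at the
#'   illuminated tissue-air surface only. See the methods vignette for how
#'   this choice moves the optimal-angle findings.
#' @return A `fluence_grid`: list with `values` (nx x ny x nz array of
#'   normalized fluence), `ledger` (launched/absorbed/escaped packet weight,
#'   plus `residual`, the net roulette imbalance: terminated mass minus
#'   survivor boosts, so the ledger closes exactly), `pitch`, and
#'   `provenance` (scene config + source).
#' @export
#' @examples
#' sc <- build_layered_scene(scene_config(side_length = 9, voxel_pitch = 0.3,
#'   skin_thickness = 0.3, bulk = tissue_spec("fibrous", 700)))
#' fg <- mc_run(sc, make_source(D = 2, theta = 45, n_photons = 1e4, seed = 1))
#' fg
mc_run <- function(scene, source, boundary = c("escape", "reflect", "top")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(scene, "pa_scene"), inherits(source, "source_spec"))
  cx <- scene$side / 2
  x_lo <- cx + source$D - source$width_mm / 2
  x_hi <- cx + source$D + source$width_mm / 2
  if (x_lo < 0 || x_hi > scene$side || source$length_mm > scene$side)
    stop("source footprint does not fit inside the volume top face")
  res <- mc_transport_cpp(scene$nx, scene$ny, scene$nz, scene$pitch,
                          scene$layer_label,
                          scene$palette$mu_a, scene$palette$mu_s,
                          scene$palette$g, scene$palette$n,
                          src_x = cx + source$D, src_y = scene$side / 2,
                          len_y = source$length_mm, wid_x = source$width_mm,
                          theta_deg = source$theta,
                          n_photons = source$n_photons,
                          seed = source$seed,
                          w_min = 1e-4, p_surv = 0.1,
                          boundary_mode = match(boundary,
                                                c("escape", "top", "reflect")) - 1L)
  new_fluence_grid(res$values, scene, source,
                   ledger = c(launched = res$launched, absorbed = res$absorbed,
                              escaped = res$escaped, residual = res$residual))
}

new_fluence_grid <- function(values, scene, source, ledger) {
  structure(list(values = values,
                 pitch = scene$pitch,
                 side = scene$side,
                 ledger = ledger,
                 provenance = list(config = scene$config, source = source)),
            class = "fluence_grid")
}

#' @export
print.fluence_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("fluence_grid: %d x %d x %d voxels @ %.3g mm\n", d[1], d[2], d[3],
              x$pitch))
  lg <- x$ledger
  cat(sprintf("  ledger: launched %g | absorbed %.4g | escaped %.4g | residual %.4g\n",
              lg["launched"], lg["absorbed"], lg["escaped"], lg["residual"]))
  cat(sprintf("  conservation gap: %.3g (relative)\n",
              abs(lg["launched"] - lg["absorbed"] - lg["escaped"] - lg["residual"]) /
                lg["launched"]))
  invisible(x)
}

#' Plot a fluence cross-section
#'
#' Displays the x-z cross-section through the volume center (perpendicular to
#' the imaging plane), on a log10 color scale.
#'
#' @param x A `fluence_grid`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.fluence_grid <- function(x, ...) {
  sec <- fluence_section(x)
  lg <- log10(sec$values + max(sec$values) * 1e-6)
  graphics::image(sec$x_mm, sec$depth_mm, lg, ylim = rev(range(sec$depth_mm)),
                  xlab = "x (mm)", ylab = "depth (mm)",
                  main = "log10 normalized fluence", ...)
  invisible(x)
}

#' Extract the central x-z section of a fluence grid
#'
#' @param grid A `fluence_grid`.
#' @return A list with `values` (nx x nz matrix), `x_mm`, `depth_mm`.
#' @export
fluence_section <- function(grid) {
  stopifnot(inherits(grid, "fluence_grid"))
  d <- dim(grid$values)
  iy <- ceiling(d[2] / 2)
  list(values = grid$values[, iy, ],
       x_mm = (seq_len(d[1]) - 0.5) * grid$pitch,
       depth_mm = (seq_len(d[3]) - 0.5) * grid$pitch)
}

#' Mirror-average a fluence grid across the imaging plane
#'
#' The fiber-bundle pair is symmetric about the imaging plane, so only one
#' source is simulated; the physical two-sided fluence field is recovered as
#' the average of the tally and its reflection across the plane:
#' `(G + reflect_x(G)) / 2`.
#'
#' @param grid A `fluence_grid`.
#' @return The mirror-averaged `fluence_grid`.
#' @export
mirror_average <- function(grid) {
  stopifnot(inherits(grid, "fluence_grid"))
  d <- dim(grid$values)
  # reflection about the central x plane is exact for even and odd voxel
  # counts alike: index reversal maps voxel centers onto voxel centers
  grid$values <- (grid$values + grid$values[rev(seq_len(d[1])), , , drop = FALSE]) / 2
  grid
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Draws deflection-angle cosines from the Henyey-Greenstein phase function by
#' closed-form inversion; `g = 0` degenerates to the isotropic uniform law on
#' \[-1, 1\]. The sample mean converges to `g`.
#'
#' @param n Number of draws.
#' @param g Anisotropy in (-1, 1).
#' @param seed Integer seed.
#' @return Numeric vector of cosines.
#' @export
sample_hg <- function(n, g, seed = 1L) {
  if (g <= -1 || g >= 1) stop("g must lie strictly inside (-1, 1)")
  mc_sample_hg_cpp(as.integer(n), g, as.numeric(seed))
}
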