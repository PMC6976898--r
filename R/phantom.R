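#' Graphite-rod layout of the validation phantom
#'
#' Eleven 0.5-mm-diameter, 20-mm-long graphite rods embedded in gelatin,
#' alternating 5 and 6 mm lateral spacing, at 2 mm depth increments starting
#' at 4 mm. Spacings are configurable; the defaults realize the nominal
#' layout.
#'
#' @param n_rods Number of rods (default 11).
#' @param depth_start_mm Depth of the shallowest rod (default 4).
#' @param depth_step_mm Depth increment between rods (default 2).
#' @param lateral_spacing_mm Alternating horizontal spacings (default 5, 6).
#' @param diameter_mm,length_mm Rod geometry.
#' @return An object of class `rod_spec` with a `positions` data frame
#'   (`rod`, `lateral_mm`, `depth_mm`).
#' @export
rod_spec <- function(n_rods = 11, depth_start_mm = 4, depth_step_mm = 2,
                     lateral_spacing_mm = c(5, 6), diameter_mm = 0.5,
                     length_mm = 20) {
  depths <- depth_start_mm + depth_step_mm * (seq_len(n_rods) - 1)
  if (any(diff(depths) <= 0)) stop("rod depths must be strictly increasing")
  lat <- cumsum(c(0, rep_len(lateral_spacing_mm, n_rods - 1)))
  structure(list(positions = data.frame(rod = seq_len(n_rods),
                                        lateral_mm = lat, depth_mm = depths),
                 diameter_mm = diameter_mm, length_mm = length_mm),
            class = "rod_spec")
}

#' @export
print.rod_spec <- function(x, ...) {
  cat(sprintf("rod_spec: %d rods, %.2g mm diameter, depths %.3g-%.3g mm\n",
              nrow(x$positions), x$diameter_mm, min(x$positions$depth_mm),
              max(x$positions$depth_mm)))
  invisible(x)
}

#' Simulate the milk/gelatin phantom fluence
#'
#' Builds the phantom scene (2 mm of milk over gelatin at 1064 nm), runs the
#' transport for the requested source geometry, and reduces to the ROI depth
#' profile, the model-side quantity compared with the rod scan.
#'
#' @param theta Emission angle in degrees (the experiment used 20, 40, 60).
#' @param D Offset in mm (the experiment used 7.5, 11.5, 15.5).
#' @param n_photons Photon budget.
#' @param voxel_pitch Voxel edge in mm.
#' @param seed Integer seed.
#' @param milk_thickness Milk layer thickness in mm.
#' @param side_length Cube side in mm.
#' @param boundary Outer-face treatment passed to [mc_run()].
#' @return A `depth_profile`.
#' @export
simulate_phantom_fluence <- function(theta, D, n_photons = 1e6,
                                     voxel_pitch = 0.15, seed = 1L,
                                     milk_thickness = 2, side_length = 36,
                                     boundary = "escape") {
  scene <- build_phantom_scene(voxel_pitch = voxel_pitch,
                               milk_thickness = milk_thickness,
                               side_length = side_length)
  src <- make_source(D = D, theta = theta, n_photons = n_photons, seed = seed)
  depth_profile(mirror_average(mc_run(scene, src, boundary = boundary)))
}

#' Generate a synthetic rod-scan acquisition
#'
#' Stands in for the ultrasound/photoacoustic acquisition of the phantom
#' scan. Per rod at depth z: the photoacoustic intensity is proportional to
#' the local fluence times a depth-dependent system factor (ultrasound
#' attenuation, obliquity and the transducer's depth-dependent focus act once
#' on the one-way photoacoustic wave), while the ultrasound intensity carries
#' the factor squared (the pulse-echo wave traverses the path twice).
#' Independent multiplicative noise of coefficient of variation `noise_cv`
#' (mean-one lognormal, strictly positive) is applied per repeat; four
#' repeats emulate the repeated acquisitions.
#'
#' @param true_fluence A `depth_profile` (or data frame with `depth_mm`,
#'   `fluence`).
#' @param rods A [rod_spec()].
#' @param system_factor Function of depth (mm) returning the positive one-way
#'   system gain, or a constant; default 1.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_repeats Repeat acquisitions per rod (default 4).
#' @param seed Integer seed.
#' @param theta,D Acquisition geometry recorded with the scan.
#' @return A `rod_scan`: data frame (`rod`, `depth_mm`, `repeat_id`, `pa`,
#'   `us`) with the geometry in attributes.
#' @export
generate_synthetic_scan <- function(true_fluence, rods, system_factor = 1,
                                    noise_cv = 0.05, n_repeats = 4, seed = 1L,
                                    theta = NA_real_, D = NA_real_) {
  stopifnot(inherits(rods, "rod_spec"), noise_cv >= 0)
  depths <- rods$positions$depth_mm
  if (min(depths) < min(true_fluence$depth_mm) ||
      max(depths) > max(true_fluence$depth_mm))
    stop("rod depths fall outside the support of the fluence profile")
  flu <- approx(true_fluence$depth_mm, true_fluence$fluence, xout = depths)$y
  sf <- if (is.function(system_factor)) system_factor(depths)
        else rep_len(system_factor, length(depths))
  if (any(sf <= 0)) stop("system_factor must be positive at all rod depths")
  set.seed(seed)
  n <- length(depths)
  noise <- function() {
    if (noise_cv == 0) return(matrix(1, n, n_repeats))
    sdlog <- sqrt(log(1 + noise_cv^2))
    matrix(rlnorm(n * n_repeats, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           n, n_repeats)
  }
  pa <- flu * sf * noise()
  us <- sf^2 * noise()
  out <- data.frame(rod = rep(rods$positions$rod, n_repeats),
                    depth_mm = rep(depths, n_repeats),
                    repeat_id = rep(seq_len(n_repeats), each = n),
                    pa = as.vector(pa), us = as.vector(us))
  structure(out, theta = theta, D = D, n_repeats = n_repeats,
            class = c("rod_scan", "data.frame"))
}

#' Ultrasound-based normalization of rod photoacoustic intensities
#'
#' Because attenuation, obliquity and the depth-dependent transducer focus
#' act on the pulse-echo ultrasound signal twice (once per direction of
#' travel) but on the one-way photoacoustic signal once, the depth-dependent
#' system response is removed by dividing each rod's mean photoacoustic
#' intensity by the square root of its max-normalized mean ultrasound
#' intensity. On a noiseless scan this recovers the true fluence shape at the
#' rod depths up to one global scale, for any positive system factor.
#'
#' @param scan A `rod_scan`.
#' @return Data frame with one row per rod: `rod`, `depth_mm`, `us_mean`,
#'   `us_norm_sqrt`, `pa_adjusted` (mean adjusted intensity), `pa_sd`
#'   (standard deviation of the adjusted intensity over repeats).
#' @export
us_normalize <- function(scan) {
  stopifnot(inherits(scan, "rod_scan") || is.data.frame(scan))
  sp <- split(scan, scan$rod)
  rods <- as.integer(names(sp))
  us_mean <- vapply(sp, function(d) mean(d$us), numeric(1))
  if (any(us_mean <= 0)) stop("non-positive mean US intensity")
  r <- sqrt(us_mean / max(us_mean))
  pa_mean <- vapply(sp, function(d) mean(d$pa), numeric(1))
  pa_sd <- vapply(sp, function(d) sd(d$pa), numeric(1))
  out <- data.frame(rod = rods,
                    depth_mm = vapply(sp, function(d) d$depth_mm[1], numeric(1)),
                    us_mean = us_mean, us_norm_sqrt = r,
                    pa_adjusted = pa_mean / r, pa_sd = pa_sd / r)
  out[order(out$rod), , drop = FALSE]
}

#' Compare a model depth profile against an adjusted rod scan
#'
#' Interpolates the model profile at the rod depths, finds the least-squares
#' scale between model and adjusted photoacoustic intensities, and reports
#' per-rod relative residuals plus the rank agreement between model and
#' measurement across depth.
#'
#' @param profile A `depth_profile` from the matching simulation.
#' @param adjusted Output of [us_normalize()].
#' @return List with `scale`, `residuals` (per-rod relative deviation,
#'   relative to the peak adjusted intensity), `rms_residual`, and
#'   `rank_agreement` (Spearman correlation of the depth orderings).
#' @export
compare_model_to_scan <- function(profile, adjusted) {
  m <- approx(profile$depth_mm, profile$fluence, xout = adjusted$depth_mm)$y
  a <- adjusted$pa_adjusted
  if (all(m == 0) || all(a == 0)) stop("degenerate all-zero inputs")
  scale <- sum(m * a) / sum(m * m)
  resid <- (a - scale * m) / max(abs(a))
  list(scale = scale, residuals = resid,
       rms_residual = sqrt(mean(resid^2)),
       rank_agreement = suppressWarnings(cor(m, a, method = "spearman")))
}
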