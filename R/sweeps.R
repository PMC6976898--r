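#' Study plan for the geometry sweeps
#'
#' Collects every knob of the two simulation sets: the emission-angle sweep
#' (20 to 70 degrees in 12.5-degree steps at fixed offset D = 7 mm) and the
#' offset sweep (D = 5 to 13 mm in 2 mm steps at fixed 45 degrees), run for
#' each species skin thickness (mouse 0.3 mm, human 2.0 mm) and bulk-tissue
#' condition. Two problem-size presets are defined: `"desk"` (0.15 mm voxels,
#' 1e7 photons per condition) and `"full"` (0.05 mm voxels, 1e9 photons, the
#' reference scale). `voxel_pitch` and `n_photons` may be overridden
#' independently of the preset to trade precision for runtime.
#'
#' @param preset `"desk"` or `"full"`.
#' @param voxel_pitch,n_photons Optional overrides of the preset values.
#' @param side_length Cube side in mm.
#' @param angle_grid Emission angles in degrees for the angle sweep.
#' @param distance_grid Offsets D in mm for the distance sweep.
#' @param D_fixed Offset during the angle sweep (mm).
#' @param theta_fixed Angle during the distance sweep (degrees).
#' @param source_length_mm,source_width_mm Fiber-bundle footprint (mm).
#' @param skin_thickness Named vector of skin thicknesses in mm.
#' @param master_seed Master seed; per-condition seeds are derived by hashing
#'   the condition labels so each condition is independently reproducible.
#' @param max_stat Summary maximized over the sweep: `"peak"` (peak of the ROI
#'   depth profile, the default) or `"mean"` (depth-averaged ROI fluence).
#' @param boundary Outer-face treatment passed to [mc_run()].
#' @return An object of class `study_plan`.
#' @export
study_plan <- function(preset = c("desk", "full"),
                       voxel_pitch = NULL, n_photons = NULL,
                       side_length = 36,
                       angle_grid = seq(20, 70, by = 12.5),
                       distance_grid = seq(5, 13, by = 2),
                       D_fixed = 7, theta_fixed = 45,
                       source_length_mm = 25, source_width_mm = 1.4,
                       skin_thickness = c(mouse = 0.3, human = 2.0),
                       master_seed = 1L,
                       max_stat = c("peak", "mean"),
                       boundary = c("escape", "reflect", "top")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     desk = list(pitch = 0.15, photons = 1e7),
                     full = list(pitch = 0.05, photons = 1e9))
  if (length(angle_grid) == 0L || length(distance_grid) == 0L)
    stop("sweep grids must be non-empty")
  structure(list(preset = preset,
                 voxel_pitch = if (is.null(voxel_pitch)) defaults$pitch else voxel_pitch,
                 n_photons = if (is.null(n_photons)) defaults$photons else n_photons,
                 side_length = side_length,
                 angle_grid = angle_grid,
                 distance_grid = distance_grid,
                 D_fixed = D_fixed, theta_fixed = theta_fixed,
                 source_length_mm = source_length_mm,
                 source_width_mm = source_width_mm,
                 skin_thickness = skin_thickness,
                 master_seed = as.integer(master_seed),
                 max_stat = match.arg(max_stat),
                 boundary = match.arg(boundary)),
            class = "study_plan")
}

#' Derive a reproducible per-condition seed
#'
#' Hashes the master seed together with arbitrary condition labels into a
#' 31-bit integer, so every (species, tissue, wavelength, parameter) cell of
#' the study draws from its own reproducible stream, independent of execution
#' order.
#'
#' @param master_seed Integer master seed.
#' @param ... Condition labels (coerced to character).
#' @return A single integer in \[0, 2^31).
#' @export
condition_seed <- function(master_seed, ...) {
  tag <- paste(c(master_seed, ...), collapse = "|")
  h <- 17
  m <- 2147483629
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  as.integer(h)
}

bulk_label <- function(bulk) {
  if (bulk$kind == "mixed")
    sprintf("mixed%02.0f@%d", 100 * bulk$fatty_fraction, bulk$wavelength_nm)
  else sprintf("%s@%d", bulk$kind, bulk$wavelength_nm)
}

profile_stat <- function(profile, max_stat) {
  if (max_stat == "mean") list(value = mean(profile$fluence),
                               depth_mm = NA_real_)
  else peak_fluence(profile)
}

run_one <- function(scene, theta, D, plan, seed, keep_profile = TRUE) {
  src <- make_source(D = D, theta = theta, n_photons = plan$n_photons,
                     seed = seed, length_mm = plan$source_length_mm,
                     width_mm = plan$source_width_mm)
  grid <- mirror_average(mc_run(scene, src, boundary = plan$boundary))
  prof <- depth_profile(grid)
  st <- profile_stat(prof, plan$max_stat)
  list(profile = if (keep_profile) prof, value = st$value,
       depth_mm = st$depth_mm, ledger = grid$ledger)
}

sweep_scene <- function(plan, bulk, skin_thickness) {
  build_layered_scene(scene_config(side_length = plan$side_length,
                                   voxel_pitch = plan$voxel_pitch,
                                   skin_thickness = skin_thickness,
                                   bulk = bulk))
}

#' Emission-angle sweep
#'
#' Runs one mirrored, ROI-reduced simulation per angle of the plan's angle
#' grid at fixed offset `D_fixed`, for one bulk tissue and skin thickness.
#'
#' @param plan A [study_plan()].
#' @param bulk A [tissue_spec()] for the bulk tissue.
#' @param skin_thickness Skin-layer thickness in mm.
#' @param seed Optional seed override; by default derived with
#'   [condition_seed()] from the plan's master seed and the condition labels.
#' @return A `sweep_table`: data frame with one row per angle (`angle_deg`,
#'   `peak_value`, `peak_depth_mm`, `seed`), with the per-angle
#'   `depth_profile`s in `attr(, "profiles")`.
#' @export
run_angle_sweep <- function(plan, bulk, skin_thickness, seed = NULL) {
  scene <- sweep_scene(plan, bulk, skin_thickness)
  rows <- lapply(plan$angle_grid, function(theta) {
    s <- if (is.null(seed))
      condition_seed(plan$master_seed, "angle", bulk_label(bulk),
                     skin_thickness, theta)
    else condition_seed(seed, "angle", bulk_label(bulk), skin_thickness, theta)
    r <- run_one(scene, theta, plan$D_fixed, plan, s)
    list(row = data.frame(angle_deg = theta, peak_value = r$value,
                          peak_depth_mm = r$depth_mm, seed = s),
         profile = r$profile)
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(tab, "profiles") <- setNames(lapply(rows, `[[`, "profile"),
                                    paste0("theta_", plan$angle_grid))
  attr(tab, "condition") <- list(bulk = bulk, skin_thickness = skin_thickness,
                                 D = plan$D_fixed)
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

#' Source-offset (distance) sweep
#'
#' Runs one simulation per offset D of the plan's distance grid at the fixed
#' angle `theta_fixed`.
#'
#' @inheritParams run_angle_sweep
#' @return A `sweep_table` with one row per offset (`D_mm`, `peak_value`,
#'   `peak_depth_mm`, `seed`).
#' @export
run_distance_sweep <- function(plan, bulk, skin_thickness, seed = NULL) {
  scene <- sweep_scene(plan, bulk, skin_thickness)
  rows <- lapply(plan$distance_grid, function(D) {
    s <- if (is.null(seed))
      condition_seed(plan$master_seed, "distance", bulk_label(bulk),
                     skin_thickness, D)
    else condition_seed(seed, "distance", bulk_label(bulk), skin_thickness, D)
    r <- run_one(scene, plan$theta_fixed, D, plan, s)
    list(row = data.frame(D_mm = D, peak_value = r$value,
                          peak_depth_mm = r$depth_mm, seed = s),
         profile = r$profile)
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(tab, "profiles") <- setNames(lapply(rows, `[[`, "profile"),
                                    paste0("D_", plan$distance_grid))
  attr(tab, "condition") <- list(bulk = bulk, skin_thickness = skin_thickness,
                                 theta = plan$theta_fixed)
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

#' @export
print.sweep_table <- function(x, ...) {
  cond <- attr(x, "condition")
  if (!is.null(cond))
    cat(sprintf("sweep_table: %s, skin %.2g mm\n", bulk_label(cond$bulk),
                cond$skin_thickness))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bulk-tissue conditions of the factorial study
#'
#' @param wavelengths Wavelengths for the pure fatty and fibrous conditions.
#' @param mixed_fractions Fatty fractions for the mixed conditions at 800 nm.
#' @return List of [tissue_spec()]s.
#' @export
study_conditions <- function(wavelengths = c(700, 800, 900, 1064),
                             mixed_fractions = c(0.2, 0.4, 0.6, 0.8)) {
  pure <- unlist(lapply(c("fatty", "fibrous"), function(k)
    lapply(wavelengths, function(w) tissue_spec(k, w))), recursive = FALSE)
  mixed <- lapply(mixed_fractions, function(f)
    tissue_spec("mixed", 800, fatty_fraction = f))
  c(pure, mixed)
}

#' Run the full species-comparison study
#'
#' For every bulk condition, runs the angle sweep with the mouse (0.3 mm) and
#' human (2.0 mm) skin thickness and forms the mouse-to-human ratio of
#' maximum fluence, producing the species-comparison ratio matrix. Conditions
#' that fail are recorded and the study continues.
#'
#' @param plan A [study_plan()].
#' @param conditions List of bulk [tissue_spec()]s (default:
#'   [study_conditions()]).
#' @return A list with `ratios` (data frame: `tissue`, `wavelength_nm`,
#'   `fatty_fraction`, `mouse_max`, `human_max`, `ratio`), `sweeps` (the
#'   per-condition `sweep_table`s), and `failures`.
#' @export
run_full_study <- function(plan, conditions = study_conditions()) {
  ratios <- NULL
  sweeps <- list()
  failures <- list()
  for (bulk in conditions) {
    lab <- bulk_label(bulk)
    res <- tryCatch({
      ms <- run_angle_sweep(plan, bulk, plan$skin_thickness[["mouse"]])
      hs <- run_angle_sweep(plan, bulk, plan$skin_thickness[["human"]])
      sweeps[[paste0(lab, "_mouse")]] <- ms
      sweeps[[paste0(lab, "_human")]] <- hs
      data.frame(tissue = bulk$kind, wavelength_nm = bulk$wavelength_nm,
                 fatty_fraction = if (is.null(bulk$fatty_fraction)) NA_real_
                                  else bulk$fatty_fraction,
                 mouse_max = max(ms$peak_value), human_max = max(hs$peak_value),
                 ratio = species_ratio(ms$peak_value, hs$peak_value))
    }, error = function(e) {
      failures[[lab]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) ratios <- rbind(ratios, res)
  }
  list(ratios = ratios, sweeps = sweeps, failures = failures)
}

#' Cross-sections illustrating ballistic versus diffusive transport
#'
#' Reruns one condition with the surface-layer scattering coefficient scaled
#' by `mu_s_scale` and returns the central x-z fluence section together with
#' the ROI depth profile. With human skin at full scattering the beam loses
#' its directionality inside the 2 mm layer; at one tenth the scattering the
#' tilted beam survives and delivers more light to the imaging plane.
#'
#' @param plan A [study_plan()].
#' @param bulk Bulk [tissue_spec()].
#' @param skin_thickness Skin thickness in mm (default human, 2.0).
#' @param theta Emission angle in degrees (default 60).
#' @param mu_s_scale Positive factor applied to the skin scattering
#'   coefficient.
#' @param seed Optional seed override.
#' @return List with `section` (from [fluence_section()]), `profile`, `peak`.
#' @export
fluence_section_figure <- function(plan, bulk, skin_thickness = 2.0,
                                   theta = 60, mu_s_scale = 1, seed = NULL) {
  stopifnot(mu_s_scale > 0)
  scene <- scale_surface_scattering(sweep_scene(plan, bulk, skin_thickness),
                                    mu_s_scale)
  s <- if (is.null(seed))
    condition_seed(plan$master_seed, "section", bulk_label(bulk),
                   skin_thickness, theta, mu_s_scale)
  else seed
  src <- make_source(D = plan$D_fixed, theta = theta,
                     n_photons = plan$n_photons, seed = s,
                     length_mm = plan$source_length_mm,
                     width_mm = plan$source_width_mm)
  grid <- mirror_average(mc_run(scene, src, boundary = plan$boundary))
  prof <- depth_profile(grid)
  list(section = fluence_section(grid), profile = prof,
       peak = peak_fluence(prof))
}
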