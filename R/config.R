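#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a study run: preset, master seed,
#' scene block, source block, and plan block. Every field has a default
#' matching the reference study (36 mm cube, D = 7 mm, angle grid 20 to 70
#' degrees in 12.5-degree steps, distance grid 5 to 13 mm in 2 mm steps), so
#' a minimal config naming only the preset is complete. Validation errors
#' name the offending field.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated `run_config` (list with `preset`, `seed`, `outdir`,
#'   `scene`, `source`, `plan`).
#' @export
load_run_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset %||% "desk"
  if (!preset %in% c("desk", "full"))
    stop("config field 'preset' must be 'desk' or 'full'; got ", preset)
  defaults <- switch(preset,
                     desk = list(voxel_pitch = 0.15, n_photons = 1e7),
                     full = list(voxel_pitch = 0.05, n_photons = 1e9))
  scene <- modifyList(list(side_length = 36,
                           voxel_pitch = defaults$voxel_pitch,
                           skin_thickness = 0.3,
                           bulk = list(kind = "fibrous", wavelength_nm = 700),
                           surface = list(kind = "skin")),
                      raw$scene %||% list())
  source <- modifyList(list(D = 7, theta = 45,
                            n_photons = defaults$n_photons,
                            length_mm = 25, width_mm = 1.4),
                       raw$source %||% list())
  plan <- modifyList(list(angle_grid = seq(20, 70, by = 12.5),
                          distance_grid = seq(5, 13, by = 2),
                          D_fixed = 7, theta_fixed = 45,
                          skin_thickness = list(mouse = 0.3, human = 2.0)),
                     raw$plan %||% list())

  check_num <- function(x, field, lo = -Inf, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) < 1L)
      stop("config field '", field, "' must be numeric")
    if (any(x < lo) || any(x > hi) || (lo_open && any(x <= lo)))
      stop(sprintf("config field '%s' = %s out of range [%g, %g]",
                   field, paste(x, collapse = ","), lo, hi))
    x
  }
  check_num(scene$side_length, "scene.side_length", 0, Inf, TRUE)
  check_num(scene$voxel_pitch, "scene.voxel_pitch", 0, Inf, TRUE)
  check_num(scene$skin_thickness, "scene.skin_thickness", 0)
  check_num(source$theta, "source.theta", 0, 90 - 1e-9)
  check_num(source$D, "source.D", 0)
  check_num(source$n_photons, "source.n_photons", 1)
  check_num(plan$angle_grid, "plan.angle_grid", 0, 90 - 1e-9)
  check_num(plan$distance_grid, "plan.distance_grid", 0)
  if (!scene$bulk$kind %in% c("skin", "fatty", "fibrous", "mixed", "milk", "gelatin"))
    stop("config field 'scene.bulk.kind' unknown: ", scene$bulk$kind)

  structure(list(preset = preset,
                 seed = as.integer(raw$seed %||% 1L),
                 outdir = raw$outdir %||% "palight-out",
                 scene = scene, source = source, plan = plan),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' Round-trips with [load_run_config()].
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a study plan from a run configuration
#'
#' @param config A `run_config`.
#' @return A [study_plan()].
#' @export
plan_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study_plan(preset = config$preset,
             voxel_pitch = config$scene$voxel_pitch,
             n_photons = config$source$n_photons,
             side_length = config$scene$side_length,
             angle_grid = config$plan$angle_grid,
             distance_grid = config$plan$distance_grid,
             D_fixed = config$plan$D_fixed,
             theta_fixed = config$plan$theta_fixed,
             source_length_mm = config$source$length_mm,
             source_width_mm = config$source$width_mm,
             skin_thickness = unlist(config$plan$skin_thickness),
             master_seed = config$seed)
}
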