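#' Write a fluence grid (or any 3-D array) as NRRD
#'
#' Writes the volume in NRRD format with text encoding, carrying the voxel
#' pitch as axis spacings, so the grid can be inspected in standard volume
#' viewers.
#'
#' @param x A `fluence_grid` or numeric 3-D array.
#' @param path Output path (conventionally `.nrrd`).
#' @param pitch Voxel pitch in mm (taken from the grid when `x` is a
#'   `fluence_grid`).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, pitch = NULL) {
  if (inherits(x, "fluence_grid")) {
    pitch <- x$pitch
    x <- x$values
  }
  stopifnot(is.array(x), length(dim(x)) == 3L, !is.null(pitch))
  d <- dim(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- c("NRRD0004",
              "type: double",
              "dimension: 3",
              sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
              sprintf("spacings: %g %g %g", pitch, pitch, pitch),
              "encoding: ascii",
              "")
  writeLines(header, con)
  writeLines(format(as.vector(x), digits = 9, scientific = TRUE,
                    trim = TRUE), con)
  invisible(path)
}

#' Stable hash of an R object
#'
#' 31-bit polynomial hash of the object's deparsed form, reported as hex;
#' used to stamp output manifests with a config fingerprint.
#'
#' @param x Any R object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "exact"), collapse = "\n")
  sprintf("%08x", condition_seed(0L, txt))
}

#' Write study outputs and a manifest
#'
#' Serializes the results of [run_full_study()] (ratio table, per-condition
#' sweep tables and depth profiles) as delimited text, and writes a JSON
#' manifest recording the configuration hash, seeds, per-run ledgers, and the
#' package version, so every published number is reconstructible from the
#' manifest alone.
#'
#' @param study Result of [run_full_study()].
#' @param directory Output directory (created if needed).
#' @param config Optional `run_config` to fingerprint.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(study, directory, config = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (!is.null(study$ratios)) {
    f <- file.path(directory, "fluence_ratios.tsv")
    write.table(study$ratios, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (nm in names(study$sweeps)) {
    tab <- study$sweeps[[nm]]
    f <- file.path(directory, paste0("sweep_", nm, ".tsv"))
    write.table(as.data.frame(tab), f, sep = "\t", row.names = FALSE,
                quote = FALSE)
    files <- c(files, f)
    profs <- attr(tab, "profiles")
    if (!is.null(profs) && !is.null(profs[[1]])) {
      wide <- data.frame(depth_mm = profs[[1]]$depth_mm)
      for (pn in names(profs)) wide[[pn]] <- profs[[pn]]$fluence
      fp <- file.path(directory, paste0("profiles_", nm, ".tsv"))
      write.table(wide, fp, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, fp)
    }
  }
  manifest <- list(package = "palight",
                   version = as.character(packageVersion("palight")),
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   config_hash = if (!is.null(config)) config_hash(unclass(config))
                                 else config_hash(study$ratios),
                   seed = if (!is.null(config)) config$seed,
                   files = basename(files),
                   n_conditions = if (!is.null(study$ratios)) nrow(study$ratios) else 0L,
                   failures = study$failures)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
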