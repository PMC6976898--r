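#' Imaging-plane region of interest
#'
#' The reported fluence is averaged over a thin rectangular region at the
#' center of the imaging plane: 0.5 mm across the plane (x) by 20 mm along
#' the transducer array (y), at every depth.
#'
#' @param x_halfwidth_mm Half-width across the imaging plane (default 0.25).
#' @param y_extent_mm Extent along the array, centered (default 20).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x_halfwidth_mm = 0.25, y_extent_mm = 20) {
  stopifnot(x_halfwidth_mm > 0, y_extent_mm > 0)
  structure(list(x_halfwidth_mm = x_halfwidth_mm, y_extent_mm = y_extent_mm),
            class = "roi_spec")
}

roi_indices <- function(grid, roi) {
  d <- dim(grid$values)
  cx <- grid$side / 2
  cy <- grid$side / 2
  xc <- (seq_len(d[1]) - 0.5) * grid$pitch
  yc <- (seq_len(d[2]) - 0.5) * grid$pitch
  ix <- which(abs(xc - cx) <= roi$x_halfwidth_mm)
  iy <- which(abs(yc - cy) <= roi$y_extent_mm / 2)
  if (length(ix) < 1L)
    stop("ROI is thinner than one voxel across the imaging plane at pitch ",
         grid$pitch)
  if (length(iy) < 1L)
    stop("ROI covers no voxels along the array at pitch ", grid$pitch)
  list(ix = ix, iy = iy)
}

#' ROI-averaged fluence versus depth
#'
#' For each depth layer, averages the normalized fluence over the voxels whose
#' centers fall inside the imaging-plane ROI.
#'
#' @param grid A `fluence_grid`.
#' @param roi An [roi_spec()].
#' @return A `depth_profile`: data frame with columns `depth_mm` (voxel-center
#'   depth) and `fluence` (mean normalized fluence, 1/mm^2).
#' @export
depth_profile <- function(grid, roi = roi_spec()) {
  stopifnot(inherits(grid, "fluence_grid"))
  id <- roi_indices(grid, roi)
  d <- dim(grid$values)
  sub <- grid$values[id$ix, id$iy, , drop = FALSE]
  prof <- apply(sub, 3L, mean)
  structure(data.frame(depth_mm = (seq_len(d[3]) - 0.5) * grid$pitch,
                       fluence = prof),
            class = c("depth_profile", "data.frame"))
}

#' Peak of a depth profile
#'
#' @param profile A `depth_profile` (or data frame with `depth_mm`,
#'   `fluence`).
#' @return A list with `value` (peak mean fluence) and `depth_mm`; ties are
#'   broken toward the shallower depth.
#' @export
peak_fluence <- function(profile) {
  if (nrow(profile) == 0L) stop("empty depth profile")
  i <- which.max(profile$fluence) # first maximum = shallowest on ties
  list(value = profile$fluence[i], depth_mm = profile$depth_mm[i])
}

#' Mouse-to-human maximum-fluence ratio
#'
#' The species comparison statistic: the maximum over the emission-angle grid
#' of the thin-skin (mouse) peak fluence, divided by the same maximum for the
#' thick-skin (human) runs.
#'
#' @param mouse_peaks Peak fluence per angle, thin (0.3 mm) skin.
#' @param human_peaks Peak fluence per angle, thick (2.0 mm) skin, on the
#'   same angle grid.
#' @return The scalar ratio.
#' @export
species_ratio <- function(mouse_peaks, human_peaks) {
  if (length(mouse_peaks) == 0L || length(human_peaks) == 0L)
    stop("peak vectors must be non-empty")
  if (length(mouse_peaks) != length(human_peaks))
    stop("mouse and human sweeps must cover the same angle grid")
  h <- max(human_peaks)
  if (h <= 0) stop("human maximum fluence is zero; ratio undefined")
  max(mouse_peaks) / h
}

#' Kernel SNR convergence score
#'
#' Monte Carlo convergence is scored on the imaging plane: the x-band of the
#' ROI is collapsed by averaging into a (y, depth) slice, then for every
#' position where a `kernel_mm` x `kernel_mm` window fits, the SNR is the
#' window mean divided by the window sample standard deviation. Windows with
#' zero variance are excluded so the average stays finite; a strictly
#' constant slice yields `NA` with `n_used = 0`.
#'
#' @param grid A `fluence_grid` (conventionally mirror-averaged).
#' @param kernel_mm Square kernel edge in mm (default 0.5).
#' @param roi ROI whose x-band defines the slice.
#' @return List with `average`, `minimum`, and `n_used` (finite-SNR windows).
#' @export
snr_score <- function(grid, kernel_mm = 0.5, roi = roi_spec()) {
  stopifnot(inherits(grid, "fluence_grid"))
  k <- floor(kernel_mm / grid$pitch + 1e-9)
  if (k < 2)
    stop(sprintf("kernel of %g mm covers fewer than 2 voxels at pitch %g mm",
                 kernel_mm, grid$pitch))
  id <- roi_indices(grid, roi)
  slice <- apply(grid$values[id$ix, , , drop = FALSE], c(2L, 3L), mean)
  ny <- nrow(slice); nz <- ncol(slice)
  if (ny < k || nz < k) stop("slice smaller than the kernel")
  my <- ny - k + 1L; mz <- nz - k + 1L
  s1 <- matrix(0, my, mz); s2 <- matrix(0, my, mz)
  for (dy in 0:(k - 1L)) for (dz in 0:(k - 1L)) {
    blk <- slice[(1L + dy):(my + dy), (1L + dz):(mz + dz)]
    s1 <- s1 + blk
    s2 <- s2 + blk * blk
  }
  n <- k * k
  mu <- s1 / n
  va <- pmax(s2 - s1 * s1 / n, 0) / (n - 1)
  sdv <- sqrt(va)
  ok <- sdv > 0
  if (!any(ok)) return(list(average = NA_real_, minimum = NA_real_, n_used = 0L))
  snr <- mu[ok] / sdv[ok]
  list(average = mean(snr), minimum = min(snr), n_used = sum(ok))
}
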