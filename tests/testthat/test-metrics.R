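# builds a fluence_grid directly from an array, bypassing the engine
grid_from_array <- function(values, pitch = 0.25, side = NULL) {
  d <- dim(values)
  side <- if (is.null(side)) d[1] * pitch else side
  structure(list(values = values, pitch = pitch, side = side,
                 ledger = c(launched = 1, absorbed = 0, escaped = 1,
                            residual = 0),
                 provenance = NULL),
            class = "fluence_grid")
}

test_that("depth profile averages exactly over the ROI", {
  # uniform grid: profile constant at the voxel value
  g <- grid_from_array(array(3.5, dim = c(40, 40, 10)))
  p <- depth_profile(g)
  expect_equal(p$fluence, rep(3.5, 10))
  expect_equal(p$depth_mm, (1:10 - 0.5) * 0.25)

  # grid nonzero only outside the ROI: all-zero profile
  arr <- array(0, dim = c(40, 40, 10))
  arr[1:5, , ] <- 7 # far from the central x band
  expect_equal(depth_profile(grid_from_array(arr))$fluence, rep(0, 10))

  # separable grid f(z) * indicator(ROI): profile recovers f(z)
  fz <- seq(1, 0.1, length.out = 10)
  arr2 <- array(0, dim = c(40, 40, 10))
  cx <- 40 * 0.25 / 2
  xc <- (1:40 - 0.5) * 0.25
  ix <- which(abs(xc - cx) <= 0.25)
  for (k in 1:10) arr2[ix, , k] <- fz[k]
  expect_equal(depth_profile(grid_from_array(arr2))$fluence, fz)
})

test_that("depth profile is linear in the grid", {
  set.seed(1)
  a1 <- array(runif(40 * 40 * 8), dim = c(40, 40, 8))
  a2 <- array(runif(40 * 40 * 8), dim = c(40, 40, 8))
  p1 <- depth_profile(grid_from_array(a1))$fluence
  p2 <- depth_profile(grid_from_array(a2))$fluence
  p12 <- depth_profile(grid_from_array(2 * a1 + 3 * a2))$fluence
  expect_equal(p12, 2 * p1 + 3 * p2)
})

test_that("profile peaks break ties toward the shallower depth", {
  prof <- structure(data.frame(depth_mm = c(1, 2, 3, 4),
                               fluence = c(0.2, 0.9, 0.9, 0.1)),
                    class = c("depth_profile", "data.frame"))
  pk <- peak_fluence(prof)
  expect_equal(pk$depth_mm, 2)
  expect_equal(pk$value, 0.9)
  # monotone decreasing profile peaks at the first layer
  prof2 <- structure(data.frame(depth_mm = 1:4, fluence = c(4, 3, 2, 1)),
                     class = c("depth_profile", "data.frame"))
  expect_equal(peak_fluence(prof2)$depth_mm, 1)
  expect_error(peak_fluence(prof[0, ]), "empty")
})

test_that("species ratio is the ratio of sweep maxima and scales linearly", {
  m <- c(1, 3, 2); h <- c(0.5, 1.5, 1)
  expect_equal(species_ratio(m, h), 2)
  expect_equal(species_ratio(m, m), 1)
  expect_equal(species_ratio(5 * m, h), 10) # scale-equivariance
  expect_error(species_ratio(numeric(0), h), "non-empty")
  expect_error(species_ratio(m, c(1, 2)), "angle grid")
  expect_error(species_ratio(m, c(0, 0, 0)), "zero")
})

test_that("kernel SNR recovers mean/sd of an i.i.d. noise field", {
  set.seed(42)
  mu <- 10; sigma <- 2
  arr <- array(stats::rnorm(8 * 200 * 200, mu, sigma), dim = c(8, 200, 200))
  g <- grid_from_array(arr, pitch = 0.25, side = 2)
  # kernel 0.5 mm = 2 voxels; the x band averages 2 voxels, reducing sd
  sc <- snr_score(g, kernel_mm = 0.5, roi = roi_spec(x_halfwidth_mm = 0.25,
                                                     y_extent_mm = 50))
  n_band <- 2
  expected <- mu / (sigma / sqrt(n_band))
  # kernel-sd estimates are chi-distributed; E[1/S] carries a small-sample
  # inflation factor for n = 4 (nu = 3 degrees of freedom)
  nu <- 3
  bias <- sqrt(nu) * gamma((nu - 1) / 2) / (sqrt(2) * gamma(nu / 2))
  expect_equal(sc$average * 1 / bias, expected, tolerance = 0.1)
  expect_gt(sc$minimum, 0)
})

test_that("a strictly constant slice yields the all-excluded sentinel", {
  g <- grid_from_array(array(1, dim = c(8, 40, 40)), pitch = 0.25, side = 2)
  sc <- snr_score(g, kernel_mm = 0.5)
  expect_true(is.na(sc$average))
  expect_identical(sc$n_used, 0L)
})

test_that("kernels below two voxels are rejected", {
  g <- grid_from_array(array(1, dim = c(8, 40, 40)), pitch = 0.3, side = 2.4)
  expect_error(snr_score(g, kernel_mm = 0.5), "fewer than 2")
})

test_that("snr_score grows like the square root of the photon budget", {
  sc <- custom_scene(mu_a = 0.05, mu_s = 1.5, g = 0.9, pitch = 0.3, side = 9)
  budgets <- c(2e3, 8e3, 32e3)
  snrs <- vapply(budgets, function(n) {
    fg <- mirror_average(mc_run(sc, narrow_beam(n_photons = n, seed = 21)))
    snr_score(fg, kernel_mm = 0.6, roi = roi_spec())$average
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(snrs) ~ log(budgets)))[2]
  expect_gt(slope, 0.3)
  expect_lt(slope, 0.7)
})
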