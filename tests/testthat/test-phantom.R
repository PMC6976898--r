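flat_profile <- function(depths = seq(0.5, 30, by = 0.5),
                         fluence = exp(-0.2 * depths)) {
  structure(data.frame(depth_mm = depths, fluence = fluence),
            class = c("depth_profile", "data.frame"))
}

test_that("the default rod layout matches the phantom build", {
  rods <- rod_spec()
  expect_equal(nrow(rods$positions), 11L)
  expect_equal(rods$positions$depth_mm, seq(4, 24, by = 2))
  expect_true(all(diff(rods$positions$depth_mm) > 0))
  expect_true(all(diff(rods$positions$lateral_mm) %in% c(5, 6)))
  expect_equal(rods$diameter_mm, 0.5)
})

test_that("noiseless synthetic scans are exact by construction", {
  prof <- flat_profile()
  rods <- rod_spec()
  flu <- approx(prof$depth_mm, prof$fluence, xout = rods$positions$depth_mm)$y

  # system factor 1: PA equals the true fluence at rod depths
  scan <- generate_synthetic_scan(prof, rods, system_factor = 1, noise_cv = 0,
                                  seed = 1)
  expect_equal(as.numeric(tapply(scan$pa, scan$rod, mean)[as.character(1:11)]),
               flu)
  expect_true(all(scan$us == 1))

  # arbitrary positive factor: US = factor^2, PA = fluence * factor
  sf <- function(z) 1 / (1 + 0.1 * z)
  scan2 <- generate_synthetic_scan(prof, rods, system_factor = sf,
                                   noise_cv = 0, seed = 1)
  z <- rods$positions$depth_mm
  one <- scan2[scan2$repeat_id == 1, ]
  expect_equal(one$us, sf(z)^2)
  expect_equal(one$pa, flu * sf(z))
})

test_that("synthetic scans are seeded and reproducible", {
  prof <- flat_profile()
  rods <- rod_spec()
  s1 <- generate_synthetic_scan(prof, rods, noise_cv = 0.05, seed = 7)
  s2 <- generate_synthetic_scan(prof, rods, noise_cv = 0.05, seed = 7)
  s3 <- generate_synthetic_scan(prof, rods, noise_cv = 0.05, seed = 8)
  expect_identical(s1$pa, s2$pa)
  expect_identical(s1$us, s2$us)
  expect_false(identical(s1$pa, s3$pa))
  expect_equal(attr(s1, "n_repeats"), 4)
  expect_true(all(s1$pa > 0) && all(s1$us > 0))
})

test_that("US normalization reproduces the worked two-rod example", {
  # US (4, 1), PA (8, 1): normalized US (1, 0.25), sqrt (1, 0.5),
  # adjusted PA (8, 2)
  scan <- structure(data.frame(rod = c(1, 2, 1, 2),
                               depth_mm = c(5, 10, 5, 10),
                               repeat_id = c(1, 1, 2, 2),
                               pa = c(8, 1, 8, 1), us = c(4, 1, 4, 1)),
                    class = c("rod_scan", "data.frame"))
  adj <- us_normalize(scan)
  expect_equal(adj$us_norm_sqrt, c(1, 0.5))
  expect_equal(adj$pa_adjusted, c(8, 2))
  # all-equal US leaves PA untouched
  scan$us <- 1
  expect_equal(us_normalize(scan)$pa_adjusted, c(8, 1))
})

test_that("US normalization recovers the fluence shape for any system factor", {
  prof <- flat_profile()
  rods <- rod_spec()
  flu <- approx(prof$depth_mm, prof$fluence, xout = rods$positions$depth_mm)$y
  for (sf in list(function(z) exp(-0.05 * z),
                  function(z) 2 + sin(z / 3),
                  function(z) 1 / (1 + z))) {
    scan <- generate_synthetic_scan(prof, rods, system_factor = sf,
                                    noise_cv = 0, seed = 1)
    adj <- us_normalize(scan)
    # adjusted PA = c * true fluence for a single global constant c
    c_est <- adj$pa_adjusted / flu
    expect_lt(diff(range(c_est)) / mean(c_est), 1e-10)
  }
})

test_that("adjusted-PA standard deviations are consistent with the noise level", {
  prof <- flat_profile()
  rods <- rod_spec(n_rods = 11)
  cv <- 0.05
  # pool many seeds: per-rod sd over 4 repeats, normalized by the mean,
  # should scatter around cv within the chi-square band for n = 4
  rel <- unlist(lapply(1:30, function(s) {
    scan <- generate_synthetic_scan(prof, rods, noise_cv = cv, seed = s)
    adj <- us_normalize(scan)
    adj$pa_sd / adj$pa_adjusted
  }))
  n <- 4
  expect_equal(mean(rel), cv, tolerance = 0.15)
  qs <- sqrt(stats::qchisq(c(0.005, 0.995), df = n - 1) / (n - 1))
  frac_in <- mean(rel / cv > qs[1] & rel / cv < qs[2])
  expect_gt(frac_in, 0.95)
})

test_that("model-to-scan comparison is self-consistent and discriminates", {
  prof <- flat_profile()
  rods <- rod_spec()
  scan <- generate_synthetic_scan(prof, rods, system_factor = function(z) 1 / (1 + 0.05 * z),
                                  noise_cv = 0, seed = 1)
  adj <- us_normalize(scan)
  cmp <- compare_model_to_scan(prof, adj)
  expect_lt(max(abs(cmp$residuals)), 1e-10)
  expect_equal(cmp$rank_agreement, 1)

  # 5% noise: residual spread consistent with the noise level
  scan_n <- generate_synthetic_scan(prof, rods, noise_cv = 0.05, seed = 2)
  cmp_n <- compare_model_to_scan(prof, us_normalize(scan_n))
  expect_gt(cmp_n$rms_residual, 1e-4)
  expect_lt(cmp_n$rms_residual, 0.1)

  # a deliberately wrong model (different decay) fits worse than the truth
  wrong <- flat_profile(fluence = exp(-0.05 * seq(0.5, 30, by = 0.5)))
  cmp_w <- compare_model_to_scan(wrong, us_normalize(scan_n))
  expect_gt(cmp_w$rms_residual, cmp_n$rms_residual)
})

test_that("rod depths outside the profile support are rejected", {
  prof <- flat_profile(depths = seq(0.5, 10, by = 0.5))
  expect_error(generate_synthetic_scan(prof, rod_spec(), noise_cv = 0),
               "support")
})
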