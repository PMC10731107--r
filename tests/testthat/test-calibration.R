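test_that("calibration fits recover exact lines on collinear rods", {
  m <- fit_calibration(c(0, 100), c(0, 100))
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0)

  m2 <- fit_calibration(c(10, 110, 210), c(0, 100, 200))
  expect_equal(m2$slope, 1, tolerance = 1e-12)
  expect_equal(m2$intercept, -10, tolerance = 1e-12)
  expect_equal(m2$r_squared, 1, tolerance = 1e-12)
  expect_equal(m2$n_rods, 3L)
})

test_that("degenerate calibration inputs error", {
  expect_error(fit_calibration(c(50, 50), c(0, 100)), "identical")
  expect_error(fit_calibration(c(1, 2, 3), c(0, 100)), "length")
  expect_error(fit_calibration(100, 100), "two rods")
})

test_that("hu_to_bmd is the affine conversion and commutes with averaging", {
  ident <- fit_calibration(c(0, 100), c(0, 100))
  expect_equal(hu_to_bmd(150, ident), 150)
  m <- structure(list(slope = 0.9, intercept = 5, r_squared = 1, n_rods = 2),
                 class = "calibration_model")
  expect_equal(hu_to_bmd(100, m), 95)
  m2 <- structure(list(slope = 1, intercept = -10, r_squared = 1, n_rods = 2),
                  class = "calibration_model")
  expect_equal(hu_to_bmd(10, m2), 0)

  hu <- rnorm(50, 150, 30)
  expect_equal(hu_to_bmd(mean(hu), m), mean(hu_to_bmd(hu, m)), tolerance = 1e-12)
})

test_that("rod means are measured on eroded rods in label order", {
  dims <- c(40, 40, 10)
  arr <- array(0, dims)
  lab <- array(0L, dims)
  ctr <- c(20.5, 20.5)
  sel <- outer(1:40, 1:40, function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2 <= 16)
  for (k in 1:10) {
    arr[, , k][sel] <- 120
    lab[, , k][sel] <- 1L
  }
  vol <- ct_volume(arr, spacing = c(1, 1, 3))
  rods <- ct_volume(lab, spacing = c(1, 1, 3))
  expect_equal(unname(measure_rod_hu(vol, rods, erosion_mm = 1)), 120)

  # noisy rod: >= 500 voxels, SE = 10/sqrt(n) keeps the mean within 1.5 HU
  set.seed(1)
  noisy <- vol
  noisy$data <- arr + rnorm(length(arr), 0, 10)
  expect_gt(sum(lab == 1L), 500)
  expect_lt(abs(measure_rod_hu(noisy, rods, erosion_mm = 1) - 120), 1.5)

  expect_error(measure_rod_hu(vol, rods, erosion_mm = 10), "empty after")
})

test_that("session calibration round-trips the generator truth at zero noise", {
  r <- render_session(vertebra_spec(), noise_sd = 0,
                      calibration_truth = list(slope = 0.8, intercept = -2),
                      texture_seed = 1)
  rods <- spineqct:::rod_label_volume(r$labels, r$legend)
  hu <- measure_rod_hu(r$volume, rods)
  fit <- fit_calibration(hu, c(0, 75, 150))
  expect_lt(abs(fit$slope - 0.8) / 0.8, 1e-6)
  expect_lt(abs(fit$intercept - (-2)) / 2, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})
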