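test_that("mid-slice selection takes the lower-median body slice", {
  mk <- function(slices) {
    arr <- array(FALSE, c(6, 6, 30))
    arr[3, 3, slices] <- TRUE
    arr
  }
  expect_equal(select_mid_slice(mk(10:20)), 15L)
  expect_equal(select_mid_slice(mk(10:21)), 15L)
  expect_equal(select_mid_slice(mk(7)), 7L)
  expect_error(select_mid_slice(mk(integer(0))), "empty")
})

test_that("the HU window is closed and excluded voxels never contribute", {
  hu <- matrix(-100, 10, 10)
  contour <- matrix(TRUE, 10, 10)
  m <- measure_muscle(hu, contour)
  expect_equal(m$csa, 0)
  expect_true(is.na(m$density))
  expect_false(m$density_defined)
  expect_equal(m$excluded_voxels, 100L)

  # boundary voxels at exactly -50 and 150 HU are retained
  hu2 <- matrix(c(-50, 150, -50.0001, 150.0001), 2, 2)
  m2 <- measure_muscle(hu2, matrix(TRUE, 2, 2))
  expect_equal(m2$retained_voxels, 2L)
  expect_equal(m2$density, mean(c(-50, 150)))

  # 800 voxels at 60 HU plus 200 fat voxels: csa 800 mm^2, density 60
  hu3 <- matrix(c(rep(60, 800), rep(-100, 200)), 40, 25)
  m3 <- measure_muscle(hu3, matrix(TRUE, 40, 25), voxel_area_mm2 = 1)
  expect_equal(m3$csa, 800)
  expect_equal(m3$density, 60)

  # window idempotence: growing the contour by out-of-window voxels is a no-op
  grown <- matrix(FALSE, 42, 25)
  grown[1:40, ] <- TRUE
  grown[41:42, 1:10] <- TRUE
  hu4 <- rbind(hu3, matrix(500, 2, 25))  # bone-bright rim
  m4 <- measure_muscle(hu4, grown, voxel_area_mm2 = 1)
  expect_equal(m4$csa, m3$csa)
  expect_equal(m4$density, m3$density)
})

test_that("totals side-average then sum, with size-weighted density", {
  mk <- function(muscle, side, csa, density) {
    data.frame(muscle = muscle, side = side, csa = csa, density = density)
  }
  meas <- rbind(mk("erector_spinae", "left", 100, 40),
                mk("erector_spinae", "right", 100, 40),
                mk("psoas_major", "left", 300, 60),
                mk("psoas_major", "right", 300, 60))
  tot <- compute_totals(meas)
  expect_equal(tot$total_csa, 400)
  expect_equal(tot$total_density, (100 * 40 + 300 * 60) / 400)  # 55 HU

  # equal densities make the weights irrelevant
  meas2 <- rbind(mk("erector_spinae", "left", 123, 47),
                 mk("erector_spinae", "right", 77, 47),
                 mk("psoas_major", "left", 310, 47),
                 mk("psoas_major", "right", 290, 47))
  expect_equal(compute_totals(meas2)$total_density, 47)

  # asymmetric sides are averaged before summing
  meas3 <- rbind(mk("psoas_major", "left", 100, 40),
                 mk("psoas_major", "right", 200, 80))
  tot3 <- compute_totals(meas3)
  expect_equal(tot3$total_csa, 150)
  expect_equal(tot3$total_density, 60)

  expect_error(compute_totals(mk("psoas_major", "left", 100, 40)), "missing a side")
  expect_equal(compute_totals(mk("psoas_major", "left", 100, 40),
                              allow_missing_side = TRUE)$total_csa, 100)
})

test_that("total density is convex in the per-muscle densities", {
  set.seed(3)
  for (i in 1:10) {
    meas <- data.frame(muscle = rep(c("a", "b", "c", "d"), each = 2),
                       side = rep(c("left", "right"), 4),
                       csa = runif(8, 50, 400), density = runif(8, -20, 120))
    tot <- compute_totals(meas)
    per <- tot$per_muscle$density
    expect_gte(tot$total_density, min(per) - 1e-12)
    expect_lte(tot$total_density, max(per) + 1e-12)
  }
})

test_that("session muscle measurement matches the analytic mixture expectation", {
  mus <- default_muscles(lean_fraction = 0.9, lean_hu = 60, fat_hu = -100)
  r <- render_session(vertebra_spec(), muscles = mus, noise_sd = 0,
                      texture_seed = 17)
  body <- ct_volume(array(r$labels$data %in% body_label_ids(r$legend),
                          dim(r$labels$data)), spacing = r$labels$spacing)
  out <- measure_session_muscles(r$volume, r$labels, r$legend, body)
  expect_equal(nrow(out$measurements), 8L)
  # all retained voxels are lean, so the weighted density is exactly lean_hu
  expect_equal(out$totals$total_density, 60)
  # total CSA approximates lean_fraction times the summed spec areas
  area_sum <- sum(vapply(mus, `[[`, 0, "area")) / 2  # side-averaged sum
  se <- sqrt(area_sum * 0.9 * 0.1)
  expect_lt(abs(out$totals$total_csa - 0.9 * area_sum), 5 * se + 0.05 * area_sum)
})
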