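test_that("zero margins return the body mask unchanged", {
  mask <- cylinder_mask(c(30, 30, 10), radius = 10, slices = 2:9)
  trab <- extract_trabecular_mask(mask, 0, 0)
  expect_equal(trab$data, mask$data)
})

test_that("in-plane erosion matches the brute-force morphology oracle", {
  mask <- cylinder_mask(c(46, 46, 6), radius = 20, slices = 1:6)
  trab <- extract_trabecular_mask(mask, cortical_margin_mm = 2,
                                  endplate_margin_mm = 2)
  oracle <- brute_erode_inplane(mask$data, 2)
  oracle[, , c(1, 2, 5, 6)] <- FALSE  # two-slice axial trim (2 mm at 1 mm slices)
  expect_identical(trab$data, oracle)
})

test_that("default margins exclude every cortical and endplate voxel", {
  r <- render_identity_session()
  body <- ct_volume(array(r$labels$data %in% body_label_ids(r$legend),
                          dim(r$labels$data)), spacing = r$labels$spacing)
  trab <- extract_trabecular_mask(body, 3, 3)
  shell_or_plate <- r$labels$data %in% c(r$legend$cortical_shell,
                                         r$legend$endplate)
  expect_equal(sum(trab$data & shell_or_plate), 0)
  # and the mask is a subset of true trabecular voxels
  expect_true(all(r$labels$data[trab$data] %in% trabecular_label_ids(r$legend)))
})

test_that("margins that consume the body raise an informative error", {
  mask <- cylinder_mask(c(20, 20, 6), radius = 5, slices = 2:5)
  expect_error(extract_trabecular_mask(mask, 10, 0), "0 voxels")
  expect_error(extract_trabecular_mask(mask, -1, 0), ">= 0")
})

test_that("partition allocates slices by fractions with remainder to transverse", {
  mk <- function(n_slices) cylinder_mask(c(12, 12, n_slices + 2), radius = 4,
                                         slices = 2:(n_slices + 1))
  p30 <- partition_regions(mk(30))
  expect_equal(unname(p30$slice_counts), c(10, 10, 10))
  p31 <- partition_regions(mk(31))
  expect_equal(unname(p31$slice_counts), c(10, 11, 10))
  p20 <- partition_regions(mk(20), fractions = c(0.5, 0.25, 0.25))
  expect_equal(unname(p20$slice_counts), c(10, 5, 5))
  expect_error(partition_regions(mk(2)), "at least 3")
  expect_error(partition_regions(mk(10), fractions = c(0.6, 0.3, 0.2)),
               "summing to 1")
})

test_that("partition tiles the trabecular mask exactly on arbitrary masks", {
  set.seed(7)
  for (i in 1:8) {
    dims <- c(16, 16, sample(5:14, 1))
    arr <- array(runif(prod(dims)) < 0.4, dims)
    if (sum(apply(arr, 3, any)) < 3) next
    mask <- ct_volume(arr, spacing = c(1, 1, 3))
    p <- partition_regions(mask)
    total <- p$inferior$data | p$transverse$data | p$superior$data
    expect_identical(total, arr)
    expect_equal(sum(p$inferior$data) + sum(p$transverse$data) +
                   sum(p$superior$data), sum(arr))
    expect_equal(sum(p$inferior$data & p$transverse$data), 0)
    expect_equal(sum(p$transverse$data & p$superior$data), 0)
  }
})

test_that("bone metrics convert region means and satisfy the weighted identity", {
  ident <- fit_calibration(c(0, 100), c(0, 100))
  mask <- cylinder_mask(c(20, 20, 9), radius = 6, slices = 1:9,
                        spacing = c(1, 1, 3))
  part <- partition_regions(mask)
  uni <- ct_volume(array(150, c(20, 20, 9)), spacing = c(1, 1, 3))
  m <- compute_bone_metrics(uni, part, ident)
  expect_equal(m$global_tb_vbmd, 150)
  expect_equal(m$rbmd_superior, 150)
  expect_equal(m$rbmd_transverse, 150)
  expect_equal(m$rbmd_inferior, 150)

  set.seed(11)
  noisy <- ct_volume(array(rnorm(20 * 20 * 9, 150, 40), c(20, 20, 9)),
                     spacing = c(1, 1, 3))
  mn <- compute_bone_metrics(noisy, part, ident)
  counts <- mn$voxel_counts
  weighted <- (counts["inferior"] * mn$rbmd_inferior +
               counts["transverse"] * mn$rbmd_transverse +
               counts["superior"] * mn$rbmd_superior) / sum(counts)
  expect_equal(unname(weighted), mn$global_tb_vbmd, tolerance = 1e-12)
})

test_that("preflight pipeline metrics recover the injected table of densities", {
  r <- render_identity_session()
  leg <- r$legend
  body <- ct_volume(array(r$labels$data %in% body_label_ids(leg),
                          dim(r$labels$data)), spacing = r$labels$spacing)
  part <- partition_regions(extract_trabecular_mask(body, 3, 3))
  ident <- fit_calibration(c(0, 100), c(0, 100))
  m <- compute_bone_metrics(r$volume, part, ident)
  expect_lt(abs(m$rbmd_superior - 178.9), 0.5)
  expect_lt(abs(m$rbmd_transverse - 177.5), 0.5)
  expect_lt(abs(m$rbmd_inferior - 196.5), 0.5)
  counts <- m$voxel_counts
  expect_lt(abs(m$global_tb_vbmd -
                  sum(counts * c(196.5, 177.5, 178.9)) / sum(counts)), 0.5)
})

test_that("raising one region's density raises only that region and the global", {
  v1 <- vertebra_spec()
  dens <- c(superior = 178.9 * 1.1, transverse = 177.5, inferior = 196.5)
  v2 <- vertebra_spec(regional_trabecular_density = dens)
  cal <- list(slope = 1, intercept = 0)
  r1 <- render_session(v1, muscles = list(), noise_sd = 0, calibration_truth = cal)
  r2 <- render_session(v2, muscles = list(), noise_sd = 0, calibration_truth = cal)
  ident <- fit_calibration(c(0, 100), c(0, 100))
  body <- ct_volume(array(r1$labels$data %in% body_label_ids(r1$legend),
                          dim(r1$labels$data)), spacing = r1$labels$spacing)
  part <- partition_regions(extract_trabecular_mask(body, 3, 3))
  m1 <- compute_bone_metrics(r1$volume, part, ident)
  m2 <- compute_bone_metrics(r2$volume, part, ident)
  expect_gt(m2$rbmd_superior, m1$rbmd_superior)
  expect_gt(m2$global_tb_vbmd, m1$global_tb_vbmd)
  expect_equal(m2$rbmd_transverse, m1$rbmd_transverse, tolerance = 1e-9)
  expect_equal(m2$rbmd_inferior, m1$rbmd_inferior, tolerance = 1e-9)
})
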