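test_that("rigid transform algebra: inverse and composition give identity", {
  tf <- rigid_transform(angles_deg = c(4, -3, 2.5), translation = c(1.5, -2, 3),
                        center = c(10, 20, 30))
  id <- compose_rigid(tf, invert_rigid(tf))
  expect_lt(max(abs(id$angles_deg)), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)

  R <- spineqct:::rotation_matrix_zyx(tf$angles_deg)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  # angle extraction inverts matrix construction
  expect_equal(spineqct:::angles_from_matrix(R), tf$angles_deg,
               tolerance = 1e-9)

  pts <- matrix(rnorm(30), 10, 3)
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("registration recovers known transforms on synthetic sessions", {
  ctr <- default_center()
  v <- vertebra_spec()
  pre <- render_session(v, noise_sd = 0, texture_seed = 21)

  # moving identical to fixed: identity within 0.1 mm / 0.1 deg
  reg0 <- register_rigid(pre$volume, pre$volume)
  expect_lt(max(abs(reg0$transform$angles_deg)), 0.1)
  expect_lt(max(abs(reg0$transform$translation)), 0.1)

  # pure translation (2, 3, 1) mm within 0.5 mm per axis
  tf_t <- rigid_transform(translation = c(2, 3, 1), center = ctr)
  mov_t <- render_session(v, noise_sd = 0, offset = tf_t, texture_seed = 21)
  reg_t <- register_rigid(mov_t$volume, pre$volume)
  expect_lt(max(abs(reg_t$transform$translation - c(2, 3, 1))), 0.5)
  expect_lt(max(abs(reg_t$transform$angles_deg)), 0.5)

  # 5 degree rotation about the longitudinal axis within 0.5 deg
  tf_r <- rigid_transform(angles_deg = c(0, 0, 5), center = ctr)
  mov_r <- render_session(v, noise_sd = 0, offset = tf_r, texture_seed = 21)
  reg_r <- register_rigid(mov_r$volume, pre$volume)
  expect_lt(abs(reg_r$transform$angles_deg[3] - 5), 0.5)
  expect_lt(max(abs(reg_r$transform$translation)), 0.5)

  # combined offset at scanner noise: within 1 mm / 1 deg
  set.seed(31)
  tf_n <- rigid_transform(angles_deg = c(2, -3, 4), translation = c(-2, 4, 1.5),
                          center = ctr)
  pre_n <- render_session(v, noise_sd = 10, texture_seed = 22)
  mov_n <- render_session(v, noise_sd = 10, offset = tf_n, texture_seed = 22)
  reg_n <- register_rigid(mov_n$volume, pre_n$volume)
  expect_lt(max(abs(reg_n$transform$angles_deg - c(2, -3, 4))), 1)
  expect_lt(max(abs(reg_n$transform$translation - c(-2, 4, 1.5))), 1)
})

test_that("resampling respects grids, labels and voxel-count conservation", {
  set.seed(5)
  vol <- ct_volume(array(rnorm(20 * 20 * 8), c(20, 20, 8)), spacing = c(1, 1, 3))
  # identity transform on the same grid returns the input unchanged
  expect_identical(resample(vol, NULL, vol, "trilinear"), vol)

  # label masks must not be interpolated
  mask <- cylinder_mask(c(20, 20, 8), radius = 6, slices = 2:7,
                        spacing = c(1, 1, 3))
  expect_error(resample(mask, NULL, vol, "trilinear"), "nearest")

  # translation by exactly one voxel pitch shifts indices, conserving count
  tf <- rigid_transform(translation = c(1, 0, 0),
                        center = default_center(c(20, 20, 8), c(1, 1, 3)))
  shifted <- resample(mask, tf, mask, "nearest")
  expect_equal(shifted$data[1:19, , ], mask$data[2:20, , ])
  expect_equal(sum(shifted$data), sum(mask$data))  # interior mask, no clipping

  # a 5-degree rotation changes mask volume by no more than 5 percent
  big <- cylinder_mask(c(40, 40, 12), radius = 12, slices = 3:10)
  tf_r <- rigid_transform(angles_deg = c(0, 0, 5),
                          center = default_center(c(40, 40, 12), c(1, 1, 1)))
  rot <- resample(big, tf_r, big, "nearest")
  expect_lt(abs(sum(rot$data) - sum(big$data)) / sum(big$data), 0.05)
  expect_true(all(unique(as.integer(rot$data)) %in% c(0L, 1L)))
})

test_that("label voting maps masks with sub-voxel boundaries and valid labels", {
  mask <- cylinder_mask(c(30, 30, 10), radius = 9, slices = 3:8)
  lab <- ct_volume(array(as.integer(mask$data), dim(mask$data)),
                   spacing = mask$spacing)
  lab$data[, , 6:8][mask$data[, , 6:8]] <- 2L
  tf <- rigid_transform(angles_deg = c(2, 1, -3), translation = c(0.4, -0.6, 0.3),
                        center = default_center(c(30, 30, 10), c(1, 1, 1)))
  mapped <- resample_label_vote(lab, tf, lab)
  expect_true(all(unique(as.integer(mapped$data)) %in% 0:2))
  expect_lt(abs(sum(mapped$data > 0) - sum(lab$data > 0)) / sum(lab$data > 0),
            0.05)
})

test_that("transforms survive JSON serialization", {
  tf <- rigid_transform(angles_deg = c(1, 2, 3), translation = c(-1, 0.5, 2),
                        center = c(47.5, 47.5, 58.5),
                        fixed_space_id = "preflight",
                        moving_space_id = "postflight")
  path <- tempfile(fileext = ".json")
  write_transform_json(tf, path)
  back <- read_transform_json(path)
  expect_equal(back$angles_deg, tf$angles_deg, tolerance = 1e-12)
  expect_equal(back$translation, tf$translation, tolerance = 1e-12)
  expect_identical(back$moving_space_id, "postflight")
  unlink(path)
})
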