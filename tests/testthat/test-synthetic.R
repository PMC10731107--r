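test_that("spec constructors validate their fields by name", {
  expect_error(vertebra_spec(cortical_thickness = 20), "cortical_thickness")
  expect_error(vertebra_spec(body_height = -1), "body_height")
  expect_error(vertebra_spec(regional_trabecular_density =
                               c(superior = -1, transverse = 1, inferior = 1)),
               "regional_trabecular_density")
  expect_error(muscle_spec("psoas_major", "left", area = -5,
                           center_offset = c(0, 0)), "area")
  expect_error(muscle_spec("psoas_major", "up", area = 5,
                           center_offset = c(0, 0)), "side")
  expect_error(muscle_spec("psoas_major", "left", area = 5, fat_hu = -20,
                           center_offset = c(0, 0)), "fat_hu")
  expect_error(phantom_spec(rod_nominal_densities = c(100, 100)), "distinct")
  expect_error(phantom_spec(rod_x_offsets = c(0, 5, 10)), "overlap")
  expect_error(cohort_config(n_subjects = 3, n_followup = 5), "n_followup")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
})

test_that("noiseless rendering hits the injected regional densities exactly", {
  r <- render_identity_session()  # identity HU->BMD truth
  lab <- r$labels$data
  leg <- r$legend
  expect_equal(mean(r$volume$data[lab == leg$trab_superior]), 178.9)
  expect_equal(mean(r$volume$data[lab == leg$trab_transverse]), 177.5)
  expect_equal(mean(r$volume$data[lab == leg$trab_inferior]), 196.5)

  # uniform densities give a constant trabecular field
  v2 <- vertebra_spec(regional_trabecular_density =
                        c(superior = 150, transverse = 150, inferior = 150))
  r2 <- render_session(v2, muscles = list(), noise_sd = 0,
                       calibration_truth = list(slope = 1, intercept = 0))
  trab <- r2$labels$data %in% trabecular_label_ids(r2$legend)
  expect_equal(sd(r2$volume$data[trab]), 0)
})

test_that("muscle fat mixture yields the expected in-window voxel count", {
  mus <- muscle_spec("psoas_major", "left", area = 400, lean_fraction = 0.8,
                     lean_hu = 55, fat_hu = -100, center_offset = c(32.5, -22),
                     aspect = 1)
  ph <- phantom_spec(rod_nominal_densities = c(0, 75),
                     rod_x_offsets = c(-24, 0))
  r <- render_session(vertebra_spec(), muscles = list(mus), phantom = ph,
                      noise_sd = 0, texture_seed = 3)
  k <- 20L  # a central slice
  lab <- r$labels$data[, , k]
  hu <- r$volume$data[, , k]
  contour <- lab == r$legend$psoas_major_left
  n_contour <- sum(contour)
  expect_lt(abs(n_contour - 400), 30)  # discretized ellipse area
  # brute-force voxel scan of the closed window
  n_in <- sum(contour & hu >= -50 & hu <= 150)
  expect_lt(abs(n_in - 0.8 * n_contour), 4 * sqrt(n_contour * 0.8 * 0.2))
  # the same count is what measure_muscle retains
  mm <- measure_muscle(hu, contour, voxel_area_mm2 = 1)
  expect_identical(mm$retained_voxels, n_in)
})

test_that("cohort generation is deterministic under the seed", {
  cfg <- cohort_config(n_subjects = 1, n_followup = 0, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects$S01$sessions$postflight$volume$data,
                   b$subjects$S01$sessions$postflight$volume$data)
  expect_identical(a$subjects$S01$sessions$preflight$labels$data,
                   b$subjects$S01$sessions$preflight$labels$data)
})

test_that("ground truth records exact percent changes and the mission multiset", {
  cfg <- cohort_config(seed = 3)
  set.seed(3)
  tr <- spineqct:::simulate_trajectories(cfg)
  expect_equal(nrow(tr), 17)
  expect_identical(sort(tr$mission_months),
                   sort(c(4, 4, 5, 5, 5, rep(6, 7), rep(7, 5))))
  expect_equal(mean(tr$mission_months), 100 / 17)  # 5.88, rounds to 5.9
  for (r in c("superior", "transverse", "inferior")) {
    expect_equal(percent_change(tr[[paste0("pre_", r)]],
                                tr[[paste0("post_", r)]]),
                 tr[[paste0("flight_pct_", r)]], tolerance = 1e-9)
  }
  # subjects without follow-up have no injected follow-up state
  expect_true(all(is.na(tr$fup_superior[!tr$has_followup])))
  expect_equal(sum(tr$has_followup), 15)
})

test_that("zero rates leave sessions identical up to offset and noise", {
  cfg <- cohort_config(n_subjects = 1, n_followup = 1, seed = 9, noise_sd = 0,
                       max_translation_mm = 0, max_rotation_deg = 0,
                       bone_flight = list(mode = c(superior = "rate", transverse = "rate", inferior = "rate"),
                                          mean = c(superior = 0, transverse = 0, inferior = 0),
                                          sd = c(superior = 0, transverse = 0, inferior = 0)),
                       bone_readapt = list(mode = c(superior = "rate", transverse = "rate", inferior = "rate"),
                                           mean = c(superior = 0, transverse = 0, inferior = 0),
                                           sd = c(superior = 0, transverse = 0, inferior = 0)),
                       muscle_flight = list(csa = c(mean = 0, sd = 0), density = c(mean = 0, sd = 0)),
                       muscle_readapt = list(csa = c(mean = 0, sd = 0), density = c(mean = 0, sd = 0)))
  g <- generate_cohort(cfg)
  s <- g$subjects$S01$sessions
  expect_identical(s$preflight$volume$data, s$postflight$volume$data)
  expect_identical(s$preflight$volume$data, s$followup$volume$data)
})

test_that("cohort volumes and truth round-trip through the NIfTI/CSV sidecars", {
  dir <- file.path(tempdir(), "qct_sim")
  unlink(dir, recursive = TRUE)
  cfg <- cohort_config(n_subjects = 1, n_followup = 0, seed = 12)
  out <- generate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  mem <- generate_cohort(cfg)
  img <- read_nifti(file.path(dir, "S01_preflight_image.nii.gz"))
  expect_equal(img$data, mem$subjects$S01$sessions$preflight$volume$data,
               tolerance = 1e-6)
  expect_equal(img$spacing, c(1, 1, 3))
  tr <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(tr$pre_superior, mem$truth$pre_superior, tolerance = 1e-9)
  # refusing to overwrite without force
  expect_error(run_simulate(cfg, dir), "force")
  unlink(dir, recursive = TRUE)
})
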