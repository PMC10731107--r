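#' Synthetic cohort configuration
#'
#' Defines the full study design emulated by the generator: cohort size and
#' follow-up completion, the mission-duration pool, baseline regional density
#' distributions, flight and readaptation bone-change distributions per
#' region, muscle CSA/density change distributions, scanner truth
#' (calibration, noise) and session repositioning ranges. Defaults reproduce
#' the study design of a 17-crewmember ISS cohort: three sessions
#' (preflight n = 17, postflight n = 17, follow-up n = 15), missions of
#' 4-7 months (multiset 4,4,5,5,5 and seven 6s and five 7s), about 12 months
#' of readaptation, and the published preflight density and monthly-rate
#' distributions.
#'
#' Bone-change entries take a per-region `mode`: `"rate"` draws a monthly
#' rate (%/month, applied over the mission or readaptation duration) and
#' `"percent"` draws a total percent change directly (flight: vs preflight;
#' readaptation: follow-up vs preflight).
#'
#' @param n_subjects cohort size.
#' @param n_followup number of subjects (in subject order) completing
#'   follow-up.
#' @param seed integer seed fixing all downstream randomness.
#' @param dims,spacing,noise_sd scan geometry and HU noise SD.
#' @param mission_months_pool integer months; permuted across subjects when
#'   `n_subjects` does not exceed the pool, otherwise resampled.
#' @param readapt_months readaptation duration (months).
#' @param preflight_density list of `mean`/`sd` per region
#'   (superior, transverse, inferior), mg/cm^3.
#' @param bone_flight,bone_readapt lists with `mode`, `mean`, `sd` per region
#'   (superior, transverse, inferior).
#' @param muscle_flight,muscle_readapt lists with `csa` and `density`
#'   entries, each `c(mean, sd)` in %/month.
#' @param lean_fraction0,lean_fraction_sd,lean_hu0,lean_hu_sd,fat_hu baseline
#'   muscle mixture parameters (subject baselines are drawn around the
#'   means).
#' @param calibration_truth true scanner HU-to-density line (slope,
#'   intercept).
#' @param max_translation_mm,max_rotation_deg uniform ranges for
#'   session-to-session rigid repositioning.
#' @param empirical_draws if `TRUE`, injected distributions are drawn with
#'   exactly matching sample mean/SD (see [rnorm_cohort()]).
#' @param region_fractions inferior/transverse/superior split fractions.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17, n_followup = 15, seed = 1,
                          dims = c(96, 96, 40), spacing = c(1, 1, 3),
                          noise_sd = 10,
                          mission_months_pool = c(4, 4, 5, 5, 5, rep(6, 7), rep(7, 5)),
                          readapt_months = 12,
                          preflight_density = list(
                            mean = c(superior = 178.9, transverse = 177.5,
                                     inferior = 196.5),
                            sd = c(superior = 32.4, transverse = 29.6,
                                   inferior = 32.4)),
                          bone_flight = list(
                            mode = c(superior = "rate", transverse = "rate",
                                     inferior = "rate"),
                            mean = c(superior = -1.08, transverse = -0.72,
                                     inferior = -0.51),
                            sd = c(superior = 1.13, transverse = 0.77,
                                   inferior = 1.17)),
                          bone_readapt = list(
                            mode = c(superior = "rate", transverse = "rate",
                                     inferior = "rate"),
                            mean = c(superior = 0.39, transverse = 0.01,
                                     inferior = 0.05),
                            sd = c(superior = 0.80, transverse = 0.56,
                                   inferior = 0.85)),
                          muscle_flight = list(csa = c(mean = -1.02, sd = 1.29),
                                               density = c(mean = -0.83, sd = 0.89)),
                          muscle_readapt = list(csa = c(mean = 0.72, sd = 0.78),
                                                density = c(mean = 0.28, sd = 0.55)),
                          lean_fraction0 = 0.75, lean_fraction_sd = 0.03,
                          lean_hu0 = 55, lean_hu_sd = 3, fat_hu = -100,
                          calibration_truth = list(slope = 0.8, intercept = -2),
                          max_translation_mm = 5, max_rotation_deg = 5,
                          empirical_draws = FALSE,
                          region_fractions = c(1, 1, 1) / 3) {
  if (n_followup > n_subjects) {
    stop("cohort_config: field 'n_followup' must be <= n_subjects", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("cohort_config: field 'noise_sd' must be >= 0", call. = FALSE)
  }
  if (n_subjects < 1) {
    stop("cohort_config: field 'n_subjects' must be >= 1", call. = FALSE)
  }
  regions <- c("superior", "transverse", "inferior")
  for (blk in list(bone_flight, bone_readapt)) {
    if (!all(blk$mode %in% c("rate", "percent"))) {
      stop("cohort_config: bone change 'mode' must be 'rate' or 'percent'",
           call. = FALSE)
    }
    stopifnot(all(regions %in% names(blk$mode)),
              all(regions %in% names(blk$mean)),
              all(regions %in% names(blk$sd)))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_followup = as.integer(n_followup), seed = as.integer(seed),
                 dims = dims, spacing = spacing, noise_sd = noise_sd,
                 mission_months_pool = mission_months_pool,
                 readapt_months = readapt_months,
                 preflight_density = preflight_density,
                 bone_flight = bone_flight, bone_readapt = bone_readapt,
                 muscle_flight = muscle_flight,
                 muscle_readapt = muscle_readapt,
                 lean_fraction0 = lean_fraction0,
                 lean_fraction_sd = lean_fraction_sd,
                 lean_hu0 = lean_hu0, lean_hu_sd = lean_hu_sd, fat_hu = fat_hu,
                 calibration_truth = calibration_truth,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 empirical_draws = isTRUE(empirical_draws),
                 region_fractions = region_fractions),
            class = "cohort_config")
}

draw_block <- function(n, mean, sd, empirical) {
  regions <- c("superior", "transverse", "inferior")
  out <- sapply(regions, function(r) rnorm_cohort(n, mean[[r]], sd[[r]], empirical))
  matrix(out, nrow = n, dimnames = list(NULL, regions))
}

#' Draw the per-subject ground-truth trajectories of a cohort
#'
#' Consumes the RNG (callers seed it) and returns the full injected design:
#' baseline densities, flight and readaptation bone changes per region,
#' muscle trajectories, mission durations and session rigid offsets. Changes
#' compose multiplicatively on densities; percent changes recorded in the
#' table are exact by construction.
#'
#' @param config a [cohort_config].
#' @return A data frame with one row per subject (class `cohort_truth` keeps
#'   the per-session density columns).
#' @keywords internal
simulate_trajectories <- function(config) {
  n <- config$n_subjects
  nf <- config$n_followup
  emp <- config$empirical_draws
  pool <- config$mission_months_pool
  months <- if (n <= length(pool)) {
    sample(pool, n, replace = FALSE)
  } else {
    sample(pool, n, replace = TRUE)
  }
  pre <- draw_block(n, config$preflight_density$mean,
                    config$preflight_density$sd, emp)
  fl <- draw_block(n, config$bone_flight$mean, config$bone_flight$sd, emp)
  re <- draw_block(max(nf, 1L), config$bone_readapt$mean,
                   config$bone_readapt$sd, emp)
  mus_fl_csa <- rnorm_cohort(n, config$muscle_flight$csa[["mean"]],
                             config$muscle_flight$csa[["sd"]], emp)
  mus_fl_den <- rnorm_cohort(n, config$muscle_flight$density[["mean"]],
                             config$muscle_flight$density[["sd"]], emp)
  mus_re_csa <- rnorm_cohort(max(nf, 1L), config$muscle_readapt$csa[["mean"]],
                             config$muscle_readapt$csa[["sd"]], emp)
  mus_re_den <- rnorm_cohort(max(nf, 1L), config$muscle_readapt$density[["mean"]],
                             config$muscle_readapt$density[["sd"]], emp)
  lf0 <- pmin(pmax(rnorm(n, config$lean_fraction0, config$lean_fraction_sd),
                   0.05), 0.95)
  lhu0 <- pmin(pmax(rnorm(n, config$lean_hu0, config$lean_hu_sd), -49), 149)
  offsets <- matrix(0, nrow = n, ncol = 12,
                    dimnames = list(NULL, c(t(outer(c("post", "fup"),
                                                    c("rx", "ry", "rz", "tx", "ty", "tz"),
                                                    paste, sep = "_")))))
  for (i in seq_len(n)) {
    offsets[i, ] <- c(runif(3, -config$max_rotation_deg, config$max_rotation_deg),
                      runif(3, -config$max_translation_mm, config$max_translation_mm),
                      runif(3, -config$max_rotation_deg, config$max_rotation_deg),
                      runif(3, -config$max_translation_mm, config$max_translation_mm))
  }

  regions <- c("superior", "transverse", "inferior")
  out <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                    mission_months = months,
                    readapt_months = config$readapt_months,
                    has_followup = seq_len(n) <= nf)
  for (r in regions) {
    out[[paste0("pre_", r)]] <- pre[, r]
    if (config$bone_flight$mode[[r]] == "rate") {
      out[[paste0("flight_rate_", r)]] <- fl[, r]
      out[[paste0("flight_pct_", r)]] <- fl[, r] * months
    } else {
      out[[paste0("flight_pct_", r)]] <- fl[, r]
      out[[paste0("flight_rate_", r)]] <- fl[, r] / months
    }
    out[[paste0("post_", r)]] <-
      out[[paste0("pre_", r)]] * (1 + out[[paste0("flight_pct_", r)]] / 100)
    re_i <- rep(NA_real_, n)
    re_i[seq_len(nf)] <- re[seq_len(max(nf, 1L)), r][seq_len(nf)]
    if (config$bone_readapt$mode[[r]] == "rate") {
      out[[paste0("readapt_rate_", r)]] <- re_i
      out[[paste0("fup_", r)]] <-
        out[[paste0("post_", r)]] * (1 + re_i * config$readapt_months / 100)
      out[[paste0("readapt_pct_", r)]] <- re_i * config$readapt_months
    } else {
      # percent change of follow-up relative to *preflight*
      out[[paste0("fup_", r)]] <- out[[paste0("pre_", r)]] * (1 + re_i / 100)
      out[[paste0("readapt_pct_", r)]] <-
        (out[[paste0("fup_", r)]] / out[[paste0("post_", r)]] - 1) * 100
      out[[paste0("readapt_rate_", r)]] <-
        out[[paste0("readapt_pct_", r)]] / config$readapt_months
    }
    out[[paste0("fup_", r)]][!out$has_followup] <- NA_real_
  }
  out$muscle_csa_flight_rate <- mus_fl_csa
  out$muscle_density_flight_rate <- mus_fl_den
  out$muscle_csa_readapt_rate <- c(mus_re_csa[seq_len(nf)],
                                   rep(NA_real_, n - nf))
  out$muscle_density_readapt_rate <- c(mus_re_den[seq_len(nf)],
                                       rep(NA_real_, n - nf))
  out$lean_fraction_pre <- lf0
  out$lean_hu_pre <- lhu0
  out$lean_fraction_post <- pmin(lf0 * (1 + mus_fl_csa * months / 100), 0.995)
  out$lean_hu_post <- lhu0 * (1 + mus_fl_den * months / 100)
  out$lean_fraction_fup <- pmin(out$lean_fraction_post *
    (1 + out$muscle_csa_readapt_rate * config$readapt_months / 100), 0.995)
  out$lean_hu_fup <- out$lean_hu_post *
    (1 + out$muscle_density_readapt_rate * config$readapt_months / 100)
  out <- cbind(out, as.data.frame(offsets))
  out
}

subject_session_inputs <- function(config, traj_row, session) {
  regions <- c("superior", "transverse", "inferior")
  suffix <- switch(session, preflight = "pre", postflight = "post",
                   followup = "fup")
  dens <- setNames(vapply(regions, function(r) {
    traj_row[[paste0(suffix, "_", r)]]
  }, 0), regions)
  vert <- vertebra_spec(regional_trabecular_density = dens)
  lf <- traj_row[[paste0("lean_fraction_", suffix)]]
  lhu <- traj_row[[paste0("lean_hu_", suffix)]]
  muscles <- default_muscles(lean_fraction = lf, lean_hu = lhu,
                             fat_hu = config$fat_hu)
  offset <- NULL
  if (session != "preflight") {
    pfx <- if (session == "postflight") "post" else "fup"
    grid <- ct_volume(array(0L, config$dims), spacing = config$spacing)
    offset <- rigid_transform(
      angles_deg = unlist(traj_row[paste0(pfx, "_", c("rx", "ry", "rz"))]),
      translation = unlist(traj_row[paste0(pfx, "_", c("tx", "ty", "tz"))]),
      center = volume_center(grid),
      fixed_space_id = "preflight", moving_space_id = session)
  }
  list(vertebra = vert, muscles = muscles, offset = offset)
}

#' Iterate over a synthetic cohort subject by subject
#'
#' Seeds the RNG from the config, draws the trajectories, renders each
#' subject's sessions in a fixed order and hands each subject record to
#' `callback`, keeping at most one subject in memory. Both
#' [generate_cohort()] and [run_pipeline()] are built on this, so a given
#' config yields bit-identical volumes whichever entry point is used.
#'
#' @param config a [cohort_config].
#' @param callback `function(record)` called once per subject; `record` has
#'   `subject_id`, `traj` (the truth row) and `sessions` (named list of
#'   [render_session()] outputs).
#' @return The trajectory (ground-truth) data frame, invisibly.
#' @export
cohort_iterate <- function(config, callback) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  traj <- simulate_trajectories(config)
  phantom <- phantom_spec()
  for (i in seq_len(config$n_subjects)) {
    row <- traj[i, , drop = FALSE]
    sessions <- c("preflight", "postflight",
                  if (row$has_followup) "followup")
    rendered <- list()
    for (s in sessions) {
      inp <- subject_session_inputs(config, row, s)
      rendered[[s]] <- render_session(
        vertebra = inp$vertebra, muscles = inp$muscles, phantom = phantom,
        calibration_truth = config$calibration_truth,
        noise_sd = config$noise_sd, offset = inp$offset,
        dims = config$dims, spacing = config$spacing,
        region_fractions = config$region_fractions,
        texture_seed = as.numeric(config$seed) * 1000 + i)
    }
    callback(list(subject_id = row$subject_id, traj = row,
                  sessions = rendered))
  }
  invisible(traj)
}

# polynomial rolling hash (mod 2^31 - 1); detects silent config drift
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                       digits = NA))
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a synthetic CT cohort
#'
#' Renders every subject-session of the configured cohort. With `dir`, each
#' session's HU volume and label mask are written as NIfTI-1 (`.nii.gz`,
#' world mm), the label legend and a manifest (config plus hash) as JSON, and
#' the ground-truth table as CSV; the rendered volumes are not kept in
#' memory. Without `dir`, everything is returned in memory.
#'
#' Regeneration with the same config (and seed) is bit-identical.
#'
#' @param config a [cohort_config].
#' @param dir optional output directory.
#' @return List with `truth` (ground-truth data frame), `config`, and either
#'   `subjects` (in-memory records) or `dir` and the written `files`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  keep <- is.null(dir)
  subjects <- list()
  files <- character()
  if (!keep) {
    ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir)) {
      stop(sprintf("generate_cohort: cannot create output directory '%s'", dir),
           call. = FALSE)
    }
  }
  cb <- function(record) {
    if (keep) {
      subjects[[record$subject_id]] <<- record
    } else {
      for (s in names(record$sessions)) {
        base <- file.path(dir, paste0(record$subject_id, "_", s))
        write_nifti(record$sessions[[s]]$volume, paste0(base, "_image.nii.gz"))
        write_nifti(record$sessions[[s]]$labels, paste0(base, "_labels.nii.gz"))
        files <<- c(files, paste0(base, "_image.nii.gz"),
                    paste0(base, "_labels.nii.gz"))
      }
    }
  }
  truth <- cohort_iterate(config, cb)
  if (!keep) {
    legend <- render_legend(default_muscles(), phantom_spec())
    jsonlite::write_json(legend, file.path(dir, "legend.json"),
                         auto_unbox = TRUE)
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    manifest <- list(package = "spineqct", config = unclass(config),
                     config_hash = config_hash(config),
                     phantom = unclass(phantom_spec()))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(truth = truth, config = config, dir = dir,
         files = c(files, file.path(dir, c("legend.json", "ground_truth.csv",
                                           "manifest.json"))))
  } else {
    list(truth = truth, config = config, subjects = subjects)
  }
}
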