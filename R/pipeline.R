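#' Analysis options for the serial-QCT pipeline
#'
#' Every tolerance and threshold used by the analysis lives here; nothing is
#' hidden in the stage functions.
#'
#' @param cortical_margin_mm,endplate_margin_mm trabecular-mask margins (mm).
#' @param region_fractions inferior/transverse/superior slice fractions.
#' @param hu_window closed HU window for muscle analysis.
#' @param rod_densities nominal phantom rod densities (mg/cm^3), ascending
#'   rod-label order.
#' @param rod_erosion_mm in-plane erosion of rod regions before averaging
#'   (`NULL` = one in-plane voxel).
#' @param registration a [registration_options()] list.
#' @param mask_mapping how preflight masks are mapped into later sessions:
#'   `"linear_vote"` (sub-voxel label voting, [resample_label_vote()]) or
#'   `"nearest"` (plain nearest-neighbour).
#' @param region_core_weight winning-vote weight required of mapped regional
#'   voxels (linear_vote only). Values above 0.5 restrict regional means to
#'   the partial-volume-free core of each mapped region; regions are
#'   internally uniform, so the restriction is unbiased.
#' @param readapt_denominator `"readapt"` or `"mission"` (see
#'   [build_report()]).
#' @export
analysis_options <- function(cortical_margin_mm = 3, endplate_margin_mm = 3,
                             region_fractions = c(1, 1, 1) / 3,
                             hu_window = c(-50, 150),
                             rod_densities = c(0, 75, 150),
                             rod_erosion_mm = NULL,
                             registration = registration_options(),
                             mask_mapping = c("linear_vote", "nearest"),
                             region_core_weight = 0.9,
                             readapt_denominator = "readapt") {
  list(cortical_margin_mm = cortical_margin_mm,
       endplate_margin_mm = endplate_margin_mm,
       region_fractions = region_fractions, hu_window = hu_window,
       rod_densities = rod_densities, rod_erosion_mm = rod_erosion_mm,
       registration = registration,
       mask_mapping = match.arg(mask_mapping),
       region_core_weight = region_core_weight,
       readapt_denominator = readapt_denominator)
}

label_mask <- function(labels, ids) {
  ct_volume(array(labels$data %in% ids, dim = dim(labels$data)),
            spacing = labels$spacing, origin = labels$origin)
}

rod_label_volume <- function(labels, legend) {
  ids <- unlist(legend[grep("^rod_", names(legend))], use.names = FALSE)
  keep <- labels$data %in% ids
  out <- array(0L, dim = dim(labels$data))
  out[keep] <- labels$data[keep]
  ct_volume(out, spacing = labels$spacing, origin = labels$origin)
}

session_calibration <- function(volume, labels, legend, options) {
  rods <- rod_label_volume(labels, legend)
  hu <- measure_rod_hu(volume, rods, erosion_mm = options$rod_erosion_mm)
  fit_calibration(hu, options$rod_densities)
}

partition_to_labels <- function(partition) {
  ref <- partition$inferior
  out <- array(0L, dim = dim(ref$data))
  out[partition$inferior$data] <- 1L
  out[partition$transverse$data] <- 2L
  out[partition$superior$data] <- 3L
  ct_volume(out, spacing = ref$spacing, origin = ref$origin)
}

labels_to_partition <- function(lab_vol, fractions) {
  mk <- function(id) {
    ct_volume(array(lab_vol$data == id, dim = dim(lab_vol$data)),
              spacing = lab_vol$spacing, origin = lab_vol$origin)
  }
  counts <- vapply(1:3, function(id) {
    length(unique(which(lab_vol$data == id, arr.ind = TRUE)[, 3]))
  }, 0L)
  structure(list(inferior = mk(1L), transverse = mk(2L), superior = mk(3L),
                 split_fractions = fractions,
                 slice_counts = setNames(counts,
                                         c("inferior", "transverse", "superior"))),
            class = "region_partition")
}

metrics_row <- function(subject_id, session, traj_row, bone, muscles) {
  data.frame(subject_id = subject_id, session = session,
             global_tb_vbmd = bone$global_tb_vbmd,
             rbmd_superior = bone$rbmd_superior,
             rbmd_transverse = bone$rbmd_transverse,
             rbmd_inferior = bone$rbmd_inferior,
             total_muscle_csa = muscles$totals$total_csa,
             total_muscle_density = muscles$totals$total_density,
             mission_months = traj_row$mission_months,
             readapt_months = traj_row$readapt_months,
             stringsAsFactors = FALSE)
}

#' Analyze one subject's serial scans
#'
#' Runs the full measurement chain in the order calibrate, register, map
#' masks, partition, bone metrics, muscle metrics. The trabecular mask and
#' its regional partition are defined once on the preflight scan; postflight
#' and follow-up scans are rigidly registered to preflight and the
#' preflight-defined masks mapped into each session with the inverse
#' transform (nearest-neighbour), so all sessions are measured on matched
#' regions of interest. Each session is calibrated from its own phantom
#' rods.
#'
#' @param record subject record as produced by [cohort_iterate()] (or
#'   assembled from files): `subject_id`, `traj` (needs `mission_months`,
#'   `readapt_months`), `sessions` with `volume`, `labels`, `legend` each.
#' @param options an [analysis_options()] list.
#' @return List with `rows` (cohort-table rows) and `diagnostics` (per
#'   session: calibration, transform, voxel counts, mid-slice).
#' @export
analyze_subject <- function(record, options = analysis_options()) {
  pre <- record$sessions$preflight
  legend <- pre$legend
  diag <- list()

  cal_pre <- session_calibration(pre$volume, pre$labels, legend, options)
  body_pre <- label_mask(pre$labels, body_label_ids(legend))
  trab <- extract_trabecular_mask(body_pre, options$cortical_margin_mm,
                                  options$endplate_margin_mm)
  part_pre <- partition_regions(trab, options$region_fractions)
  part_labels <- partition_to_labels(part_pre)
  bone_pre <- compute_bone_metrics(pre$volume, part_pre, cal_pre)
  mus_pre <- measure_session_muscles(pre$volume, pre$labels, legend, body_pre,
                                     options$hu_window)
  diag$preflight <- list(calibration = cal_pre,
                         voxel_counts = bone_pre$voxel_counts,
                         mid_slice = mus_pre$mid_slice)
  rows <- metrics_row(record$subject_id, "preflight", record$traj, bone_pre,
                      mus_pre)

  for (s in intersect(c("postflight", "followup"), names(record$sessions))) {
    sess <- record$sessions[[s]]
    cal <- session_calibration(sess$volume, sess$labels, legend, options)
    reg <- register_rigid(moving = sess$volume, fixed = pre$volume,
                          options = options$registration)
    inv <- invert_rigid(reg$transform)
    body_int <- ct_volume(array(as.integer(body_pre$data),
                                dim(body_pre$data)),
                          spacing = body_pre$spacing,
                          origin = body_pre$origin)
    if (options$mask_mapping == "linear_vote") {
      mapped_part <- resample_label_vote(part_labels, transform = inv,
                                         target = sess$volume,
                                         min_weight = options$region_core_weight)
      mapped_body <- resample_label_vote(body_int, transform = inv,
                                         target = sess$volume)
    } else {
      mapped_part <- resample(part_labels, transform = inv,
                              target = sess$volume, interpolation = "nearest")
      mapped_body <- resample(body_int, transform = inv,
                              target = sess$volume, interpolation = "nearest")
    }
    part <- labels_to_partition(mapped_part, options$region_fractions)
    bone <- compute_bone_metrics(sess$volume, part, cal)
    mus <- measure_session_muscles(sess$volume, sess$labels, legend,
                                   mapped_body, options$hu_window)
    diag[[s]] <- list(calibration = cal, transform = reg$transform,
                      registration_metric = reg$metric,
                      converged = reg$converged,
                      voxel_counts = bone$voxel_counts,
                      mid_slice = mus$mid_slice)
    rows <- rbind(rows, metrics_row(record$subject_id, s, record$traj, bone,
                                    mus))
  }
  list(rows = rows, diagnostics = diag)
}

#' Run the full synthetic-cohort pipeline in memory
#'
#' Simulate, analyze and tabulate in one pass: subjects are rendered and
#' measured one at a time (nothing written to disk), producing the cohort
#' metrics table, the injected ground truth and per-session diagnostics. A
#' subject whose analysis fails is skipped with a recorded reason rather
#' than aborting the run.
#'
#' @param config a [cohort_config].
#' @param options an [analysis_options()]; its `rod_densities` default is
#'   taken from the generator phantom.
#' @return List: `cohort` (metrics table), `truth`, `diagnostics`, `skipped`.
#' @export
run_pipeline <- function(config, options = analysis_options()) {
  rows <- list()
  diags <- list()
  skipped <- list()
  cb <- function(record) {
    res <- tryCatch(analyze_subject(record, options), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[record$subject_id]] <<- conditionMessage(res)
    } else {
      rows[[record$subject_id]] <<- res$rows
      diags[[record$subject_id]] <<- res$diagnostics
    }
  }
  truth <- cohort_iterate(config, cb)
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(cohort = cohort, truth = truth, diagnostics = diags, skipped = skipped)
}

#' Disk-based pipeline stages
#'
#' `run_simulate` writes a cohort to `dir` (refusing to overwrite an existing
#' simulation without `force`); `run_analyze` reads a simulated cohort from
#' disk, analyzes each subject (skipping failing subjects with a logged
#' reason) and writes `cohort_metrics.csv` plus per-session JSON sidecars;
#' `run_stats` builds the cohort report from a metrics table or CSV path and
#' optionally writes report files.
#'
#' @param config a [cohort_config].
#' @param dir simulation directory.
#' @param force overwrite an existing simulation.
#' @return `run_simulate`: the [generate_cohort()] manifest listing.
#' @export
run_simulate <- function(config, dir, force = FALSE) {
  if (file.exists(file.path(dir, "manifest.json")) && !force) {
    stop(sprintf("run_simulate: '%s' already holds a simulation (use force = TRUE)",
                 dir), call. = FALSE)
  }
  generate_cohort(config, dir = dir)
}

read_session_record <- function(dir, subject_id, sessions, legend) {
  recs <- list()
  for (s in sessions) {
    base <- file.path(dir, paste0(subject_id, "_", s))
    img <- paste0(base, "_image.nii.gz")
    lab <- paste0(base, "_labels.nii.gz")
    if (!file.exists(img)) next
    labels <- read_nifti(lab)
    labels$data <- array(as.integer(round(labels$data)), dim(labels$data))
    recs[[s]] <- list(volume = read_nifti(img), labels = labels,
                      legend = legend)
  }
  recs
}

#' @rdname run_simulate
#' @param options an [analysis_options()] list.
#' @export
run_analyze <- function(dir, options = analysis_options()) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("run_analyze: no manifest.json under '%s'", dir), call. = FALSE)
  }
  legend <- jsonlite::read_json(file.path(dir, "legend.json"),
                                simplifyVector = TRUE)
  legend <- as.list(legend)
  truth <- read.csv(file.path(dir, "ground_truth.csv"),
                    stringsAsFactors = FALSE)
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, , drop = FALSE]
    sessions <- c("preflight", "postflight", if (isTRUE(row$has_followup)) "followup")
    res <- tryCatch({
      recs <- read_session_record(dir, row$subject_id, sessions, legend)
      out <- analyze_subject(list(subject_id = row$subject_id, traj = row,
                                  sessions = recs), options)
      sidecar <- file.path(dir, paste0(row$subject_id, "_analysis.json"))
      side <- lapply(out$diagnostics, function(d) {
        list(calibration = unclass(d$calibration),
             transform = if (!is.null(d$transform)) {
               list(angles_deg = d$transform$angles_deg,
                    translation_mm = d$transform$translation,
                    convention = d$transform$convention)
             },
             voxel_counts = as.list(d$voxel_counts),
             mid_slice = d$mid_slice)
      })
      jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
      out$rows
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[row$subject_id]] <- conditionMessage(res)
      message(sprintf("run_analyze: skipping %s: %s", row$subject_id,
                      conditionMessage(res)))
    } else {
      rows[[row$subject_id]] <- res
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  write.csv(cohort, file.path(dir, "cohort_metrics.csv"), row.names = FALSE)
  list(cohort = cohort, skipped = skipped)
}

#' @rdname run_simulate
#' @param cohort cohort metrics table (data frame) or path to its CSV.
#' @param out_dir optional directory for the report files.
#' @export
run_stats <- function(cohort, options = analysis_options(), out_dir = NULL) {
  if (is.character(cohort)) {
    cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  }
  report <- build_report(cohort,
                         readapt_denominator = options$readapt_denominator)
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}
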