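#' Select the mid-vertebral axial slice
#'
#' Muscle morphometry is read at the mid-vertebral body level: the median
#' mask-bearing axial slice index, taking the lower median for an even count
#' so the choice is deterministic.
#'
#' @param body_mask A [ct_volume] (or logical/integer array) marking the
#'   vertebral body in the session's grid.
#' @return Integer axial slice index.
#' @export
select_mid_slice <- function(body_mask) {
  m <- if (inherits(body_mask, "ct_volume")) body_mask$data else body_mask
  slices <- which(apply(m > 0, 3, any))
  if (length(slices) == 0) {
    stop("select_mid_slice: body mask is empty", call. = FALSE)
  }
  slices[floor((length(slices) + 1) / 2)]
}

#' Measure one muscle contour on an axial slice
#'
#' Voxels with attenuation outside the closed window (default \[-50, 150\] HU)
#' are excluded before anything is computed, removing pure fat, tendon and
#' bone at the contour periphery. CSA is the retained voxel count times the
#' in-plane voxel area; density is the mean HU of retained voxels only. A
#' contour whose voxels are all excluded yields `csa = 0` with `density = NA`
#' and `density_defined = FALSE` rather than a silent zero.
#'
#' @param slice_hu numeric matrix of HU values (one axial slice).
#' @param contour logical matrix, the muscle contour on that slice.
#' @param window length-2 closed HU interval, default `c(-50, 150)`.
#' @param voxel_area_mm2 in-plane voxel area in mm^2.
#' @param muscle,side optional labels carried into the result.
#' @return A one-row data frame: `muscle`, `side`, `csa` (mm^2), `density`
#'   (HU), `retained_voxels`, `excluded_voxels`, `density_defined`.
#' @export
measure_muscle <- function(slice_hu, contour, window = c(-50, 150),
                           voxel_area_mm2 = 1, muscle = NA_character_,
                           side = NA_character_) {
  if (!any(contour)) {
    stop("measure_muscle: contour is empty", call. = FALSE)
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("measure_muscle: `window` must be an increasing HU interval", call. = FALSE)
  }
  inside <- contour & slice_hu >= window[1] & slice_hu <= window[2]
  n_ret <- sum(inside)
  data.frame(muscle = muscle, side = side,
             csa = n_ret * voxel_area_mm2,
             density = if (n_ret > 0) mean(slice_hu[inside]) else NA_real_,
             retained_voxels = n_ret,
             excluded_voxels = sum(contour) - n_ret,
             density_defined = n_ret > 0,
             stringsAsFactors = FALSE)
}

#' Combine per-muscle measurements into paraspinal totals
#'
#' For each of the four paraspinal muscles (erector spinae, transversospinalis,
#' psoas major, quadratus lumborum) the left and right sides are averaged for
#' both CSA and density; total CSA is the sum of the four side-averaged CSAs
#' and total density their CSA-weighted mean (weighted by individual muscle
#' size).
#'
#' @param measurements data frame of [measure_muscle()] rows, one per
#'   muscle-side (normally 8 rows).
#' @param allow_missing_side if `TRUE`, a muscle present on one side only uses
#'   that side; otherwise a missing side is an error.
#' @return An object of class `muscle_totals`: `total_csa` (mm^2),
#'   `total_density` (HU) and the per-muscle side-averaged table.
#' @export
compute_totals <- function(measurements, allow_missing_side = FALSE) {
  req <- c("muscle", "side", "csa", "density")
  if (!all(req %in% names(measurements))) {
    stop("compute_totals: measurements must have columns muscle, side, csa, density",
         call. = FALSE)
  }
  muscles <- unique(measurements$muscle)
  per <- lapply(muscles, function(m) {
    rows <- measurements[measurements$muscle == m, , drop = FALSE]
    if (nrow(rows) < 2 && !allow_missing_side) {
      stop(sprintf("compute_totals: muscle '%s' is missing a side (set allow_missing_side = TRUE to accept)",
                   m), call. = FALSE)
    }
    data.frame(muscle = m, csa = mean(rows$csa),
               density = mean(rows$density), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  total_csa <- sum(per$csa)
  total_density <- if (total_csa > 0) {
    sum(per$csa * per$density) / total_csa
  } else {
    NA_real_
  }
  structure(list(total_csa = total_csa, total_density = total_density,
                 per_muscle = per),
            class = "muscle_totals")
}

#' @export
print.muscle_totals <- function(x, ...) {
  cat(sprintf("<muscle_totals> total CSA %.1f mm^2, size-weighted density %.2f HU\n",
              x$total_csa, x$total_density))
  invisible(x)
}

#' Measure all paraspinal muscles of a session at the mid-vertebral slice
#'
#' Convenience wrapper: selects the mid-vertebral slice from the (mapped)
#' body mask, measures every muscle label on that slice with the HU window,
#' and combines them into totals.
#'
#' @param volume [ct_volume] HU image of the session.
#' @param labels [ct_volume] integer label volume of the session.
#' @param legend named list mapping label names to integer values; muscle
#'   labels must be named `<muscle>_<left|right>`.
#' @param body_mask [ct_volume] used only to pick the mid-vertebral slice
#'   (the preflight-defined body mapped into this session's space).
#' @param window closed HU analysis window.
#' @return A list with `mid_slice`, `measurements` (8-row data frame) and
#'   `totals` ([compute_totals()] result).
#' @export
measure_session_muscles <- function(volume, labels, legend, body_mask,
                                    window = c(-50, 150)) {
  k <- select_mid_slice(body_mask)
  slice_hu <- volume$data[, , k]
  lab_slice <- labels$data[, , k]
  muscle_names <- grep("_(left|right)$", names(legend), value = TRUE)
  if (length(muscle_names) == 0) {
    stop("measure_session_muscles: no muscle labels in legend", call. = FALSE)
  }
  rows <- lapply(muscle_names, function(nm) {
    id <- legend[[nm]]
    contour <- lab_slice == id
    measure_muscle(slice_hu, contour, window = window,
                   voxel_area_mm2 = prod(volume$spacing[1:2]),
                   muscle = sub("_(left|right)$", "", nm),
                   side = sub("^.*_(left|right)$", "\\1", nm))
  })
  measurements <- do.call(rbind, rows)
  list(mid_slice = k, measurements = measurements,
       totals = compute_totals(measurements))
}
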