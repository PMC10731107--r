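#' In-plane binary erosion by a Euclidean disc
#'
#' A voxel is retained iff every in-plane voxel centre within Euclidean
#' distance `r_vox` (in voxels) lies inside the mask; equivalently its 2D
#' distance to the nearest background pixel exceeds `r_vox`. Computed slice by
#' slice from the Euclidean distance map.
#'
#' @param mask logical 3D array.
#' @param r_vox erosion radius in (in-plane) voxels.
#' @return logical 3D array.
#' @keywords internal
erode_inplane <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    d <- EBImage::distmap(EBImage::Image(sl * 1), metric = "euclidean")
    out[, , k] <- sl & (as.matrix(d) > r_vox)
  }
  out
}

#' Extract the trabecular mask from a vertebral body mask
#'
#' The cortical shell is removed by eroding the body mask in-plane by
#' `cortical_margin_mm`, and the endplates by trimming whole slices covering
#' `endplate_margin_mm` from both axial ends of the mask. The longitudinal
#' axis is the third array axis, index 1 inferior.
#'
#' @param body_mask A [ct_volume] with logical/integer data marking the whole
#'   vertebral body (shell and endplates included).
#' @param cortical_margin_mm in-plane margin (mm), default 3.
#' @param endplate_margin_mm axial margin (mm) trimmed at both ends, default 3;
#'   rounded up to whole slices.
#' @return A [ct_volume] with logical data (class also `trabecular_mask`),
#'   with the margins recorded in attribute `provenance`.
#' @export
extract_trabecular_mask <- function(body_mask, cortical_margin_mm = 3,
                                    endplate_margin_mm = 3) {
  stopifnot(inherits(body_mask, "ct_volume"))
  if (cortical_margin_mm < 0 || endplate_margin_mm < 0) {
    stop("extract_trabecular_mask: margins must be >= 0", call. = FALSE)
  }
  m <- body_mask$data > 0
  if (!any(m)) {
    stop("extract_trabecular_mask: body mask is empty", call. = FALSE)
  }
  if (abs(body_mask$spacing[1] - body_mask$spacing[2]) > 1e-9) {
    stop("extract_trabecular_mask: anisotropic in-plane spacing is not supported",
         call. = FALSE)
  }
  r_vox <- cortical_margin_mm / body_mask$spacing[1]
  m <- erode_inplane(m, r_vox)
  n_trim <- as.integer(ceiling(endplate_margin_mm / body_mask$spacing[3] - 1e-9))
  if (n_trim > 0) {
    slices <- which(apply(m, 3, any))
    if (length(slices) > 0) {
      drop <- c(utils::head(slices, n_trim), utils::tail(slices, n_trim))
      m[, , drop] <- FALSE
    }
  }
  if (!any(m)) {
    stop(sprintf(paste0("extract_trabecular_mask: margins (%.3g mm in-plane, ",
                        "%.3g mm axial) consume the whole body; 0 voxels remain"),
                 cortical_margin_mm, endplate_margin_mm), call. = FALSE)
  }
  out <- ct_volume(m, spacing = body_mask$spacing, origin = body_mask$origin)
  attr(out, "provenance") <- list(cortical_margin_mm = cortical_margin_mm,
                                  endplate_margin_mm = endplate_margin_mm)
  class(out) <- c("trabecular_mask", class(out))
  out
}

#' Partition a trabecular mask into inferior / transverse / superior regions
#'
#' Mask-bearing axial slices are assigned inferior-to-superior by cumulative
#' fraction: the inferior region receives `floor(f_inf * n)` slices, the
#' superior `floor(f_sup * n)`, and the transverse (middle) region the
#' remainder, so remainder slices always land in the transverse slab and the
#' three masks tile the trabecular mask exactly.
#'
#' @param mask A trabecular mask ([ct_volume], logical).
#' @param fractions length-3 non-negative fractions (inferior, transverse,
#'   superior) summing to 1. Default equal thirds.
#' @return An object of class `region_partition`: list with [ct_volume]
#'   logical masks `inferior`, `transverse`, `superior`, plus
#'   `split_fractions` and per-region `slice_counts`.
#' @export
partition_regions <- function(mask, fractions = c(1, 1, 1) / 3) {
  stopifnot(inherits(mask, "ct_volume"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("partition_regions: `fractions` must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  m <- mask$data > 0
  slices <- which(apply(m, 3, any))
  n <- length(slices)
  if (n < 3L) {
    stop(sprintf("partition_regions: mask spans only %d slice(s); need at least 3", n),
         call. = FALSE)
  }
  n_inf <- as.integer(floor(fractions[1] * n + 1e-9))
  n_sup <- as.integer(floor(fractions[3] * n + 1e-9))
  n_tra <- n - n_inf - n_sup
  if (n_inf < 1L || n_tra < 1L || n_sup < 1L) {
    stop("partition_regions: a region would receive no slices", call. = FALSE)
  }
  zero <- array(FALSE, dim = dim(m))
  inf_m <- tra_m <- sup_m <- zero
  inf_s <- slices[seq_len(n_inf)]
  tra_s <- slices[n_inf + seq_len(n_tra)]
  sup_s <- slices[n_inf + n_tra + seq_len(n_sup)]
  inf_m[, , inf_s] <- m[, , inf_s]
  tra_m[, , tra_s] <- m[, , tra_s]
  sup_m[, , sup_s] <- m[, , sup_s]
  mk <- function(x) ct_volume(x, spacing = mask$spacing, origin = mask$origin)
  structure(list(inferior = mk(inf_m), transverse = mk(tra_m),
                 superior = mk(sup_m),
                 split_fractions = fractions,
                 slice_counts = c(inferior = n_inf, transverse = n_tra,
                                  superior = n_sup)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> slices inferior/transverse/superior: %d/%d/%d\n",
              x$slice_counts[1], x$slice_counts[2], x$slice_counts[3]))
  invisible(x)
}

#' Compute calibrated global and regional trabecular BMD
#'
#' Per-region mean HU over the (possibly session-mapped) partition masks,
#' converted through the session calibration. The global value is computed
#' over the union of the three regions, hence exactly the voxel-count-weighted
#' mean of the regional values.
#'
#' @param session_volume [ct_volume] in HU.
#' @param partition A [region_partition] on the session grid.
#' @param model A `calibration_model` for this session.
#' @return An object of class `bone_metrics`: `global_tb_vbmd`,
#'   `rbmd_superior`, `rbmd_transverse`, `rbmd_inferior` (mg/cm^3) and
#'   `voxel_counts` per region.
#' @export
compute_bone_metrics <- function(session_volume, partition, model) {
  stopifnot(inherits(session_volume, "ct_volume"),
            inherits(partition, "region_partition"))
  validate_calibration(model)
  regions <- c("inferior", "transverse", "superior")
  counts <- integer(3)
  sums <- numeric(3)
  for (i in seq_along(regions)) {
    m <- partition[[regions[i]]]$data > 0
    counts[i] <- sum(m)
    if (counts[i] == 0) {
      stop(sprintf("compute_bone_metrics: mapped region '%s' is empty", regions[i]),
           call. = FALSE)
    }
    sums[i] <- sum(session_volume$data[m])
  }
  mean_hu <- sums / counts
  bmd <- hu_to_bmd(mean_hu, model)
  structure(list(global_tb_vbmd = hu_to_bmd(sum(sums) / sum(counts), model),
                 rbmd_inferior = bmd[1], rbmd_transverse = bmd[2],
                 rbmd_superior = bmd[3],
                 voxel_counts = setNames(counts, regions)),
            class = "bone_metrics")
}

#' @export
print.bone_metrics <- function(x, ...) {
  cat(sprintf(paste0("<bone_metrics> global %.1f | superior %.1f | transverse",
                     " %.1f | inferior %.1f mg/cm^3\n"),
              x$global_tb_vbmd, x$rbmd_superior, x$rbmd_transverse,
              x$rbmd_inferior))
  invisible(x)
}
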