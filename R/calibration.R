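#' Fit the linear HU-to-BMD calibration from phantom rods
#'
#' Quantitative CT expresses attenuation as volumetric bone mineral density by
#' scanning a hydroxyapatite phantom together with the subject and fitting an
#' ordinary least-squares line `density = slope * HU + intercept` through the
#' rods' mean attenuations and their nominal densities. One calibration is
#' fitted per scan session, never shared across sessions, since tracking
#' scanner drift is the phantom's purpose.
#'
#' @param rod_mean_hu numeric vector of per-rod mean attenuations (HU).
#' @param rod_densities numeric vector of nominal rod densities
#'   (mg/cm^3 hydroxyapatite), same length and order.
#' @return An object of class `calibration_model` with fields `slope`
#'   (mg/cm^3 per HU), `intercept` (mg/cm^3), `r_squared` and `n_rods`.
#' @export
fit_calibration <- function(rod_mean_hu, rod_densities) {
  if (length(rod_mean_hu) != length(rod_densities)) {
    stop("fit_calibration: rod HU and density vectors differ in length", call. = FALSE)
  }
  if (length(rod_mean_hu) < 2L) {
    stop("fit_calibration: at least two rods are required to fit a line", call. = FALSE)
  }
  if (any(!is.finite(rod_mean_hu)) || any(!is.finite(rod_densities))) {
    stop("fit_calibration: non-finite rod values", call. = FALSE)
  }
  if (diff(range(rod_mean_hu)) == 0) {
    stop("fit_calibration: degenerate input, all rod HU values identical", call. = FALSE)
  }
  fit <- lm(rod_densities ~ rod_mean_hu)
  slope <- unname(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((rod_densities - mean(rod_densities))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_rods = length(rod_mean_hu)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> BMD = %.6g * HU + %.6g  (r^2 = %.4f, %d rods)\n",
    x$slope, x$intercept, x$r_squared, x$n_rods))
  invisible(x)
}

validate_calibration <- function(model) {
  if (!inherits(model, "calibration_model") || !is.finite(model$slope) ||
      model$slope == 0) {
    stop("invalid calibration model (slope must be finite and non-zero)",
         call. = FALSE)
  }
  invisible(model)
}

#' Convert attenuation to bone mineral density
#'
#' Affine map `slope * hu + intercept`; because it is affine, converting a mean
#' HU equals the mean of converted HUs, so region means may be converted after
#' averaging.
#'
#' @param hu_value numeric HU value(s).
#' @param model A `calibration_model`.
#' @return BMD in mg/cm^3 hydroxyapatite.
#' @export
hu_to_bmd <- function(hu_value, model) {
  validate_calibration(model)
  model$slope * hu_value + model$intercept
}

#' Measure mean attenuation of each calibration rod
#'
#' Rod regions are eroded in-plane before averaging to discard the
#' partial-volume rim at the rod boundary (standard QCT practice), then the
#' mean HU is taken per rod label in ascending label order.
#'
#' @param volume A [ct_volume] in HU.
#' @param rod_mask A [ct_volume] of integer rod labels (0 = background), or an
#'   integer array on the same grid.
#' @param erosion_mm in-plane erosion radius in mm (default one in-plane voxel).
#' @return Named numeric vector of mean HU per rod, names are the rod labels.
#' @export
measure_rod_hu <- function(volume, rod_mask, erosion_mm = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  labels <- if (inherits(rod_mask, "ct_volume")) rod_mask$data else rod_mask
  if (!identical(dim(labels), dim(volume$data))) {
    stop("measure_rod_hu: rod mask grid does not match the volume", call. = FALSE)
  }
  if (is.null(erosion_mm)) erosion_mm <- volume$spacing[1]
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (length(ids) == 0) {
    stop("measure_rod_hu: rod mask is empty", call. = FALSE)
  }
  out <- numeric(length(ids))
  r_vox <- erosion_mm / volume$spacing[1]
  for (i in seq_along(ids)) {
    m <- labels == ids[i]
    if (r_vox > 0) {
      # erode within the rod's bounding box only
      w <- which(m, arr.ind = TRUE)
      rx <- range(w[, 1]); ry <- range(w[, 2]); rz <- range(w[, 3])
      sub <- m[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE]
      pad <- array(FALSE, dim = dim(sub) + c(2, 2, 0))
      pad[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), ] <- sub
      pad <- erode_inplane(pad, r_vox)
      m[] <- FALSE
      m[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2]] <-
        pad[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), ]
    }
    if (!any(m)) {
      stop(sprintf("measure_rod_hu: rod label %d empty after %.3g mm erosion",
                   ids[i], erosion_mm), call. = FALSE)
    }
    out[i] <- mean(volume$data[m])
  }
  names(out) <- ids
  out
}

#' Serialize a calibration model to JSON
#' @param model A `calibration_model`.
#' @param path File path.
#' @export
write_calibration_json <- function(model, path) {
  validate_calibration(model)
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
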