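#' Construct a CT volume
#'
#' A `ct_volume` is the package's carrier for all image math: a 3D scalar grid
#' (Hounsfield units, a density map, or integer labels) plus the voxel spacing
#' and world origin. World coordinates are in mm, RAS+-style, with the voxel
#' centre of index `(1,1,1)` at `origin` and the longitudinal (slice) axis as
#' the third array dimension.
#'
#' @param data 3D numeric or integer array.
#' @param spacing length-3 positive numeric, voxel spacing in mm.
#' @param origin length-3 numeric, world position (mm) of the first voxel centre.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 3), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    stop("ct_volume: `data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("ct_volume: `spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("ct_volume: `origin` must be three finite numbers (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, %s storage\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              storage.mode(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' World coordinates of all voxel centres
#'
#' @param vol A [ct_volume].
#' @return An n-by-3 matrix of world coordinates (mm), voxels in array order.
#' @keywords internal
voxel_world_coords <- function(vol) {
  d <- dim(vol$data)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Centre of the volume's world extent
#' @keywords internal
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) * vol$spacing / 2
}

world_to_voxel0 <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Read / write a CT volume as NIfTI-1
#'
#' Volumes are stored with the voxel spacing in `pixdim` and the origin in the
#' sform affine (RAS+, world mm). Label volumes round-trip as integers.
#'
#' @param vol A [ct_volume].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` a [ct_volume].
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  aff <- diag(4)
  aff[1, 1] <- vol$spacing[1]
  aff[2, 2] <- vol$spacing[2]
  aff[3, 3] <- vol$spacing[3]
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("failed to write NIfTI volume to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("NIfTI file not found: '%s'", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  ct_volume(arr, spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4])
}
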