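#' Rigid (6-DOF) spatial transforms
#'
#' A `rigid_transform` maps world points (mm) of the *fixed* image space into
#' the *moving* image space:
#' \deqn{x_m = R (x_f - c) + c + t}
#' where `R` is built from intrinsic Z-Y-X Euler angles in degrees
#' (`R = Rz(az) Ry(ay) Rx(ax)`), `c` is the rotation centre (by convention the
#' fixed volume's world centre), and `t` a translation in mm. This is the
#' transform estimated when registering a postflight or follow-up scan
#' (moving) to the preflight scan (fixed), and its inverse is what maps
#' preflight-defined masks into the later session's grid.
#'
#' @param angles_deg length-3 numeric, intrinsic ZYX Euler angles (degrees).
#' @param translation length-3 numeric translation (mm).
#' @param center length-3 rotation centre in world mm.
#' @param fixed_space_id,moving_space_id optional labels for bookkeeping.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0), fixed_space_id = NA_character_,
                            moving_space_id = NA_character_) {
  angles_deg <- as.numeric(angles_deg)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (length(angles_deg) != 3L || any(!is.finite(angles_deg))) {
    stop("rigid_transform: `angles_deg` must be three finite angles", call. = FALSE)
  }
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("rigid_transform: `translation` must be three finite lengths (mm)", call. = FALSE)
  }
  structure(list(angles_deg = angles_deg, translation = translation,
                 center = center, fixed_space_id = fixed_space_id,
                 moving_space_id = moving_space_id,
                 convention = "intrinsic-ZYX-degrees"),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (ZYX, deg): %s; translation (mm): %s\n",
              paste(format(x$angles_deg, digits = 4), collapse = ", "),
              paste(format(x$translation, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix from intrinsic ZYX Euler angles (degrees)
#' @keywords internal
rotation_matrix_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ca <- cos(a[1]); sa <- sin(a[1])  # about x
  cb <- cos(a[2]); sb <- sin(a[2])  # about y
  cc <- cos(a[3]); sc <- sin(a[3])  # about z
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  rz %*% ry %*% rx
}

#' ZYX Euler angles (degrees) from a rotation matrix
#' @keywords internal
angles_from_matrix <- function(R) {
  ay <- asin(pmin(1, pmax(-1, -R[3, 1])))
  ax <- atan2(R[3, 2], R[3, 3])
  az <- atan2(R[2, 1], R[1, 1])
  c(ax, ay, az) * 180 / pi
}

#' Apply, invert and compose rigid transforms
#'
#' `apply_rigid` maps an n-by-3 matrix of fixed-space world points to moving
#' space; `invert_rigid` returns the moving-to-fixed transform (same rotation
#' centre); `compose_rigid` returns the transform equivalent to applying `b`
#' after `a` (`x -> b(a(x))`).
#'
#' @param transform,a,b [rigid_transform] objects.
#' @param pts n-by-3 matrix of world points (mm).
#' @return A matrix of mapped points, or a [rigid_transform].
#' @export
apply_rigid <- function(transform, pts) {
  pts <- rbind(pts)
  R <- rotation_matrix_zyx(transform$angles_deg)
  ctr <- transform$center
  sweep(sweep(pts, 2, ctr, "-") %*% t(R), 2, ctr + transform$translation, "+")
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  R <- rotation_matrix_zyx(transform$angles_deg)
  Rt <- t(R)
  rigid_transform(angles_deg = angles_from_matrix(Rt),
                  translation = as.numeric(-Rt %*% transform$translation),
                  center = transform$center,
                  fixed_space_id = transform$moving_space_id,
                  moving_space_id = transform$fixed_space_id)
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(a, b) {
  stopifnot(all(a$center == b$center))
  Ra <- rotation_matrix_zyx(a$angles_deg)
  Rb <- rotation_matrix_zyx(b$angles_deg)
  R <- Rb %*% Ra
  t_new <- as.numeric(Rb %*% a$translation) + b$translation
  rigid_transform(angles_deg = angles_from_matrix(R), translation = t_new,
                  center = a$center)
}

#' Serialize a rigid transform to JSON (and back)
#'
#' The JSON records the rotation matrix, angle triple, translation, centre and
#' the angle convention tag so serialized transforms are self-describing.
#'
#' @param transform A [rigid_transform].
#' @param path File path.
#' @export
write_transform_json <- function(transform, path) {
  obj <- list(convention = transform$convention,
              angles_deg = transform$angles_deg,
              rotation_matrix = rotation_matrix_zyx(transform$angles_deg),
              translation_mm = transform$translation,
              center_mm = transform$center,
              fixed_space_id = transform$fixed_space_id,
              moving_space_id = transform$moving_space_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(angles_deg = obj$angles_deg, translation = obj$translation_mm,
                  center = obj$center_mm,
                  fixed_space_id = obj$fixed_space_id,
                  moving_space_id = obj$moving_space_id)
}

#' Registration options
#'
#' @param stride integer subsampling stride (x, y, z) for the fine-level cost
#'   samples.
#' @param coarse_factor block-averaging factor of the coarse pyramid level.
#' @param maxit gradient-descent (BFGS) iteration budget per pyramid level.
#' @param polish_maxit iteration budget of the final Nelder-Mead polish that
#'   rides over the kinks of the piecewise-trilinear cost.
#' @param com_init initialise the translation from the HU-weighted centre-of-mass
#'   offset between the two volumes.
#' @param com_threshold HU threshold defining "tissue" for the centre-of-mass.
#' @param reltol convergence tolerance passed to [stats::optim()].
#' @export
registration_options <- function(stride = c(4, 4, 1),
                                 coarse_factor = c(2, 2, 1), maxit = 50L,
                                 polish_maxit = 200L, com_init = TRUE,
                                 com_threshold = 100, reltol = 1e-10,
                                 smooth = TRUE) {
  list(stride = as.integer(stride), coarse_factor = as.integer(coarse_factor),
       maxit = as.integer(maxit), polish_maxit = as.integer(polish_maxit),
       com_init = isTRUE(com_init), com_threshold = com_threshold,
       reltol = reltol, smooth = isTRUE(smooth))
}

hu_center_of_mass <- function(vol, threshold) {
  w <- pmax(as.numeric(vol$data) - threshold, 0)
  if (sum(w) <= 0) return(volume_center(vol))
  pts <- voxel_world_coords(vol)
  colSums(pts * w) / sum(w)
}

#' Separable 3-point boxcar smoothing (replicate padding)
#'
#' Light low-pass used before metric evaluation: it turns the aliased
#' binary-edge profiles of CT structures into ramps that trilinear
#' interpolation represents accurately, removing the sub-voxel bias they
#' otherwise induce in the MSD optimum.
#' @keywords internal
smooth_boxcar <- function(vol, axes = 1:3) {
  a <- vol$data
  for (ax in axes) {
    d <- dim(a)
    n <- d[ax]
    take <- function(i) {
      ii <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      ii[[ax]] <- pmin(pmax(i, 1L), n)
      do.call(`[`, c(list(a), ii, list(drop = FALSE)))
    }
    a <- (take(0:(n - 1L)) + take(1:n) + take(2:(n + 1L))) / 3
  }
  ct_volume(a, vol$spacing, vol$origin)
}

#' Block-average a volume (pyramid level)
#' @keywords internal
downsample_volume <- function(vol, factor = c(2, 2, 1)) {
  d <- dim(vol$data)
  d2 <- d %/% factor
  arr <- vol$data[seq_len(d2[1] * factor[1]), seq_len(d2[2] * factor[2]),
                  seq_len(d2[3] * factor[3]), drop = FALSE]
  dim(arr) <- c(factor[1], d2[1], factor[2], d2[2], factor[3], d2[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(arr) <- c(prod(factor), prod(d2))
  out <- colMeans(arr)
  dim(out) <- d2
  ct_volume(out, spacing = vol$spacing * factor,
            origin = vol$origin + (factor - 1) * vol$spacing / 2)
}

# derivative matrices of the ZYX rotation wrt each angle, per degree
rotation_matrix_zyx_grad <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ca <- cos(a[1]); sa <- sin(a[1])
  cb <- cos(a[2]); sb <- sin(a[2])
  cc <- cos(a[3]); sc <- sin(a[3])
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  dz <- matrix(c(-sc, cc, 0, -cc, -sc, 0, 0, 0, 0), 3, 3)
  dy <- matrix(c(-sb, 0, -cb, 0, 0, 0, cb, 0, -sb), 3, 3)
  dx <- matrix(c(0, 0, 0, 0, -sa, ca, 0, -ca, -sa), 3, 3)
  k <- pi / 180
  cbind(as.numeric(rz %*% ry %*% dx) * k,
        as.numeric(rz %*% dy %*% rx) * k,
        as.numeric(dz %*% ry %*% rx) * k)
}

# strided sample of a fixed volume: world points and values
fixed_samples <- function(fixed, stride) {
  d <- dim(fixed$data)
  ii <- seq(1L, d[1], by = stride[1])
  jj <- seq(1L, d[2], by = stride[2])
  kk <- seq(1L, d[3], by = stride[3])
  xs <- fixed$origin[1] + (ii - 1) * fixed$spacing[1]
  ys <- fixed$origin[2] + (jj - 1) * fixed$spacing[2]
  zs <- fixed$origin[3] + (kk - 1) * fixed$spacing[3]
  list(pts = cbind(rep(xs, times = length(ys) * length(zs)),
                   rep(rep(ys, each = length(xs)), times = length(zs)),
                   rep(zs, each = length(xs) * length(ys))),
       vals = as.numeric(fixed$data[ii, jj, kk, drop = FALSE]))
}

#' Rigidly register a moving CT volume to a fixed CT volume
#'
#' Mono-modal serial-CT registration: mean squared intensity difference over
#' strided samples of the fixed image, minimised over the 6 rigid parameters
#' with a two-level pyramid (block-averaged then full resolution) of
#' quasi-Newton descent using the analytic cost gradient, followed by a
#' Nelder-Mead polish that is insensitive to the kinks of the
#' piecewise-trilinear cost surface. The translation is initialised from the
#' HU-weighted centre-of-mass offset. The returned transform maps fixed-space
#' world points into moving space (the resampling direction), with rotation
#' about the fixed volume's world centre.
#'
#' @param moving,fixed [ct_volume] HU images with overlapping world extents.
#' @param options A [registration_options()] list.
#' @return A list with elements `transform` ([rigid_transform]), `metric`
#'   (final mean squared difference), `converged` (logical), `n_samples`.
#' @export
register_rigid <- function(moving, fixed, options = registration_options()) {
  stopifnot(inherits(moving, "ct_volume"), inherits(fixed, "ct_volume"))
  if (prod(dim(fixed$data)) < 1000 || prod(dim(moving$data)) < 1000) {
    stop("register_rigid: volumes must have at least 1000 voxels", call. = FALSE)
  }
  ctr <- volume_center(fixed)

  make_level <- function(fx, mv, stride) {
    smp <- fixed_samples(fx, stride)
    mv_dim <- as.integer(dim(mv$data))
    mv_vec <- as.numeric(mv$data)
    list(
      cost = function(par) {
        cpp_rigid_mse(mv_vec, mv_dim, mv$spacing, mv$origin, smp$vals,
                      smp$pts, rotation_matrix_zyx(par[1:3]), ctr,
                      par[4:6])[1]
      },
      grad = function(par) {
        cpp_rigid_mse_grad(mv_vec, mv_dim, mv$spacing, mv$origin, smp$vals,
                           smp$pts, rotation_matrix_zyx(par[1:3]),
                           rotation_matrix_zyx_grad(par[1:3]), ctr,
                           par[4:6])[2:7]
      },
      n = length(smp$vals))
  }

  t0 <- c(0, 0, 0)
  if (options$com_init) {
    t0 <- hu_center_of_mass(moving, options$com_threshold) -
      hu_center_of_mass(fixed, options$com_threshold)
  }
  par <- c(0, 0, 0, t0)

  fx <- fixed
  mv <- moving
  if (options$smooth) {
    fx <- smooth_boxcar(fx)
    mv <- smooth_boxcar(mv)
  }
  coarse <- make_level(downsample_volume(fx, options$coarse_factor),
                       downsample_volume(mv, options$coarse_factor),
                       c(2L, 2L, 1L))
  fine <- make_level(fx, mv, options$stride)

  for (lvl in list(coarse, fine)) {
    f0 <- lvl$cost(par)
    fit <- optim(par, lvl$cost, gr = lvl$grad, method = "BFGS",
                 control = list(maxit = options$maxit,
                                reltol = options$reltol,
                                fnscale = max(f0, 1)))
    par <- fit$par
  }
  par_pre <- par
  fit <- optim(par, fine$cost, method = "Nelder-Mead",
               control = list(maxit = options$polish_maxit,
                              reltol = max(options$reltol, 1e-8),
                              parscale = rep(0.5, 6)))
  par <- fit$par
  # stationary if the polish stayed within the method's accuracy scale of the
  # descent optimum (0.25 deg / 0.25 mm)
  converged <- fit$convergence == 0L || max(abs(par - par_pre)) < 0.25
  if (!converged) {
    warning("register_rigid: optimiser did not converge within the iteration budget",
            call. = FALSE)
  }
  list(transform = rigid_transform(angles_deg = par[1:3], translation = par[4:6],
                                   center = ctr),
       metric = fit$value, converged = converged, n_samples = fine$n)
}

#' Resample an integer label volume by linear label voting
#'
#' Sub-voxel label mapping: each label's indicator image is resampled with
#' trilinear interpolation and every target voxel takes the label with the
#' largest interpolated weight (background weight is the remainder). On
#' anisotropic grids this places mapped label boundaries with sub-voxel
#' accuracy, where plain nearest-neighbour rounding can displace them by up
#' to half a slice.
#'
#' @param source [ct_volume] with integer labels (0 = background).
#' @param transform [rigid_transform] mapping target world coordinates to
#'   source world coordinates (or `NULL`).
#' @param target [ct_volume] defining the output grid.
#' @param min_weight minimum winning weight in (0.5, 1\]; raising it above
#'   0.5 trims voxels near mapped label boundaries, restricting each label to
#'   its partial-volume-free core.
#' @return A [ct_volume] of integer labels on the target grid.
#' @export
resample_label_vote <- function(source, transform = NULL, target = source,
                                min_weight = 0.5) {
  stopifnot(inherits(source, "ct_volume"))
  ids <- sort(setdiff(unique(as.integer(source$data)), 0L))
  d <- dim(target$data)
  # a label must beat the background remainder and the boundary trim
  best_w <- array(max(0.5, min_weight), dim = d)
  best_l <- array(0L, dim = d)
  for (id in ids) {
    ind <- ct_volume((source$data == id) * 1, source$spacing, source$origin)
    w <- resample(ind, transform = transform, target = target,
                  interpolation = "trilinear", fill = 0)
    better <- w$data > best_w
    best_l[better] <- id
    best_w[better] <- w$data[better]
  }
  ct_volume(best_l, spacing = target$spacing, origin = target$origin)
}

#' Resample a volume or label mask through a rigid transform
#'
#' For every voxel centre of the target grid, the world point is mapped with
#' `transform` (a target-space to source-space map) and the source volume is
#' sampled there. Intensity images use trilinear interpolation; label/mask
#' volumes must use nearest neighbour so labels stay categorical. Points that
#' map outside the source grid receive `fill`.
#'
#' @param source A [ct_volume] (HU image, or integer/logical labels).
#' @param transform A [rigid_transform] mapping target world coordinates to
#'   source world coordinates, or `NULL` for identity.
#' @param target A [ct_volume] defining the output grid (defaults to the
#'   source grid).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-grid voxels (default 0).
#' @return A [ct_volume] on the target grid.
#' @export
resample <- function(source, transform = NULL, target = source,
                     interpolation = c("trilinear", "nearest"), fill = 0) {
  stopifnot(inherits(source, "ct_volume"))
  interpolation <- match.arg(interpolation)
  is_label <- is.integer(source$data) || is.logical(source$data)
  if (is_label && interpolation == "trilinear") {
    stop("resample: label masks must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  }
  identity_tf <- is.null(transform) ||
    (all(transform$angles_deg == 0) && all(transform$translation == 0))
  same_grid <- identical(dim(source$data), dim(target$data)) &&
    all(source$spacing == target$spacing) && all(source$origin == target$origin)
  if (identity_tf && same_grid) {
    return(source)
  }
  pts <- voxel_world_coords(target)
  if (!identity_tf) {
    pts <- apply_rigid(transform, pts)
  }
  vox <- world_to_voxel0(source, pts)
  vals <- cpp_sample_volume(as.numeric(source$data), as.integer(dim(source$data)),
                            vox, if (interpolation == "nearest") 0L else 1L)
  vals[is.na(vals)] <- fill
  out <- array(vals, dim = dim(target$data))
  if (is_label) {
    out <- array(as.integer(round(out)), dim = dim(target$data))
    if (is.logical(source$data)) out <- array(out > 0L, dim = dim(target$data))
  }
  ct_volume(out, spacing = target$spacing, origin = target$origin)
}
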