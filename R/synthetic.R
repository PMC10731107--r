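#' Vertebra specification for the synthetic renderer
#'
#' The vertebral body is modelled as an elliptic cylinder: a cortical shell of
#' uniform thickness around a trabecular core, capped by endplate slabs, with
#' optional posterior elements (a rectangular block, excluded from all
#' metrics). Regional trabecular densities are mg/cm^3 hydroxyapatite.
#'
#' @param body_half_axes length-2 in-plane semi-axes (mm) of the body ellipse.
#' @param body_height axial height of the body (mm).
#' @param cortical_thickness shell thickness (mm).
#' @param endplate_thickness endplate slab thickness (mm) at each end.
#' @param regional_trabecular_density named numeric, mg/cm^3 for `superior`,
#'   `transverse`, `inferior`.
#' @param posterior_elements render posterior elements (on/off).
#' @param cortical_density,endplate_density,posterior_density mg/cm^3 used for
#'   the non-trabecular compartments.
#' @param center_offset world-mm offset of the body centre from the volume
#'   centre (x, y, z).
#' @return An object of class `vertebra_spec`.
#' @export
vertebra_spec <- function(body_half_axes = c(22, 16), body_height = 33,
                          cortical_thickness = 2, endplate_thickness = 2,
                          regional_trabecular_density = c(superior = 178.9,
                                                          transverse = 177.5,
                                                          inferior = 196.5),
                          posterior_elements = TRUE,
                          cortical_density = 400, endplate_density = 350,
                          posterior_density = 250,
                          center_offset = c(0, -5.5, -1.5)) {
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("vertebra_spec: field '%s' must be positive", nm), call. = FALSE)
    }
  }
  chk_pos(body_half_axes, "body_half_axes")
  chk_pos(body_height, "body_height")
  chk_pos(cortical_thickness, "cortical_thickness")
  chk_pos(endplate_thickness, "endplate_thickness")
  if (cortical_thickness + endplate_thickness >= body_height / 2) {
    stop("vertebra_spec: field 'cortical_thickness' + 'endplate_thickness' must be < body_height/2",
         call. = FALSE)
  }
  if (cortical_thickness >= min(body_half_axes)) {
    stop("vertebra_spec: field 'cortical_thickness' must be smaller than the half axes",
         call. = FALSE)
  }
  req <- c("superior", "transverse", "inferior")
  if (!all(req %in% names(regional_trabecular_density))) {
    stop("vertebra_spec: field 'regional_trabecular_density' must name superior, transverse, inferior",
         call. = FALSE)
  }
  if (any(regional_trabecular_density < 0) || cortical_density < 0 ||
      endplate_density < 0 || posterior_density < 0) {
    stop("vertebra_spec: field 'regional_trabecular_density' (and compartment densities) must be >= 0",
         call. = FALSE)
  }
  structure(list(body_half_axes = body_half_axes, body_height = body_height,
                 cortical_thickness = cortical_thickness,
                 endplate_thickness = endplate_thickness,
                 regional_trabecular_density = regional_trabecular_density[req],
                 posterior_elements = isTRUE(posterior_elements),
                 cortical_density = cortical_density,
                 endplate_density = endplate_density,
                 posterior_density = posterior_density,
                 center_offset = center_offset),
            class = "vertebra_spec")
}

#' Paraspinal muscle specification
#'
#' Each muscle is an elliptic cylinder spanning the vertebral level; its
#' voxels are a Bernoulli mixture of lean tissue at `lean_hu` (probability
#' `lean_fraction`) and fat at `fat_hu`. Fat must lie below the -50 HU
#' analysis floor so that infiltrated voxels are excluded downstream.
#'
#' @param muscle_name one of `erector_spinae`, `transversospinalis`,
#'   `psoas_major`, `quadratus_lumborum`.
#' @param side `"left"` or `"right"`.
#' @param area in-plane area (mm^2).
#' @param lean_fraction probability a voxel is lean, in \[0, 1\].
#' @param lean_hu,fat_hu attenuation of lean and fat voxels (HU).
#' @param center_offset in-plane offset (mm) of the muscle centre from the
#'   vertebral body centre.
#' @param aspect ratio of the x to y semi-axis of the muscle ellipse.
#' @return An object of class `muscle_spec`.
#' @export
muscle_spec <- function(muscle_name, side, area, lean_fraction = 0.75,
                        lean_hu = 55, fat_hu = -100, center_offset,
                        aspect = 1) {
  allowed <- c("erector_spinae", "transversospinalis", "psoas_major",
               "quadratus_lumborum")
  if (!muscle_name %in% allowed) {
    stop(sprintf("muscle_spec: field 'muscle_name' must be one of %s",
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  if (!side %in% c("left", "right")) {
    stop("muscle_spec: field 'side' must be 'left' or 'right'", call. = FALSE)
  }
  if (!is.finite(area) || area <= 0) {
    stop("muscle_spec: field 'area' must be > 0", call. = FALSE)
  }
  if (lean_fraction < 0 || lean_fraction > 1) {
    stop("muscle_spec: field 'lean_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (!(fat_hu < -50)) {
    stop("muscle_spec: field 'fat_hu' must be < -50 HU (outside the analysis window)",
         call. = FALSE)
  }
  if (lean_hu < -50 || lean_hu > 150) {
    stop("muscle_spec: field 'lean_hu' must lie within [-50, 150] HU", call. = FALSE)
  }
  structure(list(muscle_name = muscle_name, side = side, area = area,
                 lean_fraction = lean_fraction, lean_hu = lean_hu,
                 fat_hu = fat_hu, center_offset = center_offset,
                 aspect = aspect),
            class = "muscle_spec")
}

#' Default set of eight paraspinal muscle specs
#'
#' Four muscles per side in an anatomically inspired arrangement around the
#' vertebral body (erector spinae and transversospinalis posterior, psoas
#' anterolateral, quadratus lumborum lateral); areas are desk-scale rather
#' than anatomical.
#'
#' @param lean_fraction,lean_hu,fat_hu shared mixture parameters.
#' @return List of 8 [muscle_spec] objects.
#' @export
default_muscles <- function(lean_fraction = 0.75, lean_hu = 55, fat_hu = -100) {
  base <- list(
    list("erector_spinae",     c(21, 29),  pi * 10 * 7.5, 10 / 7.5),
    list("transversospinalis", c(8, 24),   pi * 3.5 * 4.5, 3.5 / 4.5),
    list("psoas_major",        c(20, -18), pi * 8 * 6,   8 / 6),
    list("quadratus_lumborum", c(34, 0),   pi * 6 * 5,   6 / 5))
  out <- list()
  for (m in base) {
    for (side in c("left", "right")) {
      off <- m[[2]]
      if (side == "left") off[1] <- -off[1]
      out[[length(out) + 1L]] <-
        muscle_spec(m[[1]], side, area = m[[3]],
                    lean_fraction = lean_fraction, lean_hu = lean_hu,
                    fat_hu = fat_hu, center_offset = off, aspect = m[[4]])
    }
  }
  out
}

#' Calibration phantom specification
#'
#' Hydroxyapatite rods of known density, modelled as cylinders running the
#' full axial extent of the scan, placed below (anterior to) the vertebral
#' body as the in-scan phantom sits under the subject.
#'
#' @param rod_nominal_densities mg/cm^3 per rod (>= 2 distinct values).
#' @param rod_radius rod radius (mm).
#' @param rod_x_offsets in-plane x offsets (mm) of the rods from the body
#'   centre.
#' @param rod_standoff distance (mm) of the rod row below the body centre.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rod_nominal_densities = c(0, 75, 150), rod_radius = 4,
                         rod_x_offsets = c(-24, 0, 24), rod_standoff = 34) {
  if (length(unique(rod_nominal_densities)) < 2L) {
    stop("phantom_spec: field 'rod_nominal_densities' needs >= 2 distinct densities",
         call. = FALSE)
  }
  if (length(rod_x_offsets) != length(rod_nominal_densities)) {
    stop("phantom_spec: field 'rod_x_offsets' must match the number of rods",
         call. = FALSE)
  }
  if (rod_radius <= 0) {
    stop("phantom_spec: field 'rod_radius' must be > 0", call. = FALSE)
  }
  if (any(diff(sort(rod_x_offsets)) <= 2 * rod_radius)) {
    stop("phantom_spec: rods overlap; increase 'rod_x_offsets' separation",
         call. = FALSE)
  }
  structure(list(rod_nominal_densities = rod_nominal_densities,
                 rod_radius = rod_radius, rod_x_offsets = rod_x_offsets,
                 rod_standoff = rod_standoff),
            class = "phantom_spec")
}

# Deterministic uniform field on in-plane anatomy-space cells (Lehmer-
# scrambled lattice hash), constant along z: fat streaks run longitudinally.
# Evaluated at scene coordinates, so the fat pattern of a subject moves
# rigidly with the anatomy across sessions and infiltration progresses at
# fixed loci as the lean fraction drops.
texture_uniform <- function(sx, sy, texture_seed, cell = c(1, 1)) {
  ix <- round(sx / cell[1])
  iy <- round(sy / cell[2])
  m <- 2147483647
  h <- (ix * 73856093 + iy * 19349663 +
          (texture_seed %% m) * 2654435761) %% m
  h <- (h * 48271) %% m
  h <- (h * 48271) %% m
  h / m
}

muscle_label_ids <- function(muscles) {
  setNames(9L + seq_along(muscles),
           vapply(muscles, function(m) paste0(m$muscle_name, "_", m$side), ""))
}

#' Label legend used by the renderer
#' @param muscles list of [muscle_spec].
#' @param phantom a [phantom_spec].
#' @return Named list mapping label names to integer label values.
#' @export
render_legend <- function(muscles = default_muscles(),
                          phantom = phantom_spec()) {
  leg <- list(cortical_shell = 1L, endplate = 2L, trab_inferior = 3L,
              trab_transverse = 4L, trab_superior = 5L,
              posterior_elements = 6L)
  leg <- c(leg, as.list(muscle_label_ids(muscles)))
  rods <- setNames(as.list(20L + seq_along(phantom$rod_nominal_densities)),
                   paste0("rod_", seq_along(phantom$rod_nominal_densities)))
  c(leg, rods)
}

#' Labels that make up the vertebral body / trabecular core
#' @param legend a label legend from [render_legend()].
#' @export
body_label_ids <- function(legend) {
  unlist(legend[c("cortical_shell", "endplate", "trab_inferior",
                  "trab_transverse", "trab_superior")], use.names = FALSE)
}

#' @rdname body_label_ids
#' @export
trabecular_label_ids <- function(legend) {
  unlist(legend[c("trab_inferior", "trab_transverse", "trab_superior")],
         use.names = FALSE)
}

#' Render one synthetic CT session
#'
#' Produces an HU volume plus a consistent integer label volume for one scan
#' session. Geometry is evaluated analytically at (rigidly back-transformed)
#' voxel centres, so a session rendered with a rigid `offset` is the exact
#' rigid motion of the preflight scene. Bone and rod attenuations are the
#' inverse of the true calibration applied to the compartment densities;
#' muscle voxels are a lean/fat mixture driven by a deterministic uniform
#' field on anatomy-space cells (marginally Bernoulli per voxel, spatially
#' fixed per subject so infiltration progresses at the same loci across
#' sessions); Gaussian HU noise is added last. Trabecular region boundaries are fixed in preflight scene
#' coordinates (equal thirds of trabecular slices, remainder to the
#' transverse slab) so that all sessions share matched regions of interest.
#'
#' Randomness (muscle mixture, noise) uses the R session RNG; seed it with
#' [set.seed()] for reproducibility.
#'
#' @param vertebra a [vertebra_spec].
#' @param muscles list of [muscle_spec] (may be empty).
#' @param phantom a [phantom_spec].
#' @param calibration_truth list with `slope` (mg/cm^3 per HU, non-zero) and
#'   `intercept` (mg/cm^3): the scanner's true HU-to-density map.
#' @param noise_sd additive Gaussian noise SD in HU.
#' @param offset a [rigid_transform] mapping preflight world coordinates to
#'   this session's coordinates (`NULL` = identity, preflight itself).
#' @param dims,spacing grid size (voxels) and spacing (mm).
#' @param region_fractions inferior/transverse/superior slice fractions used
#'   for the ground-truth region boundaries.
#' @param texture_seed integer key of the subject's fat-infiltration field;
#'   sessions of one subject must share it.
#' @return List with `volume` ([ct_volume], HU), `labels` ([ct_volume],
#'   integer), `legend`, and `region_z_breaks` (the two scene-space z cuts).
#' @export
render_session <- function(vertebra, muscles = default_muscles(),
                           phantom = phantom_spec(),
                           calibration_truth = list(slope = 0.8, intercept = -2),
                           noise_sd = 10, offset = NULL,
                           dims = c(96, 96, 40), spacing = c(1, 1, 3),
                           region_fractions = c(1, 1, 1) / 3,
                           texture_seed = 0L) {
  stopifnot(inherits(vertebra, "vertebra_spec"), inherits(phantom, "phantom_spec"))
  for (m in muscles) stopifnot(inherits(m, "muscle_spec"))
  if (!is.finite(calibration_truth$slope) || calibration_truth$slope == 0) {
    stop("render_session: calibration_truth slope must be non-zero", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("render_session: noise_sd must be >= 0", call. = FALSE)
  }
  to_hu <- function(density) {
    (density - calibration_truth$intercept) / calibration_truth$slope
  }
  grid <- ct_volume(array(0, dims), spacing = spacing)
  bc <- volume_center(grid) + vertebra$center_offset

  a <- vertebra$body_half_axes[1]
  b <- vertebra$body_half_axes[2]
  h2 <- vertebra$body_height / 2
  ct <- vertebra$cortical_thickness
  ep <- vertebra$endplate_thickness

  # ground-truth region cuts: midpoints between preflight trabecular slices
  zs <- grid$origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  trab_z <- zs[zs >= bc[3] - h2 + ep & zs <= bc[3] + h2 - ep]
  n <- length(trab_z)
  if (n < 3L) {
    stop("render_session: trabecular core spans fewer than 3 slices", call. = FALSE)
  }
  n_inf <- max(1L, floor(region_fractions[1] * n + 1e-9))
  n_sup <- max(1L, floor(region_fractions[3] * n + 1e-9))
  zb <- c(mean(trab_z[n_inf + 0:1]), mean(trab_z[n - n_sup + 0:1]))

  mus_ids <- muscle_label_ids(muscles)
  d_reg <- vertebra$regional_trabecular_density
  z_pad <- 6

  # evaluate compartment membership and attenuation at arbitrary scene
  # points; Stex carries the in-plane coordinates used for the fat-streak
  # texture (sub-slice samples reuse the slice centre's position, since the
  # streaks are z-columns and the tilt-induced in-plane shift over a third of
  # a slice is far below the streak width)
  eval_scene <- function(S, Stex = S, want_labels = FALSE) {
    sx <- S[, 1] - bc[1]
    sy <- S[, 2] - bc[2]
    sz <- S[, 3] - bc[3]
    in_z <- abs(sz) <= h2
    outer <- (sx / a)^2 + (sy / b)^2 <= 1 & in_z
    inner <- (sx / (a - ct))^2 + (sy / (b - ct))^2 <= 1 & in_z
    plate <- in_z & (sz < -h2 + ep | sz > h2 - ep)

    labels <- integer(length(sx))
    density <- rep(NA_real_, length(sx))
    trab <- inner & !plate
    reg_inf <- trab & S[, 3] < zb[1]
    reg_sup <- trab & S[, 3] > zb[2]
    reg_tra <- trab & !reg_inf & !reg_sup
    labels[plate & outer] <- 2L
    density[plate & outer] <- vertebra$endplate_density
    shell <- outer & !plate & !inner
    labels[shell] <- 1L
    density[shell] <- vertebra$cortical_density
    labels[reg_inf] <- 3L
    density[reg_inf] <- d_reg[["inferior"]]
    labels[reg_tra] <- 4L
    density[reg_tra] <- d_reg[["transverse"]]
    labels[reg_sup] <- 5L
    density[reg_sup] <- d_reg[["superior"]]

    if (vertebra$posterior_elements) {
      post <- labels == 0L & abs(sx) <= 3.5 & abs(sy - 23) <= 5 & in_z
      labels[post] <- 6L
      density[post] <- vertebra$posterior_density
    }

    hu <- numeric(length(sx))
    has_d <- !is.na(density)
    hu[has_d] <- to_hu(density[has_d])

    for (i in seq_along(muscles)) {
      m <- muscles[[i]]
      am <- sqrt(m$area * m$aspect / pi)
      bm <- sqrt(m$area / (pi * m$aspect))
      cxy <- bc[1:2] + m$center_offset
      inside <- labels == 0L &
        ((S[, 1] - cxy[1]) / am)^2 + ((S[, 2] - cxy[2]) / bm)^2 <= 1 &
        abs(sz) <= h2 + z_pad
      idx <- which(inside)
      labels[idx] <- mus_ids[[i]]
      u <- texture_uniform(Stex[idx, 1], Stex[idx, 2], texture_seed,
                           cell = spacing[1:2])
      hu[idx] <- ifelse(u <= m$lean_fraction, m$lean_hu, m$fat_hu)
    }

    for (i in seq_along(phantom$rod_nominal_densities)) {
      cxy <- c(bc[1] + phantom$rod_x_offsets[i], bc[2] - phantom$rod_standoff)
      rod <- labels == 0L &
        (S[, 1] - cxy[1])^2 + (S[, 2] - cxy[2])^2 <= phantom$rod_radius^2
      labels[rod] <- 20L + i
      hu[rod] <- to_hu(phantom$rod_nominal_densities[i])
    }
    if (want_labels) list(hu = hu, labels = labels) else list(hu = hu)
  }

  P <- voxel_world_coords(grid)
  if (is.null(offset)) {
    S <- P
    r3 <- c(0, 0, 1)
  } else {
    inv <- invert_rigid(offset)
    S <- apply_rigid(inv, P)
    r3 <- rotation_matrix_zyx(inv$angles_deg)[, 3]
  }
  # through-slice partial volume: boxcar over three sub-slice samples, so a
  # sub-slice axial shift changes boundary voxels the way a real 3-mm slice
  # sensitivity profile would
  dz <- spacing[3] / 3
  centre <- eval_scene(S, want_labels = TRUE)
  hu <- (eval_scene(sweep(S, 2, r3 * dz, "-"), Stex = S)$hu + centre$hu +
           eval_scene(sweep(S, 2, r3 * dz, "+"), Stex = S)$hu) / 3

  if (noise_sd > 0) {
    hu <- hu + rnorm(length(hu), 0, noise_sd)
  }
  list(volume = ct_volume(array(hu, dims), spacing = spacing),
       labels = ct_volume(array(centre$labels, dims), spacing = spacing),
       legend = render_legend(muscles, phantom),
       region_z_breaks = zb)
}
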