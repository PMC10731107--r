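# shared fixtures: everything is generated in code at test time

default_center <- function(dims = c(96, 96, 40), spacing = c(1, 1, 3)) {
  (dims - 1) * spacing / 2
}

# noiseless default session with identity HU->BMD truth, cached per test run
render_identity_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- render_session(vertebra_spec(), noise_sd = 0,
                               calibration_truth = list(slope = 1, intercept = 0),
                               texture_seed = 99)
    }
    cache
  }
})

# brute-force in-plane disc erosion: keep a voxel iff every in-plane voxel
# centre within Euclidean distance <= r_vox lies inside the mask
brute_erode_inplane <- function(mask, r_vox) {
  r <- floor(r_vox)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_vox^2, ]
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    keep <- sl
    for (o in seq_len(nrow(offs))) {
      dx <- offs$dx[o]; dy <- offs$dy[o]
      shifted <- matrix(FALSE, d[1], d[2])
      xi <- seq_len(d[1]) + dx
      yi <- seq_len(d[2]) + dy
      okx <- xi >= 1 & xi <= d[1]
      oky <- yi >= 1 & yi <= d[2]
      shifted[okx, oky] <- sl[xi[okx], yi[oky]]
      keep <- keep & shifted
    }
    out[, , k] <- keep
  }
  out
}

# mask volume from an array with unit test-grid geometry
as_mask_volume <- function(arr, spacing = c(1, 1, 3)) {
  ct_volume(arr, spacing = spacing)
}

# synthetic cylinder mask
cylinder_mask <- function(dims, radius, slices, spacing = c(1, 1, 1)) {
  ctr <- (dims[1:2] + 1) / 2
  arr <- array(FALSE, dims)
  for (k in slices) {
    sl <- outer(seq_len(dims[1]), seq_len(dims[2]), function(i, j) {
      (i - ctr[1])^2 + (j - ctr[2])^2 <= radius^2
    })
    arr[, , k] <- sl
  }
  ct_volume(arr, spacing = spacing)
}
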