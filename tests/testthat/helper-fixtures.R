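# Shared fixtures: small geometries and rendering helpers used across files.

small_geom <- function(n_frames = 10) {
  acquisition_geometry(stack_shape = c(20, 96, 96), n_frames = n_frames)
}

# A noiseless volume with Gaussian spots at given um positions.
spot_volume <- function(pos_um, geom = small_geom(), amp = 100,
                        sigma = c(1, 1.5, 1.5)) {
  vol <- array(0, geom$stack_shape)
  for (i in seq_len(nrow(pos_um))) {
    vox <- c(pos_um[i, 3] / geom$z_step,
             pos_um[i, 2] / geom$pixel_size_xy,
             pos_um[i, 1] / geom$pixel_size_xy)
    vol <- centrodyn:::add_gaussian_spot(vol, vox, sigma, amp)
  }
  vol
}

add_camera_noise <- function(vol, seed = 1, bg_mean = 10, bg_sd = 2) {
  withr::with_seed(seed, {
    array(stats::rpois(length(vol), pmax(vol, 0)) +
            stats::rnorm(length(vol), bg_mean, bg_sd), dim(vol))
  })
}

# per-frame x-y step magnitudes of one role's track
track_steps <- function(truth, role) {
  tr <- truth$tracks[truth$tracks$role == role, ]
  tr <- tr[order(tr$frame), ]
  sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
}
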