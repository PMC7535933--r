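#' Image-series container
#'
#' A two-channel 3D time-lapse held as a 5D numeric array with axis order
#' T-C-Z-Y-X plus its [acquisition_geometry()]. Channel 1 holds the
#' centriole spots, channel 2 the cytoplasmic reporter.
#'
#' @param data 5D array `[frame, channel, z, y, x]`.
#' @param geometry An [acquisition_geometry()].
#' @param channels Channel names.
#' @return An `img_series` object.
#' @export
img_series <- function(data, geometry,
                       channels = c("spots", "reporter")[seq_len(dim(data)[2])]) {
  stopifnot(length(dim(data)) == 5,
            inherits(geometry, "acquisition_geometry"),
            all(dim(data)[3:5] == geometry$stack_shape))
  structure(list(data = data, geometry = geometry, channels = channels),
            class = "img_series")
}

#' @export
print.img_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<img_series> %d frames x %d channels x %s voxels\n",
              d[1], d[2], paste(d[3:5], collapse = "x")))
  invisible(x)
}

#' Extract one 3D frame from an image series
#'
#' @param series An `img_series`.
#' @param frame 0-based frame index.
#' @param channel Channel index or name.
#' @return 3D array `[z, y, x]`.
#' @export
get_frame <- function(series, frame, channel = 1) {
  stopifnot(inherits(series, "img_series"))
  if (is.character(channel)) channel <- match(channel, series$channels)
  d <- dim(series$data)
  stopifnot(frame >= 0, frame < d[1], channel >= 1, channel <= d[2])
  array(series$data[frame + 1, channel, , , ], dim = d[3:5])
}

# Convert physical um coordinates to 0-based voxel indices (voxel centres at
# index * calibration).
um_to_vox <- function(x_um, y_um, z_um, geometry) {
  cbind(z = z_um / geometry$z_step,
        y = y_um / geometry$pixel_size_xy,
        x = x_um / geometry$pixel_size_xy)
}

# Add an anisotropic 3D Gaussian of peak `amp` at voxel position (z, y, x)
# (0-based, fractional) into `vol`, evaluated on a +/- 4 sigma window.
add_gaussian_spot <- function(vol, pos, sigma, amp) {
  d <- dim(vol)
  rng <- function(p, s, n) {
    lo <- max(0L, floor(p - 4 * s))
    hi <- min(n - 1L, ceiling(p + 4 * s))
    if (lo > hi) return(integer(0))
    lo:hi
  }
  iz <- rng(pos[1], sigma[1], d[1])
  iy <- rng(pos[2], sigma[2], d[2])
  ix <- rng(pos[3], sigma[3], d[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(vol)
  gz <- exp(-((iz - pos[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((iy - pos[2])^2) / (2 * sigma[2]^2))
  gx <- exp(-((ix - pos[3])^2) / (2 * sigma[3]^2))
  spot <- amp * outer(outer(gz, gy), gx)   # [z, y, x]
  vol[iz + 1, iy + 1, ix + 1] <- vol[iz + 1, iy + 1, ix + 1] + spot
  vol
}

#' Render a simulated cell as a calibrated two-channel image series
#'
#' Channel 1 receives a 3D Gaussian spot at each centriole position
#' (default sigma 1.5 px in x-y, 1 plane in z); channel 2 a filled disk of
#' the apical radius at the cell centre, spanning the apical planes and
#' scaled by the reporter curve (zero before onset). With `noise = TRUE`,
#' Poisson photon noise (after `photon_gain`) plus Gaussian read noise
#' (`background_mean`, `background_sd` from the truth's parameters) is
#' applied to both channels.
#'
#' @param truth A `cell_truth` from [simulate_cell()].
#' @param geometry An [acquisition_geometry()]; `n_frames` is taken from the
#'   truth.
#' @param noise Apply the Poisson-Gaussian noise model?
#' @param spot_sigma_xy,spot_sigma_z Rendered spot widths (pixels, planes).
#' @param seed Seed for the noise draw.
#' @return An [img_series()].
#' @export
render_image_series <- function(truth, geometry = acquisition_geometry(),
                                noise = TRUE,
                                spot_sigma_xy = 1.5, spot_sigma_z = 1,
                                seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "cell_truth"))
  geometry$n_frames <- truth$n_frames
  d <- geometry$stack_shape
  nT <- truth$n_frames
  p <- truth$params

  trk <- truth$tracks
  vox <- um_to_vox(trk$x_um, trk$y_um, trk$z_um, geometry)
  bad <- vox[, "z"] < 0 | vox[, "z"] > d[1] - 1 |
    vox[, "y"] < 0 | vox[, "y"] > d[2] - 1 |
    vox[, "x"] < 0 | vox[, "x"] > d[3] - 1
  if (any(bad)) {
    stop(sprintf("centriole outside the imaged volume at frame %d",
                 trk$frame[which(bad)[1]]), call. = FALSE)
  }

  data <- array(0, dim = c(nT, 2, d))
  sig <- c(spot_sigma_z, spot_sigma_xy, spot_sigma_xy)

  # reporter disk footprint (constant shape, translated per frame)
  yy <- matrix(0:(d[2] - 1), d[2], d[3])
  xx <- matrix(0:(d[3] - 1), d[2], d[3], byrow = TRUE)
  R_px <- truth$apical_radius / geometry$pixel_size_xy
  z_lo <- max(0, floor((p$z_mc - 1.5) / geometry$z_step))
  z_hi <- min(d[1] - 1, ceiling((p$z_mc + 0.5) / geometry$z_step))

  for (t in seq_len(nT)) {
    f <- t - 1L
    vol1 <- array(0, d)
    rows <- which(trk$frame == f)
    for (r in rows) {
      vol1 <- add_gaussian_spot(vol1, vox[r, ], sig, p$spot_intensity)
    }
    data[t, 1, , , ] <- vol1

    rep_int <- truth$reporter$intensity[t]
    if (rep_int > 0) {
      cy <- truth$center$y_um[t] / geometry$pixel_size_xy
      cx <- truth$center$x_um[t] / geometry$pixel_size_xy
      disk <- (yy - cy)^2 + (xx - cx)^2 <= R_px^2
      vol2 <- array(0, d)
      lvl <- rep_int * p$spot_intensity / p$reporter_max
      for (z in z_lo:z_hi) vol2[z + 1, , ][disk] <- lvl
      data[t, 2, , , ] <- vol2
    }
  }

  if (noise) {
    data <- with_seed(seed, {
      photons <- stats::rpois(length(data), lambda = data * p$photon_gain) /
        p$photon_gain
      array(photons + rnorm(length(data), p$background_mean, p$background_sd),
            dim = dim(data))
    })
  }
  img_series(data, geometry)
}

# Translate a 3D volume by (dz, dy, dx) voxels; trilinear interpolation for
# fractional shifts, zero fill outside. out[i] = in[i - shift].
translate_volume <- function(vol, shift, fill = 0) {
  stopifnot(length(shift) == 3, all(is.finite(shift)))
  int_shift <- function(v, s) {
    d <- dim(v)
    out <- array(fill, d)
    src <- vector("list", 3)
    dst <- vector("list", 3)
    for (k in 1:3) {
      i <- seq_len(d[k])
      j <- i - s[k]
      ok <- j >= 1 & j <= d[k]
      if (!any(ok)) return(out)
      dst[[k]] <- i[ok]
      src[[k]] <- j[ok]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  fl <- floor(shift)
  fr <- shift - fl
  if (all(fr == 0)) return(int_shift(vol, fl))
  out <- array(0, dim(vol))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- prod(ifelse(c(cz, cy, cx) == 1, fr, 1 - fr))
    if (w > 0) out <- out + w * int_shift(vol, fl + c(cz, cy, cx))
  }
  out
}

#' Inject whole-cell drift into an image series or a ground truth
#'
#' For an image series, `drift` is a matrix of per-frame shifts in voxels
#' with columns `(dy, dx)` or `(dz, dy, dx)`; each frame is translated by
#' its (cumulative, as given) shift, integer shifts exactly and fractional
#' shifts by trilinear interpolation. For a `cell_truth`, `drift` is a
#' per-frame `(dx, dy)` matrix in µm added to the centre and both tracks.
#' The applied shifts are returned alongside the shifted object so that
#' registration can be scored against them.
#'
#' @param x An `img_series` or `cell_truth`.
#' @param drift Per-frame shift matrix (one row per frame).
#' @return List with the shifted object (`series` or `truth`) and `shifts`,
#'   the per-frame true shift matrix `(dz, dy, dx)` in voxels (series) or
#'   `(dx, dy)` in µm (truth). A `clipped` attribute flags frames whose
#'   content was pushed fully outside the volume.
#' @export
inject_drift <- function(x, drift) {
  drift <- as.matrix(drift)
  stopifnot(all(is.finite(drift)))
  if (inherits(x, "cell_truth")) {
    stopifnot(nrow(drift) == x$n_frames, ncol(drift) == 2)
    for (role in c("MC", "DC")) {
      i <- x$tracks$role == role
      x$tracks$x_um[i] <- x$tracks$x_um[i] + drift[, 1]
      x$tracks$y_um[i] <- x$tracks$y_um[i] + drift[, 2]
    }
    x$center$x_um <- x$center$x_um + drift[, 1]
    x$center$y_um <- x$center$y_um + drift[, 2]
    return(list(truth = x, shifts = drift))
  }
  stopifnot(inherits(x, "img_series"))
  d <- dim(x$data)
  stopifnot(nrow(drift) == d[1], ncol(drift) %in% c(2, 3))
  if (ncol(drift) == 2) drift <- cbind(0, drift)   # (dz, dy, dx)
  clipped <- logical(d[1])
  for (t in seq_len(d[1])) {
    if (any(abs(drift[t, ]) >= d[3:5])) clipped[t] <- TRUE
    for (ch in seq_len(d[2])) {
      vol <- array(x$data[t, ch, , , ], d[3:5])
      x$data[t, ch, , , ] <- translate_volume(vol, drift[t, ])
    }
  }
  if (any(clipped)) {
    warning("drift pushed content fully out of frame for some frames")
  }
  out <- list(series = x, shifts = drift)
  attr(out, "clipped") <- clipped
  out
}

#' Write / read an image series as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in T-C-Z order as 16-bit TIFF; the sidecar
#' (`<path>.json`) stores the acquisition geometry (z spacing in µm, frame
#' interval in minutes, pixel size), channel names and the intensity scale
#' used for quantisation.
#'
#' @param series An [img_series()].
#' @param path Output TIFF path.
#' @return `path`, invisibly (`write_image_series`); an [img_series()]
#'   (`read_image_series`).
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "img_series"))
  d <- dim(series$data)
  scale <- max(series$data, 1)
  pages <- list()
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[k]] <- pmin(pmax(series$data[t, ch, z, , ] / scale, 0), 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  g <- series$geometry
  meta <- list(
    axes = "TCZYX",
    n_frames = d[1], n_channels = d[2],
    stack_shape = d[3:5],
    channels = series$channels,
    pixel_size_xy_um = g$pixel_size_xy,
    z_step_um = g$z_step,
    frame_interval_min = g$frame_interval,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_frames, meta$n_channels, meta$stack_shape)
  data <- array(0, d)
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    data[t, ch, z, , ] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  geom <- acquisition_geometry(
    pixel_size_xy = meta$pixel_size_xy_um,
    z_step = meta$z_step_um,
    frame_interval = meta$frame_interval_min,
    stack_shape = meta$stack_shape,
    n_frames = meta$n_frames
  )
  img_series(data, geom, channels = meta$channels)
}
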