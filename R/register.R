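#' @name register
#' @title Drift correction by phase-correlation registration
#' @description
#' Whole-tissue drift is corrected in two steps mirroring common
#' sequential-registration practice: x-y translation is estimated by 2D
#' phase correlation of maximum-intensity projections between consecutive
#' frames, the z translation by 1D correlation of axial mean-intensity
#' profiles, and the frame-to-frame estimates are chained cumulatively and
#' referenced to a chosen frame. Subvoxel x-y precision comes from local
#' upsampled evaluation of the cross-correlation (matrix-multiply DFT);
#' subplane z from parabolic interpolation of the correlation peak.
NULL

# fftfreq-style integer frequencies for length n (0, 1, ..., -1)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Local upsampled cross-correlation around `center` (vector, in signal
# coordinates) of the 2D cross spectrum S, evaluated on a (2*halfwidth)
# window at 1/upsample resolution. Returns the refined peak location.
dft_upsample_peak <- function(S, center, upsample, halfwidth = 1.5) {
  d <- dim(S)
  n_pts <- ceiling(2 * halfwidth * upsample) + 1
  offs <- seq(-halfwidth, halfwidth, length.out = n_pts)
  ky <- fft_freqs(d[1]); kx <- fft_freqs(d[2])
  Ey <- exp(2i * pi * outer(center[1] + offs, ky) / d[1])   # n_pts x d1
  Ex <- exp(2i * pi * outer(kx, center[2] + offs) / d[2])   # d2 x n_pts
  cc <- Re(Ey %*% S %*% Ex)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(center[1] + offs[pk[1]], center[2] + offs[pk[2]])
}

# 2D phase correlation: returns list(shift = c(dy, dx), score) such that
# `moving` is `fixed` translated by +shift (content moved by shift).
# Integer peak from the whitened (phase) correlation; subvoxel refinement by
# locally upsampled evaluation of the unwhitened cross-correlation, which is
# unbiased for interpolation-shifted content.
phase_corr_2d <- function(fixed, moving, upsample = 10) {
  if (sd(fixed) == 0 || sd(moving) == 0) {
    return(list(shift = c(0, 0), score = 0))
  }
  Fa <- stats::fft(fixed - mean(fixed))
  Fb <- stats::fft(moving - mean(moving))
  S_raw <- Fb * Conj(Fa)
  S <- S_raw / pmax(Mod(S_raw), 1e-12)
  cc <- Re(stats::fft(S, inverse = TRUE)) / length(S)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- dim(cc)
  shift <- pk - 1
  shift <- ifelse(shift > d / 2, shift - d, shift)
  score <- max(cc)
  if (upsample > 1) {
    shift <- dft_upsample_peak(S_raw, shift, upsample)
  }
  list(shift = shift, score = score)
}

# 1D correlation shift between two profiles with parabolic refinement.
profile_shift_1d <- function(fixed, moving, max_lag = NULL) {
  n <- length(fixed)
  if (sd(fixed) == 0 || sd(moving) == 0) return(0)
  if (is.null(max_lag)) max_lag <- floor(n / 3)
  a <- fixed - mean(fixed)
  b <- moving - mean(moving)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    ia <- seq_len(n)
    ib <- ia - l
    ok <- ib >= 1 & ib <= n
    if (sum(ok) < 3) return(-Inf)
    sum(a[ia[ok]] * b[ib[ok]]) / sum(ok)
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  if (i > 1 && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) lag <- lag + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  -lag
}

#' Estimate per-frame drift of a single-channel image series
#'
#' @param series An [img_series()].
#' @param channel Channel to register on (index or name).
#' @param reference 0-based frame whose shift is defined as zero.
#' @param upsample Upsampling factor for subvoxel x-y refinement (1 = integer
#'   precision).
#' @param min_score Minimum phase-correlation peak for a frame-to-frame
#'   estimate to be trusted; below it (empty, constant or featureless
#'   frames) the step is taken as zero and the low score recorded.
#' @return A tibble (`shift_series`) with columns `frame`, `dz`, `dy`, `dx`
#'   (voxels; the content displacement of each frame relative to the
#'   reference) and `score` (peak phase-correlation of the frame-to-frame
#'   estimate; at or below `min_score` flags a low-confidence zero step).
#' @export
estimate_shifts <- function(series, channel = 1, reference = 0, upsample = 10,
                            min_score = 0.1) {
  stopifnot(inherits(series, "img_series"))
  d <- dim(series$data)
  nT <- d[1]
  stopifnot(nT >= 2, reference >= 0, reference < nT)
  step <- matrix(0, nT, 3)
  score <- rep(1, nT)
  prev <- get_frame(series, 0, channel)
  prev_mip <- apply(prev, c(2, 3), max)
  prev_prof <- apply(prev, 1, mean)
  for (t in 2:nT) {
    cur <- get_frame(series, t - 1, channel)
    mip <- apply(cur, c(2, 3), max)
    prof <- apply(cur, 1, mean)
    pc <- phase_corr_2d(prev_mip, mip, upsample)
    if (pc$score <= min_score) {
      step[t, ] <- c(0, 0, 0)
    } else {
      dz <- profile_shift_1d(prev_prof, prof)
      step[t, ] <- c(dz, pc$shift)
    }
    score[t] <- pc$score
    prev_mip <- mip
    prev_prof <- prof
  }
  cum <- apply(step, 2, cumsum)
  cum <- sweep(cum, 2, cum[reference + 1, ])
  out <- tibble(
    frame = 0:(nT - 1),
    dz = cum[, 1], dy = cum[, 2], dx = cum[, 3],
    score = score
  )
  attr(out, "reference") <- as.integer(reference)
  class(out) <- c("shift_series", class(out))
  out
}

#' Apply (invert) estimated shifts to an image series
#'
#' Each frame is translated by the negated shift, so that registered frames
#' sit in the reference frame's coordinates. Integer shifts are exact;
#' fractional shifts use trilinear interpolation. Voxels translated in from
#' outside the volume are zero-filled and recorded in the `valid_mask`
#' attribute (a `[frame, z, y, x]` logical array).
#'
#' @param series An [img_series()].
#' @param shifts A `shift_series` tibble from [estimate_shifts()] (or any
#'   tibble with `frame`, `dz`, `dy`, `dx`).
#' @return The registered [img_series()] with a `valid_mask` attribute.
#' @export
apply_shifts <- function(series, shifts) {
  stopifnot(inherits(series, "img_series"))
  d <- dim(series$data)
  if (nrow(shifts) != d[1]) {
    stop("shifts must have one row per frame", call. = FALSE)
  }
  mask <- array(TRUE, c(d[1], d[3], d[4], d[5]))
  ones <- array(1, d[3:5])
  for (t in seq_len(d[1])) {
    s <- -c(shifts$dz[t], shifts$dy[t], shifts$dx[t])
    if (all(s == 0)) next
    for (ch in seq_len(d[2])) {
      vol <- array(series$data[t, ch, , , ], d[3:5])
      series$data[t, ch, , , ] <- translate_volume(vol, s)
    }
    mask[t, , , ] <- translate_volume(ones, s) > 0.999
  }
  attr(series, "valid_mask") <- mask
  series
}

#' Express a track relative to the cell centre (drift detrending)
#'
#' Subtracts the per-frame cell centre from a track's x-y coordinates,
#' removing whole-cell drift. Frames without a centre are dropped and
#' flagged. z is kept as-is (the centre is a 2D apical-surface quantity).
#'
#' @param track Tibble with `frame`, `x_um`, `y_um` (and optionally further
#'   columns, carried through).
#' @param centers Tibble with `frame`, `x_um`, `y_um` of the cell centre.
#' @return Tibble with `x_um`, `y_um` replaced by centre-relative values and
#'   a `dropped_frames` attribute listing frames without a centre.
#' @export
detrend_tracks <- function(track, centers) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)),
            all(c("frame", "x_um", "y_um") %in% names(centers)))
  joined <- dplyr::inner_join(
    track, dplyr::select(centers, "frame", cx = "x_um", cy = "y_um"),
    by = "frame"
  )
  if (nrow(joined) == 0) stop("track and centers share no frames", call. = FALSE)
  dropped <- setdiff(track$frame, centers$frame)
  out <- joined |>
    dplyr::mutate(x_um = .data$x_um - .data$cx,
                  y_um = .data$y_um - .data$cy) |>
    dplyr::select(-"cx", -"cy")
  attr(out, "dropped_frames") <- dropped
  out
}
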