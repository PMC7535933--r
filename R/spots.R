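#' Segment cells from the cytoplasmic reporter channel
#'
#' Per frame: 2D maximum-intensity projection of the reporter channel,
#' light Gaussian smoothing, global threshold (Otsu by default or a fixed
#' intensity), connected components, and a minimum-area filter. Cell
#' identity is linked across frames by maximum mask overlap. Frames before
#' reporter onset yield no mask (delayed onset is expected, not an error).
#'
#' @param series An [img_series()].
#' @param channel Reporter channel (index or name).
#' @param threshold `"otsu"` or a fixed intensity value.
#' @param min_area_um2 Minimum component area, µm².
#' @return A `cell_mask_series`: list with `masks` (per-frame integer label
#'   matrices, 0 = background) and `cells`, a tibble with `frame`,
#'   `cell_id`, `cx_um`, `cy_um`, `area_um2`, `radius_um` (equivalent-disk
#'   radius), plus a `first_frame` attribute (first frame with any mask,
#'   `NA` if none).
#' @export
segment_cells <- function(series, channel = "reporter",
                          threshold = "otsu", min_area_um2 = 3) {
  stopifnot(inherits(series, "img_series"))
  g <- series$geometry
  d <- dim(series$data)
  px <- g$pixel_size_xy
  min_px <- max(1, round(min_area_um2 / px^2))
  masks <- vector("list", d[1])
  rows <- list()
  next_id <- 1L
  prev_lab <- NULL
  prev_ids <- integer(0)

  for (t in seq_len(d[1])) {
    vol <- get_frame(series, t - 1, channel)
    mip <- apply(vol, c(2, 3), max)
    if (sd(mip) == 0) {
      masks[[t]] <- matrix(0L, d[4], d[5])
      prev_lab <- masks[[t]]
      next
    }
    sm <- as.matrix(EBImage::gblur(EBImage::Image(mip / max(mip, 1)), sigma = 1))
    thr <- if (identical(threshold, "otsu")) {
      EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
    } else {
      threshold / max(mip, 1)
    }
    bin <- sm > thr
    # contrast guard: a threshold that only splits background noise yields
    # foreground barely above background; require clear separation
    if (identical(threshold, "otsu") && any(bin) && !all(bin)) {
      if (mean(sm[bin]) - mean(sm[!bin]) < 3 * sd(sm[!bin])) {
        masks[[t]] <- matrix(0L, d[4], d[5])
        prev_lab <- masks[[t]]
        next
      }
    }
    lab <- EBImage::bwlabel(EBImage::Image(bin))
    lab <- as.matrix(EBImage::imageData(lab))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_px)
    lab[!(lab %in% keep)] <- 0L

    # relabel with persistent cell ids by maximum overlap with previous frame
    out_lab <- matrix(0L, nrow(lab), ncol(lab))
    ids_here <- integer(0)
    for (comp in keep) {
      sel <- lab == comp
      id <- NA_integer_
      if (!is.null(prev_lab)) {
        ov <- prev_lab[sel]
        ov <- ov[ov > 0]
        if (length(ov)) {
          cand <- as.integer(names(which.max(table(ov))))
          if (!(cand %in% ids_here)) id <- cand
        }
      }
      if (is.na(id)) {
        id <- next_id
        next_id <- next_id + 1L
      }
      out_lab[sel] <- id
      ids_here <- c(ids_here, id)
      idx <- which(sel, arr.ind = TRUE)
      area <- nrow(idx) * px^2
      rows[[length(rows) + 1L]] <- tibble(
        frame = t - 1L, cell_id = id,
        cx_um = mean(idx[, 2] - 1) * px,
        cy_um = mean(idx[, 1] - 1) * px,
        area_um2 = area,
        radius_um = sqrt(area / pi)
      )
    }
    masks[[t]] <- out_lab
    prev_lab <- out_lab
    prev_ids <- ids_here
  }
  cells <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(frame = integer(), cell_id = integer(), cx_um = numeric(),
           cy_um = numeric(), area_um2 = numeric(), radius_um = numeric())
  out <- list(masks = masks, cells = cells, geometry = g)
  attr(out, "first_frame") <- if (nrow(cells)) min(cells$frame) else NA_integer_
  class(out) <- "cell_mask_series"
  out
}

#' @export
print.cell_mask_series <- function(x, ...) {
  cat(sprintf("<cell_mask_series> %d frames, %d cell-frames, first mask at frame %s\n",
              length(x$masks), nrow(x$cells),
              format(attr(x, "first_frame"))))
  invisible(x)
}

#' Zero the centriole channel outside (dilated) cell masks
#'
#' Centriole spots without overlapping reporter signal belong to
#' neighbouring unlabelled cells and are eliminated before detection.
#'
#' @param series An [img_series()].
#' @param masks A `cell_mask_series` from [segment_cells()].
#' @param dilation_um Isotropic x-y dilation of the masks, µm.
#' @param channel Spot channel to mask.
#' @return The [img_series()] with the spot channel zeroed outside masks.
#' @export
mask_centriole_channel <- function(series, masks, dilation_um = 0.5,
                                   channel = "spots") {
  stopifnot(inherits(series, "img_series"),
            inherits(masks, "cell_mask_series"))
  d <- dim(series$data)
  if (length(masks$masks) != d[1]) stop("mask/series frame mismatch", call. = FALSE)
  ch <- if (is.character(channel)) match(channel, series$channels) else channel
  r_px <- round(dilation_um / series$geometry$pixel_size_xy)
  brush <- if (r_px >= 1) EBImage::makeBrush(2 * r_px + 1, shape = "disc") else NULL
  for (t in seq_len(d[1])) {
    m <- masks$masks[[t]] > 0
    if (any(dim(m) != d[4:5])) stop("mask/series shape mismatch", call. = FALSE)
    if (!is.null(brush) && any(m)) {
      m <- as.matrix(EBImage::imageData(
        EBImage::dilate(EBImage::Image(m * 1), brush))) > 0
    }
    keep <- array(rep(m, each = d[3]), d[3:5])
    series$data[t, ch, , , ] <- array(series$data[t, ch, , , ], d[3:5]) * keep
  }
  series
}

# separable Gaussian smoothing of a 3D volume (sigma in voxels, per axis;
# sigma 0 skips an axis)
gauss_smooth_3d <- function(vol, sigma) {
  smooth_axis <- function(v, axis, s) {
    if (s <= 0) return(v)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    d <- dim(v)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    m <- matrix(vp, dp[1], dp[2] * dp[3])
    n <- dp[1]
    padded <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    sm <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) sm <- sm + k[j] * padded[j:(j + n - 1), , drop = FALSE]
    vp <- array(sm, dp)
    aperm(vp, order(perm))
  }
  v <- smooth_axis(vol, 1, sigma[1])
  v <- smooth_axis(v, 2, sigma[2])
  smooth_axis(v, 3, sigma[3])
}

#' Detect centriole spots in one 3D frame
#'
#' Blob detection by a scale-matched difference-of-Gaussians approximation
#' to the Laplacian of Gaussian: local maxima of the band-pass response
#' above `k_mad` robust deviations of background are refined to subvoxel
#' precision by an intensity-weighted centroid over a 3x3 x-y neighbourhood
#' and a 3-plane parabolic fit in z. Detections whose intensity-weighted
#' x-y width clearly exceeds the detection scale are flagged as possible
#' merges of two unresolved spots.
#'
#' @param volume 3D array `[z, y, x]` (one frame, one channel).
#' @param geometry An [acquisition_geometry()] giving the calibration.
#' @param sigma_xy,sigma_z Detection scale in pixels / planes (must be > 0).
#' @param k_mad Detection threshold in MADs of the response above its median.
#' @param merge_factor Flag a merge when the squared x-y width exceeds
#'   `merge_factor * sigma_xy^2`.
#' @return Tibble with `x_um`, `y_um`, `z_um`, `intensity` (raw voxel value
#'   at the peak), `quality` (band-pass response), `merged`.
#' @export
detect_spots <- function(volume, geometry = acquisition_geometry(),
                         sigma_xy = 1.5, sigma_z = 1, k_mad = 5,
                         merge_factor = 1.05) {
  if (sigma_xy <= 0 || sigma_z <= 0) stop("sigma must be positive", call. = FALSE)
  d <- dim(volume)
  g1 <- gauss_smooth_3d(volume, c(sigma_z, sigma_xy, sigma_xy))
  g2 <- gauss_smooth_3d(volume, 1.6 * c(sigma_z, sigma_xy, sigma_xy))
  resp <- g1 - g2
  thr <- stats::median(resp) + k_mad * stats::mad(resp)
  cand <- which(resp > thr)
  if (!length(cand)) {
    return(tibble(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                  intensity = numeric(), quality = numeric(),
                  merged = logical()))
  }
  idx <- arrayInd(cand, d)
  # strict 3x3x3 local maxima (volume borders excluded)
  is_max <- vapply(seq_len(nrow(idx)), function(i) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    if (z < 2 || y < 2 || x < 2 || z > d[1] - 1 || y > d[2] - 1 || x > d[3] - 1)
      return(FALSE)
    nb <- resp[(z - 1):(z + 1), (y - 1):(y + 1), (x - 1):(x + 1)]
    resp[z, y, x] >= max(nb) && sum(nb == max(nb)) == 1
  }, logical(1))
  idx <- idx[is_max, , drop = FALSE]
  if (!nrow(idx)) {
    return(tibble(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                  intensity = numeric(), quality = numeric(),
                  merged = logical()))
  }

  px <- geometry$pixel_size_xy
  bg_level <- stats::median(volume)
  out <- purrr::map_dfr(seq_len(nrow(idx)), function(i) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    # x-y: intensity-weighted centroid over a 3x3 window in the peak plane
    w <- g1[z, (y - 1):(y + 1), (x - 1):(x + 1)]
    w <- w - min(w)
    ys <- (y - 1):(y + 1); xs <- (x - 1):(x + 1)
    cy <- sum(outer(ys, c(1, 1, 1)) * w) / sum(w)
    cx <- sum(outer(c(1, 1, 1), xs) * w) / sum(w)
    # z: parabolic fit through 3 planes of the smoothed response
    p <- g1[(z - 1):(z + 1), y, x]
    denom <- p[1] - 2 * p[2] + p[3]
    dz <- if (denom < 0) 0.5 * (p[1] - p[3]) / denom else 0
    cz <- z + max(min(dz, 0.5), -0.5)
    # width along x / y for merge flagging: raw-intensity second moments
    # over a 7-voxel window (a merged pair is broader than the PSF scale)
    ys7 <- max(1, y - 3):min(d[2], y + 3)
    xs7 <- max(1, x - 3):min(d[3], x + 3)
    wy <- pmax(volume[z, ys7, x] - bg_level, 0)
    wx <- pmax(volume[z, y, xs7] - bg_level, 0)
    my <- sum(ys7 * wy) / sum(wy)
    mx <- sum(xs7 * wx) / sum(wx)
    var_y <- sum(wy * (ys7 - my)^2) / sum(wy)
    var_x <- sum(wx * (xs7 - mx)^2) / sum(wx)
    tibble(
      x_um = (cx - 1) * px, y_um = (cy - 1) * px,
      z_um = (cz - 1) * geometry$z_step,
      intensity = volume[z, y, x],
      quality = resp[z, y, x],
      merged = max(var_x, var_y) > merge_factor * sigma_xy^2
    )
  })
  out
}

#' Detect spots across all frames of a series
#'
#' Convenience wrapper: runs [detect_spots()] per frame on the (optionally
#' masked) spot channel and assigns each detection the cell id of the mask
#' underneath it.
#'
#' @inheritParams detect_spots
#' @param series An [img_series()].
#' @param channel Spot channel.
#' @param masks Optional `cell_mask_series` for cell assignment.
#' @return Tibble of detections with a `frame` column (and `cell_id` when
#'   masks are given; `NA` outside any mask).
#' @export
detect_spots_series <- function(series, channel = "spots", masks = NULL,
                                sigma_xy = 1.5, sigma_z = 1, k_mad = 5) {
  stopifnot(inherits(series, "img_series"))
  d <- dim(series$data)
  px <- series$geometry$pixel_size_xy
  purrr::map_dfr(seq_len(d[1]), function(t) {
    det <- detect_spots(get_frame(series, t - 1, channel), series$geometry,
                        sigma_xy = sigma_xy, sigma_z = sigma_z, k_mad = k_mad)
    det$frame <- t - 1L
    if (!is.null(masks) && nrow(det)) {
      m <- masks$masks[[t]]
      det$cell_id <- vapply(seq_len(nrow(det)), function(i) {
        yy <- round(det$y_um[i] / px) + 1
        xx <- round(det$x_um[i] / px) + 1
        yy <- max(1, min(nrow(m), yy)); xx <- max(1, min(ncol(m), xx))
        v <- m[yy, xx]
        if (v > 0) as.integer(v) else NA_integer_
      }, integer(1))
    }
    det
  })
}

#' Link per-frame detections into centriole tracks
#'
#' Frame-to-frame assignment minimising the summed displacement subject to
#' a distance gate. Each hair cell carries exactly one MC and one DC, so at
#' most two tracks are kept per cell: with two active tracks and two
#' detections both pairings are compared exhaustively (optimal for this
#' cardinality). Tracks missing a detection are carried over for up to
#' `max_gap` frames, with missed positions filled by linear interpolation
#' and flagged. Frames with more than two detections in a cell keep the two
#' highest-quality ones and are flagged ambiguous.
#'
#' @param detections Tibble from [detect_spots_series()] (needs `frame`,
#'   `x_um`, `y_um`, `z_um`; `quality` and `cell_id` optional).
#' @param d_max Gate: maximum linking distance, µm per frame (scaled by the
#'   gap length when closing gaps).
#' @param max_gap Maximum number of consecutive missed frames to bridge.
#' @return Tibble with `track_id`, `cell_id`, `frame`, `x_um`, `y_um`,
#'   `z_um`, `gap_filled`, `ambiguous`.
#' @export
link_tracks <- function(detections, d_max = 2.5, max_gap = 2) {
  stopifnot(d_max > 0, max_gap >= 0)
  if (!nrow(detections)) {
    return(tibble(track_id = character(), cell_id = integer(),
                  frame = integer(), x_um = numeric(), y_um = numeric(),
                  z_um = numeric(), gap_filled = logical(),
                  ambiguous = logical()))
  }
  det <- detections
  if (!"quality" %in% names(det)) det$quality <- 1
  if (!"cell_id" %in% names(det)) det$cell_id <- 1L
  det <- det[!is.na(det$cell_id), ]
  purrr::map_dfr(split(det, det$cell_id), function(dc) {
    link_cell_tracks(dc, d_max, max_gap)
  })
}

link_cell_tracks <- function(det, d_max, max_gap) {
  det <- det[order(det$frame, -det$quality), ]
  frames <- sort(unique(det$frame))
  tracks <- list()   # each: list(points = tibble, last_frame, active)
  amb_frames <- integer(0)
  for (f in frames) {
    rows <- det[det$frame == f, ]
    if (nrow(rows) > 2) {
      rows <- rows[1:2, ]   # two highest quality (sorted above)
      amb_frames <- c(amb_frames, f)
    }
    pts <- as.matrix(rows[, c("x_um", "y_um", "z_um")])
    act <- which(vapply(tracks, function(tr)
      f - tr$last_frame <= max_gap + 1, logical(1)))
    assigned <- rep(NA_integer_, nrow(pts))   # detection -> track index
    if (length(act) && nrow(pts)) {
      heads <- t(vapply(tracks[act], function(tr)
        unlist(tr$points[nrow(tr$points), c("x_um", "y_um", "z_um")]),
        numeric(3)))
      gaps <- vapply(tracks[act], function(tr) f - tr$last_frame, numeric(1))
      cost <- matrix(Inf, length(act), nrow(pts))
      for (i in seq_along(act)) for (j in seq_len(nrow(pts))) {
        dd <- sqrt(sum((heads[i, ] - pts[j, ])^2))
        if (dd <= d_max * gaps[i]) cost[i, j] <- dd
      }
      assigned <- best_assignment(cost)
    }
    for (j in seq_len(nrow(pts))) {
      if (!is.na(assigned[j])) {
        ti <- act[assigned[j]]
        tr <- tracks[[ti]]
        # close any gap by linear interpolation, flagged
        if (f - tr$last_frame > 1) {
          last <- tr$points[nrow(tr$points), ]
          for (fg in (tr$last_frame + 1):(f - 1)) {
            a <- (fg - tr$last_frame) / (f - tr$last_frame)
            tr$points <- dplyr::bind_rows(tr$points, tibble(
              frame = fg,
              x_um = (1 - a) * last$x_um + a * pts[j, 1],
              y_um = (1 - a) * last$y_um + a * pts[j, 2],
              z_um = (1 - a) * last$z_um + a * pts[j, 3],
              gap_filled = TRUE
            ))
          }
        }
        tr$points <- dplyr::bind_rows(tr$points, tibble(
          frame = f, x_um = pts[j, 1], y_um = pts[j, 2], z_um = pts[j, 3],
          gap_filled = FALSE
        ))
        tr$last_frame <- f
        tracks[[ti]] <- tr
      } else if (length(tracks) < 2 ||
                 sum(vapply(tracks, function(tr)
                   f - tr$last_frame <= max_gap + 1, logical(1))) < 2) {
        tracks[[length(tracks) + 1L]] <- list(
          points = tibble(frame = f, x_um = pts[j, 1], y_um = pts[j, 2],
                          z_um = pts[j, 3], gap_filled = FALSE),
          last_frame = f
        )
      }
    }
  }
  if (!length(tracks)) {
    return(tibble(track_id = character(), cell_id = integer(),
                  frame = integer(), x_um = numeric(), y_um = numeric(),
                  z_um = numeric(), gap_filled = logical(),
                  ambiguous = logical()))
  }
  # keep the two longest tracks per cell
  lens <- vapply(tracks, function(tr) nrow(tr$points), integer(1))
  keep <- order(lens, decreasing = TRUE)[seq_len(min(2, length(tracks)))]
  cid <- det$cell_id[1]
  purrr::map_dfr(seq_along(keep), function(k) {
    tr <- tracks[[keep[k]]]
    tr$points |>
      dplyr::mutate(
        track_id = sprintf("%s_T%d", cid, k),
        cell_id = cid,
        ambiguous = .data$frame %in% amb_frames,
        .before = 1
      ) |>
      dplyr::select("track_id", "cell_id", "frame", "x_um", "y_um", "z_um",
                    "gap_filled", "ambiguous")
  })
}

# Minimal-cost one-to-one assignment of columns (detections) to rows
# (tracks) for small matrices; Inf = forbidden. Returns, per column, the
# assigned row index or NA. Exhaustive over row permutations (<= 2 rows in
# practice; falls back to greedy above 4).
best_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nc))
  if (nr <= 4) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      unlist(lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
    }
    best <- NULL; best_cost <- Inf
    k <- min(nr, nc)
    for (rows in perms(seq_len(nr))) {
      # try assigning the first k rows of this order to subsets of columns
      for (cols in perms(seq_len(nc))) {
        tot <- 0; ass <- rep(NA_integer_, nc); used <- 0
        for (i in seq_len(k)) {
          r <- rows[i]; cc <- cols[i]
          if (is.finite(cost[r, cc])) {
            tot <- tot + cost[r, cc]
            ass[cc] <- r
            used <- used + 1
          }
        }
        # prefer more matches, then lower cost
        score <- -used * 1e9 + tot
        if (score < best_cost) { best_cost <- score; best <- ass }
      }
    }
    return(best)
  }
  # greedy fallback
  ass <- rep(NA_integer_, nc)
  used_r <- logical(nr)
  repeat {
    m <- which(cost == min(cost), arr.ind = TRUE)
    if (!is.finite(min(cost))) break
    r <- m[1, 1]; cc <- m[1, 2]
    ass[cc] <- r
    cost[r, ] <- Inf; cost[, cc] <- Inf
  }
  ass
}

#' Assign mother / daughter roles to a pair of tracks
#'
#' The mother centriole nucleates the kinocilium and sits more apically;
#' over the tracks' common frames the track with the greater mean z is
#' labelled MC. When the mean-z difference is below `z_tie` the tie is
#' broken by x-y displacement variance (the MC is the steadier centriole)
#' and the ambiguity flag is set.
#'
#' @param tracks Tibble from [link_tracks()] for a single cell (two tracks).
#' @param z_tie Mean-z tie threshold, µm.
#' @return The input with a `role` column (`"MC"`, `"DC"`, or `"unknown"`)
#'   and a `role_ambiguous` attribute.
#' @export
assign_mc_dc <- function(tracks, z_tie = 0.1) {
  ids <- unique(tracks$track_id)
  tracks$role <- "unknown"
  attr(tracks, "role_ambiguous") <- FALSE
  if (length(ids) != 2) return(tracks)
  a <- tracks[tracks$track_id == ids[1], ]
  b <- tracks[tracks$track_id == ids[2], ]
  common <- intersect(a$frame, b$frame)
  if (length(common) < 5) return(tracks)
  za <- mean(a$z_um[a$frame %in% common])
  zb <- mean(b$z_um[b$frame %in% common])
  amb <- FALSE
  if (abs(za - zb) >= z_tie) {
    mc_id <- if (za > zb) ids[1] else ids[2]
  } else {
    va <- var(diff(a$x_um)) + var(diff(a$y_um))
    vb <- var(diff(b$x_um)) + var(diff(b$y_um))
    mc_id <- if (va <= vb) ids[1] else ids[2]
    amb <- TRUE
  }
  tracks$role <- ifelse(tracks$track_id == mc_id, "MC", "DC")
  attr(tracks, "role_ambiguous") <- amb
  tracks
}

#' Write / read centriole tracks as CSV
#'
#' The schema is `cell_id`, `track_id`, `role`, `frame`, `t_min`, `x_um`,
#' `y_um`, `z_um`. `read_tracks()` also accepts external spot tables (e.g.
#' TrackMate/Imaris exports) through `column_map`, a named character vector
#' mapping schema names to file column names.
#'
#' @param tracks Tibble in the track schema (missing `role`/`t_min` columns
#'   are filled with `"unknown"` / `NA`).
#' @param path CSV path.
#' @param column_map Named character vector, e.g.
#'   `c(track_id = "TRACK_ID", frame = "FRAME", x_um = "POSITION_X", ...)`.
#' @param frame_interval Minutes per frame, used to fill `t_min` when the
#'   file lacks it.
#' @return `path` invisibly; a tibble in the track schema for `read_tracks`.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("cell_id", "track_id", "role", "frame", "t_min",
            "x_um", "y_um", "z_um")
  if (!"role" %in% names(tracks)) tracks$role <- "unknown"
  if (!"t_min" %in% names(tracks)) tracks$t_min <- NA_real_
  if (!"cell_id" %in% names(tracks)) tracks$cell_id <- "cell_001"
  readr::write_csv(tracks[, cols], path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, column_map = NULL, frame_interval = 10) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(raw)) {
        stop(sprintf("mapped column '%s' not found", column_map[[nm]]),
             call. = FALSE)
      }
      raw[[nm]] <- raw[[column_map[[nm]]]]
    }
  }
  need <- c("track_id", "frame", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("track table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cell_id" %in% names(raw)) raw$cell_id <- "cell_001"
  if (!"role" %in% names(raw)) raw$role <- "unknown"
  if (!"t_min" %in% names(raw)) raw$t_min <- raw$frame * frame_interval
  out <- tibble::as_tibble(raw[, c("cell_id", "track_id", "role", "frame",
                                   "t_min", "x_um", "y_um", "z_um")])
  out$frame <- as.integer(out$frame)
  dplyr::arrange(out, .data$cell_id, .data$track_id, .data$frame)
}
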