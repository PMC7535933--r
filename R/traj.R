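#' Build the per-frame cell-centre series with MC-proxy fallback
#'
#' The cell centre is the reporter-mask centroid wherever a valid mask
#' exists. Before the first valid mask frame (delayed reporter onset) the
#' mother centriole's position stands in as a proxy for the centre, with
#' the per-frame centering mode and the proxy-switch frame recorded. The
#' polarity axis defaults to the unit vector from the mean centre to the
#' DC's mean position over the final `axis_window_min` minutes of the
#' recording, and can be overridden from ground truth or tissue metadata.
#'
#' @param masks Either a `cell_mask_series` from [segment_cells()] or a
#'   tibble with `frame`, `cx_um`, `cy_um`, `radius_um` (one cell).
#' @param mc_track Tibble with `frame`, `x_um`, `y_um` for the MC.
#' @param dc_track Optional DC track tibble used for the default polarity
#'   axis.
#' @param cell Cell id to extract when `masks` covers several cells.
#' @param polarity_axis Optional length-2 override (unit vector, lateral).
#' @param apical_radius Optional override of R (µm); default is the mean
#'   equivalent mask radius.
#' @param axis_window_min Length of the late-recording window used for the
#'   default axis, minutes.
#' @param frame_interval Minutes per frame.
#' @return A `cell_frame_series`: tibble with `frame`, `cx_um`, `cy_um`,
#'   `mode` (`"mask_centroid"` or `"mc_proxy"`), plus attributes
#'   `polarity_axis`, `apical_radius`, `proxy_switch_frame`.
#' @export
build_center_series <- function(masks, mc_track, dc_track = NULL,
                                cell = NULL, polarity_axis = NULL,
                                apical_radius = NULL,
                                axis_window_min = 180,
                                frame_interval = 10) {
  if (inherits(masks, "cell_mask_series")) {
    cells <- masks$cells
    if (!is.null(cell)) cells <- cells[cells$cell_id == cell, ]
    if (length(unique(cells$cell_id)) > 1) {
      # keep the cell seen in the most frames
      keep <- names(which.max(table(cells$cell_id)))
      cells <- cells[cells$cell_id == keep, ]
    }
    mask_tab <- tibble(frame = cells$frame, cx_um = cells$cx_um,
                       cy_um = cells$cy_um, radius_um = cells$radius_um)
  } else {
    mask_tab <- tibble::as_tibble(masks)
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(mc_track)))

  frames <- sort(union(mask_tab$frame, mc_track$frame))
  first_mask <- if (nrow(mask_tab)) min(mask_tab$frame) else NA_integer_
  out <- purrr::map_dfr(frames, function(f) {
    mrow <- mask_tab[mask_tab$frame == f, ]
    if (nrow(mrow) && (!is.na(first_mask) && f >= first_mask)) {
      tibble(frame = f, cx_um = mrow$cx_um[1], cy_um = mrow$cy_um[1],
             mode = "mask_centroid")
    } else {
      trow <- mc_track[mc_track$frame == f, ]
      if (!nrow(trow)) return(NULL)   # neither mask nor MC: frame dropped
      tibble(frame = f, cx_um = trow$x_um[1], cy_um = trow$y_um[1],
             mode = "mc_proxy")
    }
  })
  # mask gaps after onset: carry the nearest previous centroid forward
  if (!is.na(first_mask)) {
    post <- out$frame >= first_mask & out$mode == "mc_proxy"
    if (any(post)) {
      for (i in which(post)) {
        prev <- which(out$frame < out$frame[i] & out$mode == "mask_centroid")
        if (length(prev)) {
          j <- prev[length(prev)]
          out$cx_um[i] <- out$cx_um[j]
          out$cy_um[i] <- out$cy_um[j]
          out$mode[i] <- "mask_centroid"
        }
      }
    }
  }

  R <- if (!is.null(apical_radius)) apical_radius else
    if (nrow(mask_tab)) mean(mask_tab$radius_um) else NA_real_
  axis <- polarity_axis
  if (is.null(axis)) {
    if (is.null(dc_track)) stop("need dc_track or an explicit polarity_axis",
                                call. = FALSE)
    wlen <- max(1L, round(axis_window_min / frame_interval))
    late <- utils::tail(sort(intersect(dc_track$frame, out$frame)), wlen)
    dd <- dplyr::inner_join(dc_track[dc_track$frame %in% late, ],
                            out, by = "frame")
    axis <- c(mean(dd$x_um - dd$cx_um), mean(dd$y_um - dd$cy_um))
    if (vnorm(axis) == 0) stop("degenerate polarity axis", call. = FALSE)
  }
  axis <- axis / vnorm(axis)
  attr(out, "polarity_axis") <- axis
  attr(out, "apical_radius") <- R
  attr(out, "proxy_switch_frame") <- first_mask
  class(out) <- c("cell_frame_series", class(out))
  out
}

#' Inter-centriole distance series
#'
#' Per common frame, the planar distance `d_xy` (Euclidean norm of the x-y
#' difference) and the axial distance `d_z = |z_MC - z_DC|`.
#'
#' @param mc,dc Track tibbles with `frame`, `x_um`, `y_um`, `z_um`.
#' @return Tibble with `frame`, `d_xy`, `d_z` (µm).
#' @export
pair_distances <- function(mc, dc) {
  j <- dplyr::inner_join(mc, dc, by = "frame", suffix = c("_mc", "_dc"))
  if (!nrow(j)) stop("tracks share no frames", call. = FALSE)
  tibble(
    frame = j$frame,
    d_xy = sqrt((j$x_um_mc - j$x_um_dc)^2 + (j$y_um_mc - j$y_um_dc)^2),
    d_z = abs(j$z_um_mc - j$z_um_dc)
  )
}

#' Per-frame x-y migration speed on centre-relative coordinates
#'
#' The speed at frame t is the x-y displacement of the centre-relative
#' position between frames t and t+1, in µm per frame (10-min frames by
#' default). Gap-interpolated frames are flagged so summaries can exclude
#' them (interpolation deflates step sizes).
#'
#' @param track Track tibble (`frame`, `x_um`, `y_um`, optional
#'   `gap_filled`).
#' @param centers A `cell_frame_series` (or tibble `frame`, `cx_um`,
#'   `cy_um`); if `NULL` the track is used as-is (already detrended).
#' @return Tibble with `frame` (the step's first frame), `speed` (µm/frame)
#'   and `interpolated` (step touches a gap-filled frame).
#' @export
frame_speeds <- function(track, centers = NULL) {
  if (nrow(track) < 2) stop("need at least two frames", call. = FALSE)
  if (!is.null(centers)) {
    cc <- tibble(frame = centers$frame, cx = centers$cx_um, cy = centers$cy_um)
    track <- dplyr::inner_join(track, cc, by = "frame") |>
      dplyr::mutate(x_um = .data$x_um - .data$cx,
                    y_um = .data$y_um - .data$cy)
  }
  track <- dplyr::arrange(track, .data$frame)
  gf <- if ("gap_filled" %in% names(track)) track$gap_filled else
    rep(FALSE, nrow(track))
  n <- nrow(track)
  tibble(
    frame = track$frame[-n],
    speed = sqrt(diff(track$x_um)^2 + diff(track$y_um)^2),
    interpolated = gf[-n] | gf[-1]
  )
}

#' Time-averaged mean squared displacement and its scaling exponent
#'
#' MSD(tau) is averaged over all start frames for each lag; the anomalous
#' exponent alpha is the slope of a log-log least-squares fit over lags
#' 1..min(10, max_lag). alpha near 1 indicates Brownian motion (MSD = 4 D
#' tau in x-y), near 2 directed motion, below 1 confinement.
#'
#' @param track Tibble with `x_um`, `y_um` at consecutive frames (centre-
#'   relative coordinates).
#' @param max_lag Largest lag, frames.
#' @param frame_interval Minutes per frame.
#' @return An `msd_curve`: tibble with `lag_frames`, `lag_min`, `msd`
#'   (µm²), with attributes `alpha`, `fit_lags`.
#' @export
msd_curve <- function(track, max_lag = 20, frame_interval = 10) {
  n <- nrow(track)
  if (n < 10) stop("need at least 10 frames for an MSD", call. = FALSE)
  max_lag <- min(max_lag, n - 1)
  x <- track$x_um; y <- track$y_um
  msd <- vapply(seq_len(max_lag), function(lag) {
    dx <- x[(1 + lag):n] - x[1:(n - lag)]
    dy <- y[(1 + lag):n] - y[1:(n - lag)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  fit_lags <- seq_len(min(10, max_lag))
  pos <- msd[fit_lags] > 0
  alpha <- if (sum(pos) >= 2) {
    unname(stats::coef(stats::lm(log(msd[fit_lags][pos]) ~
                                   log(fit_lags[pos])))[2])
  } else {
    NA_real_
  }
  out <- tibble(lag_frames = seq_len(max_lag),
                lag_min = seq_len(max_lag) * frame_interval,
                msd = msd)
  attr(out, "alpha") <- alpha
  attr(out, "fit_lags") <- fit_lags
  class(out) <- c("msd_curve", class(out))
  out
}

#' Radial and signed-axis coordinates of a track
#'
#' r is the x-y distance from the cell centre; s is the projection of the
#' centre-relative position onto the polarity axis (positive =
#' periphery-ward / lateral, negative = medial).
#'
#' @param track Track tibble (`frame`, `x_um`, `y_um`).
#' @param centers A `cell_frame_series` (its `polarity_axis` attribute
#'   supplies the axis) or a tibble plus an explicit `axis`.
#' @param axis Optional length-2 axis override.
#' @return Tibble with `frame`, `r`, `s` (µm).
#' @export
radial_series <- function(track, centers, axis = NULL) {
  if (is.null(axis)) axis <- attr(centers, "polarity_axis")
  if (is.null(axis)) stop("polarity axis undefined", call. = FALSE)
  axis <- axis / vnorm(axis)
  cc <- tibble(frame = centers$frame, cx = centers$cx_um, cy = centers$cy_um)
  j <- dplyr::inner_join(track, cc, by = "frame")
  rx <- j$x_um - j$cx
  ry <- j$y_um - j$cy
  tibble(frame = j$frame,
         r = sqrt(rx^2 + ry^2),
         s = rx * axis[1] + ry * axis[2])
}

#' Per-phase summary of distances and speeds
#'
#' Means of d_xy and d_z and per-centriole mean and maximum speed within
#' each phase. With `lat_rule = TRUE` (the lateral-HC convention) the
#' Phase-I averages use only the last 30 frames before Phase-II entry,
#' excluding earlier frames when the cell may still have been a progenitor;
#' medial HCs use all Phase-I frames.
#'
#' @param distances Tibble from [pair_distances()].
#' @param speeds_mc,speeds_dc Tibbles from [frame_speeds()].
#' @param phase2_entry Phase-II entry frame (`NA` = all Phase I).
#' @param lat_rule Apply the last-30-frames Phase-I rule?
#' @param lat_window Number of Phase-I frames kept under the rule.
#' @return Tibble with one row per phase: `phase`, `n_frames`, `mean_d_xy`,
#'   `mean_d_z`, `mean_speed_mc`, `max_speed_mc`, `mean_speed_dc`,
#'   `max_speed_dc`.
#' @export
phase_summary <- function(distances, speeds_mc, speeds_dc,
                          phase2_entry = NA, lat_rule = FALSE,
                          lat_window = 30) {
  entry <- if (is.na(phase2_entry)) Inf else phase2_entry
  in_phase1 <- function(f) {
    if (!lat_rule || !is.finite(entry)) return(f < entry)
    f < entry & f >= entry - lat_window
  }
  summarise_phase <- function(sel_d, sel_smc, sel_sdc, name) {
    d <- distances[sel_d, ]
    smc <- speeds_mc[sel_smc & !speeds_mc$interpolated, ]
    sdc <- speeds_dc[sel_sdc & !speeds_dc$interpolated, ]
    if (!nrow(d) && !nrow(smc) && !nrow(sdc)) {
      return(tibble(phase = name, n_frames = 0L, mean_d_xy = NA_real_,
                    mean_d_z = NA_real_, mean_speed_mc = NA_real_,
                    max_speed_mc = NA_real_, mean_speed_dc = NA_real_,
                    max_speed_dc = NA_real_))
    }
    tibble(
      phase = name, n_frames = nrow(d),
      mean_d_xy = if (nrow(d)) mean(d$d_xy) else NA_real_,
      mean_d_z = if (nrow(d)) mean(d$d_z) else NA_real_,
      mean_speed_mc = if (nrow(smc)) mean(smc$speed) else NA_real_,
      max_speed_mc = if (nrow(smc)) max(smc$speed) else NA_real_,
      mean_speed_dc = if (nrow(sdc)) mean(sdc$speed) else NA_real_,
      max_speed_dc = if (nrow(sdc)) max(sdc$speed) else NA_real_
    )
  }
  dplyr::bind_rows(
    summarise_phase(in_phase1(distances$frame), in_phase1(speeds_mc$frame),
                    in_phase1(speeds_dc$frame), "I"),
    summarise_phase(distances$frame >= entry, speeds_mc$frame >= entry,
                    speeds_dc$frame >= entry, "II")
  )
}
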