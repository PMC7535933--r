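#' Track centrioles in a rendered image series
#'
#' The imaging route end-to-end: segment cells from the reporter channel,
#' mask the spot channel to labelled cells, detect spots per frame, link
#' them into tracks, and assign MC/DC roles by mean apicality.
#'
#' @param series An [img_series()] (registered, if drift is present).
#' @param threshold Cell-segmentation threshold policy (see
#'   [segment_cells()]).
#' @param dilation_um Mask dilation for spot masking, µm.
#' @param sigma_xy,sigma_z,k_mad Spot-detection parameters.
#' @param d_max,max_gap Linking gate (µm/frame) and gap closing (frames).
#' @param use_masks If `FALSE` (single-cell fixtures without a reporter),
#'   skip segmentation and track all detections as one cell.
#' @return List with `tracks` (role-labelled tibble), `masks`
#'   (`cell_mask_series` or `NULL`), `detections`.
#' @export
track_image_series <- function(series, threshold = "otsu", dilation_um = 0.5,
                               sigma_xy = 1.5, sigma_z = 1, k_mad = 5,
                               d_max = 2.5, max_gap = 2, use_masks = TRUE) {
  masks <- NULL
  if (use_masks) {
    masks <- segment_cells(series, threshold = threshold)
    series <- mask_centriole_channel(series, masks, dilation_um = dilation_um)
  }
  det <- detect_spots_series(series, masks = masks,
                             sigma_xy = sigma_xy, sigma_z = sigma_z,
                             k_mad = k_mad)
  if (use_masks && nrow(det)) {
    # keep detections inside cells; fall back to all if masking loses all
    kept <- det[!is.na(det$cell_id), ]
    if (nrow(kept)) det <- kept else det$cell_id <- 1L
  }
  tracks <- link_tracks(det, d_max = d_max, max_gap = max_gap)
  tracks <- purrr::map_dfr(split(tracks, tracks$cell_id), assign_mc_dc)
  list(tracks = tracks, masks = masks, detections = det)
}

#' Analyse a pair of role-labelled tracks against a cell-centre series
#'
#' Computes the full per-frame quantification (centre-relative radial and
#' signed-axis coordinates, inter-centriole distances, drift-corrected
#' speeds), detects Phase-II entry, late Phase II and the trajectory mode,
#' and summarises distances and speeds per phase.
#'
#' @param tracks Tibble with `role` (`"MC"`, `"DC"`), `frame`, `x_um`,
#'   `y_um`, `z_um` (optional `gap_filled`).
#' @param centers A `cell_frame_series` from [build_center_series()] (or a
#'   tibble `frame`, `cx_um`, `cy_um`, `mode` with `polarity_axis` /
#'   `apical_radius` attributes).
#' @param reporter Optional tibble `frame`, `intensity` for onset
#'   detection.
#' @param drug_window Optional half-open frame window of a drug treatment.
#' @param entry Parameters of [detect_phase2_entry()] (list `W`, `q`,
#'   `dr_min`, `rho`).
#' @param mode_pars Parameters of [classify_mode()] (list `delta`, `m`).
#' @param onset_pars Parameters of [detect_reporter_onset()] (list
#'   `background_frames`, `k`, `m`).
#' @param rho_loss Peripheral-loss threshold fraction.
#' @param lat_rule Apply the lateral-HC last-30-frames Phase-I rule in the
#'   phase summary.
#' @param frame_interval Minutes per frame.
#' @return A `cell_analysis` list: `per_frame` tibble (`frame`, `t_min`,
#'   `phase`, `r_mc`, `r_dc`, `s_mc`, `s_dc`, `d_xy`, `d_z`, `v_mc`,
#'   `v_dc`, `centering_mode`), `events` (one-row tibble), `phase_summary`,
#'   `params`.
#' @export
analyze_tracks <- function(tracks, centers, reporter = NULL,
                           drug_window = NULL,
                           entry = list(W = 9, q = 0.6, dr_min = 1.0,
                                        rho = 0.6),
                           mode_pars = list(delta = 1.0, m = 6),
                           onset_pars = list(background_frames = 0:5,
                                             k = 3, m = 3),
                           rho_loss = 0.5,
                           lat_rule = FALSE,
                           frame_interval = 10) {
  mc <- tracks[tracks$role == "MC", ]
  dc <- tracks[tracks$role == "DC", ]
  if (!nrow(mc) || !nrow(dc)) {
    stop("need one MC and one DC track", call. = FALSE)
  }
  R <- attr(centers, "apical_radius")
  axis <- attr(centers, "polarity_axis")

  rad_mc <- radial_series(mc, centers, axis = axis)
  rad_dc <- radial_series(dc, centers, axis = axis)
  dist <- pair_distances(mc, dc)
  v_mc <- frame_speeds(mc, centers)
  v_dc <- frame_speeds(dc, centers)

  entry_idx <- detect_phase2_entry(rad_dc$r, R = R, W = entry$W,
                                   q = entry$q, dr_min = entry$dr_min,
                                   rho = entry$rho)
  entry_frame <- if (is.na(entry_idx)) NA_integer_ else
    rad_dc$frame[entry_idx + 1L]
  common <- dplyr::inner_join(rad_mc, rad_dc, by = "frame",
                              suffix = c("_mc", "_dc"))
  late_frame <- {
    lf <- detect_late_phase2(common$r_mc, common$r_dc, R = R,
                             rho = entry$rho)
    if (!is.na(lf)) common$frame[lf + 1L] else NA_integer_
  }

  onset <- NA_integer_
  if (!is.null(reporter)) {
    onset <- detect_reporter_onset(
      reporter$intensity,
      background_frames = onset_pars$background_frames,
      k = onset_pars$k, m = onset_pars$m
    )
  }
  ev <- perturbation_events(
    s_dc = rad_dc$s, r_dc = rad_dc$r, R = R,
    onset_frame = onset, drug_window = drug_window,
    rho_loss = rho_loss, delta = mode_pars$delta, m = mode_pars$m,
    frame_interval = frame_interval
  )
  ev$phase2_entry <- as.integer(entry_frame)
  ev$late_phase2 <- as.integer(late_frame)

  phs <- phase_summary(dist, v_mc, v_dc, phase2_entry = entry_frame,
                       lat_rule = lat_rule)

  label_phase <- function(f) {
    if (is.na(entry_frame)) return(rep("I", length(f)))
    out <- ifelse(f < entry_frame, "I", "II-early")
    if (!is.na(late_frame)) out[f >= late_frame] <- "II-late"
    out
  }
  per_frame <- common |>
    dplyr::left_join(dist, by = "frame") |>
    dplyr::left_join(dplyr::select(v_mc, "frame", v_mc = "speed"),
                     by = "frame") |>
    dplyr::left_join(dplyr::select(v_dc, "frame", v_dc = "speed"),
                     by = "frame") |>
    dplyr::left_join(tibble(frame = centers$frame,
                            centering_mode = centers$mode),
                     by = "frame") |>
    dplyr::mutate(t_min = .data$frame * frame_interval,
                  phase = label_phase(.data$frame)) |>
    dplyr::select("frame", "t_min", "phase", "r_mc", "r_dc",
                  "s_mc", "s_dc", "d_xy", "d_z", "v_mc", "v_dc",
                  "centering_mode")

  structure(
    list(per_frame = per_frame, events = ev, phase_summary = phs,
         params = list(entry = entry, mode = mode_pars,
                       onset = onset_pars, rho_loss = rho_loss,
                       lat_rule = lat_rule, apical_radius = R,
                       polarity_axis = axis,
                       frame_interval = frame_interval)),
    class = "cell_analysis"
  )
}

#' @export
print.cell_analysis <- function(x, ...) {
  cat(sprintf("<cell_analysis> %d frames; mode %s; entry %s; late %s\n",
              nrow(x$per_frame), x$events$mode,
              format(x$events$phase2_entry), format(x$events$late_phase2)))
  invisible(x)
}

#' Analyse a simulated cell from its ground truth
#'
#' Ground-truth route: builds the centre series from the simulated cell
#' centre, takes the polarity axis and apical radius from the truth, adds
#' camera-level noise to the reporter curve (so onset detection faces the
#' same noise it would in images), and runs [analyze_tracks()].
#'
#' @param truth A `cell_truth`.
#' @param reporter_noise Add Gaussian background noise (from the truth's
#'   noise model) to the reporter curve before onset detection?
#' @param ... Passed to [analyze_tracks()].
#' @return A `cell_analysis`.
#' @export
analyze_cell_truth <- function(truth, reporter_noise = TRUE, ...) {
  stopifnot(inherits(truth, "cell_truth"))
  centers <- tibble(frame = truth$center$frame,
                    cx_um = truth$center$x_um,
                    cy_um = truth$center$y_um,
                    mode = "mask_centroid")
  attr(centers, "polarity_axis") <- truth$polarity_axis
  attr(centers, "apical_radius") <- truth$apical_radius
  rep_tab <- truth$reporter
  if (reporter_noise) {
    p <- truth$params
    rep_tab$intensity <- with_seed(truth$seed + 7L, {
      rep_tab$intensity +
        rnorm(nrow(rep_tab), p$background_mean, p$background_sd)
    })
  }
  drug <- NULL
  for (pb in truth$perturbations) {
    if (pb$kind == "nocodazole") drug <- c(pb$start, pb$end)
  }
  analyze_tracks(
    truth$tracks, centers, reporter = rep_tab, drug_window = drug,
    frame_interval = truth$frame_interval, ...
  )
}

#' Analyse every cell of a simulated cohort
#'
#' @param cohort A `cell_cohort`.
#' @param ... Passed to [analyze_cell_truth()].
#' @return Tibble with one row per cell: detected events plus the
#'   ground-truth labels (`true_mode`, `true_entry`, `true_reversal`,
#'   `true_onset`, `true_loss`) and per-phase means.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cell_cohort"))
  purrr::map_dfr(seq_along(cohort), function(i) {
    truth <- cohort[[i]]
    an <- analyze_cell_truth(truth, ...)
    ph <- an$phase_summary
    p1 <- ph[ph$phase == "I", ]
    p2 <- ph[ph$phase == "II", ]
    dplyr::bind_cols(
      tibble(cell_id = if (!is.null(truth$cell_id)) truth$cell_id
             else sprintf("cell_%03d", i)),
      an$events,
      tibble(
        true_mode = truth$mode_label,
        true_entry = truth$events$phase2_entry,
        true_reversal = truth$events$reversal,
        true_onset = truth$events$reporter_onset,
        true_loss = truth$events$peripheral_loss,
        mean_d_xy_I = p1$mean_d_xy, mean_d_xy_II = p2$mean_d_xy,
        mean_d_z_I = p1$mean_d_z, mean_d_z_II = p2$mean_d_z,
        mean_v_mc_I = p1$mean_speed_mc, mean_v_mc_II = p2$mean_speed_mc,
        mean_v_dc_I = p1$mean_speed_dc, mean_v_dc_II = p2$mean_speed_dc,
        max_v_mc = max(p1$max_speed_mc, p2$max_speed_mc, na.rm = TRUE),
        max_v_dc = max(p1$max_speed_dc, p2$max_speed_dc, na.rm = TRUE)
      )
    )
  })
}

#' Export ground truth to plain-text files
#'
#' Writes `tracks.csv` in the standard track schema and `metadata.json`
#' with parameters, seeds, per-cell events, polarity axes and mode labels.
#' A write-then-read roundtrip through [read_tracks()] reproduces the
#' coordinates at full stored precision.
#'
#' @param truth A `cell_truth` or `cell_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (inherits(truth, "cell_cohort")) truth else {
    structure(list(truth), class = "cell_cohort")
  }
  tracks <- truth_tracks(cohort)
  write_tracks(tracks, file.path(dir, "tracks.csv"))
  meta <- purrr::map(seq_along(cohort), function(i) {
    ct <- cohort[[i]]
    list(
      cell_id = if (!is.null(ct$cell_id)) ct$cell_id else
        sprintf("cell_%03d", i),
      seed = ct$seed,
      mode_label = ct$mode_label,
      polarity_axis = ct$polarity_axis,
      apical_radius = ct$apical_radius,
      frame_interval = ct$frame_interval,
      n_frames = ct$n_frames,
      events = ct$events,
      params = unclass(ct$params)
    )
  })
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
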