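#' Acquisition geometry of a two-channel 3D time-lapse recording
#'
#' Physical calibration of the voxel grid and the frame clock. Defaults match
#' a spinning-disk recording of utricular explants: 0.216 µm x-y pixels,
#' 0.5 µm z step, one two-channel z-stack every 10 minutes.
#'
#' @param pixel_size_xy Pixel size in the focal plane, µm/pixel.
#' @param z_step Axial plane spacing, µm/plane.
#' @param frame_interval Time between frames, minutes.
#' @param stack_shape Integer vector `c(planes, rows, cols)` of one frame's
#'   voxel grid.
#' @param n_frames Number of frames in the recording.
#'
#' @return An object of class `acquisition_geometry` (a named list).
#' @examples
#' geom <- acquisition_geometry(stack_shape = c(16, 64, 64), n_frames = 20)
#' geom$pixel_size_xy
#' @export
acquisition_geometry <- function(pixel_size_xy = 0.216,
                                 z_step = 0.5,
                                 frame_interval = 10,
                                 stack_shape = c(20L, 96L, 96L),
                                 n_frames = 250L) {
  stopifnot(
    is.numeric(pixel_size_xy), pixel_size_xy > 0,
    is.numeric(z_step), z_step > 0,
    is.numeric(frame_interval), frame_interval > 0,
    length(stack_shape) == 3, all(stack_shape >= 1),
    n_frames >= 1
  )
  structure(
    list(
      pixel_size_xy = pixel_size_xy,
      z_step = z_step,
      frame_interval = frame_interval,
      stack_shape = as.integer(stack_shape),
      n_frames = as.integer(n_frames)
    ),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> %d frames of %s voxels; %.3f um px, %.2f um z, %g min/frame\n",
    x$n_frames, paste(x$stack_shape, collapse = "x"),
    x$pixel_size_xy, x$z_step, x$frame_interval
  ))
  invisible(x)
}

#' Simulation parameters for two-centriole dynamics
#'
#' Parameters of the stochastic model used by [simulate_cell()]: both
#' centrioles follow mean-reverting (Ornstein-Uhlenbeck-style) dynamics on
#' the apical surface, integrated with Euler steps at the frame interval.
#' During the confined phase (Phase I) the mother centriole (MC) is tethered
#' to the apical cell centre with small diffusion and the daughter centriole
#' (DC) is tethered to the MC with much larger diffusion. From
#' `phase2_entry_frame` the DC acquires a directed drift toward a peripheral
#' anchor at radius `peripheral_fraction * apical_radius` along the polarity
#' axis; the MC re-anchors to the same bearing `mc_follow_lag` frames later.
#' Per-frame x-y displacements are hard-capped at `mc_step_max` /
#' `dc_step_max`, reproducing the observed speed bounds (MC not exceeding
#' 0.5 µm and DC up to 1.2 µm per 10-min frame).
#'
#' @param apical_radius Apical cell radius R, µm.
#' @param tether_stiffness_mc,tether_stiffness_dc Relaxation rates of the
#'   mean-reverting pull toward each centriole's anchor, 1/min.
#' @param diffusion_mc,diffusion_dc Diffusion coefficients, µm^2/min.
#' @param drift_speed_phase2 Directed DC migration speed in Phase II, µm/min.
#' @param mc_follow_lag Frames after Phase-II entry before the MC follows.
#' @param phase1_confinement Fraction of R confining both centrioles during
#'   Phase I (positions are projected back inside this radius).
#' @param z_mc Mean MC z position (apical; z increases apically), µm.
#' @param z_gap_phase1,z_gap_phase2 Mean axial MC-DC separation per phase, µm
#'   (the gap shrinks as the pair flattens onto the apical surface).
#' @param z_sd Per-frame axial jitter, µm.
#' @param phase2_entry_frame Ground-truth frame at which directed DC
#'   migration begins (half-open phase spans, 0-based frames).
#' @param peripheral_fraction Tether radius of the peripheral anchor as a
#'   fraction of R (rho).
#' @param recenter_pair If `TRUE`, both anchors return to the centre from
#'   `recenter_frame` onward (late paired recentering; off by default).
#' @param recenter_frame Start frame of paired recentering.
#' @param reporter_onset_frame Frame at which the cytoplasmic reporter turns
#'   on (delayed onset; `NA` for a reporter already on at frame 0).
#' @param reporter_ramp_rate Linear reporter ramp, intensity units/frame.
#' @param reporter_max Saturation level of the reporter ramp.
#' @param cell_drift_velocity Length-2 vector, whole-cell x-y drift µm/frame.
#' @param mc_step_max,dc_step_max Hard per-frame x-y step caps, µm.
#' @param spot_intensity Rendered spot peak photon count.
#' @param photon_gain Multiplicative gain applied before Poisson sampling.
#' @param background_mean,background_sd Gaussian read-noise model of the
#'   camera background (intensity units).
#'
#' @return An object of class `sim_params` (a named list).
#' @export
sim_params <- function(apical_radius = 4,
                       tether_stiffness_mc = 0.05,
                       tether_stiffness_dc = 0.035,
                       diffusion_mc = 0.00005,
                       diffusion_dc = 0.0001,
                       drift_speed_phase2 = 0.0135,
                       mc_follow_lag = 12L,
                       phase1_confinement = 0.3,
                       z_mc = 7,
                       z_gap_phase1 = 1.2,
                       z_gap_phase2 = 0.3,
                       z_sd = 0.06,
                       phase2_entry_frame = 60L,
                       peripheral_fraction = 0.8,
                       recenter_pair = FALSE,
                       recenter_frame = NA_integer_,
                       reporter_onset_frame = 54L,
                       reporter_ramp_rate = 4,
                       reporter_max = 400,
                       cell_drift_velocity = c(0, 0),
                       mc_step_max = 0.5,
                       dc_step_max = 1.2,
                       spot_intensity = 100,
                       photon_gain = 1,
                       background_mean = 10,
                       background_sd = 2) {
  p <- as.list(environment())
  num <- vapply(p, function(v) all(is.numeric(v) | is.logical(v)), logical(1))
  stopifnot(all(num))
  fin <- unlist(p[!names(p) %in% c("recenter_frame", "reporter_onset_frame")])
  if (!all(is.finite(as.numeric(fin)))) {
    stop("sim_params: all parameters must be finite", call. = FALSE)
  }
  stopifnot(
    apical_radius > 0,
    diffusion_mc >= 0, diffusion_dc >= 0,
    tether_stiffness_mc >= 0, tether_stiffness_dc >= 0,
    peripheral_fraction > 0, peripheral_fraction <= 1,
    phase1_confinement > 0, phase1_confinement <= 1,
    mc_step_max > 0, dc_step_max > 0,
    length(cell_drift_velocity) == 2
  )
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' A perturbation applied during a simulated recording
#'
#' Two perturbations are modelled. `emx2_switch` flips the sign of the
#' polarity axis at its start frame, sending the DC from the lateral to the
#' medial periphery (the transcription-factor-induced reversal).
#' `nocodazole` models microtubule depolymerisation: during the half-open
#' window both centriole anchors are recalled toward the cell centre at
#' `recall_rate` (fraction of the remaining distance removed per frame) and
#' DC diffusion is multiplied by `wander_factor`; the prior regime is
#' restored when the window closes.
#'
#' @param kind `"emx2_switch"` or `"nocodazole"`.
#' @param start,end Half-open frame window `[start, end)`, 0-based.
#' @param recall_rate Nocodazole recall rate per frame (default recalls to
#'   the centre well within 30 min, i.e. 3 frames).
#' @param wander_factor Multiplier on DC diffusion during nocodazole.
#'
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(kind = c("emx2_switch", "nocodazole"),
                         start, end = Inf,
                         recall_rate = 0.5,
                         wander_factor = 1.5) {
  kind <- match.arg(kind)
  stopifnot(is.finite(start), start >= 0, end > start,
            recall_rate > 0, recall_rate <= 1, wander_factor > 0)
  structure(
    list(kind = kind, start = as.integer(start), end = end,
         recall_rate = recall_rate, wander_factor = wander_factor),
    class = "perturbation"
  )
}
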