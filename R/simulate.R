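#' Simulate one hair cell's two-centriole trajectory
#'
#' Generates ground-truth mother (MC) and daughter (DC) centriole tracks on
#' the apical surface of a single hair cell, in physical µm within the stack
#' coordinate frame (origin at the stack corner, z increasing apically;
#' frames 0-based, phase spans half-open).
#'
#' The dynamics have two phases. In Phase I both centrioles are confined
#' near the apical centre: the MC reverts to the centre with small
#' diffusion, the DC reverts to the MC with much larger diffusion, and both
#' are kept within `phase1_confinement * apical_radius` of the centre. From
#' `phase2_entry_frame` the DC migrates with directed speed
#' `drift_speed_phase2` toward a peripheral anchor at
#' `peripheral_fraction * R` along the polarity axis and tethers there; the
#' MC re-anchors toward the same bearing `mc_follow_lag` frames later. The
#' axial MC-DC gap shrinks from `z_gap_phase1` to `z_gap_phase2` at entry.
#' Per-frame x-y steps are capped at `mc_step_max` / `dc_step_max`.
#'
#' An `emx2_switch` perturbation flips the sign of the migration target
#' along the polarity axis at its start frame; a flip after Phase-II entry
#' produces a lateral-to-medial positional reversal, a flip at or before
#' entry sends the DC directly to the medial side. A `nocodazole`
#' perturbation recalls both anchors to the centre during its window and
#' restores the prior regime afterwards.
#'
#' @param params A [sim_params()] object.
#' @param perturbations List of [perturbation()] objects.
#' @param seed Integer seed; fixed seeds give bit-reproducible output.
#' @param n_frames Number of frames to simulate.
#' @param frame_interval Minutes per frame (the Euler step of the dynamics).
#' @param center0 Length-2 vector, initial cell centre (x, y) µm in stack
#'   coordinates.
#' @param polarity_axis Unit 2-vector pointing periphery-ward (lateral). If
#'   `NULL`, a random direction is drawn from the seed.
#'
#' @return A `cell_truth` object: list with `tracks` (tibble: `role`,
#'   `frame`, `t_min`, `x_um`, `y_um`, `z_um`), `center` (tibble: `frame`,
#'   `x_um`, `y_um`), `reporter` (tibble: `frame`, `intensity`),
#'   `polarity_axis`, `apical_radius`, `mode_label` (`"direct"`,
#'   `"reversal"` or `"none"`), `events` (ground-truth frames: Phase-II
#'   entry, late Phase II, Emx2 switch, positional reversal, reporter onset,
#'   peripheral loss), `params`, `seed`.
#' @examples
#' truth <- simulate_cell(sim_params(), seed = 1, n_frames = 120)
#' truth$events$phase2_entry
#' @export
simulate_cell <- function(params = sim_params(),
                          perturbations = list(),
                          seed = 1L,
                          n_frames = 250L,
                          frame_interval = 10,
                          center0 = c(10.4, 10.4),
                          polarity_axis = NULL) {
  stopifnot(inherits(params, "sim_params"), n_frames >= 2)
  if (inherits(perturbations, "perturbation")) perturbations <- list(perturbations)
  for (pb in perturbations) {
    stopifnot(inherits(pb, "perturbation"))
    if (pb$start >= n_frames) {
      stop("perturbation window starts outside the recording", call. = FALSE)
    }
  }
  dt <- frame_interval
  R <- params$apical_radius
  rhoR <- params$peripheral_fraction * R
  conf <- params$phase1_confinement * R
  entry <- params$phase2_entry_frame
  sd_mc <- sqrt(2 * params$diffusion_mc * dt)
  sd_dc <- sqrt(2 * params$diffusion_dc * dt)

  with_seed(seed, {
    if (is.null(polarity_axis)) {
      th <- runif(1, 0, 2 * pi)
      polarity_axis <- c(cos(th), sin(th))
    }
    polarity_axis <- polarity_axis / vnorm(polarity_axis)

    # per-frame target sign along the polarity axis (+1 lateral), after flips
    sign_t <- rep(1, n_frames)
    for (pb in perturbations) {
      if (pb$kind == "emx2_switch") {
        idx <- (pb$start + 1L):n_frames   # 0-based frame pb$start onward
        sign_t[idx] <- -sign_t[idx]
      }
    }
    noco <- rep(FALSE, n_frames)
    recall <- 0
    wander <- 1
    for (pb in perturbations) {
      if (pb$kind == "nocodazole") {
        idx <- seq.int(pb$start, min(pb$end - 1, n_frames - 1)) + 1L
        noco[idx] <- TRUE
        recall <- pb$recall_rate
        wander <- pb$wander_factor
      }
    }

    mc <- matrix(0, n_frames, 2)  # centre-relative x-y
    dc <- matrix(0, n_frames, 2)
    # initial positions drawn from each tether's stationary spread (zero
    # diffusion puts each centriole exactly at its anchor)
    sd0 <- function(D, k) if (k > 0) sqrt(D / k) else sqrt(2 * D * dt)
    mc[1, ] <- rnorm(2, 0, sd0(params$diffusion_mc, params$tether_stiffness_mc))
    dc[1, ] <- mc[1, ] +
      rnorm(2, 0, sd0(params$diffusion_dc, params$tether_stiffness_dc))

    cap_step <- function(step, cap) {
      n <- vnorm(step)
      if (n > cap) step * (cap / n) else step
    }
    confine <- function(x, r) {
      n <- vnorm(x)
      if (n > r) x * (r / n) else x
    }

    for (t in 2:n_frames) {
      f <- t - 1L                      # 0-based frame being generated
      in_phase2 <- f >= entry
      tgt <- sign_t[t] * rhoR * polarity_axis

      if (noco[t]) {
        mc_step <- -recall * mc[t - 1, ] + rnorm(2, 0, sd_mc)
        dc_step <- -recall * dc[t - 1, ] + rnorm(2, 0, sd_dc * wander)
        mc[t, ] <- mc[t - 1, ] + cap_step(mc_step, params$mc_step_max)
        dc[t, ] <- dc[t - 1, ] + cap_step(dc_step, params$dc_step_max)
        next
      }

      # DC update
      if (!in_phase2) {
        pull <- params$tether_stiffness_dc * dt * (mc[t - 1, ] - dc[t - 1, ])
        dc_step <- pull + rnorm(2, 0, sd_dc)
      } else {
        gap_v <- tgt - dc[t - 1, ]
        d <- vnorm(gap_v)
        # directed migration saturating into the peripheral tether
        speed <- min(params$tether_stiffness_dc * dt * d,
                     params$drift_speed_phase2 * dt)
        drift <- if (d > 0) speed * gap_v / d else c(0, 0)
        dc_step <- drift + rnorm(2, 0, sd_dc)
      }
      dc[t, ] <- dc[t - 1, ] + cap_step(dc_step, params$dc_step_max)

      # MC update: anchors to the centre until mc_follow_lag frames after
      # entry, then follows the DC's bearing to a slightly more central
      # anchor, at a directed speed below the DC's (the MC trails)
      mc_follows <- f >= entry + params$mc_follow_lag
      anchor <- if (mc_follows) 0.85 * tgt else c(0, 0)
      gap_mc <- anchor - mc[t - 1, ]
      d_mc <- vnorm(gap_mc)
      if (mc_follows && d_mc > 0) {
        v_follow <- min(params$tether_stiffness_mc * dt * d_mc,
                        0.8 * params$drift_speed_phase2 * dt)
        pull <- v_follow * gap_mc / d_mc
      } else {
        pull <- params$tether_stiffness_mc * dt * gap_mc
      }
      mc_step <- pull + rnorm(2, 0, sd_mc)
      mc[t, ] <- mc[t - 1, ] + cap_step(mc_step, params$mc_step_max)

      if (!in_phase2) {
        mc[t, ] <- confine(mc[t, ], conf)
        dc[t, ] <- confine(dc[t, ], conf)
      }
    }

    # axial coordinates: MC apical, DC below by a phase-dependent gap
    zmc <- params$z_mc + rnorm(n_frames, 0, params$z_sd)
    gap_target <- ifelse(seq_len(n_frames) - 1L >= entry,
                         params$z_gap_phase2, params$z_gap_phase1)
    gap <- pmax(gap_target + rnorm(n_frames, 0, 2 * params$z_sd), 0.05)
    zdc <- zmc - gap

    # whole-cell drift (applied to centre and both centrioles)
    drift_xy <- matrix(rep(params$cell_drift_velocity, each = n_frames),
                       n_frames, 2)
    drift_cum <- apply(drift_xy, 2, cumsum) - drift_xy  # zero at frame 0
    center <- cbind(center0[1] + drift_cum[, 1], center0[2] + drift_cum[, 2])
    mc_abs <- mc + center
    dc_abs <- dc + center

    # reporter: zero before onset, then a saturating linear ramp
    onset <- params$reporter_onset_frame
    fr <- seq_len(n_frames) - 1L
    if (is.na(onset)) onset <- 0L
    reporter <- pmin(pmax(fr - onset + 1, 0) * params$reporter_ramp_rate,
                     params$reporter_max)

    # ground-truth events from the generated trajectory (fixed conventions:
    # signed-axis threshold 1 um sustained 6 frames; peripheral rho 0.6
    # sustained 3 frames; loss rho 0.5 sustained 3 frames)
    s_dc <- as.numeric(dc %*% polarity_axis)
    r_dc <- sqrt(rowSums(dc^2))
    r_mc <- sqrt(rowSums(mc^2))
    rev_idx <- NA_integer_
    switch_frames <- vapply(
      Filter(function(p) p$kind == "emx2_switch", perturbations),
      function(p) p$start, integer(1)
    )
    mode_label <- "none"
    if (length(switch_frames)) {
      mode_label <- if (any(switch_frames > entry)) "reversal" else "direct"
    }
    if (mode_label == "reversal") {
      sw <- min(switch_frames[switch_frames > entry])
      after <- which(fr >= sw)
      k <- first_sustained(s_dc[after] <= -1, 6L)
      if (!is.na(k)) rev_idx <- after[k]
    }
    late_idx <- first_sustained(r_dc >= 0.6 * R & r_mc >= 0.6 * R, 3L)
    loss_idx <- NA_integer_
    if (any(noco)) {
      dstart <- min(which(noco))
      aft <- which(seq_len(n_frames) >= dstart)
      k <- first_sustained(r_dc[aft] < 0.5 * R, 3L)
      if (!is.na(k)) loss_idx <- aft[k]
    }

    events <- list(
      phase2_entry = entry,
      mc_follow = entry + params$mc_follow_lag,
      late_phase2 = if (is.na(late_idx)) NA_integer_ else late_idx - 1L,
      emx2_switch = if (length(switch_frames)) min(switch_frames) else NA_integer_,
      reversal = if (is.na(rev_idx)) NA_integer_ else rev_idx - 1L,
      reporter_onset = if (is.na(params$reporter_onset_frame)) NA_integer_
                       else as.integer(params$reporter_onset_frame),
      peripheral_loss = if (is.na(loss_idx)) NA_integer_ else loss_idx - 1L,
      noco_start = if (any(noco)) min(which(noco)) - 1L else NA_integer_
    )

    tracks <- dplyr::bind_rows(
      tibble(role = "MC", frame = fr, t_min = fr * dt,
             x_um = mc_abs[, 1], y_um = mc_abs[, 2], z_um = zmc),
      tibble(role = "DC", frame = fr, t_min = fr * dt,
             x_um = dc_abs[, 1], y_um = dc_abs[, 2], z_um = zdc)
    )

    structure(
      list(
        tracks = tracks,
        center = tibble(frame = fr, x_um = center[, 1], y_um = center[, 2]),
        reporter = tibble(frame = fr, intensity = reporter),
        polarity_axis = polarity_axis,
        apical_radius = R,
        mode_label = mode_label,
        events = events,
        params = params,
        perturbations = perturbations,
        frame_interval = dt,
        n_frames = as.integer(n_frames),
        seed = as.integer(seed)
      ),
      class = "cell_truth"
    )
  })
}

#' @export
print.cell_truth <- function(x, ...) {
  cat(sprintf(
    "<cell_truth> %d frames, mode %s, Phase-II entry at frame %d, R = %.1f um\n",
    x$n_frames, x$mode_label, x$events$phase2_entry, x$apical_radius
  ))
  invisible(x)
}

#' Simulate a cohort of hair cells
#'
#' Draws `n` cells with per-cell seeds derived deterministically from the
#' master seed. Trajectory modes (`direct` vs `reversal`) are assigned
#' either exactly (`round(n * fraction)` cells per mode) or by independent
#' draws. Reversal cells receive an `emx2_switch` perturbation at reporter
#' onset plus a latency drawn uniformly from `latency_frames`; direct cells
#' receive the switch at reporter onset (before Phase-II entry), sending the
#' DC straight to the medial side. Phase-II entry and reporter onset are
#' jittered per cell.
#'
#' @param params Base [sim_params()].
#' @param n Number of cells (0 allowed).
#' @param mode_fractions Named numeric, fractions for `direct` and
#'   `reversal`; must sum to 1.
#' @param seed Master seed.
#' @param n_frames Frames per recording.
#' @param exact If `TRUE`, assign exactly `round(n * fraction)` cells per
#'   mode (largest-remainder fix-up so counts sum to `n`).
#' @param latency_frames Length-2 integer range of the Emx2 axis-flip delay
#'   after reporter onset, frames. The observable positional reversal (the
#'   DC's sustained medial excursion) occurs about 5 hr after the flip at
#'   the default migration speed, so the default 30-40 frames (5-6.7 hr)
#'   places the positional reversal 10-12 hr after onset.
#' @param entry_jitter,onset_jitter Half-width of the uniform integer jitter
#'   applied to Phase-II entry and reporter onset, frames.
#' @param perturbations Extra perturbations applied to every cell (e.g. a
#'   nocodazole window).
#' @inheritParams simulate_cell
#'
#' @return List of `cell_truth` objects (class `cell_cohort`).
#' @export
simulate_cohort <- function(params = sim_params(),
                            n = 50L,
                            mode_fractions = c(direct = 0.5, reversal = 0.5),
                            seed = 1L,
                            n_frames = 250L,
                            exact = TRUE,
                            latency_frames = c(30L, 40L),
                            entry_jitter = 8L,
                            onset_jitter = 4L,
                            perturbations = list(),
                            frame_interval = 10) {
  stopifnot(n >= 0)
  if (n == 0) return(structure(list(), class = "cell_cohort"))
  stopifnot(abs(sum(mode_fractions) - 1) < 1e-8,
            all(names(mode_fractions) %in% c("direct", "reversal", "none")))

  with_seed(seed, {
    cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
    modes <- if (exact) {
      counts <- round(n * mode_fractions)
      # largest-remainder adjustment so the counts sum to n
      while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
      while (sum(counts) < n) counts[which.max(n * mode_fractions - counts)] <-
          counts[which.max(n * mode_fractions - counts)] + 1
      sample(rep(names(mode_fractions), counts))
    } else {
      sample(names(mode_fractions), n, replace = TRUE, prob = mode_fractions)
    }
    entry_j <- sample(-entry_jitter:entry_jitter, n, replace = TRUE)
    onset_j <- sample(-onset_jitter:onset_jitter, n, replace = TRUE)
    latency <- sample(latency_frames[1]:latency_frames[2], n, replace = TRUE)
    angles <- runif(n, 0, 2 * pi)

    cohort <- vector("list", n)
    for (i in seq_len(n)) {
      p <- params
      p$phase2_entry_frame <- max(10L, params$phase2_entry_frame + entry_j[i])
      onset <- if (is.na(params$reporter_onset_frame)) NA_integer_ else
        max(1L, params$reporter_onset_frame + onset_j[i])
      p$reporter_onset_frame <- onset
      perts <- perturbations
      if (modes[i] == "reversal") {
        sw <- (if (is.na(onset)) p$phase2_entry_frame else onset) + latency[i]
        sw <- min(sw, n_frames - 2L)
        perts <- c(perts, list(perturbation("emx2_switch", start = sw)))
      } else if (modes[i] == "direct") {
        sw <- min(if (is.na(onset)) 0L else onset, p$phase2_entry_frame - 1L,
                  n_frames - 2L)
        perts <- c(perts, list(perturbation("emx2_switch", start = max(sw, 0L))))
      }
      cohort[[i]] <- simulate_cell(
        p, perturbations = perts, seed = cell_seeds[i], n_frames = n_frames,
        frame_interval = frame_interval,
        polarity_axis = c(cos(angles[i]), sin(angles[i]))
      )
      cohort[[i]]$cell_id <- sprintf("cell_%03d", i)
    }
    structure(cohort, class = "cell_cohort")
  })
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat(sprintf("<cell_cohort> %d cells\n", length(x)))
  if (length(x)) {
    tab <- table(vapply(x, function(c) c$mode_label, character(1)))
    cat("  modes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ground-truth tracks of a cell or cohort as one tidy tibble
#'
#' @param truth A `cell_truth` or `cell_cohort`.
#' @return Tibble with columns `cell_id`, `track_id`, `role`, `frame`,
#'   `t_min`, `x_um`, `y_um`, `z_um` (the track CSV schema).
#' @export
truth_tracks <- function(truth) {
  if (inherits(truth, "cell_cohort")) {
    return(purrr::map_dfr(truth, truth_tracks))
  }
  stopifnot(inherits(truth, "cell_truth"))
  id <- if (!is.null(truth$cell_id)) truth$cell_id else "cell_001"
  truth$tracks |>
    dplyr::mutate(
      cell_id = id,
      track_id = paste0(id, "_", .data$role),
      .before = 1
    ) |>
    dplyr::arrange(.data$role, .data$frame)
}
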