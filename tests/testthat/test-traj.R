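make_centers <- function(frames = 0:9, cx = 0, cy = 0,
                         axis = c(1, 0), R = 4) {
  out <- tibble::tibble(frame = frames, cx_um = cx, cy_um = cy,
                        mode = "mask_centroid")
  attr(out, "polarity_axis") <- axis
  attr(out, "apical_radius") <- R
  out
}

test_that("centre series uses the MC proxy before the first mask frame", {
  mask_tab <- tibble::tibble(frame = 5:9, cx_um = 10, cy_um = 10,
                             radius_um = 4)
  mc <- tibble::tibble(frame = 0:9, x_um = 9.5, y_um = 10.2, z_um = 7)
  cs <- build_center_series(mask_tab, mc, polarity_axis = c(1, 0))
  expect_equal(cs$mode, c(rep("mc_proxy", 5), rep("mask_centroid", 5)))
  expect_equal(attr(cs, "proxy_switch_frame"), 5L)
  expect_equal(cs$cx_um[1:5], rep(9.5, 5))
  expect_equal(cs$cx_um[6:10], rep(10, 5))
  expect_equal(attr(cs, "apical_radius"), 4)

  all_mask <- build_center_series(
    tibble::tibble(frame = 0:9, cx_um = 10, cy_um = 10, radius_um = 4),
    mc, polarity_axis = c(1, 0))
  expect_true(all(all_mask$mode == "mask_centroid"))
})

test_that("the default polarity axis points at the DC's late position", {
  mask_tab <- tibble::tibble(frame = 0:19, cx_um = 10, cy_um = 10,
                             radius_um = 4)
  mc <- tibble::tibble(frame = 0:19, x_um = 10, y_um = 10, z_um = 7)
  dc <- tibble::tibble(frame = 0:19, x_um = 10 + (0:19) * 0.2, y_um = 10,
                       z_um = 6.5)
  cs <- build_center_series(mask_tab, mc, dc_track = dc)
  expect_equal(attr(cs, "polarity_axis"), c(1, 0), tolerance = 1e-9)
})

test_that("pair distances follow the planar/axial decomposition", {
  mc <- tibble::tibble(frame = 0:1, x_um = 0, y_um = 0, z_um = 0)
  dc <- tibble::tibble(frame = 0:1, x_um = c(0, 3), y_um = c(0, 4),
                       z_um = c(0, 1))
  d <- pair_distances(mc, dc)
  expect_equal(d$d_xy, c(0, 5))
  expect_equal(d$d_z, c(0, 1))
  expect_error(pair_distances(mc, dplyr::mutate(dc, frame = frame + 10)),
               "no frames")
})

test_that("frame speeds are centre-relative step magnitudes", {
  track <- tibble::tibble(frame = 0:4, x_um = (0:4) * 0.3,
                          y_um = (0:4) * 0.4, z_um = 7)
  sp <- frame_speeds(track)
  expect_equal(sp$speed, rep(0.5, 4))
  static <- frame_speeds(tibble::tibble(frame = 0:4, x_um = 1, y_um = 2))
  expect_true(all(static$speed == 0))
  expect_error(frame_speeds(track[1, ]), "two frames")
})

test_that("detrended MC speed respects the 0.5 um/frame bound under drift", {
  p <- sim_params(cell_drift_velocity = c(0.3, -0.2))
  truth <- simulate_cell(p, seed = 6, n_frames = 200)
  mc <- truth$tracks[truth$tracks$role == "MC", ]
  centers <- tibble::tibble(frame = truth$center$frame,
                            cx_um = truth$center$x_um,
                            cy_um = truth$center$y_um)
  sp <- frame_speeds(mc, centers)
  expect_lte(max(sp$speed), 0.5)
})

test_that("MSD matches a brute-force double loop and known exponents", {
  track <- withr::with_seed(3, tibble::tibble(
    x_um = cumsum(stats::rnorm(20)), y_um = cumsum(stats::rnorm(20))))
  m <- msd_curve(track, max_lag = 10)
  brute <- vapply(1:10, function(lag) {
    acc <- 0; n <- 0
    for (i in 1:(20 - lag)) {
      acc <- acc + (track$x_um[i + lag] - track$x_um[i])^2 +
        (track$y_um[i + lag] - track$y_um[i])^2
      n <- n + 1
    }
    acc / n
  }, numeric(1))
  expect_equal(m$msd, brute)

  ball <- tibble::tibble(x_um = (0:199) * 0.25, y_um = 0)
  expect_equal(attr(msd_curve(ball), "alpha"), 2, tolerance = 0.05)

  brown <- withr::with_seed(9, tibble::tibble(
    x_um = cumsum(stats::rnorm(1000, 0, 0.2)),
    y_um = cumsum(stats::rnorm(1000, 0, 0.2))))
  a <- attr(msd_curve(brown), "alpha")
  expect_gte(a, 0.85); expect_lte(a, 1.15)

  static <- tibble::tibble(x_um = rep(1, 30), y_um = rep(2, 30))
  expect_true(all(msd_curve(static)$msd == 0))
  expect_error(msd_curve(static[1:5, ]), "at least 10")
})

test_that("radial and signed coordinates behave under the axis geometry", {
  cs <- make_centers()
  track <- tibble::tibble(frame = 0:9, x_um = c(0, 2, -2, rep(1, 7)),
                          y_um = c(0, 0, 0, rep(2, 7)), z_um = 7)
  rs <- radial_series(track, cs)
  expect_equal(rs$r[1], 0)
  expect_equal(rs$s[1], 0)
  expect_equal(rs$s[2], 2)
  expect_equal(rs$s[3], -2)

  # rotating data and axis together leaves (r, s) unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- rot %*% rbind(track$x_um, track$y_um)
  track2 <- tibble::tibble(frame = 0:9, x_um = xy[1, ], y_um = xy[2, ],
                           z_um = 7)
  cs2 <- make_centers(axis = as.vector(rot %*% c(1, 0)))
  rs2 <- radial_series(track2, cs2)
  expect_equal(rs2$r, rs$r)
  expect_equal(rs2$s, rs$s)
  expect_error(radial_series(track, make_centers(axis = NULL)), "axis")
})

test_that("phase summaries honour the lateral last-30-frames rule", {
  frames <- 0:79
  dist <- tibble::tibble(frame = frames, d_xy = frames * 0.01, d_z = 1)
  spd <- tibble::tibble(frame = frames[-80], speed = 0.1,
                        interpolated = FALSE)
  ps <- phase_summary(dist, spd, spd, phase2_entry = 50, lat_rule = TRUE)
  p1 <- ps[ps$phase == "I", ]
  expect_equal(p1$n_frames, 30L)
  expect_equal(p1$mean_d_xy, mean((20:49) * 0.01))   # frames 20..49 only
  ps_all <- phase_summary(dist, spd, spd, phase2_entry = 50)
  expect_equal(ps_all[ps_all$phase == "I", ]$mean_d_xy, mean((0:49) * 0.01))

  # single-phase series leaves Phase-II fields empty
  single <- phase_summary(dist, spd, spd, phase2_entry = NA)
  expect_true(is.na(single[single$phase == "II", ]$mean_d_xy))

  # hand-computed four-frame check
  d4 <- tibble::tibble(frame = 0:3, d_xy = c(1, 2, 3, 4), d_z = c(4, 3, 2, 1))
  s4 <- tibble::tibble(frame = 0:2, speed = c(0.1, 0.2, 0.3),
                       interpolated = c(FALSE, TRUE, FALSE))
  ps4 <- phase_summary(d4, s4, s4, phase2_entry = 2)
  expect_equal(ps4$mean_d_xy, c(1.5, 3.5))
  expect_equal(ps4$mean_d_z, c(3.5, 1.5))
  expect_equal(ps4$mean_speed_mc, c(0.1, 0.3))   # interpolated step excluded
})

test_that("analysis output is invariant to a common translation", {
  truth <- simulate_cell(sim_params(), seed = 12, n_frames = 80)
  an0 <- analyze_cell_truth(truth, reporter_noise = FALSE)
  shifted <- inject_drift(truth, matrix(rep(c(3, -2), each = 80), 80, 2))
  an1 <- analyze_cell_truth(shifted$truth, reporter_noise = FALSE)
  expect_equal(an1$per_frame, an0$per_frame)
  expect_equal(an1$events, an0$events)
})
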