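test_that("zero diffusion and drift freeze both centrioles at their anchors", {
  p <- sim_params(diffusion_mc = 0, diffusion_dc = 0,
                  drift_speed_phase2 = 0, z_sd = 0)
  truth <- simulate_cell(p, seed = 1, n_frames = 20)
  for (role in c("MC", "DC")) {
    tr <- truth$tracks[truth$tracks$role == role, ]
    expect_equal(tr$x_um, rep(tr$x_um[1], 20))
    expect_equal(tr$y_um, rep(tr$y_um[1], 20))
  }
})

test_that("DC steps dominate MC steps and both respect the printed bounds", {
  truth <- simulate_cell(sim_params(), seed = 7, n_frames = 250)
  s_mc <- track_steps(truth, "MC")
  s_dc <- track_steps(truth, "DC")
  # recomputed directly from the emitted tracks
  expect_gt(unname(stats::quantile(s_dc, 0.95)),
            unname(stats::quantile(s_mc, 0.95)))
  expect_lte(max(s_mc), 0.5)
  expect_lte(max(s_dc), 1.2)
})

test_that("the mother centriole is the more apical centriole", {
  truth <- simulate_cell(sim_params(), seed = 3, n_frames = 100)
  z_mc <- mean(truth$tracks$z_um[truth$tracks$role == "MC"])
  z_dc <- mean(truth$tracks$z_um[truth$tracks$role == "DC"])
  expect_gt(z_mc, z_dc)
})

test_that("Phase I confines both centrioles near the apical centre", {
  truth <- simulate_cell(sim_params(), seed = 11, n_frames = 150)
  rel <- detrend_tracks(truth$tracks, truth$center)
  ph1 <- rel$frame < truth$events$phase2_entry
  r <- sqrt(rel$x_um^2 + rel$y_um^2)
  expect_lte(max(r[ph1]), 0.3 * truth$apical_radius + 1e-9)
})

test_that("cohort mode assignment is exact and seeds reproduce bit-for-bit", {
  coh <- simulate_cohort(sim_params(), n = 39,
                         mode_fractions = c(direct = 0.154, reversal = 0.846),
                         seed = 5, n_frames = 200)
  modes <- vapply(coh, function(x) x$mode_label, character(1))
  expect_equal(sum(modes == "reversal"), 33L)
  expect_equal(sum(modes == "direct"), 6L)

  coh2 <- simulate_cohort(sim_params(), n = 39,
                          mode_fractions = c(direct = 0.154, reversal = 0.846),
                          seed = 5, n_frames = 200)
  expect_identical(truth_tracks(coh), truth_tracks(coh2))
  expect_length(simulate_cohort(sim_params(), n = 0, seed = 1), 0)
})

test_that("ground-truth distances move in the reported directions", {
  coh <- simulate_cohort(sim_params(), n = 8, seed = 2, n_frames = 200)
  d1 <- d2 <- z1 <- z2 <- numeric(0)
  for (ct in coh) {
    mc <- ct$tracks[ct$tracks$role == "MC", ]
    dc <- ct$tracks[ct$tracks$role == "DC", ]
    dist <- pair_distances(mc, dc)
    ph2 <- dist$frame >= ct$events$phase2_entry
    d1 <- c(d1, mean(dist$d_xy[!ph2])); d2 <- c(d2, mean(dist$d_xy[ph2]))
    z1 <- c(z1, mean(dist$d_z[!ph2]));  z2 <- c(z2, mean(dist$d_z[ph2]))
  }
  expect_gt(mean(d2), mean(d1))   # planar separation grows in Phase II
  expect_lt(mean(z2), mean(z1))   # axial separation shrinks
})

test_that("a free DC's MSD matches the 4 D tau diffusion law", {
  p <- sim_params(tether_stiffness_dc = 0, diffusion_dc = 0.0001,
                  tether_stiffness_mc = 0, diffusion_mc = 0,
                  phase1_confinement = 1, phase2_entry_frame = 5000L,
                  drift_speed_phase2 = 0)
  truth <- simulate_cell(p, seed = 4, n_frames = 1500)
  dc <- truth$tracks[truth$tracks$role == "DC", ]
  m <- msd_curve(dc, max_lag = 5)
  expected <- 4 * 0.0001 * 10 * (1:5)
  expect_lt(max(abs(m$msd / expected - 1)), 0.15)
})

test_that("nocodazole recalls the DC from the periphery within the window", {
  drug <- perturbation("nocodazole", start = 150, end = 200)
  truth <- simulate_cell(sim_params(), list(drug), seed = 3, n_frames = 220)
  rel <- detrend_tracks(truth$tracks[truth$tracks$role == "DC", ],
                        truth$center)
  r <- sqrt(rel$x_um^2 + rel$y_um^2)
  in_window <- rel$frame >= 153 & rel$frame < 200   # after the 30-min recall
  expect_true(all(r[in_window] < 0.5 * truth$apical_radius))
  expect_equal(truth$events$noco_start, 150L)
  expect_false(is.na(truth$events$peripheral_loss))
})

test_that("perturbation windows outside the recording are rejected", {
  expect_error(
    simulate_cell(sim_params(), list(perturbation("nocodazole", start = 500)),
                  seed = 1, n_frames = 100),
    "outside the recording"
  )
})
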