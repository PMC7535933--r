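# one bright rendered cell used by several blocks
seg_truth <- simulate_cell(
  sim_params(reporter_onset_frame = 4L, reporter_ramp_rate = 400),
  seed = 9, n_frames = 12
)
seg_series <- render_image_series(seg_truth, small_geom(12), noise = TRUE,
                                  seed = 31)

test_that("an all-zero reporter channel yields no cells", {
  dat <- seg_series$data
  dat[, 2, , , ] <- 0
  ser <- img_series(dat, seg_series$geometry)
  cm <- segment_cells(ser)
  expect_equal(nrow(cm$cells), 0L)
  expect_true(is.na(attr(cm, "first_frame")))
})

test_that("a rendered disk is segmented at its true centre and area", {
  cm <- segment_cells(seg_series)
  px <- seg_series$geometry$pixel_size_xy
  cells <- cm$cells
  expect_gte(min(cells$frame), 4L)   # no mask before reporter onset
  late <- cells[cells$frame >= 6, ]
  truth_c <- seg_truth$center[match(late$frame, seg_truth$center$frame), ]
  expect_lt(max(abs(late$cx_um - truth_c$x_um)) / px, 0.5)
  expect_lt(max(abs(late$cy_um - truth_c$y_um)) / px, 0.5)
  expect_lt(max(abs(late$area_um2 / (pi * 4^2) - 1)), 0.10)
})

test_that("spots outside the reporter mask are eliminated, inside kept", {
  cm <- segment_cells(seg_series)
  # plant an extra spot far from the cell in the last frame
  dat <- seg_series$data
  far <- spot_volume(matrix(c(2, 2, 7), 1), seg_series$geometry)
  dat[12, 1, , , ] <- dat[12, 1, , , ] + far
  ser <- img_series(dat, seg_series$geometry)
  masked <- mask_centriole_channel(ser, cm, dilation_um = 0.5)
  det <- detect_spots(get_frame(masked, 11, 1), seg_series$geometry)
  expect_true(all(sqrt((det$x_um - 2)^2 + (det$y_um - 2)^2) > 2))
  # voxels inside the mask are unchanged
  inside <- get_frame(masked, 11, 1)[, 40:55, 40:55]
  expect_equal(inside, get_frame(ser, 11, 1)[, 40:55, 40:55])
  # empty masks zero everything
  empty <- cm
  empty$masks <- lapply(empty$masks, function(m) m * 0L)
  ser0 <- mask_centriole_channel(ser, empty)
  expect_true(all(ser0$data[, 1, , , ] == 0))
})

test_that("a blank volume has no detections and sigma must be positive", {
  expect_equal(nrow(detect_spots(array(0, c(10, 20, 20)), small_geom())), 0L)
  expect_error(detect_spots(array(0, c(10, 20, 20)), small_geom(),
                            sigma_xy = 0), "positive")
})

test_that("two spots 2 um apart at SNR 10 are both localized sub-voxel", {
  geom <- small_geom()
  pos <- rbind(c(8, 10, 7), c(10, 10, 7))
  vol <- add_camera_noise(spot_volume(pos, geom), seed = 5)
  det <- detect_spots(vol, geom)
  expect_equal(nrow(det), 2L)
  det <- det[order(det$x_um), ]
  err <- sqrt((det$x_um - pos[, 1])^2 + (det$y_um - pos[, 2])^2) /
    geom$pixel_size_xy
  expect_lt(max(err), 0.5)
})

test_that("two spots 0.4 um apart merge into one flagged detection", {
  geom <- small_geom()
  pos <- rbind(c(10, 10, 7), c(10.4, 10, 7))
  det <- detect_spots(spot_volume(pos, geom) + 0.01, geom)
  expect_equal(nrow(det), 1L)
  expect_true(det$merged)
})

test_that("a static spot links into a single full-length track", {
  det <- tibble::tibble(frame = 0:9, x_um = 5, y_um = 5, z_um = 7,
                        quality = 1)
  tk <- link_tracks(det)
  expect_equal(length(unique(tk$track_id)), 1L)
  expect_equal(nrow(tk), 10L)
  expect_false(any(tk$gap_filled))
})

test_that("crossing tracks follow the minimum-total-displacement pairing", {
  # brute-force oracle over both pairings at every frame
  xa <- c(0, 0.5, 1, 1.5, 1.3)
  xb <- c(3, 2.5, 2, 1.7, 2.2)
  det <- tibble::tibble(frame = rep(0:4, each = 2),
                        x_um = as.vector(rbind(xa, xb)),
                        y_um = 0, z_um = 0, quality = 1)
  tk <- link_tracks(det, d_max = 2.5)
  got <- lapply(split(tk, tk$track_id), function(t) t$x_um[order(t$frame)])
  # oracle: continue each track with whichever pairing adds less distance
  oa <- xa[1]; ob <- xb[1]
  for (f in 2:5) {
    straight <- abs(xa[f] - oa[length(oa)]) + abs(xb[f] - ob[length(ob)])
    swapped <- abs(xb[f] - oa[length(oa)]) + abs(xa[f] - ob[length(ob)])
    if (straight <= swapped) {
      oa <- c(oa, xa[f]); ob <- c(ob, xb[f])
    } else {
      oa <- c(oa, xb[f]); ob <- c(ob, xa[f])
    }
  }
  expect_setequal(lapply(got, unname), list(oa, ob))
})

test_that("a missed detection is bridged by flagged interpolation", {
  det <- tibble::tibble(frame = c(0:4, 6:9), x_um = c(0:4, 6:9) * 0.1,
                        y_um = 0, z_um = 7, quality = 1)
  tk <- link_tracks(det, max_gap = 2)
  expect_equal(length(unique(tk$track_id)), 1L)
  expect_equal(nrow(tk), 10L)
  filled <- tk[tk$gap_filled, ]
  expect_equal(filled$frame, 5L)
  expect_equal(unname(filled$x_um), 0.5, tolerance = 1e-9)
})

test_that("linking is invariant to detection input order", {
  det <- tibble::tibble(frame = rep(0:5, each = 2),
                        x_um = rep(c(1, 3), 6) + rep(0:5, each = 2) * 0.1,
                        y_um = 0, z_um = 7, quality = 1)
  tk1 <- link_tracks(det)
  tk2 <- link_tracks(withr::with_seed(4, det[sample.int(nrow(det)), ]))
  # track ids may swap; compare the set of trajectories
  trajs <- function(t) {
    unname(lapply(split(t, t$track_id),
                  function(x) unname(x$x_um[order(x$frame)])))
  }
  expect_setequal(trajs(tk1), trajs(tk2))
})

test_that("role assignment follows mean apicality with a variance tie-break", {
  mk <- function(id, z, wob = 0) {
    tibble::tibble(track_id = id, cell_id = 1L, frame = 0:9,
                   x_um = 5 + wob * (0:9 %% 2), y_um = 5, z_um = z,
                   gap_filled = FALSE, ambiguous = FALSE)
  }
  tk <- dplyr::bind_rows(mk("a", 7.4), mk("b", 7.0))
  out <- assign_mc_dc(tk)
  expect_equal(unique(out$role[out$track_id == "a"]), "MC")
  expect_false(attr(out, "role_ambiguous"))

  tie <- dplyr::bind_rows(mk("a", 7.0, wob = 0.5), mk("b", 7.0))
  out2 <- assign_mc_dc(tie)
  expect_equal(unique(out2$role[out2$track_id == "b"]), "MC")
  expect_true(attr(out2, "role_ambiguous"))

  one <- mk("a", 7.2)
  expect_equal(unique(assign_mc_dc(one)$role), "unknown")
})

test_that("roles recovered from blinded ground-truth tracks are accurate", {
  coh <- simulate_cohort(sim_params(), n = 20, seed = 17, n_frames = 120)
  correct <- 0
  for (ct in coh) {
    blind <- truth_tracks(ct)
    blind$track_id <- ifelse(blind$role == "MC", "t1", "t2")
    truth_roles <- blind$role
    blind$role <- NULL
    blind$gap_filled <- FALSE
    out <- assign_mc_dc(blind)
    if (all(out$role == truth_roles)) correct <- correct + 1
  }
  expect_gte(correct / 20, 0.95)
})

test_that("the rendered route recovers tracks with sub-voxel localization", {
  truth <- simulate_cell(
    sim_params(reporter_onset_frame = 0L, reporter_ramp_rate = 400,
               phase2_entry_frame = 15L),
    seed = 3, n_frames = 40
  )
  ser <- render_image_series(truth, small_geom(40), noise = TRUE, seed = 99)
  tk <- track_image_series(ser)
  expect_lte(length(unique(tk$tracks$track_id)), 2L)
  j <- dplyr::inner_join(tk$tracks[!tk$tracks$gap_filled, ], truth$tracks,
                         by = c("frame", "role"), suffix = c("_est", "_tru"))
  err <- sqrt((j$x_um_est - j$x_um_tru)^2 + (j$y_um_est - j$y_um_tru)^2) /
    small_geom()$pixel_size_xy
  expect_lt(stats::median(err), 0.5)
})

test_that("external spot tables import through a column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    TRACK_ID = rep(c("T1", "T2"), each = 3), FRAME = rep(0:2, 2),
    POSITION_X = runif(6, 0, 10), POSITION_Y = runif(6, 0, 10),
    POSITION_Z = runif(6, 0, 8)
  ), path)
  tk <- read_tracks(path, column_map = c(
    track_id = "TRACK_ID", frame = "FRAME", x_um = "POSITION_X",
    y_um = "POSITION_Y", z_um = "POSITION_Z"
  ))
  expect_equal(nrow(tk), 6L)
  expect_equal(tk$t_min, tk$frame * 10)
  expect_error(read_tracks(path, column_map = c(x_um = "NOPE")), "NOPE")
})
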