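test_that("monotone outward motion enters Phase II at frame zero", {
  r <- seq(0, 3.5, length.out = 30)
  expect_equal(detect_phase2_entry(r, R = 4), 0L)
})

test_that("a confined track yields no entry, with a reason", {
  r <- rep(c(0.2, 0.4, 0.3), 20)
  out <- detect_phase2_entry(r, R = 4)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "never_peripheral")
  expect_error(detect_phase2_entry(r[1:5], R = 4), "window")
})

test_that("entry detection is retroactive: later frames cannot change it", {
  r <- c(rep(0.2, 20), seq(0.2, 3.4, length.out = 25))
  e1 <- detect_phase2_entry(r, R = 4)
  e2 <- detect_phase2_entry(c(r, rep(0.1, 40)), R = 4)  # late return inward
  expect_equal(e1, e2)
})

test_that("late Phase II requires both centrioles peripheral", {
  R <- 4
  both <- detect_late_phase2(rep(3.6, 20), rep(3.6, 20), R, m = 3)
  expect_equal(both, 0L)
  none <- detect_late_phase2(rep(0.5, 20), rep(3.6, 20), R)
  expect_true(is.na(none))
  late <- detect_late_phase2(c(rep(1, 10), rep(3, 10)),
                             c(rep(3, 10), rep(3, 10)), R)
  expect_equal(late, 10L)
})

test_that("mode classification separates direct from reversal", {
  m <- 6
  down <- c(seq(0, -2.5, length.out = 20), rep(-2.5, 10))
  expect_equal(as.character(classify_mode(down)), "direct")
  up_down <- c(rep(2, 12), seq(2, -2.5, length.out = 15), rep(-2.5, 10))
  lab <- classify_mode(up_down)
  expect_equal(as.character(lab), "reversal")
  expect_equal(attr(lab, "lateral_frame"), 0L)
  flat <- rep(0.2, 30)
  expect_equal(as.character(classify_mode(flat)), "unclassified")
})

test_that("mode classification is antisymmetric under an axis flip", {
  s <- c(rep(1.8, 10), seq(1.8, -1.8, length.out = 10), rep(-1.8, 10))
  expect_equal(as.character(classify_mode(s)), "reversal")
  flipped <- classify_mode(-s)
  expect_equal(as.character(flipped), "direct")
  s2 <- c(seq(0, -2, length.out = 10), rep(-2, 10))
  expect_equal(as.character(classify_mode(s2)), "direct")
  expect_equal(as.character(classify_mode(-s2)), "unclassified")
})

test_that("reporter onset thresholds against the background window", {
  flat <- rep(10, 60)
  expect_true(is.na(detect_reporter_onset(flat)))

  stepped <- c(rep(10, 54), rep(10 + 5 * 2, 20))   # +5 sigma_b step
  onset <- detect_reporter_onset(stepped, k = 3, m = 3)
  expect_equal(as.integer(onset), 54L)

  # linear ramp: detected onset within 2 frames of the analytic crossing
  sigma_b <- 2
  ramp <- c(rep(0, 54), (1:46) * 4) + 10
  noisy <- ramp + withr::with_seed(8, stats::rnorm(100, 0, sigma_b))
  det <- detect_reporter_onset(noisy, k = 3, m = 3)
  mu <- attr(det, "mu_b"); sg <- attr(det, "sigma_b")
  crossing <- 54 + ceiling((mu + 3 * sg - 10) / 4) - 1
  expect_lte(abs(det - crossing), 2)
})

test_that("event records combine onset, reversal latency and drug loss", {
  s <- c(rep(2, 51), seq(2, -2, length.out = 21), rep(-2, 49))
  ev <- perturbation_events(s_dc = s, onset_frame = 0L, delta = 1, m = 6)
  expect_equal(ev$mode, "reversal")
  expect_equal(ev$reversal_frame, 66L)   # first frame at or below -1
  expect_equal(ev$latency_hr, 11.0)

  no_rev <- perturbation_events(s_dc = rep(2, 100), onset_frame = 10L)
  expect_true(is.na(no_rev$reversal_frame) && is.na(no_rev$latency_hr))

  r <- c(rep(3.5, 30), rep(0.5, 30))
  ev2 <- perturbation_events(r_dc = r, R = 4, drug_window = c(27, 60),
                             rho_loss = 0.5)
  expect_equal(ev2$loss_frame, 30L)
  expect_equal(ev2$loss_delay_min, 30)
})

test_that("the within-cutoff fraction reproduces cohort arithmetic", {
  # 17 of 28 cells constructed with a loss delay at or under 60 min
  delays <- c(seq(10, 60, length.out = 17), seq(70, 200, length.out = 8),
              rep(NA, 3))
  fw <- fraction_within(delays, cutoff_min = 60)
  expect_equal(fw$count, 17L)
  expect_equal(fw$total, 28L)
  expect_equal(fw$fraction, 17 / 28)
})

test_that("events recovered from a simulated cohort match the schedule", {
  coh <- simulate_cohort(sim_params(), n = 20, seed = 23, n_frames = 250)
  res <- analyze_cohort(coh)
  entry_err <- res$phase2_entry - res$true_entry
  expect_gte(mean(abs(entry_err) <= 3), 0.9)
  expect_gte(mean(res$mode == res$true_mode), 0.95)
  onset_err <- res$onset_frame - res$true_onset
  expect_gte(mean(abs(onset_err) <= 3, na.rm = TRUE), 0.9)
  rev <- !is.na(res$true_reversal)
  expect_gte(mean(abs(res$reversal_frame[rev] - res$true_reversal[rev]) <= 3),
             0.9)
})
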