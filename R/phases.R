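#' Detect Phase-II entry from the DC's radial series
#'
#' Operationalises the retroactive criterion "the DC is consistently moving
#' toward the peripheral direction": entry is the earliest frame t* such
#' that (i) the radial gain over the following window, `r(t*+W) - r(t*)`,
#' is at least `dr_min`; (ii) at least a fraction `q` of the per-frame
#' radial increments in `[t*, t*+W)` are positive; and (iii) r subsequently
#' reaches `rho * R`. Returns `NA` (with a reason attribute) when no frame
#' qualifies.
#'
#' @param r Numeric vector, DC radial distance per frame (µm), frame 0
#'   first.
#' @param R Apical radius, µm.
#' @param W Window length, frames (default 9 = 1.5 hr at 10-min frames).
#' @param q Minimum fraction of outward per-frame increments in the window.
#' @param dr_min Minimum radial gain over the window, µm.
#' @param rho Peripheral fraction of R that r must eventually reach.
#' @return 0-based entry frame, or `NA` with attribute `reason`.
#' @export
detect_phase2_entry <- function(r, R, W = 9, q = 0.6, dr_min = 1.0,
                                rho = 0.6) {
  n <- length(r)
  if (n < W + 1) stop("series shorter than the detection window", call. = FALSE)
  reached <- which(r >= rho * R)
  if (!length(reached)) {
    out <- NA_integer_
    attr(out, "reason") <- "never_peripheral"
    return(out)
  }
  last_reach <- reached[length(reached)]
  dr <- diff(r)
  for (t in seq_len(n - W)) {        # t is 1-based index of frame t-1
    gain <- r[t + W] - r[t]
    if (gain < dr_min) next
    frac_up <- mean(dr[t:(t + W - 1)] > 0)
    if (frac_up < q) next
    if (last_reach >= t) return(t - 1L)
  }
  out <- NA_integer_
  attr(out, "reason") <- "no_consistent_outward_window"
  out
}

#' Detect late Phase II (both centrioles peripheral)
#'
#' Earliest frame from which both centrioles sit at radius `rho * R` or
#' beyond for `m` consecutive frames.
#'
#' @param r_mc,r_dc Radial series (µm), frame 0 first.
#' @param R Apical radius, µm.
#' @param rho Peripheral fraction.
#' @param m Persistence, frames.
#' @return 0-based frame or `NA`.
#' @export
detect_late_phase2 <- function(r_mc, r_dc, R, rho = 0.6, m = 3) {
  stopifnot(length(r_mc) == length(r_dc))
  idx <- first_sustained(r_mc >= rho * R & r_dc >= rho * R, m)
  if (is.na(idx)) NA_integer_ else idx - 1L
}

#' Classify the DC trajectory mode: direct vs reversal
#'
#' On the signed polarity-axis coordinate s (positive = original
#' periphery-ward/lateral target): `"reversal"` if s holds at or above +delta
#' for `m` consecutive frames and later holds at or below -delta for `m`
#' frames (the DC reached the lateral side, then switched to the medial
#' side); `"direct"` if the sustained -delta excursion occurs without a prior
#' sustained +delta excursion; otherwise `"unclassified"`.
#'
#' @param s Signed-axis series (µm), frame 0 first.
#' @param delta Excursion threshold, µm.
#' @param m Persistence, frames (default 6 = 1 hr).
#' @return `"direct"`, `"reversal"` or `"unclassified"`, with attributes
#'   `lateral_frame` / `medial_frame` (0-based starts of the sustained
#'   excursions, `NA` if absent).
#' @export
classify_mode <- function(s, delta = 1.0, m = 6) {
  pos <- first_sustained(s >= delta, m)
  neg <- first_sustained(s <= -delta, m)
  label <- "unclassified"
  lat <- NA_integer_
  med <- NA_integer_
  if (!is.na(pos)) {
    lat <- pos - 1L
    rest <- s[pos:length(s)]
    neg_after <- first_sustained(rest <= -delta, m)
    if (!is.na(neg_after)) {
      med <- pos + neg_after - 2L
      label <- "reversal"
    } else if (!is.na(neg) && neg < pos) {
      med <- neg - 1L
      label <- "direct"
    }
  } else if (!is.na(neg)) {
    med <- neg - 1L
    label <- "direct"
  }
  attr(label, "lateral_frame") <- lat
  attr(label, "medial_frame") <- med
  label
}

#' Detect reporter onset against an early-frames background
#'
#' Background mean and SD come from the declared background window (default
#' the first 6 frames); onset is the first frame whose intensity exceeds
#' `mu_b + k * sigma_b` for `m` consecutive frames.
#'
#' @param intensity Reporter intensity per frame, frame 0 first.
#' @param background_frames 0-based frames used as background, or a numeric
#'   vector of background intensities via `background_values`.
#' @param background_values Optional explicit background sample (e.g. a
#'   neighbouring-region series), overriding `background_frames`.
#' @param k Threshold in background SDs.
#' @param m Persistence, frames.
#' @return 0-based onset frame or `NA`, with attributes `mu_b`, `sigma_b`.
#' @export
detect_reporter_onset <- function(intensity, background_frames = 0:5,
                                  background_values = NULL, k = 3, m = 3) {
  if (length(intensity) < m) stop("series shorter than persistence m",
                                  call. = FALSE)
  bg <- if (!is.null(background_values)) background_values else
    intensity[background_frames + 1]
  mu <- mean(bg)
  sg <- sd(bg)
  if (!is.finite(sg) || sg == 0) sg <- 0
  idx <- first_sustained(intensity > mu + k * sg, m)
  out <- if (is.na(idx)) NA_integer_ else idx - 1L
  attr(out, "mu_b") <- mu
  attr(out, "sigma_b") <- sg
  out
}

#' Assemble per-cell event annotations
#'
#' Combines reporter onset, the mode classification's sustained medial
#' excursion (the positional reversal), and nocodazole-window peripheral
#' loss into one record. Latency is `(reversal - onset) * frame_interval`;
#' the peripheral-loss frame is the first frame at or after the drug start
#' where `r_dc < rho_loss * R` holds for `m` consecutive frames.
#'
#' @param s_dc Signed-axis DC series (for reversal), or `NULL`.
#' @param r_dc Radial DC series (for drug loss), or `NULL`.
#' @param R Apical radius, µm.
#' @param onset_frame 0-based reporter onset (`NA` if absent).
#' @param drug_window Length-2 half-open frame window of the drug, or
#'   `NULL`.
#' @param rho_loss Peripheral-loss radius fraction.
#' @param delta,m Mode-classification thresholds (see [classify_mode()]).
#' @param frame_interval Minutes per frame.
#' @return One-row tibble: `mode`, `onset_frame`, `reversal_frame`,
#'   `latency_hr`, `loss_frame`, `loss_delay_min`.
#' @export
perturbation_events <- function(s_dc = NULL, r_dc = NULL, R = NA,
                                onset_frame = NA, drug_window = NULL,
                                rho_loss = 0.5, delta = 1.0, m = 6,
                                frame_interval = 10) {
  mode <- "unclassified"
  reversal <- NA_integer_
  if (!is.null(s_dc)) {
    mode <- classify_mode(s_dc, delta = delta, m = m)
    if (identical(as.character(mode), "reversal")) {
      reversal <- attr(mode, "medial_frame")
    }
  }
  latency <- if (!is.na(reversal) && !is.na(onset_frame)) {
    (reversal - onset_frame) * frame_interval / 60
  } else {
    NA_real_
  }
  loss <- NA_integer_
  loss_delay <- NA_real_
  if (!is.null(drug_window) && !is.null(r_dc)) {
    start <- drug_window[1]
    aft <- (start + 1):length(r_dc) - 1L      # 0-based frames >= start
    idx <- first_sustained(r_dc[aft + 1] < rho_loss * R, 3L)
    if (!is.na(idx)) {
      loss <- aft[idx]
      loss_delay <- (loss - start) * frame_interval
    }
  }
  tibble(
    mode = as.character(mode),
    onset_frame = as.integer(onset_frame),
    reversal_frame = as.integer(reversal),
    latency_hr = latency,
    loss_frame = as.integer(loss),
    loss_delay_min = loss_delay
  )
}

#' Fraction of cells losing peripheral position within a cutoff
#'
#' Cohort helper for drug experiments: of the cells with a defined loss
#' delay or with the drug applied, the fraction whose loss delay is at most
#' `cutoff_min` minutes (cells that never lose the peripheral position
#' count in the denominator).
#'
#' @param loss_delay_min Numeric vector of per-cell loss delays (`NA` =
#'   never lost).
#' @param cutoff_min Cutoff, minutes.
#' @return List with `fraction`, `count`, `total`.
#' @export
fraction_within <- function(loss_delay_min, cutoff_min = 60) {
  total <- length(loss_delay_min)
  count <- sum(!is.na(loss_delay_min) & loss_delay_min <= cutoff_min)
  list(fraction = count / total, count = count, total = total)
}
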