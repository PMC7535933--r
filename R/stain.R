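#' Background-subtracted mean reporter intensity
#'
#' Mean intensity inside the cell mask minus the mean of a surrounding
#' background region; negative values are reported as-is.
#'
#' @param image 2D numeric matrix.
#' @param mask Logical matrix selecting the cell.
#' @param background Logical matrix selecting the background region.
#' @return Background-subtracted mean (scalar).
#' @export
reporter_intensity <- function(image, mask, background) {
  stopifnot(is.matrix(image), all(dim(mask) == dim(image)),
            all(dim(background) == dim(image)))
  if (!any(mask) || !any(background)) {
    stop("mask and background must be non-empty", call. = FALSE)
  }
  mean(image[mask]) - mean(image[background])
}

#' Area above an intensity threshold
#'
#' Counts suprathreshold pixels and converts to µm² via the pixel size
#' (strictly-greater comparison; monotone non-increasing in the threshold).
#'
#' @param image 2D numeric matrix.
#' @param threshold Intensity threshold, or `"otsu"`.
#' @param pixel_size_xy Pixel size, µm.
#' @return Area, µm², with attribute `threshold`.
#' @export
area_above_threshold <- function(image, threshold, pixel_size_xy = 0.216) {
  stopifnot(is.matrix(image))
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    norm <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    threshold <- rng[1] + (rng[2] - rng[1]) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  stopifnot(is.finite(threshold))
  out <- sum(image > threshold) * pixel_size_xy^2
  attr(out, "threshold") <- threshold
  out
}

#' Intensity profile along the segment joining two centrioles
#'
#' Samples the image by bilinear interpolation at `n_samples` evenly spaced
#' points from `point_a` to `point_b` (pixel coordinates, 0-based, `(x, y)`)
#' and summarises the a-associated, midpoint and b-associated intensities
#' as means over windows of `window` samples.
#'
#' @param image 2D numeric matrix (rows = y, columns = x).
#' @param point_a,point_b Length-2 `(x, y)` pixel coordinates, 0-based.
#' @param n_samples Number of samples along the segment.
#' @param window Samples per summary window.
#' @return List with `profile` (tibble: `t`, `x`, `y`, `intensity`),
#'   `a_mean`, `mid_mean`, `b_mean`.
#' @export
line_profile <- function(image, point_a, point_b, n_samples = 25,
                         window = 3) {
  stopifnot(is.matrix(image), length(point_a) == 2, length(point_b) == 2)
  inside <- function(p) p[1] >= 0 && p[1] <= ncol(image) - 1 &&
    p[2] >= 0 && p[2] <= nrow(image) - 1
  if (!inside(point_a) || !inside(point_b)) {
    stop("profile endpoints must lie inside the image", call. = FALSE)
  }
  if (all(point_a == point_b)) n_samples <- 1L
  tt <- if (n_samples == 1) 0 else seq(0, 1, length.out = n_samples)
  xs <- point_a[1] + tt * (point_b[1] - point_a[1])
  ys <- point_a[2] + tt * (point_b[2] - point_a[2])
  bilinear <- function(x, y) {
    x0 <- pmin(floor(x), ncol(image) - 2); x0 <- pmax(x0, 0)
    y0 <- pmin(floor(y), nrow(image) - 2); y0 <- pmax(y0, 0)
    fx <- x - x0; fy <- y - y0
    i00 <- image[cbind(y0 + 1, x0 + 1)]
    i01 <- image[cbind(y0 + 1, x0 + 2)]
    i10 <- image[cbind(y0 + 2, x0 + 1)]
    i11 <- image[cbind(y0 + 2, x0 + 2)]
    (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
  }
  vals <- if (nrow(image) == 1 || ncol(image) == 1) {
    image[cbind(round(ys) + 1, round(xs) + 1)]
  } else {
    bilinear(xs, ys)
  }
  w <- min(window, n_samples)
  mid0 <- floor((n_samples - w) / 2) + 1
  list(
    profile = tibble(t = tt, x = xs, y = ys, intensity = vals),
    a_mean = mean(vals[seq_len(w)]),
    mid_mean = mean(vals[mid0:(mid0 + w - 1)]),
    b_mean = mean(vals[(n_samples - w + 1):n_samples])
  )
}
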