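# Gap-assay fiber quantification: threshold the axon image, draw two ROIs
# parallel to the gap (ROI 1 inside the gap against the boundary, ROI 2
# directly behind it, each ~20 um wide over the full lateral extent), count
# signal peaks in every pixel row, and derive percent stopping from the
# mean counts. Plus a synthetic fluorescence-image generator with known
# ground truth to validate the pipeline end to end.
#
# Images are plain numeric matrices, rows = y (lateral), columns = x
# (growth direction), intensities in [0, 1].

#' ROI geometry for gap-assay quantification
#'
#' @param gap_far_edge x pixel (column) of the boundary between the gap
#'   and the second cue field.
#' @param roi_width_um ROI width along the growth axis in micrometers
#'   (about 20 in the original protocol).
#' @param pixel_size_um physical pixel size.
#' @param lateral_extent optional `c(first_row, last_row)` restricting the
#'   ROIs to the lateral span of the gap; default: all rows.
#' @param gap_axis growth direction; only `"horizontal"` (fibers grow
#'   along x/columns) is implemented.
#' @return List of class `roi_spec`.
#' @export
roi_spec <- function(gap_far_edge, roi_width_um = 20, pixel_size_um = 1,
                     lateral_extent = NULL, gap_axis = "horizontal") {
  stopifnot(gap_far_edge >= 1, roi_width_um > 0, pixel_size_um > 0,
            identical(gap_axis, "horizontal"))
  structure(list(gap_far_edge = as.integer(gap_far_edge),
                 roi_width_px = max(1L,
                                    as.integer(round(roi_width_um /
                                                       pixel_size_um))),
                 pixel_size_um = pixel_size_um,
                 lateral_extent = lateral_extent, gap_axis = gap_axis),
            class = "roi_spec")
}

#' Generate a synthetic gap-assay fluorescence image
#'
#' Renders roughly parallel, lightly meandering bright fiber traces
#' growing along x. A `stop_fraction` share of the fibers terminates just
#' in front of the gap's far edge (where stalling growth cones accumulate
#' in the real assay); the rest continue beyond the second ROI. The clean
#' rendering is blurred with a small Gaussian kernel and Gaussian noise is
#' added. The pre-noise binary mask and the per-fiber ground truth are
#' returned alongside the image.
#'
#' @param n_fibers number of fibers.
#' @param stop_fraction fraction of fibers stopping at the boundary; the
#'   number of crossing fibers is exactly
#'   `round(n_fibers * (1 - stop_fraction))`.
#' @param roi a [roi_spec()]; its `gap_far_edge` defines the boundary.
#' @param width,height image size in pixels.
#' @param fiber_width_px rendered fiber thickness.
#' @param meander standard deviation of the per-step lateral drift.
#' @param noise_sigma additive Gaussian noise level.
#' @param seed optional RNG seed.
#' @return List with `image`, `mask` (pre-noise binary), and `truth`
#'   (n_fibers, stop_fraction, end column per fiber).
#' @examples
#' g <- generate_gap_image(10, 0.5, roi_spec(120), width = 200,
#'                         height = 80, seed = 1)
#' dim(g$image)
#' @export
generate_gap_image <- function(n_fibers = 40, stop_fraction = 0.5,
                               roi = roi_spec(150), width = 240,
                               height = 160, fiber_width_px = 3,
                               meander = 0.25, noise_sigma = 0.05,
                               seed = NULL) {
  stopifnot(n_fibers >= 1, stop_fraction >= 0, stop_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  edge <- roi$gap_far_edge
  stopifnot(edge + roi$roi_width_px <= width, edge - roi$roi_width_px >= 1)
  n_cross <- round(n_fibers * (1 - stop_fraction))
  crosses <- rep(FALSE, n_fibers)
  if (n_cross > 0) crosses[sample.int(n_fibers, n_cross)] <- TRUE
  img <- matrix(0, nrow = height, ncol = width)
  margin <- max(4, fiber_width_px + 2)
  y0 <- seq(margin, height - margin, length.out = n_fibers) +
    stats::runif(n_fibers, -1, 1)
  ends <- integer(n_fibers)
  half <- floor(fiber_width_px / 2)
  for (i in seq_len(n_fibers)) {
    # stalled growth cones pile up within a few pixels of the boundary
    end_x <- if (crosses[i]) width else
      edge - sample.int(max(2, round(roi$roi_width_px / 3)), 1)
    ends[i] <- end_x
    drift <- stats::rnorm(end_x, 0, meander)
    ypath <- y0[i] + cumsum(drift) - seq_len(end_x) * mean(drift)
    ypath <- pmin(pmax(ypath, 1 + half), height - half)
    for (x in seq_len(end_x)) {
      rows <- (round(ypath[x]) - half):(round(ypath[x]) + half)
      img[rows, x] <- 1
    }
  }
  mask <- img > 0
  img <- blur_gaussian(img, sigma = 0.8)
  img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                      nrow = height)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask,
       truth = list(n_fibers = n_fibers, stop_fraction = stop_fraction,
                    end_col = ends, crosses = crosses))
}

# separable Gaussian blur with a small odd kernel
blur_gaussian <- function(img, sigma = 0.8) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  img <- apply(img, 2, pad_conv)
  t(apply(img, 1, pad_conv))
}

#' Threshold a grayscale image
#'
#' Separates axon signal (foreground) from background either with Otsu's
#' criterion (maximising between-class variance on a 256-bin histogram)
#' or with a fixed cutoff.
#'
#' @param image numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value cutoff for `method = "fixed"`.
#' @return Logical matrix with attributes `method` and `threshold`.
#' @export
threshold_image <- function(image, method = c("otsu", "fixed"),
                            fixed_value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  thr <- if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed thresholding needs fixed_value")
    fixed_value
  } else {
    otsu_threshold(image)
  }
  if (is.na(thr)) {
    warning("degenerate image; empty foreground returned")
    bin <- matrix(FALSE, nrow(image), ncol(image))
    thr <- Inf
  } else {
    bin <- image > thr
  }
  attr(bin, "method") <- method
  attr(bin, "threshold") <- thr
  bin
}

otsu_threshold <- function(image, n_bins = 256) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) <= 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(image, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Count signal peaks in each pixel row of an ROI
#'
#' A peak is a maximal run of consecutive foreground pixels along the row
#' (one fiber cross-section). Runs narrower than `min_width` pixels can be
#' suppressed to reject noise specks.
#'
#' @param roi logical (or 0/1) matrix, rows perpendicular to the growth
#'   direction.
#' @param min_width minimum run length counted as a fiber (default 1).
#' @return Integer vector of per-row peak counts.
#' @examples
#' count_peaks_per_row(rbind(c(0, 1, 1, 0, 0, 1, 0)))  # 2
#' @export
count_peaks_per_row <- function(roi, min_width = 1) {
  stopifnot(is.matrix(roi))
  apply(roi, 1, function(row) {
    r <- rle(as.logical(row))
    sum(r$values & r$lengths >= min_width)
  })
}

#' Quantify percent stopping from a gap-assay image
#'
#' Thresholds the image, extracts ROI 1 (inside the gap, flush against the
#' boundary to the second field) and ROI 2 (directly behind the boundary),
#' counts signal peaks in each pixel row of both ROIs, and reports
#' `100 * (1 - mean_peaks(ROI2) / mean_peaks(ROI1))`, clipped to
#' `[0, 100]` (fasciculation can make ROI 2 counts exceed ROI 1).
#'
#' @param image numeric matrix (see [generate_gap_image()] for
#'   conventions).
#' @param roi a [roi_spec()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value cutoff for fixed thresholding.
#' @param min_width minimum peak width (pixels).
#' @return List with `stopping_percent`, `mean_counts` (both ROIs) and the
#'   parameters used.
#' @examples
#' g <- generate_gap_image(20, 0.8, roi_spec(120), width = 200,
#'                         height = 120, seed = 2)
#' quantify_stopping(g$image, roi_spec(120))$stopping_percent
#' @export
quantify_stopping <- function(image, roi,
                              threshold_method = c("otsu", "fixed"),
                              fixed_value = NULL, min_width = 1) {
  stopifnot(inherits(roi, "roi_spec"))
  threshold_method <- match.arg(threshold_method)
  w <- roi$roi_width_px
  edge <- roi$gap_far_edge
  if (edge - w < 1 || edge + w - 1 > ncol(image))
    stop("ROIs do not fit inside the image")
  rows <- if (is.null(roi$lateral_extent)) seq_len(nrow(image)) else
    seq(roi$lateral_extent[1], roi$lateral_extent[2])
  bin <- threshold_image(image, threshold_method, fixed_value)
  roi1 <- bin[rows, (edge - w):(edge - 1), drop = FALSE]
  roi2 <- bin[rows, edge:(edge + w - 1), drop = FALSE]
  m1 <- mean(count_peaks_per_row(roi1, min_width))
  m2 <- mean(count_peaks_per_row(roi2, min_width))
  if (m1 == 0)
    stop("no fibers reached the gap: mean peak count in ROI 1 is zero")
  list(stopping_percent = min(max(100 * (1 - m2 / m1), 0), 100),
       mean_counts = c(roi1 = m1, roi2 = m2),
       params = list(threshold_method = threshold_method,
                     threshold = attr(bin, "threshold"),
                     min_width = min_width, roi = roi))
}
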