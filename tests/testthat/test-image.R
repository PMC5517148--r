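# gap-assay image quantification and its synthetic validator

test_that("per-row peak counting equals maximal foreground runs", {
  expect_equal(count_peaks_per_row(rbind(c(0, 1, 1, 0, 0, 1, 0))), 2)
  expect_equal(count_peaks_per_row(rbind(rep(0, 7))), 0)
  expect_equal(count_peaks_per_row(rbind(rep(1, 7))), 1)
  m <- rbind(c(1, 0, 1, 0, 1), c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1))
  expect_equal(count_peaks_per_row(m), c(3, 0, 1))
  # min_width suppresses one-pixel specks
  expect_equal(count_peaks_per_row(rbind(c(0, 1, 0, 1, 1, 0)),
                                   min_width = 2), 1)
})

test_that("thresholding separates a two-level image exactly", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)
  bin <- threshold_image(img, "otsu")
  expect_equal(unclass(bin), img > 0.5, ignore_attr = TRUE)
  expect_warning(b0 <- threshold_image(matrix(0.3, 4, 4)), "degenerate")
  expect_false(any(b0))
  bf <- threshold_image(img, "fixed", fixed_value = 0.9)
  expect_equal(sum(bf), 2)
  expect_equal(attr(bf, "threshold"), 0.9)
  expect_error(threshold_image(img, "fixed"), "fixed_value")
})

test_that("percent stopping follows the two-ROI mean-count formula", {
  # 20 rows x 60 cols; boundary at column 41; ROI width 10
  img <- matrix(0, 20, 60)
  img[1:10, 1:50] <- 0  # fibers drawn below
  for (r in 1:10) img[r, 1:40] <- 1   # ten fibers reach the boundary
  for (r in 1:2) img[r, 41:60] <- 1   # two continue beyond
  roi <- roi_spec(41, roi_width_um = 10, pixel_size_um = 1)
  q <- quantify_stopping(img, roi, threshold_method = "fixed",
                         fixed_value = 0.5)
  expect_equal(unname(q$mean_counts["roi1"]), 0.5)  # 10 rows of 20
  expect_equal(unname(q$mean_counts["roi2"]), 0.1)
  expect_equal(q$stopping_percent, 80)

  # more signal behind than in the gap clips to 0
  img2 <- matrix(0, 20, 60)
  img2[1:2, 31:40] <- 1
  img2[1:10, 41:50] <- 1
  expect_equal(quantify_stopping(img2, roi, "fixed",
                                 fixed_value = 0.5)$stopping_percent, 0)

  blank <- matrix(0, 20, 60)
  blank[1, 55] <- 1
  expect_error(quantify_stopping(blank, roi, "fixed", fixed_value = 0.5),
               "no fibers")
  expect_error(quantify_stopping(img, roi_spec(5, roi_width_um = 10)),
               "fit inside")
})

test_that("the synthetic generator honours its ground truth", {
  roi <- roi_spec(150, roi_width_um = 20)
  g1 <- generate_gap_image(12, stop_fraction = 1, roi, width = 240,
                           height = 100, seed = 1)
  expect_false(any(g1$mask[, 151:240]))      # nobody crosses (pre-noise)
  g0 <- generate_gap_image(12, stop_fraction = 0, roi, width = 240,
                           height = 100, seed = 2)
  expect_true(all(colSums(g0$mask[, 151:240]) > 0))
  g5 <- generate_gap_image(20, stop_fraction = 0.5, roi, width = 240,
                           height = 100, seed = 3)
  expect_equal(sum(g5$truth$crosses), 10)    # round(n * (1 - sf))
  expect_true(all(g5$image >= 0 & g5$image <= 1))
})

test_that("quantification is invariant to intensity rescaling with Otsu", {
  roi <- roi_spec(150)
  g <- generate_gap_image(30, 0.5, roi, width = 240, height = 120,
                          noise_sigma = 0, seed = 4)
  q1 <- quantify_stopping(g$image, roi)
  q2 <- quantify_stopping(g$image * 0.4, roi)
  expect_equal(q1$stopping_percent, q2$stopping_percent)
})

test_that("generator -> quantifier round trip recovers the stop fraction", {
  roi <- roi_spec(150)
  errs <- sapply(1:4, function(s) {
    g <- generate_gap_image(40, 0.5, roi, width = 240, height = 160,
                            seed = s)
    abs(quantify_stopping(g$image, roi)$stopping_percent / 100 - 0.5)
  })
  expect_lt(mean(errs), 0.1)
})
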