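# Dead-time correction, plane alignment, accumulation, automatic ROI
# extraction and tabulation.

make_stack <- function(counts, dwell = 0.015, channels = NULL) {
  # counts: array (channel, plane, row, col) or a matrix for one channel
  if (is.matrix(counts)) {
    a <- array(0, dim = c(1, 1, nrow(counts), ncol(counts)))
    a[1, 1, , ] <- counts
    counts <- a
  }
  if (is.null(channels)) channels <- mass_channels()$label[seq_len(dim(counts)[1])]
  ion_stack(counts, channels, dwell_time = dwell, raster_size = 30)
}

seven_channel_images <- function(img) {
  out <- rep(list(img), 7)
  names(out) <- mass_channels()$label
  out
}

test_that("dead-time correction follows the rate formula and its limits", {
  m <- matrix(c(0, 660, 10, 100), 2, 2)
  st <- make_stack(m)
  # tau = 0: identity
  expect_equal(dead_time_correct(st, 0)$counts, st$counts)
  corr <- dead_time_correct(st, 44e-9)$counts[1, 1, , ]
  expect_equal(corr[1, 1], 0)                       # zero stays zero
  expect_equal(corr[2, 1], 660 / (1 - 44000 * 44e-9))  # = 661.28
  expect_equal(round(corr[2, 1], 2), 661.28)
  expect_true(all(corr >= m))                        # corrected >= measured
  # strictly increasing in measured counts
  x <- matrix(seq(0, 5000, length.out = 16), 4, 4)
  cx <- dead_time_correct(make_stack(x), 44e-9)$counts[1, 1, , ]
  expect_true(all(diff(cx[order(x)]) > 0))
  # saturation names the pixel and channel
  sat <- make_stack(matrix(c(0, 0, 0, 4e5), 2, 2), dwell = 0.015)
  expect_error(dead_time_correct(sat, 44e-6), "saturated.*12C")
})

test_that("alignment recovers constructed integer shifts", {
  set.seed(42)
  base <- matrix(rpois(64 * 64, 3), 64, 64)
  base[20:30, 10:40] <- base[20:30, 10:40] + 50   # structure
  shift_img <- function(img, dy, dx) {
    out <- matrix(0, nrow(img), ncol(img))
    src_r <- seq_len(nrow(img)) - dy
    src_c <- seq_len(ncol(img)) - dx
    vr <- src_r >= 1 & src_r <= nrow(img)
    vc <- src_c >= 1 & src_c <= ncol(img)
    out[vr, vc] <- img[src_r[vr], src_c[vc]]
    out
  }
  a <- array(0, dim = c(1, 3, 64, 64))
  a[1, 1, , ] <- base
  a[1, 2, , ] <- shift_img(base, 2, -3)
  a[1, 3, , ] <- shift_img(base, -4, 1)
  st <- ion_stack(a, "14N12C", dwell_time = 0.015, raster_size = 30)
  sh <- align_planes(st, max_shift = 6)
  expect_equal(sh[1, ], c(dy = 0L, dx = 0L))
  expect_equal(unname(sh[2, ]), c(2L, -3L))
  expect_equal(unname(sh[3, ]), c(-4L, 1L))
  # single plane: trivially (0,0)
  st1 <- make_stack(base, channels = "14N12C")
  expect_equal(nrow(align_planes(st1)), 1)
  # identical planes: all shifts zero
  ai <- array(rep(base, 3), dim = c(1, 3, 64, 64))
  for (p in 1:3) ai[1, p, , ] <- base
  expect_true(all(align_planes(ion_stack(ai, "14N12C", 0.015, 30)) == 0))
  # flat reference plane is an error
  flat <- make_stack(matrix(5, 8, 8), channels = "14N12C")
  expect_error(align_planes(flat), "flat")
})

test_that("accumulation sums planes over the common overlap", {
  a <- array(0, dim = c(1, 3, 4, 4))
  for (p in 1:3) a[1, p, , ] <- matrix(1:16, 4, 4)
  st <- ion_stack(a, "14N12C", 0.015, 30)
  acc <- accumulate_planes(st)
  expect_equal(unname(acc[["14N12C"]][, ]), 3 * matrix(1:16, 4, 4),
               ignore_attr = TRUE)
  # conservation with zero shifts
  expect_equal(sum(acc[["14N12C"]]), sum(a))
  # shifts (0,0), (1,0): overlap excludes one row
  b <- array(0, dim = c(1, 2, 4, 4))
  m1 <- matrix(1:16, 4, 4)
  b[1, 1, , ] <- m1
  m2 <- matrix(0, 4, 4); m2[2:4, ] <- m1[1:3, ]   # content moved down 1
  b[1, 2, , ] <- m2
  st2 <- ion_stack(b, "14N12C", 0.015, 30)
  shifts <- matrix(c(0L, 0L, 1L, 0L), 2, 2, byrow = TRUE)
  acc2 <- accumulate_planes(st2, shifts)[["14N12C"]]
  expect_equal(attr(acc2, "overlap_rows"), c(1, 3))
  expect_equal(unname(acc2[1:3, ]), unname(2 * m1[1:3, ]))
  expect_true(all(is.na(acc2[4, ])))
  expect_error(accumulate_planes(st2, shifts[1, , drop = FALSE]),
               "every plane")
})

test_that("automatic ROI extraction labels 8-connected components above threshold", {
  img <- matrix(0, 40, 40)
  img[5:12, 5:12] <- 100                      # disk-ish blob 1
  img[25:30, 20:32] <- 80                     # blob 2
  mask <- extract_rois_auto(img, min_area_px = 5)
  expect_equal(max(mask), 2)
  expect_equal(sort(unique(mask[img > 0])), 1:2)
  expect_true(all(mask[img == 0] == 0))
  # raster-scan labeling order: first pixel of ROI 1 precedes ROI 2
  expect_equal(unname(mask[5, 5]), 1)
  expect_equal(unname(mask[25, 20]), 2)
  # min_area filter removes a 3-px component
  img2 <- matrix(0, 20, 20)
  img2[2, 2:4] <- 50
  img2[10:15, 10:15] <- 50
  m2 <- extract_rois_auto(img2, min_area_px = 5)
  expect_equal(max(m2), 1)
  expect_true(all(m2[2, 2:4] == 0))
  # empty foreground warns and returns an all-background mask
  expect_warning(m0 <- extract_rois_auto(matrix(0, 5, 5)), "empty|no foreground")
  expect_true(all(m0 == 0))
  # 8-connectivity against a brute-force flood fill, diagonals included
  set.seed(3)
  fg_img <- matrix(rbinom(400, 1, 0.35) * 10, 20, 20)
  m3 <- extract_rois_auto(fg_img, threshold = 5, min_area_px = 1)
  bf <- bf_components(fg_img > 5)
  expect_equal(max(m3), max(bf))
  expect_equal(partition_signature(m3[m3 > 0]),
               partition_signature(bf[bf > 0]))
})

test_that("tabulation sums counts per ROI with centroids and additivity", {
  img <- matrix(2, 10, 10)
  mask <- matrix(0L, 10, 10)
  mask[2:3, 2:6] <- 1L   # 10 px
  tab <- tabulate_roi_counts(seven_channel_images(img), mask)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$c12, 20)
  expect_equal(tab$area_px, 10L)
  # 0-based centroid: rows 2:3 -> y mean 1.5; cols 2:6 -> x mean 3
  expect_equal(tab$centroid_y, 1.5)
  expect_equal(tab$centroid_x, 3)
  # two disjoint ROIs: row count 2, totals bounded by image total
  mask[7:8, 7:8] <- 2L
  tab2 <- tabulate_roi_counts(seven_channel_images(img), mask)
  expect_equal(nrow(tab2), 2)
  expect_lte(sum(tab2$c12), sum(img))
  # additivity: splitting an ROI into two masks sums to the single-ROI row
  maskA <- matrix(0L, 10, 10); maskA[2:3, 2:4] <- 1L
  maskB <- matrix(0L, 10, 10); maskB[2:3, 5:6] <- 1L
  tA <- tabulate_roi_counts(seven_channel_images(img), maskA)
  tB <- tabulate_roi_counts(seven_channel_images(img), maskB)
  expect_equal(tA$nc14 + tB$nc14, tab$nc14)
  # dimension mismatch errors
  expect_error(
    tabulate_roi_counts(seven_channel_images(img), matrix(0L, 5, 5)),
    "dimensions")
  # Poisson uncertainty attached as sqrt of totals
  expect_equal(attr(tab, "sigma")$c12, sqrt(20))
})
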