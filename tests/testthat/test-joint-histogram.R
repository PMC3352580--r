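test_that("histogram parameters must span the 0-100 scale", {
  p <- histogram_params()
  expect_identical(p$n_bins, 400L)
  expect_equal(p$bin_width, 0.25)
  expect_equal(p$n_bins * p$bin_width, 100)
  expect_error(histogram_params(bin_width = 0.25, n_bins = 100), "span")
  expect_error(histogram_params(smoothing_fwhm_bins = 0), "smoothing")
})

test_that("joint histogram bins voxel pairs by floor(intensity / width)", {
  inp <- intensity_volume(array(c(10, 10, 10, 30), c(4, 1, 1)))
  std <- intensity_volume(array(c(20, 20, 20, 40), c(4, 1, 1)))
  h <- compute_joint_histogram(inp, std, array(TRUE, c(4, 1, 1)))
  expect_equal(h$counts[41, 81], 3)     # 0-based bin (40, 80)
  expect_equal(h$counts[121, 161], 1)   # 0-based bin (120, 160)
  expect_equal(sum(h$counts), 4)
  expect_equal(h$n_voxels, 4L)
})

test_that("histogram mass equals the masked voxel count and sits on the diagonal for identical images", {
  set.seed(21)
  a <- intensity_volume(array(runif(512, 0, 100), c(8, 8, 8)))
  mask <- array(runif(512) < 0.4, c(8, 8, 8))
  h <- compute_joint_histogram(a, a, mask)
  expect_equal(sum(h$counts), sum(mask))
  expect_equal(sum(diag(h$counts)), sum(mask))  # identity correspondence

  expect_error(compute_joint_histogram(a, a, array(FALSE, c(8, 8, 8))),
               "empty mask")
  b <- intensity_volume(array(runif(512, 0, 100), c(8, 8, 8)))
  big <- intensity_volume(array(0, c(9, 8, 8)))
  expect_error(compute_joint_histogram(a, big, mask), "shape mismatch")
  hot <- a; hot$data[which(mask)[1]] <- 101
  expect_error(compute_joint_histogram(hot, b, mask), "\\[0, 100\\]")
})

test_that("smoothing preserves mass, leaves a delta's argmax in place, and is uniform in the interior", {
  inp <- intensity_volume(array(50.1, c(2, 2, 2)))
  std <- intensity_volume(array(25.1, c(2, 2, 2)))
  h <- compute_joint_histogram(inp, std, array(TRUE, c(2, 2, 2)))
  hs <- smooth_histogram(h)
  expect_equal(which.max(hs$counts), which.max(h$counts))
  expect_lt(abs(sum(hs$counts) - sum(h$counts)), 1e-9)
  expect_true(all(hs$counts >= 0))

  p40 <- histogram_params(bin_width = 2.5, n_bins = 40,
                          smoothing_fwhm_bins = 4)
  flat <- smooth_histogram(hist_from_counts(matrix(1, 40, 40), p40))
  expect_lt(abs(sum(flat$counts) - 1600), 1e-9)
  interior <- flat$counts[10:31, 10:31]   # > kernel radius from every edge
  expect_lt(max(interior) - min(interior), 1e-12)
})

test_that("separable smoothing equals direct 2D convolution", {
  p40 <- histogram_params(bin_width = 2.5, n_bins = 40,
                          smoothing_fwhm_bins = 4)
  set.seed(31)
  counts <- matrix(rpois(1600, 3), 40, 40)
  got <- smooth_histogram(hist_from_counts(counts, p40))$counts
  want <- smooth_direct_2d(counts, 4)
  expect_lt(max(abs(got - want)), 1e-10)

  corner <- matrix(0, 40, 40); corner[2, 39] <- 7   # edge handling
  got2 <- smooth_histogram(hist_from_counts(corner, p40))$counts
  expect_lt(max(abs(got2 - smooth_direct_2d(corner, 4))), 1e-10)
})

test_that("find_mode returns bin centers with the documented tie-break", {
  # delta at 0-based bin (40, 80): bin 40 spans [10, 10.25), center 10.125
  inp <- intensity_volume(array(10.1, c(1, 1, 1)))
  std <- intensity_volume(array(20.1, c(1, 1, 1)))
  h <- compute_joint_histogram(inp, std, array(TRUE, c(1, 1, 1)))
  m <- find_mode(h)
  expect_equal(m$m_r, 10.125)
  expect_equal(m$m_s, 20.125)

  # equal maxima at input bins 40 and 60 -> smaller input bin wins
  inp2 <- intensity_volume(array(c(15.1, 10.1), c(2, 1, 1)))
  std2 <- intensity_volume(array(c(20.1, 20.1), c(2, 1, 1)))
  h2 <- compute_joint_histogram(inp2, std2, array(TRUE, c(2, 1, 1)))
  expect_equal(find_mode(h2)$m_r, 10.125)
})

test_that("input-intensity exclusion restricts the search and never raises the peak", {
  inp <- intensity_volume(array(c(10.1, 10.1, 30.1), c(3, 1, 1)))
  std <- intensity_volume(array(c(20.1, 20.1, 40.1), c(3, 1, 1)))
  h <- compute_joint_histogram(inp, std, array(TRUE, c(3, 1, 1)))
  full <- find_mode(h)
  expect_equal(full$m_r, 10.125)
  cut <- find_mode(h, input_exclusion = c(0, 15))
  expect_equal(cut$m_r, 30.125)
  expect_lte(cut$peak_count, full$peak_count)
  expect_error(find_mode(h, input_exclusion = c(0, 100)), "no mode")

  # widening the exclusion can only lower the attainable peak
  set.seed(5)
  hr <- hist_from_counts(matrix(rpois(160000, 1), 400, 400))
  peaks <- vapply(c(10, 30, 50, 70),
                  function(w) find_mode(hr, c(0, w))$peak_count, 0)
  expect_true(all(diff(peaks) <= 0))
})
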