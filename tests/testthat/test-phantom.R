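test_that("phantom labels partition the grid and tissues hit their means", {
  spec <- phantom_spec(seed = 17)
  ph <- generate_phantom(spec)
  m <- ph$masks
  expect_true(all(m$bkg + m$wm + m$gm == 1))   # disjoint and covering
  for (t in c("bkg", "wm", "gm")) expect_gt(sum(m[[t]]), 0)

  wm_vals <- ph$volume$data[ph$labels == 3L]
  expect_lte(abs(mean(wm_vals) - 75), 3 * 2 / sqrt(length(wm_vals)))
  expect_gte(min(ph$volume$data), 0)
  expect_lte(max(ph$volume$data), 100)

  # CSF shell is absorbed into BKG by default, kept separate on request
  expect_true(any(m$bkg & ph$labels == 1L))
  kept <- generate_phantom(phantom_spec(seed = 17, csf_to_bkg = FALSE))
  expect_false(any(kept$masks$bkg & kept$labels == 1L))
})

test_that("phantom generation is seed-reproducible", {
  a <- generate_phantom(phantom_spec(seed = 23))
  b <- generate_phantom(phantom_spec(seed = 23))
  c <- generate_phantom(phantom_spec(seed = 24))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("distortion applies the transfer, then noise, then clipping", {
  ph <- generate_phantom(phantom_spec(seed = 19))
  ident <- distortion_spec(function(v) v, noise_sd = 0)
  expect_identical(distort_volume(ph$volume, ident)$data, ph$volume$data)

  aff <- distortion_spec(function(v) 0.8 * v + 5, noise_sd = 0)
  out <- distort_volume(ph$volume, aff)
  wm_mean <- mean(out$data[ph$labels == 3L])
  expect_lt(abs(wm_mean - 65), 0.2)           # 0.8 * 75 + 5

  expect_error(distortion_spec(function(v) -v), "into \\[0,100\\]|non-monotone")
  expect_error(distortion_spec(function(v) 50 + 30 * sin(v / 5)),
               "non-monotone")
})

test_that("monotone distortions preserve tissue-mean ordering", {
  ph <- generate_phantom(phantom_spec(seed = 20))
  set.seed(41)
  for (rep in 1:5) {
    pts <- cbind(c(0, sort(runif(2, 20, 80)), 100),
                 c(0, sort(runif(2, 10, 90)), 100))
    out <- distort_volume(ph$volume, distortion_spec(pts, noise_sd = 1,
                                                     seed = rep))
    means <- vapply(c(0L, 2L, 3L),
                    function(l) mean(out$data[ph$labels == l]), 0)
    expect_true(all(diff(means) > 0))          # BKG < GM < WM survives
  }
})

test_that("the multisite suite is aligned, sized n_subjects x n_sites, and reproducible", {
  base <- phantom_spec(shape = c(24, 24, 24))
  suite <- generate_multisite_suite(2, 3, base = base, seed = 7)
  expect_length(suite$cases, 6L)
  for (cs in suite$cases) {
    expect_true(validate_aligned(cs$input, cs$standard))
    expect_true(validate_aligned(cs$input, cs$masks))
  }
  # same anatomy within a subject, distinct across subjects
  expect_identical(suite$cases[[1]]$standard$data,
                   suite$cases[[2]]$standard$data)
  expect_false(identical(suite$cases[[1]]$standard$data,
                         suite$cases[[4]]$standard$data))

  again <- generate_multisite_suite(2, 3, base = base, seed = 7)
  expect_identical(suite$cases[[5]]$input$data, again$cases[[5]]$input$data)

  solo <- generate_multisite_suite(1, 1, base = base,
                                   site_transfers = list(function(v) v),
                                   site_noise_sd = 0, seed = 8)
  expect_identical(solo$cases[[1]]$input$data, solo$cases[[1]]$standard$data)
})

test_that("both methods improve the default suite and WM medians are equivalent", {
  rep <- default_suite_report(seed = 1)
  for (vs in c("FRG", "WM", "GM")) for (cond in c("L4", "STI"))
    expect_lt(median_mae(rep, vs, cond), median_mae(rep, vs, "Original"))
  # equivalence margin: half the irreducible site-noise MAE floor
  # (0.5 * sqrt(2/pi) * 2 intensity units); see the methods vignette
  expect_lte(median_mae(rep, "WM", "STI") - median_mae(rep, "WM", "L4"),
             0.5 * sqrt(2 / pi) * 2)
})

test_that("a suite round-trips through NIfTI files and a manifest", {
  out <- file.path(tempdir(), "suite_out")
  suite <- generate_multisite_suite(1, 2,
                                    base = phantom_spec(shape = c(16, 16, 16)),
                                    seed = 9)
  manifest <- write_phantom_suite(suite, out)
  expect_true(file.exists(manifest))
  back <- read_volume(file.path(out, "sub1_site2_input.nii.gz"))
  expect_lt(max(abs(back$data - suite$cases[[2]]$input$data)), 1e-9)
  parsed <- jsonlite::read_json(manifest)
  expect_length(parsed$cases, 2L)
  unlink(out, recursive = TRUE)
})
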