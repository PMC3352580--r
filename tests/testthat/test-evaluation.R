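vols_pair <- function(seed, delta = NULL) {
  set.seed(seed)
  a <- intensity_volume(array(runif(216, 0, 100), c(6, 6, 6)))
  b <- if (is.null(delta))
    intensity_volume(array(runif(216, 0, 100), c(6, 6, 6)))
  else intensity_volume(pmin(pmax(a$data + delta, 0), 100))
  list(a = a, b = b)
}

test_that("MAE matches closed forms and a direct loop", {
  p <- vols_pair(1)
  every <- voxel_set(array(TRUE, c(6, 6, 6)), "all")
  expect_equal(mean_absolute_error(p$a, p$a, every), 0)

  shifted <- intensity_volume(p$a$data - 7)   # constant offset, in range
  expect_equal(mean_absolute_error(shifted, p$a, every), 7)

  two <- array(FALSE, c(6, 6, 6)); two[1:2, 1, 1] <- TRUE
  x <- p$a; x$data[1, 1, 1] <- 30; x$data[2, 1, 1] <- 50
  y <- p$a; y$data[1, 1, 1] <- 40; y$data[2, 1, 1] <- 70
  expect_equal(mean_absolute_error(x, y, voxel_set(two, "pair")), 15)

  # direct-loop oracle on a random mask
  set.seed(8)
  m <- array(runif(216) < 0.3, c(6, 6, 6))
  acc <- 0; n <- 0
  for (i in seq_along(m)) if (m[i]) {
    acc <- acc + abs(p$a$data[i] - p$b$data[i]); n <- n + 1
  }
  expect_equal(mean_absolute_error(p$a, p$b, voxel_set(m, "rand")), acc / n)
  expect_error(mean_absolute_error(p$a, p$b, array(FALSE, c(6, 6, 6))),
               "empty")
})

test_that("MAE is symmetric and satisfies the triangle inequality", {
  p <- vols_pair(2); q <- vols_pair(3)
  every <- voxel_set(array(TRUE, c(6, 6, 6)), "all")
  expect_equal(mean_absolute_error(p$a, p$b, every),
               mean_absolute_error(p$b, p$a, every))
  ab <- mean_absolute_error(p$a, p$b, every)
  bc <- mean_absolute_error(p$b, q$a, every)
  ac <- mean_absolute_error(p$a, q$a, every)
  expect_lte(ac, ab + bc + 1e-12)
})

test_that("paired comparison matches the closed-form t statistic", {
  expect_equal(compare_paired(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2L, p = 1))
  a <- c(5, 7, 9); b <- c(4, 5, 6)      # differences 1, 2, 3
  got <- compare_paired(a, b)
  t_exp <- 2 / (1 / sqrt(3))            # mean/ (sd/sqrt(n))
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p, 2 * pt(-t_exp, df = 2), tolerance = 1e-12)

  rev <- compare_paired(b, a)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  expect_error(compare_paired(1, 2), "at least 2")
  expect_error(compare_paired(1:3, 1:4), "length mismatch")
})

test_that("worsened fraction counts strict regressions in percent", {
  expect_equal(worsened_fraction(c(1, 2, 3), c(2, 3, 4)), 0)
  expect_equal(worsened_fraction(c(rep(1, 19), 5), c(rep(2, 19), 4)), 5)
  set.seed(4)
  std <- runif(50); orig <- runif(50)
  n_worse <- 0
  for (i in 1:50) if (std[i] > orig[i]) n_worse <- n_worse + 1
  expect_equal(worsened_fraction(std, orig), 100 * n_worse / 50)
  expect_error(worsened_fraction(1:3, 1:2), "length mismatch")
})

test_that("batch evaluation aggregates per-case MAE and is order-invariant", {
  suite <- generate_multisite_suite(n_subjects = 1, n_sites = 2,
                                    base = phantom_spec(shape = c(24, 24, 24)),
                                    seed = 5)
  cases <- lapply(suite$cases, function(cs) {
    list(id = cs$id, standard = cs$standard, masks = cs$masks,
         outputs = list(Original = cs$input,
                        Copy = cs$input))   # trivially tied condition
  })
  rep <- evaluate_batch(cases)
  expect_identical(nrow(rep$mae), 2L * 3L * 2L)  # cases x sets x conditions
  expect_setequal(rep$voxel_sets, c("FRG", "WM", "GM"))

  # tied conditions: every paired test is t = 0, p = 1; worsened 0%
  expect_true(all(rep$tests$t == 0) && all(rep$tests$p == 1))
  expect_true(all(rep$worsened$worsened_pct == 0))

  # totals equal a per-case recomputation
  cs1 <- suite$cases[[1]]
  expect_equal(
    rep$mae$mae[rep$mae$case == cs1$id & rep$mae$voxel_set == "WM" &
                rep$mae$condition == "Original"],
    mean_absolute_error(cs1$input, cs1$standard,
                        voxel_set(cs1$masks$wm, "WM")))

  rep_perm <- evaluate_batch(rev(cases))
  a <- rep$mae[order(rep$mae$case, rep$mae$voxel_set, rep$mae$condition), ]
  b <- rep_perm$mae[order(rep_perm$mae$case, rep_perm$mae$voxel_set,
                          rep_perm$mae$condition), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("reports can be written as CSV plus JSON summary", {
  suite <- generate_multisite_suite(n_subjects = 1, n_sites = 1,
                                    base = phantom_spec(shape = c(24, 24, 24)),
                                    seed = 6)
  cs <- suite$cases[[1]]
  rep <- evaluate_batch(list(list(id = cs$id, standard = cs$standard,
                                  masks = cs$masks,
                                  outputs = list(Original = cs$input))))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_mae_report(rep, csv, js)
  expect_identical(nrow(utils::read.csv(csv)), 3L)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed$median_mae, 3L)
})
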