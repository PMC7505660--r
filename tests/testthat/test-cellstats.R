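make_records <- function(n, yfp = 1000, mch = 500, area = 2, bg_y = 100,
                         bg_m = 80, af_y = 10, af_m = 8) {
  data.frame(yfp_pixel_mean = rep(yfp, n), mcherry_pixel_mean = rep(mch, n),
             area = rep(area, n), frame_background_yfp = bg_y,
             frame_background_mcherry = bg_m, autofluor_yfp = af_y,
             autofluor_mcherry = af_m)
}

test_that("corrections apply in order: background, autofluorescence, crosstalk, area", {
  cc <- pipeline_constants(1, 1, gamma_cross = 0.0025)
  # corrected YFP pixel = 1000; mCherry pixel after bg+af = 100
  rec <- make_records(1, yfp = 1000 + 100 + 10, mch = 100 + 80 + 8,
                      area = 1, bg_y = 100, bg_m = 80, af_y = 10, af_m = 8)
  out <- correct_cells(rec, cc)
  expect_equal(out$mcherry_total, 100 - 0.0025 * 1000)  # 97.5
  expect_equal(out$yfp_total, 1000)
  # area multiplies totals
  rec$area <- 3
  out3 <- correct_cells(rec, cc)
  expect_equal(out3$mcherry_total, 3 * 97.5)
  # no YFP signal means no crosstalk correction
  rec0 <- make_records(1, yfp = 110, mch = 188, area = 1)
  expect_equal(correct_cells(rec0, cc)$mcherry_total, 100)
  # an all-background record corrects to zero
  bgrec <- make_records(1, yfp = 110, mch = 88, area = 5)
  z <- correct_cells(bgrec, cc)
  expect_equal(z$yfp_total, 0)
  expect_equal(z$mcherry_total, 0)
})

test_that("crosstalk injection and correction round-trip exactly", {
  set.seed(2)
  n <- 40
  sig_y <- stats::runif(n, 0, 2000)
  sig_m <- stats::runif(n, 0, 800)
  gx <- 0.004
  rec <- data.frame(
    yfp_pixel_mean = sig_y + 120 + 15,
    mcherry_pixel_mean = sig_m + 90 + 12 + gx * sig_y,
    area = stats::runif(n, 1, 4),
    frame_background_yfp = 120, frame_background_mcherry = 90,
    autofluor_yfp = 15, autofluor_mcherry = 12)
  out <- correct_cells(rec, pipeline_constants(1, 1, gamma_cross = gx))
  expect_equal(out$yfp_total, sig_y * rec$area, tolerance = 1e-12)
  expect_equal(out$mcherry_total, sig_m * rec$area, tolerance = 1e-10)
})

test_that("fold-changes are scale invariant and need positive baselines", {
  set.seed(3)
  rec <- make_records(20)
  rec$yfp_pixel_mean <- rec$yfp_pixel_mean * stats::runif(20, 0.5, 1.5)
  cc <- pipeline_constants(1800, 900)
  fc1 <- per_cell_fold_change(correct_cells(rec, cc), cc)
  # multiply every fluorescence value and baseline by c
  c0 <- 7.3
  rec2 <- rec
  for (col in c("yfp_pixel_mean", "mcherry_pixel_mean",
                "frame_background_yfp", "frame_background_mcherry",
                "autofluor_yfp", "autofluor_mcherry"))
    rec2[[col]] <- rec2[[col]] * c0
  cc2 <- pipeline_constants(1800 * c0, 900 * c0)
  fc2 <- per_cell_fold_change(correct_cells(rec2, cc2), cc2)
  expect_equal(fc1$fc_tf, fc2$fc_tf, tolerance = 1e-12)
  expect_equal(fc1$fc_target, fc2$fc_target, tolerance = 1e-12)
  cc0 <- pipeline_constants(0, 900)
  expect_error(per_cell_fold_change(correct_cells(rec, cc), cc0),
               "positive")
  # a cell exactly at the constitutive mean has unit fold-change
  one <- data.frame(yfp_total = 1800, mcherry_total = 900)
  expect_equal(per_cell_fold_change(one, cc),
               data.frame(fc_tf = 1, fc_target = 1, asymmetry = 0))
})

test_that("binning drops sparse bins and bootstraps the survivors", {
  set.seed(4)
  # two well-separated clusters: 60 cells and 49 cells
  fc <- data.frame(fc_tf = c(stats::rnorm(60, 0.2, 0.005),
                             stats::rnorm(49, 0.8, 0.005)))
  fc$fc_target <- fc$fc_tf + 0.05
  fc$asymmetry <- fc$fc_target - fc$fc_tf
  cc <- pipeline_constants(1, 1, min_bin_count = 50, n_boot = 200,
                           bin_spec = list(type = "width", n_bins = 4),
                           seed = 9)
  curve <- bin_bootstrap(fc, cc)
  expect_equal(nrow(curve), 1L)  # the 49-cell cluster is excluded
  expect_equal(curve$count, 60)
  expect_lt(abs(curve$fc_tf_mean - 0.2), 4 * 0.005 / sqrt(60))
  # bootstrap sd consistent with the plain standard error
  expect_lt(curve$fc_tf_sd, 4 * 0.005 / sqrt(60) + 1e-3)
  # identical cells have zero bootstrap spread
  fc0 <- data.frame(fc_tf = rep(0.4, 80), fc_target = rep(0.5, 80))
  fc0$asymmetry <- 0.1
  curve0 <- bin_bootstrap(fc0, cc)
  expect_equal(curve0$fc_tf_sd, 0)
  expect_equal(curve0$fc_target_sd, 0)
  # deterministic under a seed
  expect_equal(bin_bootstrap(fc, cc), bin_bootstrap(fc, cc))
})

test_that("asymmetry histograms center symmetric cohorts at zero", {
  set.seed(5)
  fc <- data.frame(fc_tf = stats::rnorm(500, 0.5, 0.1),
                   fc_target = stats::rnorm(500, 0.5, 0.1))
  fc$asymmetry <- fc$fc_target - fc$fc_tf
  h <- asymmetry_histogram(fc, bin_width = 0.05)
  expect_equal(sum(h$counts), 500)
  se_med <- 1.25 * stats::sd(fc$asymmetry) / sqrt(500)
  expect_lt(abs(unname(h$quantiles["50%"])), 2 * se_med + 0.02)
  expect_true(any(h$counts == 0) || length(h$counts) > 0)
  expect_equal(h$frac_positive, mean(fc$asymmetry > 0))
})
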