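test_that("zero-noise cohorts invert exactly through the pipeline", {
  rs <- small_rates(alpha = 0.03, n_decoy = 10L)
  nm <- noise_model_exact(seed = 21)
  reg <- generate_cells(rs, 150, nm)
  const <- generate_constitutive(rs, 150, nm)
  res <- analyze_cohorts(reg, const, min_bin_count = 10)
  fc_tf_true <- mean(reg$truth$tf_counts) / mean(const$truth$tf_counts)
  fc_y_true <- mean(reg$truth$y_counts) / mean(const$truth$y_counts)
  expect_equal(res$fc_tf, fc_tf_true, tolerance = 1e-9)
  expect_equal(res$fc_target, fc_y_true, tolerance = 1e-9)
})

test_that("generation is reproducible and validates inputs", {
  rs <- small_rates(alpha = 0.02)
  nm <- noise_model(seed = 33)
  a <- generate_cells(rs, 50, nm)
  b <- generate_cells(rs, 50, nm)
  expect_identical(a$records, b$records)
  expect_error(generate_cells(rs, 0, nm), "n_cells")
  expect_error(generate_constitutive(rs, 0, nm), "n_cells")
})

test_that("noisy cohorts recover the true fold-change within bootstrap error", {
  rs <- small_rates(alpha = 0.03, n_decoy = 30L)
  nm <- noise_model(seed = 7, cv = 0.05)
  reg <- generate_cells(rs, 400, nm)
  nm2 <- noise_model(seed = 8, cv = 0.05)
  const <- generate_constitutive(rs, 400, nm2)
  res <- analyze_cohorts(reg, const, min_bin_count = 20, n_boot = 300,
                         seed = 1)
  fc_tf_true <- mean(reg$truth$tf_counts) / mean(const$truth$tf_counts)
  fc_y_true <- mean(reg$truth$y_counts) / mean(const$truth$y_counts)
  # cohort-level recovery despite background, autofluorescence, crosstalk,
  # area scaling and measurement noise
  boot_sd_tf <- stats::sd(res$fc$fc_tf) / sqrt(nrow(res$fc))
  boot_sd_y <- stats::sd(res$fc$fc_target) / sqrt(nrow(res$fc))
  expect_lt(abs(res$fc_tf - fc_tf_true), 4 * boot_sd_tf + 0.01)
  expect_lt(abs(res$fc_target - fc_y_true), 4 * boot_sd_y + 0.01)
})

test_that("constitutive cohorts match the birth-death closed form", {
  rs <- small_rates(alpha = 0.05)
  nm <- noise_model_exact(seed = 11)
  const <- generate_constitutive(rs, 300, nm)
  cc <- pipeline_constants(1, 1, gamma_cross = 0)
  corr <- correct_cells(const$records, cc)
  expected_y <- nm$scale_yfp * rs$beta / rs$gamma_m * rs$alpha / rs$gamma
  se <- stats::sd(corr$yfp_total) / sqrt(nrow(corr))
  expect_lt(abs(mean(corr$yfp_total) - expected_y), 4 * se)
})

test_that("plasmid copy-number noise spreads the decoy count across cells", {
  rs <- small_rates(alpha = 0.02, n_decoy = 8L)
  nm <- noise_model(seed = 13, plasmid = "poisson")
  reg <- generate_cells(rs, 60, nm)
  expect_equal(nrow(reg$records), 60)
  expect_true(all(is.finite(reg$records$mcherry_pixel_mean)))
})

test_that("strongly titrated fast-growth cohorts skew to positive asymmetry", {
  rs <- preset("O1", "RDM", n_decoy = 300L)
  reg <- generate_cells(rs, 250, noise_model(seed = 4))
  const <- generate_constitutive(rs, 250, noise_model(seed = 14))
  res <- analyze_cohorts(reg, const, min_bin_count = 20, n_boot = 100,
                         seed = 1)
  h <- asymmetry_histogram(res$fc)
  expect_gt(h$frac_positive, 0.5)
  expect_gt(unname(h$quantiles["50%"]), 0)
  expect_gt(res$fc_target - res$fc_tf, 0)
})
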