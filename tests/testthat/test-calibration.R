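test_that("presets return the published rate table", {
  rs <- preset("O1", "Glucose")
  expect_equal(rs$kon, 0.0015)
  expect_equal(rs$koff_tf, 0.00149)
  expect_equal(rs$gamma, log(2) / (55 * 60))
  expect_equal(rs$beta, 0.1)
  expect_equal(rs$gamma_m, 0.033)
  expect_equal(rs$kp, 1.38)
  expect_equal(rs$km, 2e-6)
  expect_equal(rs$koff_decoy, 0.00042)  # decoy arrays use Oid
  oid <- preset("Oid", "RDM")
  expect_equal(oid$koff_tf, 0.00042)
  expect_equal(oid$gamma, log(2) / (25 * 60))
  expect_equal(preset("O2", "Acetate")$koff_tf, 0.0167)
  expect_equal(preset("O1", "Glycerol")$gamma, log(2) / (125 * 60))
  expect_error(preset("O3", "Glucose"), "unknown operator")
  expect_error(preset("O1", "LB"), "unknown medium")
  expect_error(preset("O1", "Glucose", tag = "AAV"), "unknown tag")
  expect_equal(attr(preset("O1", "Glucose", tag = "LAA"),
                    "tag_rate_per_min_per_enzyme"), 0.21)
})

test_that("the minimal-model mapping preserves the constitutive level", {
  rs <- small_rates(alpha = 0.05)
  cfg <- as_cme_config(rs)
  # dimers produced at half the monomer rate; constitutive binder count is
  # half the monomer count
  monomers <- rs$beta / rs$gamma_m * rs$alpha / rs$gamma
  expect_equal(cfg$alpha_eff / cfg$gamma, monomers / 2)
  expect_equal(cfg$koff, rs$koff_tf)
  expect_equal(cfg$n_decoy, rs$n_decoy)
})

test_that("fitting recovers the generating grid point from a clean curve", {
  grid <- fit_grid(kon_values = c(0.0015, 0.003), beta_values = 0.1,
                   gamma_m_values = 1 / 60, tf0_values = c(80, 160))
  template <- small_rates()
  truth <- template
  truth$kon <- 0.003
  truth$gamma_m <- 1 / 60
  truth$alpha <- 160 * truth$gamma * truth$gamma_m / truth$beta
  decoys <- c(0, 10, 25)
  fc <- asymreg:::model_curve(truth, decoys, engine = "cme")
  curve <- data.frame(n_decoy = decoys, fc_tf = fc["fc_tf", ],
                      fc_tf_sd = 0.02, fc_target = fc["fc_target", ],
                      fc_target_sd = 0.02)
  fit <- fit_rates(curve, grid, template)
  expect_equal(fit$best$kon, truth$kon)
  expect_equal(fit$best$alpha, truth$alpha)
  expect_equal(fit$objective, 0, tolerance = 1e-12)
  expect_equal(which.min(fit$table$objective), fit$best_index)
})

test_that("fit input validation rejects degenerate curves", {
  grid <- fit_grid(kon_values = 0.0015, beta_values = 0.1,
                   gamma_m_values = 1 / 60, tf0_values = 80)
  curve <- data.frame(n_decoy = c(0, 10, 25), fc_tf = c(0.1, 0.2, 0.3),
                      fc_tf_sd = c(0.01, 0, 0.01),
                      fc_target = c(0.1, 0.2, 0.3),
                      fc_target_sd = 0.01)
  expect_error(fit_rates(curve, grid, small_rates()), "positive")
  expect_error(fit_rates(curve[1:2, ], grid, small_rates()),
               "3 decoy levels")
})
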