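test_that("thermodynamic fold-change follows the scaling relation", {
  expect_equal(thermo_fold_change(0, 0.0015, 0.00149, 2.1e-4), 1)
  g <- glucose_gamma
  # R* = 1 gives half repression
  r_half <- (0.00149 + g) / 0.0015
  expect_equal(thermo_fold_change(r_half, 0.0015, 0.00149, g), 0.5)
  expect_equal(thermo_fold_change(10, 0.0015, 0.00149, glucose_gamma),
               1 / (1 + 10 * 0.0015 / (0.00149 + glucose_gamma)))
})

test_that("naive mass-action model predicts strictly symmetric regulation", {
  grid <- expand.grid(alpha = c(0.02, 0.1), koff = c(0.00149, 0.0167),
                      n_decoy = c(0L, 50L, 300L))
  for (i in seq_len(nrow(grid))) {
    rs <- small_rates(alpha = grid$alpha[i], n_decoy = grid$n_decoy[i],
                      koff_tf = grid$koff[i])
    s <- naive_steady_state(rs)
    expect_equal(s$asymmetry, 0, tolerance = 1e-12)
    # occupancy balance is consistent with the thermodynamic relation
    g_tf <- rs$gamma + rs$gamma_tag_tf
    expect_equal(s$fc_tf,
                 thermo_fold_change(s$r_free, rs$kon, rs$koff_tf, g_tf),
                 tolerance = 1e-9)
  }
})

test_that("naive model reduces to constitutive means without binding", {
  rs <- small_rates()
  rs$kon <- 0
  s <- naive_steady_state(rs)
  expect_equal(s$fc_tf, 1)
  expect_equal(s$fc_target, 1)
  expect_equal(s$y, rs$beta / rs$gamma_m * rs$alpha / rs$gamma,
               tolerance = 1e-9)
  expect_equal(s$tf_total, rs$beta / rs$gamma_m * rs$alpha / rs$gamma,
               tolerance = 1e-6)
})

test_that("different operators break symmetry in the naive model too", {
  rs <- small_rates(koff_target = 0.0167)  # weaker target site
  s <- naive_steady_state(rs)
  expect_gt(s$fc_target, s$fc_tf)
})

test_that("state partitioning predicts asymmetry where the naive model cannot", {
  cfg <- small_cfg(alpha_eff = 0.01)
  s <- partitioned_steady_state(cfg)
  expect_equal(sum(s$p_state), 1, tolerance = 1e-9)
  expect_true(all(s$n_state >= 0))
  expect_gt(s$asymmetry, 0)
  expect_equal(s$asymmetry, s$fc_target - s$fc_tf, tolerance = 1e-12)
  # the closure is not the full stochastic answer: asymmetry differs from
  # the master equation, but its sign agrees
  cme <- cme_steady_state(cfg)
  expect_gt(abs(s$asymmetry - cme$asymmetry), 1e-6)
  expect_equal(sign(s$asymmetry), sign(cme$asymmetry))
})

test_that("partitioned asymmetry sign tracks the master equation in a sweep", {
  set.seed(101)
  for (i in 1:6) {
    cfg <- small_cfg(alpha_eff = 10 ^ stats::runif(1, -2.5, -1.5),
                     koff = 10 ^ stats::runif(1, -3, -1.5),
                     gamma = 10 ^ stats::runif(1, -4, -3))
    part <- partitioned_steady_state(cfg)
    cme <- cme_steady_state(cfg)
    expect_equal(sign(part$asymmetry), sign(cme$asymmetry))
  }
})

test_that("partitioned model is trivial without binding", {
  cfg <- cme_config(alpha_eff = 0.01, kon = 0, koff = 0.00149,
                    gamma = 1e-4)
  s <- partitioned_steady_state(cfg)
  expect_equal(s$p_state, c(1, 0, 0, 0))
  expect_equal(s$asymmetry, 0)
  expect_equal(s$n_state[1], cfg$alpha_eff / cfg$gamma)
})
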