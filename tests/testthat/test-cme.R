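test_that("the generator conserves probability and sizes its state space", {
  cfg <- small_cfg(n_max = 40)
  gen <- build_generator(cfg)
  expect_equal(prod(gen$dims), 4 * 41)
  expect_lt(max(abs(Matrix::colSums(gen$A))), 1e-12)
  cfgd <- small_cfg(alpha_eff = 0.005, n_decoy = 6L, n_max = 40)
  gend <- build_generator(cfgd, d_min = 0L)
  expect_equal(prod(gend$dims), 4 * 7 * 41)
  expect_lt(max(abs(Matrix::colSums(gend$A))), 1e-12)
})

test_that("no production collapses onto the empty absorbing state", {
  cfg <- cme_config(alpha_eff = 0, kon = 0.001, koff = 0.01,
                    gamma = 1e-3, n_max = 15)
  s <- cme_steady_state(cfg)
  expect_equal(s$p_state, c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(s$mean_r_free, 0, tolerance = 1e-12)
})

test_that("without binding the free-TF marginal is Poisson", {
  cfg <- cme_config(alpha_eff = 8e-4, kon = 0, koff = 0.00149,
                    gamma = 1e-4)
  s <- cme_steady_state(cfg)
  lambda <- cfg$alpha_eff / cfg$gamma
  marg <- tapply(s$dist$p, s$dist$n, sum)
  nn <- as.integer(names(marg))
  expect_equal(as.numeric(marg[nn <= 30]),
               stats::dpois(nn[nn <= 30], lambda), tolerance = 1e-8)
  expect_equal(s$fc_tf, 1)
  expect_equal(s$asymmetry, 0)
})

test_that("the sparse solver matches an independent dense enumeration", {
  cfg <- small_cfg(alpha_eff = 0.004, n_max = 80)
  s <- cme_steady_state(cfg)
  oracle <- dense_cme_oracle(cfg$alpha_eff, cfg$kon, cfg$koff, cfg$gamma,
                             n_max = 80)
  expect_equal(s$dist$p, oracle$p, tolerance = 1e-10)
  p_state_oracle <- vapply(1:4, function(g) sum(oracle$p[oracle$g == g]),
                           numeric(1))
  expect_equal(s$p_state, p_state_oracle, tolerance = 1e-10)
})

test_that("summaries satisfy the exact occupancy and concentration identities", {
  for (cfg in list(small_cfg(alpha_eff = 0.01),
                   small_cfg(alpha_eff = 0.05, koff = 0.01),
                   small_cfg(alpha_eff = 0.003, n_decoy = 10L))) {
    s <- cme_steady_state(cfg)
    expect_equal(sum(s$p_state), 1, tolerance = 1e-10)
    expect_equal(s$asymmetry, s$p_state[3] - s$p_state[2],
                 tolerance = 1e-12)
    expect_equal(s$asymmetry,
                 cfg$kon / (cfg$koff + cfg$gamma) *
                   (s$n_state[2] - s$n_state[3]),
                 tolerance = 1e-8)
    # mechanism: target-bound state holds more TF than TF-gene-bound state
    expect_gt(s$n_state[2] / s$p_state[2], s$n_state[3] / s$p_state[3])
    expect_gt(s$p_state[3], s$p_state[2])
  }
})

test_that("summaries are insensitive to the truncation once converged", {
  cfg <- small_cfg(alpha_eff = 0.008)
  s1 <- cme_steady_state(cfg)
  cfg2 <- small_cfg(alpha_eff = 0.008, n_max = 2L * s1$n_max)
  s2 <- cme_steady_state(cfg2)
  expect_lt(abs(s1$fc_tf - s2$fc_tf), 1e-8)
  expect_lt(abs(s1$fc_target - s2$fc_target), 1e-8)
  expect_lt(abs(s1$mean_r_free - s2$mean_r_free), 1e-6)
})

test_that("the decoy window reproduces the full-axis solution", {
  cfg <- small_cfg(alpha_eff = 0.02, n_decoy = 40L)
  gen_full <- build_generator(cfg, d_min = 0L)
  full <- cme_summaries(stationary_distribution(gen_full), cfg)
  auto <- cme_steady_state(cfg)
  expect_equal(auto$fc_tf, full$fc_tf, tolerance = 1e-9)
  expect_equal(auto$asymmetry, full$asymmetry, tolerance = 1e-9)
  expect_equal(auto$mean_bound_decoy, full$mean_bound_decoy,
               tolerance = 1e-7)
})
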