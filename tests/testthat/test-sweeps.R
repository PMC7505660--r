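test_that("decoy titration raises both fold-changes and depletes free TF", {
  rs <- small_rates(alpha = 0.02)
  tab <- decoy_sweep(rs, c(0, 10, 30, 80), engine = "cme")
  expect_equal(tab$n_decoy, c(0, 10, 30, 80))
  expect_true(all(diff(tab$fc_tf) > 0))
  expect_true(all(diff(tab$fc_target) > 0))
  expect_true(all(diff(tab$mean_r_free) < 0))
  expect_true(all(tab$fc_target >= tab$fc_tf))
  # zero decoys reproduces the plain autoregulation summary
  plain <- cme_steady_state(as_cme_config(small_rates(alpha = 0.02)))
  expect_equal(tab$fc_tf[1], plain$fc_tf, tolerance = 1e-9)
  expect_error(decoy_sweep(rs, c(10, 0), engine = "cme"), "sorted")
})

test_that("max_asymmetry locates the decoy optimum and is zero without binding", {
  rs <- small_rates(alpha = 0.02)
  res <- max_asymmetry(rs, c(0, 20, 60), engine = "cme")
  expect_equal(res$value, max(res$table$asymmetry))
  expect_gt(res$value, 0)
  rs0 <- rs
  rs0$kon <- 0
  res0 <- max_asymmetry(rs0, c(0, 20, 60), engine = "cme")
  expect_equal(res0$value, 0, tolerance = 1e-10)
})

test_that("degradation scans expose the interior asymmetry maximum", {
  scan <- degradation_scan(c(3, 30, 500), alpha_eff = 0.02,
                           decoy_grid = c(0, 20, 60))
  expect_equal(nrow(scan), 3)
  expect_true(all(scan$max_asymmetry >= 0))
  peak <- attr(scan, "peak_half_life_min")
  expect_true(peak %in% scan$half_life_min)
})

test_that("growth scan orders asymmetry by growth rate for strong operators", {
  gs <- growth_scan("O1", media = c("RDM", "Acetate"),
                    decoy_counts = c(0, 20, 60), engine = "cme",
                    alpha = 0.02)
  mx <- attr(gs, "max_asymmetry")
  expect_named(mx, c("RDM", "Acetate"))
  # faster growth (larger gamma) shows more asymmetry
  expect_gt(mx[["RDM"]], mx[["Acetate"]])
})

test_that("the affinity-degradation phase diagram orders by binding strength", {
  hm <- asymmetry_heatmap(affinity_grid = c(0.00149, 0.0167),
                          gamma_grid = log(2) / (60 * c(6, 60)),
                          decoy_grid = c(0, 20, 60), alpha_eff = 0.02)
  expect_equal(dim(hm$max_asymmetry), c(2L, 2L))
  expect_true(all(hm$max_asymmetry >= -1e-12 & hm$max_asymmetry <= 1))
  # the weak-affinity row is flat and near zero; strong binding dominates
  expect_true(all(hm$max_asymmetry[2, ] < 0.02))
  expect_true(all(hm$max_asymmetry[1, ] > hm$max_asymmetry[2, ]))
})

test_that("growth media order asymmetry by operator strength", {
  media <- c("RDM", "Glucose", "Glycerol", "Acetate")
  weak <- growth_scan("O2", media = media, decoy_counts = c(0, 20, 60),
                      engine = "cme", alpha = 0.02)
  strong <- growth_scan("Oid", media = media, decoy_counts = c(0, 20, 60),
                        engine = "cme", alpha = 0.02)
  # the weak operator is essentially symmetric in every medium
  expect_true(all(attr(weak, "max_asymmetry") < 0.02))
  # the strongest operator is asymmetric in every medium
  expect_true(all(attr(strong, "max_asymmetry") > 0.02))
})
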