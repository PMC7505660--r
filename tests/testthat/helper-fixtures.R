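# Shared fixtures and independent oracles.

glucose_gamma <- log(2) / (55 * 60)

# modest-scale minimal-model configuration: fast to solve, strong feedback
small_cfg <- function(alpha_eff = 0.01, kon = 0.0015, koff = 0.00149,
                      gamma = glucose_gamma, ...) {
  cme_config(alpha_eff, kon, koff, gamma, ...)
}

# scaled-down full-model rate set (constitutive TF ~ alpha/gamma * beta/gm)
small_rates <- function(alpha = 0.02, n_decoy = 0L, koff_tf = 0.00149,
                        koff_target = koff_tf, ...) {
  rate_set(kon = 0.0015, koff_tf = koff_tf, koff_target = koff_target,
           beta = 0.1, alpha = alpha, gamma_m = 0.033,
           gamma = glucose_gamma, n_decoy = n_decoy, ...)
}

# Independent dense-matrix master-equation oracle for the decoy-free
# minimal model: explicit per-state loops, no shared code with
# build_generator().  States indexed (g, n) with g in 1..4, n in 0..n_max.
dense_cme_oracle <- function(alpha_eff, kon, koff, gamma, n_max) {
  id <- function(g, n) g + 4L * n
  S <- 4L * (n_max + 1L)
  A <- matrix(0, S, S)
  put <- function(from, to, rate) {
    A[to, from] <<- A[to, from] + rate
    A[from, from] <<- A[from, from] - rate
  }
  for (n in 0:n_max) {
    for (g in 1:4) {
      i <- id(g, n)
      if (g %in% c(1, 2) && n < n_max) put(i, id(g, n + 1L), alpha_eff)
      if (n > 0) put(i, id(g, n - 1L), gamma * n)
      if (n > 0) {
        if (g == 1) { put(i, id(2L, n - 1L), kon * n)
                      put(i, id(3L, n - 1L), kon * n) }
        if (g == 2) put(i, id(4L, n - 1L), kon * n)
        if (g == 3) put(i, id(4L, n - 1L), kon * n)
      }
      np <- min(n + 1L, n_max)
      if (g == 2) { put(i, id(1L, np), koff); put(i, id(1L, n), gamma) }
      if (g == 3) { put(i, id(1L, np), koff); put(i, id(1L, n), gamma) }
      if (g == 4) { put(i, id(2L, np), koff); put(i, id(2L, n), gamma)
                    put(i, id(3L, np), koff); put(i, id(3L, n), gamma) }
    }
  }
  # null space via dense solve with normalization row appended
  M <- rbind(A[-1, ], rep(1, S))
  b <- c(numeric(S - 1L), 1)
  p <- solve(M, b)
  list(p = p, g = rep(1:4, n_max + 1L), n = rep(0:n_max, each = 4L))
}

# random valid full-model state (respects occupancy bounds)
random_state <- function(network, max_count = 50) {
  s <- c(sample(0:max_count, 4, replace = TRUE),  # m_tf m_target x r_free
         sample(0:1, 2, replace = TRUE),          # b_tf b_target
         sample(0:max(0, network$n_decoy), 1),    # b_decoy
         sample(0:max_count, 1))                  # y
  names(s) <- c("m_tf", "m_target", "x", "r_free", "b_tf", "b_target",
                "b_decoy", "y")
  s
}
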