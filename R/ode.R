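#' Thermodynamic fold-change of simple repression
#'
#' `1 / (1 + R*)` with `R* = r_free * kon / (koff + gamma)`: the mean-field
#' prediction for how strongly a promoter with one repressor site is turned
#' down, given the free repressor number.  A bound repressor leaves its site
#' by unbinding or by degradation, hence the `koff + gamma` denominator.
#'
#' @param r_free Free repressor (dimer) count.
#' @param kon Binding rate per free TF per second.
#' @param koff Site unbinding rate (s^-1).
#' @param gamma Repressor decay rate (s^-1).
#' @return Fold-change in `[0, 1]`.
#' @export
thermo_fold_change <- function(r_free, kon, koff, gamma) {
  stopifnot(all(r_free >= 0), kon >= 0, koff >= 0, gamma >= 0)
  1 / (1 + r_free * kon / (koff + gamma))
}

#' Naive deterministic steady state of the full model
#'
#' Mass-action mean-field version of the stochastic network: transcription
#' `beta * (1 - occupancy)`, translation, dimerization at `(kp/2) x^2`,
#' per-site occupancy balance `kon * r * (1 - o) = (koff + gamma_tf) * o`,
#' decoy balance over `n_decoy` sites, and first-order decay of every
#' species.  Because each site's occupancy depends only on the shared free
#' dimer concentration, identical operators always receive identical
#' fold-changes: this model is structurally blind to regulatory asymmetry.
#'
#' The fixed point is found by reducing the system to a single scalar
#' balance in the free dimer concentration `r` (all other species follow
#' algebraically) and root-finding; the residual of the full system at the
#' solution must be below `tol`.
#'
#' @param rates A [rate_set()].
#' @param tol Residual tolerance (default 1e-10).
#' @return A `deterministic_summary`: steady-state values of all species,
#'   `r_free`, fold-changes and asymmetry (identically 0 for identical
#'   operators).
#' @export
naive_steady_state <- function(rates, tol = 1e-10) {
  validate_rate_set(rates)
  g_tf <- rates$gamma + rates$gamma_tag_tf
  k_tf <- rates$kon / (rates$koff_tf + g_tf)
  k_tar <- rates$kon / (rates$koff_target + g_tf)
  k_dec <- rates$kon / (rates$koff_decoy + g_tf)
  N <- rates$n_decoy
  occ <- function(k, r) k * r / (1 + k * r)
  # monomer count given r: alpha*m_tf - g_tf*x - kp*x^2 + 2*km*r = 0
  x_of_r <- function(r) {
    m_tf <- rates$beta * (1 - occ(k_tf, r)) / rates$gamma_m
    cc <- rates$alpha * m_tf + 2 * rates$km * r
    if (rates$kp == 0) return(cc / g_tf)
    (-g_tf + sqrt(g_tf^2 + 4 * rates$kp * cc)) / (2 * rates$kp)
  }
  # net production of free dimers at steady state given r
  resid_r <- function(r) {
    x <- x_of_r(r)
    o_tf <- occ(k_tf, r); o_tar <- occ(k_tar, r); dbar <- N * occ(k_dec, r)
    rates$kp / 2 * x^2 - rates$km * r - g_tf * r -
      rates$kon * r * ((1 - o_tf) + (1 - o_tar) + (N - dbar)) +
      rates$koff_tf * o_tf + rates$koff_target * o_tar +
      rates$koff_decoy * dbar
  }
  # resid_r is positive at 0 (pure production) and negative beyond the
  # constitutive dimer level, so a bracketed root always exists
  r_hi <- rates$beta / rates$gamma_m * rates$alpha / (2 * g_tf) + 1
  r <- stats::uniroot(resid_r, c(0, r_hi), tol = 1e-14,
                      extendInt = "downX")$root
  o_tf <- occ(k_tf, r); o_tar <- occ(k_tar, r); dbar <- N * occ(k_dec, r)
  m_tf <- rates$beta * (1 - o_tf) / rates$gamma_m
  m_tar <- rates$beta * (1 - o_tar) / rates$gamma_m
  x <- x_of_r(r)
  y <- rates$alpha * m_tar / rates$gamma
  res <- abs(resid_r(r))
  scale <- max(1, rates$beta / rates$gamma_m * rates$alpha)
  if (res / scale > tol)
    stop(sprintf("naive steady-state residual %.3g exceeds tol", res),
         call. = FALSE)
  structure(list(
    m_tf = m_tf, m_target = m_tar, x = x, r_free = r,
    b_tf = o_tf, b_target = o_tar, b_decoy = dbar, y = y,
    fc_tf = 1 - o_tf, fc_target = 1 - o_tar,
    asymmetry = (1 - o_tar) - (1 - o_tf),
    tf_total = x + 2 * (r + o_tf + o_tar + dbar)),
    class = "deterministic_summary")
}

#' @export
print.deterministic_summary <- function(x, ...) {
  cat(sprintf(
    "<deterministic_summary> fc_tf = %.4f, fc_target = %.4f, r_free = %.3f\n",
    x$fc_tf, x$fc_target, x$r_free))
  invisible(x)
}

# residuals of the state-partitioned balance equations; u = (P2..P4, N1..N4)
partitioned_residuals <- function(u, cfg) {
  P <- c(1 - u[1] - u[2] - u[3], u[1], u[2], u[3])
  Nst <- u[4:7]
  kon <- cfg$kon; koff <- cfg$koff; g <- cfg$gamma; a <- cfg$alpha_eff
  eps <- 1e-12
  nu <- Nst / pmax(P, eps)
  ex <- koff + g  # site-vacating rate
  # occupancy balance for states 2, 3, 4
  f2 <- kon * nu[1] * P[1] - (kon * nu[2] + ex) * P[2] + ex * P[4]
  f3 <- kon * nu[1] * P[1] - (kon * nu[3] + ex) * P[3] + ex * P[4]
  f4 <- kon * nu[2] * P[2] + kon * nu[3] * P[3] - 2 * ex * P[4]
  # TF-mass balance: binding carries nu - 1, unbinding nu + 1,
  # bound-TF degradation carries nu
  outflux <- function(i) koff * P[i] * (nu[i] + 1) + g * P[i] * nu[i]
  fN1 <- a * P[1] - g * Nst[1] - 2 * kon * nu[1] * P[1] * (nu[1] - 1) +
    outflux(2) + outflux(3)
  fN2 <- a * P[2] - g * Nst[2] + kon * nu[1] * P[1] * (nu[1] - 1) -
    kon * nu[2] * P[2] * (nu[2] - 1) - outflux(2) + outflux(4)
  fN3 <- -g * Nst[3] + kon * nu[1] * P[1] * (nu[1] - 1) -
    kon * nu[3] * P[3] * (nu[3] - 1) - outflux(3) + outflux(4)
  fN4 <- -g * Nst[4] + kon * nu[2] * P[2] * (nu[2] - 1) +
    kon * nu[3] * P[3] * (nu[3] - 1) - 2 * outflux(4)
  c(f2, f3, f4, fN1, fN2, fN3, fN4)
}

#' State-partitioned deterministic steady state of the minimal model
#'
#' Deterministic model that, unlike [naive_steady_state()], tracks each
#' promoter-occupancy state `i = 1..4` separately: its probability `P_i`
#' and the TF mass `N_i` it carries, with the single-point closure
#' `E[f(n) | state i] = f(nu_i)` where `nu_i = N_i / P_i`.  Promoter
#' transitions follow the master-equation rates with `kon * n` replaced by
#' `kon * nu_i`; binding moves `nu_i - 1` TFs into the new state, unbinding
#' moves `nu_i + 1`, bound-TF degradation moves `nu_i`; production
#' `alpha_eff` runs in states 1 and 2 and free TF decays at `gamma * N_i`.
#' Because the TF level differs between states, this model predicts
#' non-zero asymmetry, though not in quantitative agreement with the full
#' stochastic solution (the closure ignores within-state variability).
#'
#' @param cfg A [cme_config()] with `n_decoy = 0` (decoy titration is not
#'   part of the partitioned equations).
#' @param tol Maximum absolute residual of the balance equations.
#' @param max_iter Newton iteration cap.
#' @return A `partitioned_summary`: `p_state`, `n_state` (joint masses
#'   `N_i`), closure values `nu`, fold-changes and asymmetry.
#' @export
partitioned_steady_state <- function(cfg, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(cfg, "cme_config"))
  if (cfg$n_decoy > 0L)
    stop("partitioned model is defined for the decoy-free minimal model",
         call. = FALSE)
  if (cfg$kon == 0) {
    nbar <- cfg$alpha_eff / cfg$gamma
    return(structure(list(
      p_state = c(1, 0, 0, 0), n_state = c(nbar, 0, 0, 0),
      nu = c(nbar, NA, NA, NA), fc_tf = 1, fc_target = 1, asymmetry = 0,
      residual = 0), class = "partitioned_summary"))
  }
  nstar <- minimal_fixed_point(cfg)
  k <- cfg$kon / (cfg$koff + cfg$gamma)
  pb <- k * nstar / (1 + k * nstar)
  P0 <- c((1 - pb)^2, pb * (1 - pb), pb * (1 - pb), pb^2)
  u <- c(P0[2], P0[3], P0[4], nstar * P0)
  fn <- function(u) partitioned_residuals(u, cfg)
  scale <- max(1, cfg$alpha_eff)
  f <- fn(u)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) / scale < tol * 1e-2) break
    J <- numeric_jacobian(fn, u)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step))
      stop("partitioned solve: singular Jacobian", call. = FALSE)
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      # keep probabilities and masses feasible
      u_new[1:3] <- pmin(pmax(u_new[1:3], 0), 1)
      u_new[4:7] <- pmax(u_new[4:7], 0)
      f_new <- fn(u_new)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    u <- u_new; f <- f_new
  }
  res <- max(abs(f)) / scale
  if (res > tol)
    stop(sprintf("partitioned solve did not converge: residual %.3g (P = %s)",
                 res, paste(sprintf("%.3g", c(1 - sum(u[1:3]), u[1:3])),
                            collapse = ", ")), call. = FALSE)
  P <- c(1 - sum(u[1:3]), u[1:3])
  Nst <- u[4:7]
  structure(list(
    p_state = P, n_state = Nst, nu = Nst / pmax(P, 1e-12),
    fc_tf = P[1] + P[2], fc_target = P[1] + P[3],
    asymmetry = P[3] - P[2], residual = res),
    class = "partitioned_summary")
}

#' @export
print.partitioned_summary <- function(x, ...) {
  cat(sprintf(
    "<partitioned_summary> fc_tf = %.4f, fc_target = %.4f, asym = %.4g\n",
    x$fc_tf, x$fc_target, x$asymmetry))
  invisible(x)
}

numeric_jacobian <- function(f, x, eps = 1e-7) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
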