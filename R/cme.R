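#' Configuration of the minimal-model master equation
#'
#' The minimal model keeps only the ingredients needed for regulatory
#' asymmetry: a TF born directly as a binder at rate `alpha_eff` while its
#' own gene is unbound, first-order decay at `gamma`, and binding/unbinding
#' to the two promoters (and optionally `n_decoy` decoy sites).  There is no
#' mRNA stage and no dimerization; fold-changes are promoter unbound
#' fractions.
#'
#' @param alpha_eff TF production rate (s^-1) while the TF gene is unbound.
#' @param kon Binding rate per free TF per second.
#' @param koff Operator unbinding rate (s^-1), shared by both promoters.
#' @param gamma TF decay rate (s^-1), > 0.
#' @param n_decoy Number of decoy sites (default 0).
#' @param koff_decoy Decoy unbinding rate; defaults to `koff`.
#' @param n_max Truncation of the free-TF axis; `NULL` (default) chooses it
#'   adaptively so that the stationary tail mass at `n_max` is below 1e-8.
#' @return An object of class `cme_config`.
#' @export
cme_config <- function(alpha_eff, kon, koff, gamma, n_decoy = 0L,
                       koff_decoy = koff, n_max = NULL) {
  for (f in c("alpha_eff", "kon", "koff", "gamma", "koff_decoy")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("cme_config field '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.null(n_max) && n_max < 10) stop("n_max must be >= 10")
  structure(list(alpha_eff = alpha_eff, kon = kon, koff = koff,
                 gamma = gamma, n_decoy = as.integer(n_decoy),
                 koff_decoy = koff_decoy,
                 n_max = if (is.null(n_max)) NULL else as.integer(n_max)),
            class = "cme_config")
}

# deterministic fixed point of free TF in the autoregulated minimal model,
# used to seed the adaptive truncation
minimal_fixed_point <- function(cfg) {
  k <- cfg$kon / (cfg$koff + cfg$gamma)
  kd <- cfg$kon / (cfg$koff_decoy + cfg$gamma)
  N <- cfg$n_decoy
  if (cfg$kon == 0 || cfg$alpha_eff == 0) return(cfg$alpha_eff / cfg$gamma)
  f <- function(n) {
    occ <- k * n / (1 + k * n)
    occ_d <- kd * n / (1 + kd * n)
    cfg$alpha_eff * (1 - occ) - cfg$gamma * (n + 2 * occ + N * occ_d)
  }
  hi <- cfg$alpha_eff / cfg$gamma + 1
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(0, hi), tol = 1e-9)$root
}

default_nmax <- function(cfg) {
  nstar <- minimal_fixed_point(cfg)
  max(10L, as.integer(ceiling(nstar + 12 * sqrt(nstar + 10) + 30)))
}

state_dims <- function(cfg, n_max, d_min = 0L) {
  c(g = 4L, d = cfg$n_decoy - d_min + 1L, n = n_max + 1L)
}

# lower truncation of the bound-decoy axis: when decoys are nearly
# saturated the marginal of d concentrates near n_decoy, and carrying the
# empty-decoy states is wasted work.  A 1D birth-death surrogate (decoy
# binding at kon * nbar(d) * (N - d) against unbinding/degradation at
# (koff_decoy + gamma) * d, with nbar the deterministic free-TF level)
# gives the left tail location; the window is inflated several-fold
# because slow TF fluctuations overdisperse the true marginal, and the
# boundary-mass check in stationary_distribution() backstops the guess.
default_dmin <- function(cfg, n_max) {
  N <- cfg$n_decoy
  if (N == 0L || cfg$kon == 0 || cfg$alpha_eff == 0) return(0L)
  nbar <- minimal_fixed_point(cfg)
  b <- cfg$kon * nbar * (N - 0:N)            # birth rates b_d
  m <- (cfg$koff_decoy + cfg$gamma) * (0:N)  # death rates m_d
  logpi <- cumsum(c(0, log(b[1:N] / m[2:(N + 1L)])))
  logpi <- logpi - max(logpi)
  pi1 <- exp(logpi) / sum(exp(logpi))
  q <- suppressWarnings(min(which(cumsum(pi1) > 1e-12)) - 1L)
  mode <- which.max(pi1) - 1L
  d_min <- max(0L, q - 4L * (mode - q) - 20L)
  as.integer(d_min)
}

#' Build the transition-rate generator of the minimal model
#'
#' Enumerates the state space `(g, d, n)` with occupancy state
#' `g in 1..4` (1 both promoters free, 2 target bound, 3 TF gene bound,
#' 4 both bound), `d` bound decoys and `n` free TF copies, and assembles the
#' sparse master-equation operator `A` with `A[j, i]` the rate from state
#' `i` to state `j` (columns sum to zero).  Transitions: TF birth at
#' `alpha_eff` in states 1 and 2; free-TF death at `gamma * n`; binding to
#' each open site at `kon * n`; unbinding at `koff` (site freed, `n + 1`);
#' bound-TF degradation at `gamma` (site freed, `n` unchanged); analogous
#' decoy channels.  Probability flux that would leave through the `n_max`
#' boundary by unbinding is lumped at `n_max`; the truncation check in
#' [stationary_distribution()] guarantees this is negligible.  When the
#' decoy pool is near saturation the bound-decoy axis is likewise windowed
#' from below (`d_min`), with its own boundary check.
#'
#' @param cfg A [cme_config()].
#' @param n_max Optional override of the truncation.
#' @param d_min Optional lower truncation of the bound-decoy axis
#'   (default adaptive).
#' @return A list with the sparse generator `A` (`dgCMatrix`), `dims`, and
#'   the grids `g`, `d`, `n` aligned with the state indexing.
#' @export
build_generator <- function(cfg, n_max = NULL, d_min = NULL) {
  stopifnot(inherits(cfg, "cme_config"))
  if (is.null(n_max)) n_max <- cfg$n_max
  if (is.null(n_max)) n_max <- default_nmax(cfg)
  if (is.null(d_min)) d_min <- default_dmin(cfg, n_max)
  N <- cfg$n_decoy
  d_min <- as.integer(max(0L, min(d_min, N)))
  dims <- state_dims(cfg, n_max, d_min)
  S <- prod(dims)
  D <- N - d_min + 1L
  idx <- function(g, d, n) g + 4L * ((d - d_min) + D * n)
  grid <- expand.grid(g = 1:4, d = d_min:N, n = 0:n_max)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    keep <- rate > 0
    ii <<- c(ii, to[keep], from[keep])
    jj <<- c(jj, from[keep], from[keep])
    xx <<- c(xx, rate[keep], -rate[keep])
  }
  g <- grid$g; d <- grid$d; n <- grid$n
  from_all <- idx(g, d, n)
  # birth (TF gene unbound: states 1, 2), blocked at the truncation edge
  sel <- g %in% c(1L, 2L) & n < n_max
  add(from_all[sel], idx(g[sel], d[sel], n[sel] + 1L),
      rep(cfg$alpha_eff, sum(sel)))
  # free TF death
  sel <- n > 0L
  add(from_all[sel], idx(g[sel], d[sel], n[sel] - 1L), cfg$gamma * n[sel])
  # promoter binding (n -> n - 1): target 1->2, 3->4; TF gene 1->3, 2->4
  for (tr in list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L))) {
    sel <- g == tr[1] & n > 0L
    add(from_all[sel], idx(rep(tr[2], sum(sel)), d[sel], n[sel] - 1L),
        cfg$kon * n[sel])
  }
  # promoter unbinding (n -> n + 1, lumped at n_max): 2->1, 4->3, 3->1, 4->2
  for (tr in list(c(2L, 1L), c(4L, 3L), c(3L, 1L), c(4L, 2L))) {
    sel <- g == tr[1]
    np <- pmin(n[sel] + 1L, n_max)
    add(from_all[sel], idx(rep(tr[2], sum(sel)), d[sel], np),
        rep(cfg$koff, sum(sel)))
    # bound-TF degradation frees the site without returning a TF
    add(from_all[sel], idx(rep(tr[2], sum(sel)), d[sel], n[sel]),
        rep(cfg$gamma, sum(sel)))
  }
  if (N > 0L) {
    sel <- d < N & n > 0L
    add(from_all[sel], idx(g[sel], d[sel] + 1L, n[sel] - 1L),
        cfg$kon * n[sel] * (N - d[sel]))
    sel <- d > d_min  # down-transitions blocked at the window edge
    np <- pmin(n[sel] + 1L, n_max)
    add(from_all[sel], idx(g[sel], d[sel] - 1L, np),
        cfg$koff_decoy * d[sel])
    add(from_all[sel], idx(g[sel], d[sel] - 1L, n[sel]),
        cfg$gamma * d[sel])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(S, S))
  list(A = A, dims = dims, n_max = n_max, d_min = d_min, cfg = cfg,
       g = g, d = d, n = n)
}

#' Stationary distribution of the truncated master equation
#'
#' Solves the balance equations `A p = 0`, `sum(p) = 1` by pinning the
#' probability of one reference state (a state near the distribution's
#' mode, guessed from the deterministic fixed point), solving the sparse
#' linear system for all other states relative to it, and normalizing.
#' Pinning a single state keeps the system a sparse lattice -- appending a
#' dense normalization row would ruin the factorization fill.  Errors if
#' the residual of the balance equations exceeds `tol_residual` or if the
#' truncation tail mass (probability at `n = n_max`) is not below
#' `tol_tail`.
#'
#' @param gen Output of [build_generator()].
#' @param tol_residual Maximum allowed `max |A p|` (default 1e-9).
#' @param tol_tail Maximum allowed probability mass at the truncation
#'   boundary (default 1e-8).
#' @return An object of class `stationary_distribution`: the probability
#'   vector `p` plus the state grids.
#' @export
stationary_distribution <- function(gen, tol_residual = 1e-9,
                                    tol_tail = 1e-8) {
  A <- gen$A
  S <- nrow(A)
  cfg <- gen$cfg
  # pin a state near the mode: both promoters bound (if binding happens),
  # decoys mostly occupied, free TF at the deterministic fixed point
  nstar <- min(round(minimal_fixed_point(cfg)), gen$n_max)
  kd <- cfg$kon / (cfg$koff_decoy + cfg$gamma)
  dmode <- round(cfg$n_decoy * kd * nstar / (1 + kd * nstar))
  dmode <- min(max(dmode, gen$d_min), cfg$n_decoy)
  gmode <- if (cfg$kon > 0 && nstar > 0) 4L else 1L
  D <- cfg$n_decoy - gen$d_min + 1L
  k <- gmode + 4L * ((dmode - gen$d_min) + D * nstar)
  x <- Matrix::solve(A[-k, -k, drop = FALSE], -A[-k, k, drop = FALSE],
                     sparse = TRUE)
  p <- numeric(S)
  p[-k] <- as.numeric(x)
  p[k] <- 1
  p[p < 0] <- 0
  p <- p / sum(p)
  res <- max(abs(as.numeric(A %*% p)))
  if (res > tol_residual)
    stop(sprintf("stationary solve residual %.3g exceeds %.3g",
                 res, tol_residual), call. = FALSE)
  tail_mass <- sum(p[gen$n == gen$n_max])
  if (tail_mass > tol_tail)
    stop(sprintf("truncation tail mass %.3g at n_max = %d exceeds %.3g",
                 tail_mass, gen$n_max, tol_tail), call. = FALSE)
  d_tail <- if (gen$d_min > 0L) sum(p[gen$d == gen$d_min]) else 0
  if (d_tail > tol_tail)
    stop(sprintf("window tail mass %.3g at d_min = %d exceeds %.3g",
                 d_tail, gen$d_min, tol_tail), call. = FALSE)
  structure(list(p = p, g = gen$g, d = gen$d, n = gen$n,
                 n_max = gen$n_max, d_min = gen$d_min, cfg = gen$cfg,
                 residual = res, tail_mass = tail_mass, d_tail = d_tail),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat(sprintf(
    "<stationary_distribution> %d states (n_max = %d), residual %.2g\n",
    length(x$p), x$n_max, x$residual))
  invisible(x)
}

#' Summaries of a minimal-model stationary distribution
#'
#' Marginal occupancy probabilities `P1..P4`, the joint state-conditional
#' TF expectations `n_i = E[n * 1{g = i}]`, fold-changes read from promoter
#' occupancy (`fc_tf = P1 + P2`, `fc_target = P1 + P3`), the asymmetry
#' `fc_target - fc_tf` (identically `P3 - P2`), mean free and bound TF, and
#' `R* = E[n] * kon / (koff + gamma)`.
#'
#' @param dist A [stationary_distribution()].
#' @param cfg Optional [cme_config()]; defaults to the one stored in `dist`.
#' @return An object of class `summary_stats`.
#' @export
cme_summaries <- function(dist, cfg = NULL) {
  stopifnot(inherits(dist, "stationary_distribution"))
  if (is.null(cfg)) cfg <- dist$cfg
  p_state <- vapply(1:4, function(i) sum(dist$p[dist$g == i]), numeric(1))
  n_state <- vapply(1:4, function(i)
    sum(dist$p[dist$g == i] * dist$n[dist$g == i]), numeric(1))
  mean_n <- sum(dist$p * dist$n)
  mean_d <- sum(dist$p * dist$d)
  bound_prom <- sum(dist$p * ((dist$g %in% c(2L, 4L)) +
                                (dist$g %in% c(3L, 4L))))
  fc_tf <- p_state[1] + p_state[2]
  fc_target <- p_state[1] + p_state[3]
  structure(list(
    mean_tf_total = mean_n + mean_d + bound_prom,
    mean_r_free = mean_n,
    mean_bound_decoy = mean_d,
    r_star = mean_n * cfg$kon / (cfg$koff + cfg$gamma),
    fc_tf = fc_tf, fc_target = fc_target,
    asymmetry = fc_target - fc_tf,
    fc_tf_occ = fc_tf, fc_target_occ = fc_target,
    asymmetry_occ = p_state[3] - p_state[2],
    p_state = p_state, n_state = n_state,
    se_fc_tf = 0, se_fc_target = 0, se_asymmetry = 0,
    engine = "cme"), class = "summary_stats")
}

#' Steady-state solve of the minimal model in one call
#'
#' Builds the generator, solves for the stationary distribution (growing
#' `n_max` geometrically until the truncation tolerance holds) and returns
#' [cme_summaries()].
#'
#' @param cfg A [cme_config()].
#' @param max_grow Maximum number of truncation enlargements (default 6).
#' @return An object of class `summary_stats`.
#' @export
cme_steady_state <- function(cfg, max_grow = 8L) {
  n_max <- if (is.null(cfg$n_max)) default_nmax(cfg) else cfg$n_max
  d_min <- default_dmin(cfg, n_max)
  for (i in seq_len(max_grow + 1L)) {
    gen <- build_generator(cfg, n_max = n_max, d_min = d_min)
    dist <- tryCatch(stationary_distribution(gen), error = function(e) e)
    if (!inherits(dist, "error")) {
      out <- cme_summaries(dist, cfg)
      out$n_max <- dist$n_max
      out$dist <- dist
      return(out)
    }
    msg <- conditionMessage(dist)
    if (grepl("at n_max", msg)) {
      n_max <- as.integer(ceiling(n_max * 1.6) + 10L)
    } else if (grepl("at d_min", msg)) {
      d_min <- max(0L, d_min - max(20L, cfg$n_decoy - d_min))
    } else {
      stop(dist)
    }
  }
  stop("could not satisfy truncation tolerance after enlarging the window",
       call. = FALSE)
}
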