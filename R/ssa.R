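#' Sampling plan for stochastic simulations
#'
#' @param t_end Total simulated time in seconds.
#' @param burn_in Seconds discarded before sampling starts.
#' @param ts Sampling interval in seconds; default spaces 1e5 snapshots over
#'   `t_end - burn_in`.  Use [suggest_ts()] after a run to check the
#'   slowest-reaction spacing rule.
#' @param seed Integer seed; replicate `r` is seeded with
#'   `seed + 977 * (r - 1)` so replicate streams are reproducible
#'   individually.
#' @param n_replicates Number of independent trajectories.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(t_end = 1e6, burn_in = 1e5, ts = NULL, seed = NULL,
                          n_replicates = 1L) {
  if (is.null(ts)) ts <- (t_end - burn_in) / 1e5
  if (!(burn_in >= 0 && burn_in < t_end)) stop("need 0 <= burn_in < t_end")
  if (ts <= 0) stop("ts must be > 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(t_end = t_end, burn_in = burn_in, ts = ts, seed = seed,
                 n_replicates = as.integer(n_replicates)),
            class = "sampling_plan")
}

#' Exact stochastic simulation of a reaction network
#'
#' Runs the Gillespie direct method (exponential waiting times from the
#' total propensity; channel chosen with probability proportional to its
#' propensity) on a network built by [build_reactions()] or
#' [build_minimal_reactions()].  The initial state is all counts zero, so
#' trajectories include the relaxation transient; `plan$burn_in` discards
#' it.  If the system freezes (all propensities zero), remaining snapshots
#' hold the frozen state and the `frozen` flag is set.
#'
#' @param network A `reaction_network`.
#' @param plan A [sampling_plan()].
#' @param init Optional initial state (8 counts); default all zero.
#' @return A `sample_set`: snapshot times, per-replicate state matrices
#'   stacked with a `rep` column, derived TF mass (monomer equivalents:
#'   `x + 2 * (r_free + b_tf + b_target + b_decoy)`) and the occupancy-state
#'   index 1..4.
#' @export
simulate_ssa <- function(network, plan, init = NULL) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(plan, "sampling_plan"))
  if (is.null(init)) init <- numeric(8)
  validate_state(network, init)
  stoich <- network$stoich
  storage.mode(stoich) <- "integer"
  runs <- vector("list", plan$n_replicates)
  for (r in seq_len(plan$n_replicates)) {
    if (!is.null(plan$seed)) set.seed(plan$seed + 977L * (r - 1L))
    runs[[r]] <- ssa_run_cpp(stoich, network$rate, network$kind,
                             network$n_decoy, as.numeric(init),
                             plan$t_end, plan$burn_in, plan$ts)
  }
  state <- do.call(rbind, lapply(runs, `[[`, "state"))
  colnames(state) <- SPECIES
  rep_id <- rep(seq_len(plan$n_replicates),
                each = nrow(runs[[1]]$state))
  tf_total <- state[, "x"] + 2 * (state[, "r_free"] + state[, "b_tf"] +
                                    state[, "b_target"] + state[, "b_decoy"])
  structure(list(
    time = runs[[1]]$time, rep = rep_id, state = state,
    tf_total = tf_total,
    state_idx = state_index(state[, "b_tf"], state[, "b_target"]),
    frozen = any(vapply(runs, `[[`, logical(1), "frozen")),
    events_burnin = Reduce(`+`, lapply(runs, `[[`, "events_burnin")),
    prop_time_burnin = Reduce(`+`, lapply(runs, `[[`, "prop_time_burnin")),
    network = network, plan = plan), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d snapshots x %d replicate(s)%s\n",
              length(x$time), max(x$rep),
              if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

#' Sampling interval implied by the slowest active reaction
#'
#' Returns `20 / a_min` where `a_min` is the smallest time-averaged
#' burn-in propensity among channels that fired at least once during the
#' burn-in and whose expected event count over the full run is at least
#' one (this excludes essentially inert channels such as de-dimerization,
#' whose nominal rate would otherwise dictate an interval longer than the
#' run).
#'
#' @param samples A `sample_set`.
#' @return Suggested `ts` in seconds (`NA` if no channel qualifies).
#' @export
suggest_ts <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  plan <- samples$plan
  nrep <- max(samples$rep)
  avg <- samples$prop_time_burnin / (plan$burn_in * nrep)
  fired <- samples$events_burnin > 0
  active <- fired & (avg * plan$t_end >= 1)
  if (!any(active)) return(NA_real_)
  20 / min(avg[active])
}

batch_means <- function(mat, rep_id, n_batches = 32L) {
  # contiguous batches within each replicate; returns matrix of batch means
  out <- list()
  for (r in unique(rep_id)) {
    rows <- which(rep_id == r)
    nb <- min(n_batches, length(rows))
    grp <- ceiling(seq_along(rows) / (length(rows) / nb))
    out[[length(out) + 1L]] <-
      apply(mat[rows, , drop = FALSE], 2, function(col)
        tapply(col, grp, mean))
  }
  do.call(rbind, out)
}

#' Steady-state summary statistics from SSA samples
#'
#' Computes the observables of interest: mean total TF (monomer
#' equivalents), mean free dimers `Rfree`, the scaled repressor number
#' `R* = Rfree * kon / (koff_tf + gamma_tf)`, mean target protein,
#' fold-changes against supplied baselines, asymmetry
#' (`fc_target - fc_tf`), occupancy-state probabilities `P1..P4`, the
#' state-conditional free-TF mass `n_i = E[r_free * 1{state i}]`, and
#' occupancy-based fold-changes (`P1 + P2` for the TF gene, `P1 + P3` for
#' the target) which are engine-independent.  Standard errors come from
#' batch means over contiguous blocks, which respects autocorrelation of
#' the sampled trajectory.
#'
#' @param samples A `sample_set`.
#' @param baseline_tf,baseline_y Constitutive means used as fold-change
#'   denominators (see [constitutive_baseline()]); both must be positive.
#' @param rates The [rate_set()] (or [cme_config()]) that generated the
#'   samples; used for `R*`.
#' @param n_batches Number of batches per replicate for standard errors.
#' @return An object of class `summary_stats`.
#' @export
summarize_samples <- function(samples, baseline_tf, baseline_y, rates,
                              n_batches = 32L) {
  stopifnot(inherits(samples, "sample_set"))
  if (length(samples$time) == 0L) stop("empty sample set")
  if (baseline_tf <= 0 || baseline_y <= 0)
    stop("baselines must be positive", call. = FALSE)
  if (inherits(rates, "cme_config")) {
    kon <- rates$kon; koff <- rates$koff; g <- rates$gamma
  } else {
    kon <- rates$kon; koff <- rates$koff_tf
    g <- rates$gamma + rates$gamma_tag_tf
  }
  st <- samples$state
  ind <- outer(samples$state_idx, 1:4, "==") * 1
  colnames(ind) <- paste0("s", 1:4)
  nmat <- ind * st[, "r_free"]
  colnames(nmat) <- paste0("n", 1:4)
  mat <- cbind(tf = samples$tf_total, y = st[, "y"],
               r_free = st[, "r_free"], ind, nmat)
  bm <- batch_means(mat, samples$rep, n_batches)
  mu <- colMeans(bm)
  se <- apply(bm, 2, stats::sd) / sqrt(nrow(bm))
  p_state <- mu[paste0("s", 1:4)]
  n_state <- mu[paste0("n", 1:4)]
  fc_tf <- mu[["tf"]] / baseline_tf
  fc_target <- mu[["y"]] / baseline_y
  # per-batch fold changes -> correlated-aware asymmetry error
  fc_tf_b <- bm[, "tf"] / baseline_tf
  fc_y_b <- bm[, "y"] / baseline_y
  asym_b <- fc_y_b - fc_tf_b
  occ_tf_b <- bm[, "s1"] + bm[, "s2"]
  occ_y_b <- bm[, "s1"] + bm[, "s3"]
  nb <- nrow(bm)
  structure(list(
    mean_tf_total = mu[["tf"]], se_tf_total = se[["tf"]],
    mean_y = mu[["y"]], se_y = se[["y"]],
    mean_r_free = mu[["r_free"]], se_r_free = se[["r_free"]],
    r_star = mu[["r_free"]] * kon / (koff + g),
    fc_tf = fc_tf, se_fc_tf = stats::sd(fc_tf_b) / sqrt(nb),
    fc_target = fc_target, se_fc_target = stats::sd(fc_y_b) / sqrt(nb),
    asymmetry = fc_target - fc_tf,
    se_asymmetry = stats::sd(asym_b) / sqrt(nb),
    fc_tf_occ = p_state[["s1"]] + p_state[["s2"]],
    se_fc_tf_occ = stats::sd(occ_tf_b) / sqrt(nb),
    fc_target_occ = p_state[["s1"]] + p_state[["s3"]],
    se_fc_target_occ = stats::sd(occ_y_b) / sqrt(nb),
    asymmetry_occ = p_state[["s3"]] - p_state[["s2"]],
    se_asymmetry_occ = stats::sd(bm[, "s3"] - bm[, "s2"]) / sqrt(nb),
    p_state = unname(p_state), n_state = unname(n_state),
    engine = "ssa"), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats/%s>\n", x$engine))
  cat(sprintf("  fc_tf = %.4f, fc_target = %.4f, asymmetry = %.4f\n",
              x$fc_tf, x$fc_target, x$asymmetry))
  cat(sprintf("  mean TF = %.1f, Rfree = %.2f, R* = %.3f\n",
              x$mean_tf_total, x$mean_r_free, x$r_star))
  cat(sprintf("  P(state) = %s\n",
              paste(sprintf("%.3f", x$p_state), collapse = ", ")))
  invisible(x)
}

#' Constitutive (unregulated) expression baseline
#'
#' Simulates the same network with `kon = 0` so neither promoter is ever
#' bound, and returns the mean TF mass and mean target protein, the
#' denominators of the fold-change.  The closed-form means of the two-stage
#' birth-death process, `(beta/gamma_m) * (alpha/gamma)`, are returned
#' alongside for cross-checking (TF uses `gamma + gamma_tag_tf`).
#'
#' @param rates A [rate_set()].
#' @param plan A [sampling_plan()].
#' @return List with `baseline_tf`, `baseline_y`, their standard errors,
#'   the analytic means, and the underlying `sample_set`.
#' @export
constitutive_baseline <- function(rates, plan) {
  r0 <- rates
  r0$kon <- 0
  net <- build_reactions(r0)
  samp <- simulate_ssa(net, plan)
  bm <- batch_means(cbind(tf = samp$tf_total, y = samp$state[, "y"]),
                    samp$rep)
  g_tf <- rates$gamma + rates$gamma_tag_tf
  list(baseline_tf = mean(bm[, "tf"]),
       se_tf = stats::sd(bm[, "tf"]) / sqrt(nrow(bm)),
       baseline_y = mean(bm[, "y"]),
       se_y = stats::sd(bm[, "y"]) / sqrt(nrow(bm)),
       analytic_tf = rates$beta / rates$gamma_m * rates$alpha / g_tf,
       analytic_y = rates$beta / rates$gamma_m * rates$alpha / rates$gamma,
       samples = samp)
}
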