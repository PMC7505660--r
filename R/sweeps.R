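# Sweep drivers: in-silico experiments over decoy number, degradation rate,
# binding affinity and growth medium.

engine_summary <- function(rates, engine, plan, baseline = NULL) {
  if (engine == "cme") return(cme_steady_state(as_cme_config(rates)))
  if (is.null(baseline)) baseline <- constitutive_baseline(rates, plan)
  samp <- simulate_ssa(build_reactions(rates), plan)
  s <- summarize_samples(samp, baseline$baseline_tf, baseline$baseline_y,
                         rates)
  s
}

#' Fold-change and asymmetry versus network size (decoy count)
#'
#' Runs the model at each decoy count and collects fold-changes of both
#' genes, the mean free TF and the asymmetry.  With the SSA engine a single
#' constitutive baseline (`kon = 0`, shared seed policy) is reused across
#' counts.  The master-equation engine works on the minimal-model mapping
#' of the rates (see [as_cme_config()]) and is deterministic.
#'
#' @param rates A [rate_set()]; its own `n_decoy` is ignored.
#' @param decoy_counts Non-negative, increasing decoy counts.
#' @param plan [sampling_plan()] for the SSA engine.
#' @param engine `"ssa"` or `"cme"`.
#' @return A `data.frame` (class `curve_table`) with one row per count:
#'   fold-changes (protein-based for the SSA, occupancy-based for the CME),
#'   standard errors, mean free TF and asymmetry.
#' @export
decoy_sweep <- function(rates, decoy_counts, plan = NULL,
                        engine = c("ssa", "cme")) {
  engine <- match.arg(engine)
  if (any(decoy_counts < 0) || is.unsorted(decoy_counts, strictly = FALSE))
    stop("decoy_counts must be non-negative and sorted", call. = FALSE)
  if (engine == "ssa" && is.null(plan)) plan <- sampling_plan(seed = 1)
  baseline <- if (engine == "ssa") constitutive_baseline(rates, plan)
  rows <- lapply(decoy_counts, function(N) {
    r <- rates; r$n_decoy <- as.integer(N)
    s <- engine_summary(r, engine, plan, baseline)
    data.frame(n_decoy = N, fc_tf = s$fc_tf, se_fc_tf = s$se_fc_tf,
               fc_target = s$fc_target, se_fc_target = s$se_fc_target,
               asymmetry = s$asymmetry, se_asymmetry = s$se_asymmetry,
               mean_r_free = s$mean_r_free,
               se_r_free = if (engine == "ssa") s$se_r_free else 0,
               r_star = s$r_star, engine = engine,
               seed = if (engine == "ssa") plan$seed %||% NA_integer_
                      else NA_integer_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("curve_table", "data.frame")
  out
}

#' Maximum asymmetry over a decoy-count grid
#'
#' The asymmetry of the motif depends non-monotonically on the number of
#' competing sites; this helper scans a decoy grid and reports the maximum
#' and where it occurs.
#'
#' @inheritParams decoy_sweep
#' @param decoy_grid Decoy counts to scan.
#' @return List with `value`, `n_decoy` (argmax) and the full `table`.
#' @export
max_asymmetry <- function(rates, decoy_grid, engine = c("cme", "ssa"),
                          plan = NULL) {
  engine <- match.arg(engine)
  tab <- decoy_sweep(rates, sort(decoy_grid), plan, engine)
  i <- which.max(tab$asymmetry)
  list(value = tab$asymmetry[i], n_decoy = tab$n_decoy[i], table = tab)
}

#' Asymmetry versus TF degradation rate (minimal-model scan)
#'
#' Scans the TF decay rate (expressed as protein half-life in minutes,
#' `gamma = ln(2) / (60 * half_life)`) at fixed binding kinetics and fixed
#' production rate `alpha_eff`, taking at each point the maximum asymmetry
#' over a decoy grid.  This reproduces a horizontal slice of the
#' affinity-degradation phase diagram: asymmetry vanishes for degradation
#' that is too fast (too few TFs to occupy the promoters) or too slow
#' (promoters saturated), with an interior maximum at half-lives comparable
#' to typical division times.
#'
#' @param half_lives_min TF half-lives to scan, minutes.
#' @param kon,koff Binding kinetics (s^-1); O1-like by default.
#' @param alpha_eff Minimal-model TF production rate (s^-1), held fixed
#'   across the scan so the TF pool grows as degradation slows.
#' @param decoy_grid Decoy counts maximized over at each half-life.
#' @param koff_decoy Decoy unbinding rate (defaults to `koff`).
#' @return A `data.frame`: half-life, gamma, max asymmetry, argmax decoy
#'   count; attribute `peak` holds the half-life of the global maximum.
#' @export
degradation_scan <- function(half_lives_min, kon = 0.0015, koff = 0.00149,
                             alpha_eff, decoy_grid = c(0, 10, 30, 75, 150,
                                                       300),
                             koff_decoy = koff) {
  stopifnot(length(half_lives_min) > 0, all(half_lives_min > 0))
  rows <- lapply(half_lives_min, function(h) {
    gamma <- log(2) / (60 * h)
    best <- list(value = -Inf, n_decoy = NA)
    for (N in decoy_grid) {
      cfg <- cme_config(alpha_eff, kon, koff, gamma, n_decoy = N,
                        koff_decoy = koff_decoy)
      s <- cme_steady_state(cfg)
      if (s$asymmetry > best$value)
        best <- list(value = s$asymmetry, n_decoy = N)
    }
    data.frame(half_life_min = h, gamma = gamma,
               max_asymmetry = best$value, n_decoy = best$n_decoy)
  })
  out <- do.call(rbind, rows)
  attr(out, "peak_half_life_min") <-
    out$half_life_min[which.max(out$max_asymmetry)]
  out
}

#' Phase diagram of maximum asymmetry: binding affinity x degradation
#'
#' For every combination of operator unbinding rate and TF decay rate,
#' computes the maximum asymmetry over a decoy grid with the
#' master-equation engine.  Strong binding (small `koff`) enhances
#' asymmetry; the degradation axis shows an interior maximum.
#'
#' @param affinity_grid Operator affinities: either unbinding rates in
#'   s^-1, or binding energies in kBT if `affinity_units = "kBT"` (then
#'   converted per [energy_to_koff()] with each row's `gamma`).
#' @param gamma_grid TF decay rates (s^-1).
#' @param decoy_grid Decoy counts maximized over per cell.
#' @param alpha_eff Minimal-model production rate (s^-1), fixed.
#' @param kon Binding rate (s^-1).
#' @param affinity_units `"koff"` (default) or `"kBT"`.
#' @param n_ns Non-specific site count for the kBT conversion.
#' @return A `heatmap_result`: `max_asymmetry` matrix (affinity x gamma),
#'   matching `argmax_decoy` matrix, and the axes.
#' @export
asymmetry_heatmap <- function(affinity_grid, gamma_grid, decoy_grid,
                              alpha_eff, kon = 0.0015,
                              affinity_units = c("koff", "kBT"),
                              n_ns = 5e6) {
  affinity_units <- match.arg(affinity_units)
  stopifnot(length(affinity_grid) > 0, length(gamma_grid) > 0,
            length(decoy_grid) > 0)
  M <- matrix(NA_real_, length(affinity_grid), length(gamma_grid))
  D <- M
  for (i in seq_along(affinity_grid)) {
    for (j in seq_along(gamma_grid)) {
      gamma <- gamma_grid[j]
      koff <- if (affinity_units == "kBT")
        energy_to_koff(kon, affinity_grid[i], gamma, n_ns)
      else affinity_grid[i]
      best <- list(value = -Inf, n_decoy = NA)
      for (N in decoy_grid) {
        s <- cme_steady_state(cme_config(alpha_eff, kon, koff, gamma,
                                         n_decoy = N))
        if (s$asymmetry > best$value)
          best <- list(value = s$asymmetry, n_decoy = N)
      }
      M[i, j] <- best$value
      D[i, j] <- best$n_decoy
    }
  }
  structure(list(max_asymmetry = M, argmax_decoy = D,
                 affinity_grid = affinity_grid, gamma_grid = gamma_grid,
                 affinity_units = affinity_units, decoy_grid = decoy_grid),
            class = "heatmap_result")
}

#' @export
print.heatmap_result <- function(x, ...) {
  cat(sprintf("<heatmap_result> %d affinities x %d decay rates, max %.4f\n",
              nrow(x$max_asymmetry), ncol(x$max_asymmetry),
              max(x$max_asymmetry)))
  invisible(x)
}

#' Fold-change curves across growth media
#'
#' One decoy sweep per growth medium for a given operator.  Following the
#' published simulation protocol, only the dilution rate `gamma` changes
#' between media (division times 25/55/125/225 min); transcription and
#' translation multipliers are available for sensitivity analyses but
#' default to 1.
#'
#' @param operator `"O1"`, `"O2"` or `"Oid"`.
#' @param media Character vector of media names.
#' @param decoy_counts Decoy counts per sweep.
#' @param engine `"cme"` (default) or `"ssa"`.
#' @param plan [sampling_plan()] for the SSA engine.
#' @param beta_mult,alpha_mult Optional per-medium multipliers (named or
#'   recycled) for transcription/translation rates.
#' @param ... Passed to [preset()].
#' @return Named list of `curve_table`s, one per medium, with an attribute
#'   `max_asymmetry` (named vector of the per-medium maxima).
#' @export
growth_scan <- function(operator, media = names(MEDIA_TAU_DIV),
                        decoy_counts = c(0, 30, 100, 300),
                        engine = c("cme", "ssa"), plan = NULL,
                        beta_mult = 1, alpha_mult = 1, ...) {
  engine <- match.arg(engine)
  beta_mult <- rep_len(beta_mult, length(media))
  alpha_mult <- rep_len(alpha_mult, length(media))
  out <- list()
  for (i in seq_along(media)) {
    rs <- preset(operator, media[i], ...)
    rs$beta <- rs$beta * beta_mult[i]
    rs$alpha <- rs$alpha * alpha_mult[i]
    out[[media[i]]] <- decoy_sweep(rs, decoy_counts, plan, engine)
  }
  attr(out, "max_asymmetry") <-
    vapply(out, function(tab) max(tab$asymmetry), numeric(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
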