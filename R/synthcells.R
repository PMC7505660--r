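# Synthetic-cell generator: draws per-cell protein counts from the
# stochastic gene-expression model and dresses them with the measurement
# structure of the microscopy pipeline (fluorescence scales, background,
# autofluorescence, channel crosstalk, cell-area scaling), keeping the
# ground truth.

#' Measurement-noise model for synthetic cells
#'
#' Describes how protein copy numbers map to the recorded per-cell pixel
#' intensities.  Defaults are chosen to resemble working bacterial
#' fluorescence microscopy at the copy numbers this model produces
#' (hundreds to a couple thousand proteins per cell): fluorescence scales
#' that put per-pixel signal comfortably above the autofluorescence
#' scatter even for repressed cells, a frame background much brighter
#' than autofluorescence, a few percent multiplicative measurement noise,
#' ~25% cell-area variability, and the measured 0.25% YFP-to-mCherry
#' crosstalk.
#'
#' @param scale_yfp,scale_mcherry Fluorescence units per protein copy.
#' @param bg_yfp_mean,bg_mcherry_mean Mean frame background (per pixel).
#' @param bg_sd Between-frame background standard deviation.
#' @param af_yfp_mean,af_mcherry_mean Mean per-cell autofluorescence (per
#'   pixel).
#' @param af_sd Cell-to-cell autofluorescence standard deviation.
#' @param cv Multiplicative measurement noise (coefficient of variation) on
#'   each cell's fluorescent signal.
#' @param gamma_cross Injected YFP-to-mCherry crosstalk fraction.
#' @param area_mean,area_sd Cell area distribution (pixels).
#' @param plasmid `"fixed"` (default: every cell carries exactly `n_decoy`
#'   sites, matching the simulations), `"poisson"`, or `"overdispersed"`
#'   (negative binomial with `plasmid_size` dispersion) per-cell decoy
#'   counts.
#' @param plasmid_size Dispersion parameter for the overdispersed option.
#' @param cells_per_frame Cells imaged per frame (shared background draw).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(scale_yfp = 20, scale_mcherry = 10,
                        bg_yfp_mean = 200, bg_mcherry_mean = 150,
                        bg_sd = 4, af_yfp_mean = 40, af_mcherry_mean = 30,
                        af_sd = 4, cv = 0.05, gamma_cross = 0.0025,
                        area_mean = 150, area_sd = 35,
                        plasmid = c("fixed", "poisson", "overdispersed"),
                        plasmid_size = 5, cells_per_frame = 100L,
                        seed = NULL) {
  plasmid <- match.arg(plasmid)
  if (scale_yfp <= 0 || scale_mcherry <= 0)
    stop("fluorescence scales must be > 0", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (gamma_cross < 0 || gamma_cross >= 1)
    stop("gamma_cross must be in [0, 1)", call. = FALSE)
  structure(list(scale_yfp = scale_yfp, scale_mcherry = scale_mcherry,
                 bg_yfp_mean = bg_yfp_mean,
                 bg_mcherry_mean = bg_mcherry_mean, bg_sd = bg_sd,
                 af_yfp_mean = af_yfp_mean,
                 af_mcherry_mean = af_mcherry_mean, af_sd = af_sd,
                 cv = cv, gamma_cross = gamma_cross,
                 area_mean = area_mean, area_sd = area_sd,
                 plasmid = plasmid, plasmid_size = plasmid_size,
                 cells_per_frame = as.integer(cells_per_frame),
                 seed = seed), class = "noise_model")
}

#' Zero-noise measurement model
#'
#' Convenience constructor: fixed area, no background, autofluorescence,
#' measurement noise or crosstalk.  With this model the analysis pipeline
#' inverts the generator exactly.
#'
#' @param ... Overrides passed to [noise_model()].
#' @export
noise_model_exact <- function(...) {
  noise_model(bg_yfp_mean = 0, bg_mcherry_mean = 0, bg_sd = 0,
              af_yfp_mean = 0, af_mcherry_mean = 0, af_sd = 0, cv = 0,
              gamma_cross = 0, area_sd = 0, ...)
}

# draw n_cells (tf_mass, y) pairs from stationary SSA samples spaced by at
# least 5 protein lifetimes
sample_cells_ssa <- function(rates, n_cells, plan = NULL) {
  g_tf <- rates$gamma + rates$gamma_tag_tf
  spacing <- 5 / min(g_tf, rates$gamma)
  if (is.null(plan)) {
    burn <- 10 / g_tf
    plan <- sampling_plan(t_end = burn + spacing * n_cells, burn_in = burn,
                          ts = spacing)
  }
  samp <- simulate_ssa(build_reactions(rates), plan)
  take <- seq_len(min(n_cells, length(samp$tf_total)))
  if (length(take) < n_cells)
    stop("sampling plan yields fewer snapshots than cells", call. = FALSE)
  data.frame(tf = samp$tf_total[take], y = samp$state[take, "y"])
}

#' Generate synthetic single-cell records
#'
#' Draws independent per-cell protein counts (total TF mass and target
#' protein) from steady-state samples of the stochastic model -- snapshots
#' spaced five protein lifetimes apart so consecutive cells are essentially
#' uncorrelated -- then maps counts to fluorescence records: per-protein
#' scales, per-frame background, per-cell autofluorescence, multiplicative
#' measurement noise, YFP-to-mCherry crosstalk, and division by cell area
#' into pixel means.  Optionally the decoy count is resampled per cell to
#' emulate plasmid copy-number noise.
#'
#' Records store the values the analysis pipeline expects: the per-frame
#' background actually applied and the cohort-mean autofluorescence (the
#' per-cell draw differs from the stored mean by `af_sd`, a residual error
#' real pipelines also carry).
#'
#' @param rates A [rate_set()].
#' @param n_cells Number of cells (>= 1).
#' @param noise A [noise_model()].
#' @param plan Optional [sampling_plan()] override for the SSA sampling.
#' @return List with `records` (a cell-record data frame for
#'   [correct_cells()]) and `truth` (per-cell counts, cohort means,
#'   analytic constitutive baselines and the exact cohort fold-changes).
#' @export
generate_cells <- function(rates, n_cells, noise, plan = NULL) {
  stopifnot(inherits(rates, "rate_set"), inherits(noise, "noise_model"))
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$plasmid == "fixed" || rates$n_decoy == 0L) {
    counts <- sample_cells_ssa(rates, n_cells, plan)
  } else {
    ndec <- switch(noise$plasmid,
      poisson = stats::rpois(n_cells, rates$n_decoy),
      overdispersed = stats::rnbinom(n_cells, size = noise$plasmid_size,
                                     mu = rates$n_decoy))
    counts <- data.frame(tf = numeric(n_cells), y = numeric(n_cells))
    for (N in unique(ndec)) {
      idx <- which(ndec == N)
      r <- rates; r$n_decoy <- as.integer(N)
      counts[idx, ] <- sample_cells_ssa(r, length(idx), plan)
    }
  }
  n_frames <- max(1L, ceiling(n_cells / noise$cells_per_frame))
  frame <- rep(seq_len(n_frames), each = noise$cells_per_frame,
               length.out = n_cells)
  bg_y <- stats::rnorm(n_frames, noise$bg_yfp_mean, noise$bg_sd)
  bg_m <- stats::rnorm(n_frames, noise$bg_mcherry_mean, noise$bg_sd)
  area <- pmax(1, stats::rnorm(n_cells, noise$area_mean, noise$area_sd))
  af_y <- stats::rnorm(n_cells, noise$af_yfp_mean, noise$af_sd)
  af_m <- stats::rnorm(n_cells, noise$af_mcherry_mean, noise$af_sd)
  sig_y <- noise$scale_yfp * counts$y *
    (1 + noise$cv * stats::rnorm(n_cells))
  sig_m <- noise$scale_mcherry * counts$tf *
    (1 + noise$cv * stats::rnorm(n_cells))
  yfp_px <- sig_y / area + af_y + bg_y[frame]
  mch_px <- sig_m / area + af_m + bg_m[frame] +
    noise$gamma_cross * sig_y / area
  records <- data.frame(
    yfp_pixel_mean = yfp_px, mcherry_pixel_mean = mch_px, area = area,
    frame = frame,
    frame_background_yfp = bg_y[frame],
    frame_background_mcherry = bg_m[frame],
    autofluor_yfp = noise$af_yfp_mean,
    autofluor_mcherry = noise$af_mcherry_mean)
  g_tf <- rates$gamma + rates$gamma_tag_tf
  base_tf <- rates$beta / rates$gamma_m * rates$alpha / g_tf
  base_y <- rates$beta / rates$gamma_m * rates$alpha / rates$gamma
  truth <- list(tf_counts = counts$tf, y_counts = counts$y,
                mean_tf = mean(counts$tf), mean_y = mean(counts$y),
                analytic_baseline_tf = base_tf,
                analytic_baseline_y = base_y,
                fc_tf = mean(counts$tf) / base_tf,
                fc_target = mean(counts$y) / base_y,
                rates = rates, noise = noise)
  list(records = records, truth = truth)
}

#' Generate a constitutive (unregulated) synthetic cohort
#'
#' Same measurement model as [generate_cells()] but with `kon = 0`, so
#' neither gene is ever repressed.  The corrected totals of this cohort
#' provide the constitutive means for [pipeline_constants()].
#'
#' @inheritParams generate_cells
#' @return As [generate_cells()].
#' @export
generate_constitutive <- function(rates, n_cells, noise, plan = NULL) {
  r0 <- rates
  r0$kon <- 0
  generate_cells(r0, n_cells, noise, plan)
}

#' Run the full analysis pipeline on paired synthetic cohorts
#'
#' Computes constitutive means from the unregulated cohort, corrects and
#' fold-changes the regulated cohort, and returns the per-cell values plus
#' the binned bootstrap curve.
#'
#' @param reg,const Outputs of [generate_cells()] and
#'   [generate_constitutive()].
#' @param ... Overrides passed to [pipeline_constants()].
#' @return List with `constants`, `fc` (per-cell fold-changes),
#'   `curve` ([bin_bootstrap()] output) and the cohort mean fold-changes.
#' @export
analyze_cohorts <- function(reg, const, ...) {
  noise <- reg$truth$noise
  cc0 <- pipeline_constants(constitutive_mean_yfp = 1,
                            constitutive_mean_mcherry = 1,
                            gamma_cross = noise$gamma_cross, ...)
  corr0 <- correct_cells(const$records, cc0)
  constants <- pipeline_constants(
    constitutive_mean_yfp = mean(corr0$yfp_total),
    constitutive_mean_mcherry = mean(corr0$mcherry_total),
    gamma_cross = noise$gamma_cross, ...)
  corr <- correct_cells(reg$records, constants)
  fc <- per_cell_fold_change(corr, constants)
  curve <- bin_bootstrap(fc, constants)
  list(constants = constants, fc = fc, curve = curve,
       fc_tf = mean(fc$fc_tf), fc_target = mean(fc$fc_target))
}
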