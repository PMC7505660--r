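# Single-cell fluorescence analysis pipeline: background/autofluorescence/
# crosstalk correction, per-cell fold-change, binning with bootstrap errors,
# and per-cell asymmetry histograms.

#' Constants of the single-cell analysis pipeline
#'
#' @param constitutive_mean_yfp,constitutive_mean_mcherry Mean corrected
#'   total fluorescence of the unregulated (constitutive) strains; the
#'   fold-change denominators.
#' @param gamma_cross Fraction of YFP signal bleeding into the mCherry
#'   channel (default 0.0025, i.e. 0.25%).
#' @param min_bin_count Bins with fewer cells are dropped (default 50).
#' @param n_boot Bootstrap resamples per bin (default 1000).
#' @param bin_spec List describing the binning of cells by TF fold-change:
#'   `type = "width"` with `n_bins` equal-width bins (default 20).
#' @param seed Seed for the bootstrap.
#' @return An object of class `pipeline_constants`.
#' @export
pipeline_constants <- function(constitutive_mean_yfp,
                               constitutive_mean_mcherry,
                               gamma_cross = 0.0025, min_bin_count = 50L,
                               n_boot = 1000L,
                               bin_spec = list(type = "width", n_bins = 20L),
                               seed = NULL) {
  if (gamma_cross < 0 || gamma_cross >= 1)
    stop("gamma_cross must be in [0, 1)", call. = FALSE)
  if (min_bin_count < 1) stop("min_bin_count must be >= 1", call. = FALSE)
  structure(list(constitutive_mean_yfp = constitutive_mean_yfp,
                 constitutive_mean_mcherry = constitutive_mean_mcherry,
                 gamma_cross = gamma_cross,
                 min_bin_count = as.integer(min_bin_count),
                 n_boot = as.integer(n_boot), bin_spec = bin_spec,
                 seed = seed),
            class = "pipeline_constants")
}

check_records <- function(records) {
  need <- c("yfp_pixel_mean", "mcherry_pixel_mean", "area",
            "frame_background_yfp", "frame_background_mcherry",
            "autofluor_yfp", "autofluor_mcherry")
  if (!all(need %in% names(records)))
    stop("cell records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no cell records", call. = FALSE)
  if (any(records$area <= 0)) stop("cell areas must be > 0", call. = FALSE)
  invisible(records)
}

#' Correct per-cell fluorescence
#'
#' Applies the corrections in the pipeline's fixed order: subtract the
#' frame background, subtract autofluorescence, subtract YFP-to-mCherry
#' crosstalk (`gamma_cross` times the *corrected* YFP pixel intensity from
#' the mCherry pixel intensity), then multiply by cell area to obtain total
#' fluorescence.  Negative corrected values are retained so cohort means
#' stay unbiased; they are flagged.
#'
#' @param records Data frame of cell records with columns
#'   `yfp_pixel_mean`, `mcherry_pixel_mean`, `area`,
#'   `frame_background_yfp`, `frame_background_mcherry`, `autofluor_yfp`,
#'   `autofluor_mcherry`.
#' @param constants A [pipeline_constants()].
#' @return Data frame with `yfp_total`, `mcherry_total` and a `negative`
#'   flag, one row per cell.
#' @export
correct_cells <- function(records, constants) {
  check_records(records)
  yfp_px <- records$yfp_pixel_mean - records$frame_background_yfp -
    records$autofluor_yfp
  mch_px <- records$mcherry_pixel_mean - records$frame_background_mcherry -
    records$autofluor_mcherry - constants$gamma_cross * yfp_px
  out <- data.frame(yfp_total = yfp_px * records$area,
                    mcherry_total = mch_px * records$area)
  out$negative <- out$yfp_total < 0 | out$mcherry_total < 0
  out
}

#' Per-cell fold-change and asymmetry
#'
#' Divides each cell's corrected total fluorescence by the constitutive
#' cohort mean of the matching channel: mCherry reports the TF gene,
#' YFP the target.
#'
#' @param corrected Output of [correct_cells()].
#' @param constants A [pipeline_constants()] with positive constitutive
#'   means.
#' @return Data frame with `fc_tf`, `fc_target` and per-cell `asymmetry`
#'   (`fc_target - fc_tf`).
#' @export
per_cell_fold_change <- function(corrected, constants) {
  if (constants$constitutive_mean_yfp <= 0 ||
      constants$constitutive_mean_mcherry <= 0)
    stop("constitutive means must be positive", call. = FALSE)
  fc_tf <- corrected$mcherry_total / constants$constitutive_mean_mcherry
  fc_target <- corrected$yfp_total / constants$constitutive_mean_yfp
  data.frame(fc_tf = fc_tf, fc_target = fc_target,
             asymmetry = fc_target - fc_tf)
}

#' Bin cells by TF fold-change and bootstrap the bin means
#'
#' Cells are binned by `fc_tf` (equal-width bins per
#' `constants$bin_spec`); bins with fewer than `min_bin_count` cells are
#' excluded.  In each surviving bin, the mean `fc_tf` and `fc_target` are
#' bootstrapped (`n_boot` resamples with replacement, seeded): the
#' reported value is the bootstrapped mean and the error its standard
#' deviation.
#'
#' @param fc_pairs Output of [per_cell_fold_change()].
#' @param constants A [pipeline_constants()].
#' @return A `data.frame` (class `binned_curve`) ordered by `fc_tf`, one
#'   row per surviving bin, with columns `fc_tf_mean`, `fc_tf_sd`,
#'   `fc_target_mean`, `fc_target_sd`, `count`.  If no bin survives, an
#'   empty frame with attribute `empty = TRUE`.
#' @export
bin_bootstrap <- function(fc_pairs, constants) {
  stopifnot(inherits(constants, "pipeline_constants"))
  n <- nrow(fc_pairs)
  if (n < constants$min_bin_count)
    stop("fewer cells than min_bin_count overall", call. = FALSE)
  nb <- constants$bin_spec$n_bins %||% 20L
  rng <- range(fc_pairs$fc_tf)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  bin <- findInterval(fc_pairs$fc_tf, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  if (!is.null(constants$seed)) set.seed(constants$seed)
  rows <- list()
  for (b in sort(unique(bin))) {
    in_bin <- which(bin == b)
    if (length(in_bin) < constants$min_bin_count) next
    m <- length(in_bin)
    boot_tf <- boot_tar <- numeric(constants$n_boot)
    for (k in seq_len(constants$n_boot)) {
      take <- in_bin[sample.int(m, m, replace = TRUE)]
      boot_tf[k] <- mean(fc_pairs$fc_tf[take])
      boot_tar[k] <- mean(fc_pairs$fc_target[take])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fc_tf_mean = mean(boot_tf), fc_tf_sd = stats::sd(boot_tf),
      fc_target_mean = mean(boot_tar), fc_target_sd = stats::sd(boot_tar),
      count = m)
  }
  if (length(rows) == 0L) {
    out <- data.frame(fc_tf_mean = numeric(0), fc_tf_sd = numeric(0),
                      fc_target_mean = numeric(0),
                      fc_target_sd = numeric(0), count = integer(0))
    attr(out, "empty") <- TRUE
    class(out) <- c("binned_curve", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$fc_tf_mean), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  class(out) <- c("binned_curve", "data.frame")
  out
}

#' Histogram of per-cell regulatory asymmetry
#'
#' @param fc_pairs Output of [per_cell_fold_change()].
#' @param bin_width Width of asymmetry bins (default 0.05); bins are
#'   aligned so that 0 is a bin edge.
#' @return List with `breaks`, `counts` (zero counts kept), `mids`, the
#'   fraction of cells with positive asymmetry, and summary quantiles.
#' @export
asymmetry_histogram <- function(fc_pairs, bin_width = 0.05) {
  a <- fc_pairs$asymmetry
  if (length(a) == 0L) stop("no cells", call. = FALSE)
  lo <- floor(min(a) / bin_width) * bin_width
  hi <- ceiling(max(a) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(a, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       frac_positive = mean(a > 0),
       quantiles = stats::quantile(a, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       n = length(a))
}
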