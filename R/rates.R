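#' Kinetic parameter set for the autoregulatory network
#'
#' Bundles every rate constant of the stochastic model: an autoregulated
#' transcription-factor (TF) gene, one identically transcribed target gene,
#' and `n_decoy` competing (non-regulatory) binding sites.  All rates are in
#' events per second.
#'
#' @param kon TF binding rate per free TF dimer per second (same for every
#'   open site).
#' @param koff_tf,koff_target,koff_decoy Unbinding rates (s^-1) of the TF
#'   gene operator, target operator and decoy sites.
#' @param beta mRNA production rate from an unbound promoter (s^-1).
#' @param alpha Translation rate, proteins per mRNA per second.
#' @param gamma_m mRNA decay rate (s^-1).
#' @param gamma Protein decay rate (s^-1): dilution by growth plus any
#'   untagged degradation.  Applies to TF and target protein alike.
#' @param gamma_tag_tf Extra enzymatic degradation applied to TF species only
#'   (ssrA-tagged TF constructs), s^-1.  Default 0.
#' @param kp Dimerization rate constant (s^-1); the stochastic propensity is
#'   `kp * x * (x - 1) / 2` for `x` monomers.
#' @param km De-dimerization rate (s^-1).
#' @param n_decoy Number of decoy binding sites (non-negative integer).
#'
#' @return An object of class `rate_set`.
#' @seealso [preset()] for published parameterizations, [energy_to_koff()]
#'   for deriving unbinding rates from operator binding energies.
#' @export
rate_set <- function(kon, koff_tf, koff_target = koff_tf,
                     koff_decoy = koff_tf, beta, alpha, gamma_m, gamma,
                     gamma_tag_tf = 0, kp = 1.38, km = 2e-6, n_decoy = 0L) {
  rs <- list(kon = kon, koff_tf = koff_tf, koff_target = koff_target,
             koff_decoy = koff_decoy, beta = beta, alpha = alpha,
             gamma_m = gamma_m, gamma = gamma, gamma_tag_tf = gamma_tag_tf,
             kp = kp, km = km, n_decoy = as.integer(n_decoy))
  validate_rate_set(rs)
  structure(rs, class = "rate_set")
}

validate_rate_set <- function(rs) {
  num <- c("kon", "koff_tf", "koff_target", "koff_decoy", "beta", "alpha",
           "gamma_m", "gamma", "gamma_tag_tf", "kp", "km")
  for (f in num) {
    v <- rs[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate_set field '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (rs$gamma <= 0)
    stop("gamma must be > 0: dilution by growth is always present",
         call. = FALSE)
  if (is.na(rs$n_decoy) || rs$n_decoy < 0L)
    stop("n_decoy must be a non-negative integer", call. = FALSE)
  invisible(rs)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>\n")
  cat(sprintf("  kon = %g /TF/s; koff (TF, target, decoy) = %g, %g, %g /s\n",
              x$kon, x$koff_tf, x$koff_target, x$koff_decoy))
  cat(sprintf("  beta = %g, alpha = %g, gamma_m = %g, gamma = %g (+%g tag) /s\n",
              x$beta, x$alpha, x$gamma_m, x$gamma, x$gamma_tag_tf))
  cat(sprintf("  kp = %g, km = %g /s; decoy sites = %d\n",
              x$kp, x$km, x$n_decoy))
  invisible(x)
}

#' Operator binding-energy specification
#'
#' @param operator_name Label, e.g. `"O1"`, `"O2"`, `"Oid"`.
#' @param delta_eps Binding-energy magnitude in kBT units (positive).
#' @param n_ns Number of non-specific genomic binding sites (default 5e6,
#'   the genome size in base pairs).
#' @return An object of class `binding_spec`.
#' @export
binding_spec <- function(operator_name, delta_eps, n_ns = 5e6) {
  if (!is.numeric(delta_eps) || length(delta_eps) != 1L || delta_eps <= 0)
    stop("delta_eps must be a single positive number (kBT)", call. = FALSE)
  if (!is.numeric(n_ns) || length(n_ns) != 1L || n_ns <= 0)
    stop("n_ns must be a single positive number", call. = FALSE)
  structure(list(operator_name = operator_name, delta_eps = delta_eps,
                 n_ns = n_ns), class = "binding_spec")
}

#' Growth condition (division time and protein half-life)
#'
#' @param tau_div Cell division time in minutes.
#' @param tau_half Protein half-life in minutes; `Inf` (default) for stable
#'   proteins whose decay is set by dilution alone.
#' @param label Medium name.
#' @return An object of class `growth_condition`.
#' @export
growth_condition <- function(tau_div, tau_half = Inf, label = "") {
  if (!is.numeric(tau_div) || length(tau_div) != 1L || tau_div <= 0)
    stop("tau_div must be a single positive number of minutes", call. = FALSE)
  if (!is.numeric(tau_half) || length(tau_half) != 1L || tau_half <= 0)
    stop("tau_half must be positive (possibly Inf) minutes", call. = FALSE)
  structure(list(tau_half = tau_half, tau_div = tau_div, label = label),
            class = "growth_condition")
}

#' Convert an operator binding energy to an unbinding rate
#'
#' Solves the thermodynamic relation `kon / (koff + gamma) =
#' exp(-delta_eps) / Nns` for `koff`: the effective dissociation constant of
#' a site is set by its binding energy relative to the pool of non-specific
#' genomic sites, and a bound TF leaves the site either by unbinding or by
#' being degraded (rate `gamma`).
#'
#' @param kon Binding rate per free TF per second (> 0).
#' @param spec A [binding_spec()], or a single positive number taken as
#'   `delta_eps` in kBT.
#' @param gamma TF protein decay rate (s^-1).
#' @param n_ns Non-specific site count; used only when `spec` is numeric.
#' @return `koff` in s^-1.
#' @examples
#' g <- gamma_from_growth(growth_condition(55))
#' energy_to_koff(0.0015, binding_spec("O1", 15.3), g)  # ~0.00149
#' @export
energy_to_koff <- function(kon, spec, gamma, n_ns = 5e6) {
  if (!is.numeric(kon) || length(kon) != 1L || kon <= 0)
    stop("kon must be a single positive number", call. = FALSE)
  if (is.numeric(spec)) spec <- binding_spec("", spec, n_ns)
  if (!inherits(spec, "binding_spec")) stop("spec must be a binding_spec")
  koff <- kon * spec$n_ns * exp(-spec$delta_eps) - gamma
  if (koff < 0)
    stop(sprintf(paste0("binding energy %.3g kBT is too strong for ",
                        "kon = %g and gamma = %g (koff would be negative)"),
                 spec$delta_eps, kon, gamma), call. = FALSE)
  koff
}

#' Invert the binding-energy relation
#'
#' Returns the binding energy (kBT) implied by a `(kon, koff, gamma)`
#' triplet; exact inverse of [energy_to_koff()].
#'
#' @inheritParams energy_to_koff
#' @param koff Unbinding rate (s^-1).
#' @return `delta_eps` in kBT.
#' @export
koff_to_energy <- function(kon, koff, gamma, n_ns = 5e6) {
  if (koff + gamma <= 0) stop("koff + gamma must be positive", call. = FALSE)
  log(kon * n_ns / (koff + gamma))
}

#' Protein decay rate from growth physiology
#'
#' `gamma = ln(2)/tau_half + ln(2)/tau_div` converted to per-second, plus an
#' optional targeted (tag-mediated) degradation rate.
#'
#' @param cond A [growth_condition()].
#' @param gamma_tag Extra enzymatic degradation rate in s^-1 (default 0).
#' @return Decay rate in s^-1.
#' @export
gamma_from_growth <- function(cond, gamma_tag = 0) {
  if (!inherits(cond, "growth_condition"))
    stop("cond must be a growth_condition", call. = FALSE)
  g <- log(2) / (cond$tau_half * 60) + log(2) / (cond$tau_div * 60) + gamma_tag
  if (g <= 0)
    stop("gamma must be > 0: both lifetimes are infinite and no tag is set",
         call. = FALSE)
  g
}

#' Write or read a rate set as a flat YAML file
#'
#' All rates are stored in s^-1 under their `rate_set` field names; the file
#' carries a comment header documenting units.
#'
#' @param rs A [rate_set()].
#' @param path File path.
#' @return `read_rate_set()` returns a [rate_set()]; `write_rate_set()`
#'   returns `path` invisibly.
#' @export
write_rate_set <- function(rs, path) {
  stopifnot(inherits(rs, "rate_set"))
  header <- c("# asymreg rate_set: all rates in s^-1; n_decoy is a count.",
              "# kon is per free TF dimer per second.")
  body <- yaml::as.yaml(unclass(rs), precision = 15L)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_rate_set
#' @export
read_rate_set <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(rate_set, vals)
}
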