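# Reaction-network construction.
#
# The integer state vector has eight species, in this fixed order:
#   1 m_tf      TF mRNA
#   2 m_target  target mRNA
#   3 x         TF monomers
#   4 r_free    free TF dimers
#   5 b_tf      TF-gene operator occupancy (0/1)
#   6 b_target  target operator occupancy (0/1)
#   7 b_decoy   bound decoy sites (0..n_decoy)
#   8 y         target protein
#
# Each reaction channel is (stoichiometry, rate constant, propensity kind).
# Kind codes give the combinatorial factor multiplying the rate constant;
# they are implemented identically here (for tests and diagnostics) and in
# the C++ simulator:
#   1  1                      8  r_free * (1 - b_tf)
#   2  (1 - b_tf)             9  r_free * (1 - b_target)
#   3  (1 - b_target)        10  r_free * (n_decoy - b_decoy)
#   4  m_tf                  11  b_tf
#   5  m_target              12  b_target
#   6  x * (x - 1) / 2       13  b_decoy
#   7  r_free                14  x
#                            15  y

SPECIES <- c("m_tf", "m_target", "x", "r_free", "b_tf", "b_target",
             "b_decoy", "y")

new_network <- function(stoich, rate, kind, name, n_decoy, kind_label) {
  colnames(stoich) <- name
  rownames(stoich) <- SPECIES
  structure(list(stoich = stoich, rate = rate, kind = kind, name = name,
                 n_decoy = as.integer(n_decoy), kind_label = kind_label),
            class = "reaction_network")
}

#' Build the stochastic reaction network of the full model
#'
#' Translates a [rate_set()] into the list of elementary reactions simulated
#' by [simulate_ssa()]: transcription of each gene while its operator is
#' free, translation, mRNA decay, TF dimerization/de-dimerization, binding
#' of free dimers to any open site, unbinding, and first-order decay of
#' every protein species.  Bound TF (operator or decoy) degrades at the same
#' rate as free TF and vacates its site.  TF species (monomer, free dimer,
#' bound dimer) decay at `gamma + gamma_tag_tf`; target protein at `gamma`.
#'
#' @param rates A [rate_set()].
#' @param autoregulation If `FALSE` the TF gene is made constitutive: its
#'   operator never binds TF (no TF-promoter binding/unbinding channels) so
#'   TF production is constant in time.  Used for baselines and for
#'   collapse-onto-thermodynamic-model checks.
#' @return A `reaction_network` object with a stoichiometry matrix (species
#'   x channels), per-channel rate constants and propensity kinds.
#' @export
build_reactions <- function(rates, autoregulation = TRUE) {
  validate_rate_set(rates)
  g_tf <- rates$gamma + rates$gamma_tag_tf
  ch <- list()  # each entry: list(name, dstate (named), rate, kind)
  add <- function(name, rate, kind, ...) {
    d <- numeric(8); names(d) <- SPECIES
    upd <- list(...)
    d[names(upd)] <- unlist(upd)
    ch[[length(ch) + 1L]] <<- list(name = name, d = d, rate = rate,
                                   kind = kind)
  }
  if (autoregulation) {
    add("transcribe_tf", rates$beta, 2L, m_tf = 1)
  } else {
    add("transcribe_tf", rates$beta, 1L, m_tf = 1)
  }
  add("transcribe_target", rates$beta, 3L, m_target = 1)
  add("translate_tf", rates$alpha, 4L, x = 1)
  add("translate_target", rates$alpha, 5L, y = 1)
  add("decay_m_tf", rates$gamma_m, 4L, m_tf = -1)
  add("decay_m_target", rates$gamma_m, 5L, m_target = -1)
  add("dimerize", rates$kp, 6L, x = -2, r_free = 1)
  add("dedimerize", rates$km, 7L, x = 2, r_free = -1)
  if (autoregulation) {
    add("bind_tf_promoter", rates$kon, 8L, r_free = -1, b_tf = 1)
    add("unbind_tf_promoter", rates$koff_tf, 11L, r_free = 1, b_tf = -1)
    add("degrade_bound_tf_promoter", g_tf, 11L, b_tf = -1)
  }
  add("bind_target_promoter", rates$kon, 9L, r_free = -1, b_target = 1)
  add("unbind_target_promoter", rates$koff_target, 12L, r_free = 1,
      b_target = -1)
  add("degrade_bound_target_promoter", g_tf, 12L, b_target = -1)
  add("decay_x", g_tf, 14L, x = -1)
  add("decay_r_free", g_tf, 7L, r_free = -1)
  add("decay_y", rates$gamma, 15L, y = -1)
  if (rates$n_decoy > 0L) {
    add("bind_decoy", rates$kon, 10L, r_free = -1, b_decoy = 1)
    add("unbind_decoy", rates$koff_decoy, 13L, r_free = 1, b_decoy = -1)
    add("degrade_bound_decoy", g_tf, 13L, b_decoy = -1)
  }
  finish_network(ch, rates$n_decoy)
}

#' Build the minimal-model reaction network
#'
#' The minimal model drops the mRNA and dimerization stages: the TF is born
#' directly as a binder at rate `alpha_eff` while its own gene is unbound,
#' and there is no target protein.  Fold-changes for this network are read
#' from promoter occupancy.  This is the stochastic twin of the master
#' equation built by [build_generator()].
#'
#' @param cfg A [cme_config()].
#' @return A `reaction_network` on the same species vector as
#'   [build_reactions()] (`r_free` is the free TF count; unused species stay
#'   at zero).
#' @export
build_minimal_reactions <- function(cfg) {
  stopifnot(inherits(cfg, "cme_config"))
  ch <- list()
  add <- function(name, rate, kind, ...) {
    d <- numeric(8); names(d) <- SPECIES
    upd <- list(...)
    d[names(upd)] <- unlist(upd)
    ch[[length(ch) + 1L]] <<- list(name = name, d = d, rate = rate,
                                   kind = kind)
  }
  add("birth_tf", cfg$alpha_eff, 2L, r_free = 1)
  add("decay_tf", cfg$gamma, 7L, r_free = -1)
  add("bind_tf_promoter", cfg$kon, 8L, r_free = -1, b_tf = 1)
  add("bind_target_promoter", cfg$kon, 9L, r_free = -1, b_target = 1)
  add("unbind_tf_promoter", cfg$koff, 11L, r_free = 1, b_tf = -1)
  add("unbind_target_promoter", cfg$koff, 12L, r_free = 1, b_target = -1)
  add("degrade_bound_tf_promoter", cfg$gamma, 11L, b_tf = -1)
  add("degrade_bound_target_promoter", cfg$gamma, 12L, b_target = -1)
  if (cfg$n_decoy > 0L) {
    add("bind_decoy", cfg$kon, 10L, r_free = -1, b_decoy = 1)
    add("unbind_decoy", cfg$koff_decoy, 13L, r_free = 1, b_decoy = -1)
    add("degrade_bound_decoy", cfg$gamma, 13L, b_decoy = -1)
  }
  finish_network(ch, cfg$n_decoy)
}

finish_network <- function(ch, n_decoy) {
  stoich <- vapply(ch, function(c) c$d, numeric(8))
  new_network(stoich = stoich,
              rate = vapply(ch, function(c) c$rate, numeric(1)),
              kind = vapply(ch, function(c) c$kind, integer(1)),
              name = vapply(ch, function(c) c$name, character(1)),
              n_decoy = n_decoy,
              kind_label = NULL)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d channels, %d decoy sites\n",
              length(x$rate), x$n_decoy))
  invisible(x)
}

#' Propensities of every channel in a given state
#'
#' Pure-R mirror of the propensity evaluation used inside the C++
#' simulator; mainly for tests and diagnostics.
#'
#' @param network A `reaction_network`.
#' @param state Numeric vector of 8 species counts (see [build_reactions()]
#'   for the ordering).
#' @return Numeric vector of per-channel propensities.
#' @export
propensities <- function(network, state) {
  stopifnot(length(state) == 8L)
  s <- as.numeric(state)
  N <- network$n_decoy
  f <- c(1, 1 - s[5], 1 - s[6], s[1], s[2], s[3] * (s[3] - 1) / 2, s[4],
         s[4] * (1 - s[5]), s[4] * (1 - s[6]), s[4] * (N - s[7]),
         s[5], s[6], s[7], s[3], s[8])
  network$rate * f[network$kind]
}

#' Validate a copy-number state vector
#'
#' Checks the state invariants: all counts non-negative, operator
#' occupancies in \{0, 1\}, bound decoys at most `n_decoy`.
#'
#' @inheritParams propensities
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_state <- function(network, state) {
  s <- as.numeric(state)
  if (length(s) != 8L || any(s < 0))
    stop("state must be 8 non-negative counts", call. = FALSE)
  if (!all(s[5:6] %in% c(0, 1)))
    stop("operator occupancies must be 0 or 1", call. = FALSE)
  if (s[7] > network$n_decoy)
    stop("bound decoys exceed n_decoy", call. = FALSE)
  invisible(TRUE)
}

# occupancy state index: 1 both free, 2 target bound, 3 TF gene bound, 4 both
state_index <- function(b_tf, b_target) 1L + b_target + 2L * b_tf
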