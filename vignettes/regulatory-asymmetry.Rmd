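---
title: "Models and methods: regulatory asymmetry in a negative single-input module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: regulatory asymmetry in a negative single-input module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymreg)
```

## The system

`asymreg` models a negative single-input module (SIM): one transcription
factor (TF) represses its own gene and an identically regulated target
gene, while `N` competing "decoy" binding sites titrate the free TF pool.
The motivating experimental system is LacI-mCherry autoregulating itself
and a YFP target in *E. coli*, with decoy arrays on a multicopy plasmid,
but every quantity here is computed from the kinetic model alone.

The full stochastic model tracks eight species: the two mRNAs, TF
monomers `x`, free TF dimers `r` (the binding-competent form), the two
operator occupancies, bound decoys, and target protein `y`.  A free
promoter transcribes at `beta`; mRNA translates at `alpha` and decays at
`gamma_m`; monomers dimerize at propensity `kp x (x-1) / 2` (the matching
deterministic term is `(kp/2) x^2`) and dimers dissociate at `km`; a free
dimer binds any open site at `kon` per site and unbinds at the site's
`koff`; every protein species decays at `gamma` (dilution plus optional
untargeted degradation), with an optional extra `gamma_tag_tf` on TF
species only, standing for ssrA-tag proteolysis.  Bound TF degrades at
the same rate as free TF and vacates its site without returning a dimer
to the pool.  Dimers degrade as a unit -- a single event removes one
dimer -- which keeps total protein decay first order; monomers degrade
singly.

Quantities of interest are fold-changes, `FC = regulated / constitutive`
expression of the same gene, and the *asymmetry* `FC_target - FC_TF`.
The thermodynamic mean-field expectation is

    FC = 1 / (1 + R*),   R* = R_free * kon / (koff + gamma)

for *both* genes, i.e. zero asymmetry whenever the two regulatory
regions are identical.  The stochastic model disagrees: the TF gene is
systematically more repressed than its target.

## Rate calibration

`energy_to_koff()` solves `kon / (koff + gamma) = exp(-deltaE) / Nns`
for `koff`, with `Nns = 5e6` non-specific genomic sites.  With
`kon = 0.0015` per TF per second and the operator binding energies 15.3
(O1), 13.9 (O2) and 16.3 kBT (Oid), this yields 0.00149 s^-1 for O1 and
0.00042 s^-1 for Oid at the glucose dilution rate.  `preset()` carries
the published rate table (`beta = 0.1`, `gamma_m = 0.033`, `kp = 1.38`,
`km = 2e-6` s^-1; division times 25/55/125/225 min for RDM, glucose,
glycerol and acetate).  One caveat is stored deliberately: the published
O2 unbinding rate is 0.0167 s^-1, whereas the energy relation at 13.9
kBT gives about 0.0067 s^-1.  Presets use the published literal;
`energy_to_koff()` exposes the derived value, and nothing in the package
silently reconciles the two.

Protein decay is `gamma = ln 2 / tau_half + ln 2 / tau_div` (converted
to s^-1).  The literature proteolysis rates of the ssrA tags (0.00063,
0.0011 and 0.21 per min per adaptor enzyme for DAS, DAS+4 and LAA) need
an in vivo enzyme copy number the model does not contain, so presets
attach them as metadata only and the effective extra decay
`gamma_tag_tf` is a direct input.

## Exact stochastic simulation

`simulate_ssa()` implements the Gillespie direct method in C++:
exponential waiting times from the total propensity, channel choice
proportional to propensity.  No tau-leaping or hybrid approximation is
used anywhere; exactness is part of the contract.  Trajectories start
from the empty state (all counts zero), which makes the relaxation
transient observable; the default plan simulates 1e6 s, discards 1e5 s
of burn-in -- steady state is reached well within that for the preset
rates -- and records 1e5 equally spaced snapshots.

The published sampling rule spaces snapshots so the slowest reaction
fires ~20 times per interval.  Applied literally, near-inert channels
(de-dimerization at `km = 2e-6` s^-1 acting on a handful of dimers)
would dictate intervals longer than the run, so `suggest_ts()`
interprets "slowest" as the smallest time-averaged propensity among
channels that fired during burn-in *and* are expected to fire at least
once over the run.  Means are insensitive to this choice; standard
errors are computed by batch means over contiguous blocks, which is
autocorrelation-aware, so closely spaced snapshots do not understate
uncertainty.

Fold-change baselines default to a matched `kon = 0` simulation rather
than the closed form `(beta/gamma_m) (alpha/gamma)` (also reported), so
any discretization bias cancels in the ratio.  Replicate `r` of a plan
is seeded `seed + 977 (r - 1)`, making individual replicates
reproducible in isolation.

## The minimal model and its master equation

Asymmetry does not need the mRNA or dimerization stages, so the analysis
model -- the *minimal model* -- has a TF born directly as a binder at
rate `alpha_eff` while its own gene is unbound, decaying at `gamma`, and
binding/unbinding the two promoters and optional decoys.  Fold-changes
are promoter unbound fractions.  `as_cme_config()` maps the full model
onto it with `alpha_eff = beta * alpha / (2 * gamma_m)` (dimer
production per unbound promoter).

`build_generator()` enumerates states `(g, d, n)`: occupancy state `g`
(1 both promoters free, 2 target bound, 3 TF gene bound, 4 both bound),
`d` bound decoys, `n` free TF copies.  `stationary_distribution()`
solves the balance equations exactly (sparse LU) and `cme_summaries()`
reports `P_1..P_4`, the joint expectations `n_i = E[n 1{g=i}]`,
`fc_TF = P1 + P2`, `fc_target = P1 + P3`.

Two identities are exact in this model and are asserted in the test
suite at solver precision:

1. `asymmetry = P3 - P2` -- fold-change differences are occupancy-time
   differences;
2. `(koff + gamma)(P3 - P2) = kon (n2 - n3)` -- subtracting the
   stationary balance equations of states 2 and 3 (decoy transitions
   cancel within each `g`-marginal, so this survives titration).

Identity 2 holds with the joint expectation `n_i`, not the conditional
mean `n_i / P_i`; that is why the package defines `n_i` jointly.  The
mechanism follows from identity 2: state 2 (target bound, TF gene still
producing) carries more TF than state 3, so the system leaves state 2
faster than state 3, spends more time with its own gene silenced, and
the TF gene ends up more repressed.

### Truncation

The free-TF axis is truncated at `n_max`, chosen adaptively: the
starting guess is the deterministic autoregulated fixed point (decoy
aware) plus a 12-sigma margin -- not the constitutive mean, which
overshoots by orders of magnitude at slow degradation where feedback
caps the free pool -- and the solver grows it geometrically until the
stationary mass at the boundary is below 1e-8.  When decoys are nearly
saturated the bound-decoy axis is likewise windowed from below at
`d_min`, guessed from a one-dimensional birth-death surrogate of the
decoy pool, inflated four-fold because slow TF fluctuations overdisperse
the true marginal; a boundary-mass check (same 1e-8 tolerance) widens
the window on failure.  Both truncations lump the outgoing boundary flux
rather than leaking probability, so the generator stays conservative.
Doubling `n_max` beyond convergence changes reported summaries by less
than 1e-8 (tested).

The linear solve pins one reference state near the distribution's mode
and solves for all probabilities relative to it.  Appending a dense
normalization row instead would destroy the sparsity pattern of the LU
factorization (measured: ~20M fill-ins versus ~1M on a 16k-state
problem) and is the single most expensive mistake available here.

## Deterministic models

`naive_steady_state()` is the mass-action mean field of the full model.
Each site's occupancy balance `kon r (1 - o) = (koff + gamma) o`
depends only on the shared free-dimer level, so identical operators
always get identical fold-changes: the model is structurally blind to
asymmetry, and the test suite asserts its asymmetry is zero to 1e-12
across a parameter grid.  The fixed point reduces to a scalar root-find
in `r` (every other species follows algebraically), bracketed and solved
to residual 1e-10.

`partitioned_steady_state()` rewrites the deterministic model with one
probability `P_i` *and one TF mass `N_i` per occupancy state*, closing
the hierarchy with the single-point closure `E[f(n) | i] = f(nu_i)`,
`nu_i = N_i / P_i`: promoter transitions use `kon nu_i`; binding moves
`nu_i - 1` TFs into the receiving state, unbinding `nu_i + 1`, bound-TF
degradation `nu_i`; production runs in states 1 and 2.  The published
account describes the construction ("keep track individually of each
state") without printing the equations, so the balance equations here
are re-derived from that description with the simplest closure, kept in
one function (`partitioned_residuals`) so alternatives can be swapped.
This model *does* predict asymmetry, with the same sign as the master
equation, but not the same magnitude -- the closure discards
within-state variability -- and the tests assert exactly that:
sign agreement, quantitative disagreement.  It is solved by damped
Newton iteration from a product-measure initial guess at the naive fixed
point, to residual 1e-10.

## Rate fitting

`fit_rates()` scans a grid (defaults follow the published search
ranges: `kon` 0.0015-0.003 s^-1, mRNA lifetime 30-90 s, `beta` 0.1-0.3
s^-1, translation rate pinned by a constitutive TF count of 1000-2600)
and minimizes an independent-Gaussian objective -- the published
analysis says "maximum likelihood" without specifying a likelihood, and
sd-weighted least squares is the minimal faithful reading.  The
master-equation engine is the default (fast, deterministic).  Note an
identifiability limit of that engine: `beta` and `gamma_m` enter the
minimal model only through `alpha_eff` and the pinned constitutive
count, so with `tf0` fixed they are degenerate and only `kon` (and
`tf0`) are genuinely recoverable; recovery tests therefore score `kon`.
The SSA engine, which sees burst noise, does distinguish them in
principle.

## Sweep drivers and the degradation optimum

`decoy_sweep()`, `max_asymmetry()`, `asymmetry_heatmap()`,
`degradation_scan()` and `growth_scan()` reproduce the in-silico
experiments: fold-change versus network size, the affinity-degradation
phase diagram, and growth-media comparisons (only `gamma` changes across
media; multipliers for `beta` and `alpha` exist but default to 1).  The
default decoy grid spans 0-300 sites, matching 0-5 plasmid sites at
~60 copies.

The degradation scan holds `alpha_eff` fixed (the TF pool then grows as
degradation slows, which is the physical situation) and takes the
maximum asymmetry over the decoy grid at each half-life.  Asymmetry
vanishes at both extremes -- too little TF to occupy anything, or so
much that both promoters saturate -- with an interior maximum at
half-lives of order ten minutes, comparable to fast division times.
`scripts/acceptance.R` runs this scan over 1-1000 min (20 log-spaced
points, decoys 0-300) with `alpha_eff` fixed for ~1500 constitutive TF
monomers (750 binders, via the same monomer-to-dimer conversion as
`as_cme_config()`) at the glucose dilution rate.  Two caveats on
comparing the scan's peak position with full-model simulations: the
minimal model lacks transcriptional bursting, and holding `koff` fixed
while `gamma` scans means the effective affinity `kon/(koff + gamma)`
weakens at fast degradation, whereas holding the *binding energy* fixed
would let `koff` compensate.  Both push the minimal-model peak toward
slightly faster turnover than a full-model scan at fixed binding
energy.

## Synthetic cells and the analysis pipeline

`generate_cells()` draws independent per-cell (TF mass, target protein)
pairs from stationary SSA snapshots spaced five protein lifetimes apart,
then applies the measurement model: fluorescence scales per protein,
per-frame background, per-cell autofluorescence, multiplicative
measurement noise (`cv`), 0.25% YFP-to-mCherry crosstalk, and cell-area
scaling into pixel means.  The default scales (20 and 10 units per
protein for YFP and mCherry) are sized so that even a strongly repressed
cell's per-pixel signal stands above the autofluorescence scatter --
the defining property of a usable assay; scales low enough to bury the
signal in autofluorescence would emulate an experiment that could not
have produced per-cell fold-changes in the first place.  Records store the per-frame background
actually applied and the cohort-mean autofluorescence, exactly what a
real pipeline would have; the per-cell autofluorescence draw differs
from that mean, a residual error real data also carries.  Lineage and
cell-cycle correlations are deliberately not modeled -- cells are
stationary time samples, as in the published simulations -- so passing
round trips demonstrate correctness of the *pipeline*, not realism of
cell-cycle dynamics.  Plasmid copy-number noise is optional (fixed
count by default, matching the simulations; Poisson or overdispersed
otherwise).

`correct_cells()` applies corrections in the fixed order background,
autofluorescence, crosstalk, area.  The published description is
ambiguous about whether crosstalk subtraction uses raw or corrected YFP;
the corrected (background- and autofluorescence-subtracted) signal is
used, which makes injection and correction exact inverses (tested).
Negative corrected intensities are kept, flagged, so cohort means stay
unbiased.  `bin_bootstrap()` bins by TF fold-change in equal-width bins
(the published account does not state the bin width or whether binning
was equal-width or equal-count; equal-width with a configurable count is
the default), drops bins under 50 cells, and reports seeded bootstrap
means and standard deviations (default 1000 resamples).

## Problem sizes and numerical defaults

Test-suite simulations use scaled-down conditions chosen to leave Monte
Carlo error well below the effects under test: SSA runs of 1e6 s with
1e5 snapshots for cross-validation and titration sweeps, 24-replicate
ensembles for relaxation, 100-point random sweeps for the exact
identities, cohorts of a few hundred synthetic cells, and master
equations up to ~1e5 states.  The acceptance script's degradation scan
is the largest computation (20 half-lives x 5 decoy counts, the largest
solves ~1e5 states).  Key tolerances: stationary-solve residual 1e-9,
truncation tails 1e-8, deterministic residuals 1e-10, identity checks at
1e-10/1e-8.

## Known limitations

- The minimal model's decoys share one `koff` (`koff_decoy` defaults to
  `koff`); the full model allows per-class unbinding rates.
- `partitioned_steady_state()` covers the decoy-free minimal model; the
  partitioned hierarchy with decoys would need per-state decoy masses.
- The master-equation path to synthetic cells is not provided: the
  minimal model carries no target-protein count, so `generate_cells()`
  samples the full model by SSA.
- No tetramerization, DNA looping or inducer kinetics (the modeled
  construct lacks the tetramerization domain), and no time-dependent
  master-equation solutions.
- Growth-rate effects enter only through `gamma` unless multipliers are
  set; systematic transcription/translation rescaling with growth is out
  of scope.
- Synthetic cells are instantaneous stationary snapshots.  Measured
  fluorescence integrates protein over maturation and the cell cycle,
  which narrows per-cell distributions, so single-cell asymmetry
  histograms from `generate_cells()` are broader than microscopy ones:
  a cohort whose measured counterpart is almost entirely
  positive-asymmetric shows a positive median and majority here, with
  heavier tails.  Cohort-level fold-changes are unaffected.
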