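# asymreg

Regulatory asymmetry in negatively autoregulated single-input modules.

## The problem

In the single-input module (SIM) motif, one transcription factor (TF)
represses a set of genes *and itself*. Even when the TF gene and a target
gene carry identical promoters and identical operator sites, they are not
regulated equally: the TF gene is systematically more repressed. The
mean-field intuition — that both genes should obey the thermodynamic
relation

    FC = 1 / (1 + R*),    R* = R_free · kon / (koff + γ)

and hence respond identically — fails, because the two genes sample the
free-TF pool at different moments. When the target's operator is bound
(and the TF gene is free), the cell is still producing TF; when the TF
gene's operator is bound, it is not. The two promoters therefore
experience different effective TF concentrations, and the *asymmetry*

    asymmetry = FC_target − FC_TF  =  P3 − P2  =  kon/(koff+γ) · (n2 − n3)

is exactly the difference in stationary occupancy of the two
single-bound promoter states (state 2: target bound; state 3: TF gene
bound), equivalently the difference in the TF mass those states carry.
Both identities are exact in the minimal model and are verified by the
test suite at solver precision.

`asymreg` is aimed at quantitative gene-regulation and synthetic-biology
work: it provides an exact Gillespie simulator of the full reaction
network (mRNA, monomers, dimers, two promoters, decoy sites), a sparse
chemical-master-equation solver for the minimal model, naive and
state-partitioned deterministic models, calibration of binding kinetics
from operator binding energies, sweep drivers (network size, binding
affinity, degradation rate, growth medium), the single-cell fluorescence
analysis pipeline (background/autofluorescence/crosstalk correction,
binning, bootstrap), and a synthetic-cell generator with retained ground
truth.

## Worked example

Fold-change of TF and target versus network size (decoy count), at the
published glucose/O1 kinetics:

```r
library(asymreg)

rs <- preset("O1", "Glucose")          # kon = 0.0015, koff = 0.00149 /s, ...
plan <- sampling_plan(t_end = 1e6, burn_in = 1e5, seed = 7)
tab <- decoy_sweep(rs, c(0, 50, 150, 300), plan = plan, engine = "ssa")
tab[, c("n_decoy", "fc_tf", "fc_target", "asymmetry", "mean_r_free")]
#>   n_decoy      fc_tf  fc_target   asymmetry mean_r_free
#> 1       0 0.04066643 0.04217474 0.001508316    27.41271
#> 2      50 0.08483532 0.14126576 0.056430436    12.84372
#> 3     150 0.17825555 0.35648397 0.178228421     4.16128
#> 4     300 0.31174335 0.47760829 0.165864937     1.83024
```

Both genes are *de-repressed* as decoys titrate the free pool
(`mean_r_free` falls from ~27 to ~1.8 dimers), and the target is always
expressed above the autoregulated TF gene — at 300 decoys the TF gene
sits at 31% of its constitutive level while its identically regulated
target sits at 48%. The same sweep through the master-equation engine
(`engine = "cme"`) is deterministic and seconds-fast.

The degradation dependence (minimal model, production fixed for ~1500
constitutive TF monomers, i.e. 750 binding dimers, at the glucose
dilution rate):

```r
scan <- degradation_scan(c(2, 6, 15, 40, 100, 250, 600),
                         alpha_eff = 750 * gamma_from_growth(growth_condition(55)),
                         decoy_grid = c(0, 30, 300))
scan
#>   half_life_min        gamma max_asymmetry n_decoy
#> 1             2 5.776227e-03   0.139098264      30
#> 2             6 1.925409e-03   0.224536307      30
#> 3            15 7.701635e-04   0.159147047      30
#> 4            40 2.888113e-04   0.116735479     300
#> 5           100 1.155245e-04   0.076578473     300
#> 6           250 4.620981e-05   0.029029655     300
#> 7           600 1.925409e-05   0.005652583     300
attr(scan, "peak_half_life_min")
#> [1] 6
```

Asymmetry vanishes when TF turnover is too fast or too slow, with an
interior maximum at half-lives of order ten minutes — comparable to
fast bacterial division times.

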