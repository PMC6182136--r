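# transokin

Stochastic kinetics of transpososome assembly.

## The problem

Cut-and-paste DNA transposons are mobilized only after their transposase
binds both transposon ends and joins them in a paired-ends complex (PEC,
the transpososome). Transposase subunit architecture splits the known
enzymes into two assembly pathways with very different systems-level
consequences:

* **S-NEC** (synapsis by naked-end capture): transposases that are
  multimers *before* touching DNA — the eukaryotic pattern, and engineered
  single-chain dimers — bind one end and then capture the naked partner
  end.
* **S-PD** (synapsis by protein dimerization): monomeric bacterial
  transposases bind the two ends independently and synapse by
  protein–protein dimerization.

S-NEC is intrinsically faster (fewer bodies must meet), but it carries an
emergent cost: at high transposase concentration both ends become occupied
and no naked end remains to capture, so the transposition rate *falls* —
over-production inhibition (OPI). The pathway choice also dictates how the
rate responds to genome size, because nonspecific DNA sequesters
transposase. `transokin` implements these models for simulation and
hypothesis testing: reaction-network builders (with mutants: DDE→ADE
active sites, G462D dimer-interface, single-chain dimers), an exact
Gillespie engine with a finite-state CTMC oracle, mean-field ODE
integration, dose-response / genome-size sweeps with OPI detection,
generation-based genomic-invasion simulations, and archetype parameter
ensembles for a bacterial-style (Tn5-like) and a eukaryotic-style
(Hsmar1-like mariner) enzyme.

The core state machine per element (S-NEC shown; `b = k1·[T]`,
`u = k-1`, capture at `k2·attenuation`):

    FF  --2b-->  BF/FB  --k2·att-->  PEC  --k3-->  DONE
    BF/FB --b--> BB   (doubly occupied: OPI-blocked, exits only at 2u)

Transposition rate is operationalized as 1 / (mean first-passage time to
PEC), since synapsis is irreversible and commits the element.

## Worked example: OPI is an emergent property of the dimer

```r
library(transokin)

rates <- make_archetype_params("HSMAR1")   # eukaryotic-style natural dimer
net <- build_network("S_NEC", rates, genome_context(4e3),
                     mutant_spec("NATURAL_DIMER"),
                     transposase_count = concentration_to_count(100e-9, 1e-15))
net
#> <reaction_network> pathway=S_NEC, 10 species, 14 reactions (9 labels)
#>   initial state: T=60, E_FF=1, E_BF=0, E_FB=0, E_BB=0, PEC=0, DONE=0, NS=4000, TNS=0, TMONO=0

tab <- dose_response("S_NEC", rates, genome_context(4e3),
                     mutant_spec("NATURAL_DIMER"), reps = 200, seed = 1)
print(as.data.frame(tab), digits = 3)
#>   grid_value mean_rate       se reps censored_fraction
#> 1   7.00e-11  0.000000       NA  200             1.000
#> 2   2.21e-10  0.000000       NA  200             1.000
#> 3   7.00e-10  0.000000       NA  200             1.000
#> 4   2.21e-09  0.004392 2.62e-04  200             0.005
#> 5   7.00e-09  0.000360 2.41e-05  200             0.000
#> 6   2.21e-08  0.000184 1.02e-05  200             0.190
#> 7   7.00e-08  0.000141 9.47e-06  200             0.580
#> 8   2.21e-07  0.000131 1.16e-05  200             0.805
#> 9   7.00e-07  0.000125 1.98e-05  200             0.940

detect_opi(tab)
#> <opi_verdict> is_opi=TRUE (peak index 4; z vs first 16.80, z vs last 16.27)
```

Reading the table: the rate (per element per second, `1/mean first-passage
to PEC`) peaks at ~2 nM transposase and *declines* thirty-fold by 700 nM —
the ends are doubly occupied and capture starves. The three lowest points
are zero because sub-0.1 nM in the 1 fL default volume rounds to zero
molecules. Running the same sweep with the Tn5-like single-chain dimer
archetype (`TN5_SCD`, weak single-end binding) gives a monotone increasing
curve and `is_opi=FALSE`: the same assembly pathway, but rate constants
unfavourable to OPI.

Other entry points: `solve_ctmc_exact()` (exact oracle the SSA is
validated against), `genome_size_response()` (sequestration-driven
genome-size effects), `run_invasion()` (self-limiting S-NEC invasions vs
runaway S-PD amplification), `predict_cleavage_products()` (single-chain
dimer mutant combinatorics), and the CLI:

```sh
Rscript inst/cli/transokin dose-response --archetype HSMAR1 --out results/
Rscript inst/cli/transokin validate
```

Every output TSV is paired with a JSON sidecar holding the fully resolved
configuration and seed; re-running with `--config <sidecar>` reproduces
the run bit-identically.

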