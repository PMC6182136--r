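---
title: "Kinetic models of transpososome assembly: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of transpososome assembly: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transokin)
```

## The model

Before a cut-and-paste transposon can be excised, its transposase must bind
both transposon ends and bring them together in a paired-ends complex (PEC,
the transpososome). `transokin` simulates the two canonical assembly
pathways as elementary mass-action reaction networks:

* **S-NEC (synapsis by naked-end capture).** A pre-formed transposase
  multimer (a natural dimer, or an engineered single-chain dimer) binds one
  end (rate constant $k_1$, per molar per second), may dissociate
  ($k_{-1}$), and captures the naked partner end ($k_2$). Capture is
  modelled as *unimolecular* because the partner end is tethered on the
  same DNA molecule; its molecularity is not observable from bulk kinetics
  and intramolecular synapsis is the natural reading for plasmid or
  chromosomal substrates. When **both** ends carry a dimer there is no
  naked end left to capture: that doubly occupied state has no synapsis
  channel and exits only by unbinding. This blocked state is the entire
  mechanism of over-production inhibition (OPI) in the model — no
  dedicated inhibition parameter exists.
* **S-PD (synapsis by protein dimerization).** Monomeric transposases bind
  the two ends independently; synapsis requires protein–protein
  dimerization of the two end-bound monomers. The literal four-body
  collision is decomposed into elementary steps: two independent binding
  events followed by a unimolecular dimerization at $k_2$ from the doubly
  occupied state. The pathways are therefore mirror images: S-NEC cannot
  synapse *from* double occupancy, S-PD can synapse *only* from it.

Synapsis is treated as irreversible and as the commitment point of the
reaction, so "transposition rate" is operationalized throughout as the
reciprocal mean first-passage time to the PEC per element (first passage
to the completed state, after the lumped post-synapsis constant $k_3$,
is available via `target = "DONE"`). Nonspecific DNA is a pool of
`floor(genome_length / spacing)` sites binding transposase with
$k_{ns}^{on}/k_{ns}^{off}$; it sequesters protein in proportion to genome
size. A `cis_acting` context removes that competition and makes the
effective transposase concentration genome-size independent, which is how
bacterial cis-acting transposases are represented.

## Parameters and defaults

All internal time is seconds and all concentrations molar; counts are
converted only at the boundary (`concentration_to_count()`, nearest
integer, default volume 1 fL so nanomolar concentrations give tractable
molecule counts).

Only two absolute rates are anchored by measurement: the eukaryotic-style
dimer's subunit-exchange rate ($t_{1/2} \approx 3$ h $\Rightarrow
k = \ln 2 / t_{1/2} = 6\times10^{-5}\,s^{-1}$; note that a $1/t_{1/2}$
convention would give $9\times10^{-5}$, so the exponential-decay convention
is load-bearing) and its single-end dwell time ($\approx 10$ min
$\Rightarrow k_{-1} = 1/600\,s^{-1}$). Everything else is pinned once in
the archetype table and never revisited:

| parameter | TN5 archetypes | HSMAR1 archetype | rationale |
|---|---|---|---|
| $k_1$ (`k_bind`) | $10^5$ /M/s | $10^7$ /M/s | one specific helix vs two HTH domains; only the ordering is constrained |
| $k_{-1}$ (`k_unbind`) | $0.1$ /s | $1/600$ /s | "sub-minute" vs 10-min dwell; 0.1 is a decision |
| $k_2$ (`k_synapsis`) | $0.05$ /s | $0.05$ /s | chosen so the reference in-vitro condition (7 nM two-ended substrate, 100 nM transposase) completes synapsis in minutes, well inside a 4 h incubation |
| attenuation | 1 | 0.1 | the conformational change after single-end binding that lowers effective $k_2$ exists only in the eukaryotic-style enzyme |
| $k_3$ (`k_post`) | 0.01 /s | 0.01 /s | lumped post-synapsis steps; rarely rate-limiting |
| $K_{d,ns}$ | 100 µM | 1 mM | "significant" vs "weak" nonspecific binding; a ten-fold contrast, with the absolute scale set so sequestration becomes substantial between the 4 kb plasmid and Mb-scale genomes at cellular DNA concentrations (4 Mb in 1 fL is ~6.6 mM of 1-bp sites) |
| multimer dissociation | 0 | $6\times10^{-5}$ /s | covalent vs natural dimer |

`make_archetype_params()` can jitter these log-normally into ensembles;
draws are rejected until the qualitative orderings hold.

## Engines and numerical choices

* **SSA**: the Gillespie direct method, in C++, with a counter-seeded
  xoshiro256++ generator so that `(network, horizon, seed)` is bit-identical
  across platforms and replicate streams are derived deterministically.
  Tau-leaping is deliberately absent: exactness is required for oracle
  comparisons and the networks are small. A state with zero total
  propensity terminates cleanly (`status = "exhausted"`); no tie-breaking
  is ever needed because the waiting time is then infinite.
* **Exact oracle**: breadth-first state enumeration (hard cap 20 000
  states), sparse generator, transient distribution by uniformization,
  and mean first-passage times from the standard linear system restricted
  to transient states reachable without touching the target set. The
  package validates the SSA against this oracle (`validate_engines()`,
  CLI `validate`).
* **Mean field**: mass-action ODEs over species means with an adaptive
  Cash–Karp RK4(5) integrator written in R (no ODE-solver package is
  assumed present); conserved totals are preserved to within $10\times$
  the requested tolerance.
* **Censoring**: replicates that miss the horizon are reported, never
  raised. Rates use $1/\overline{t}$ of the uncensored times with the
  censoring fraction attached; at heavily censored grid points this
  estimator is biased toward the fast tail, which is why the genome-size
  sweeps that need uncensored comparisons use longer horizons
  ($10^5$–$2\times10^5$ s) rather than a different estimator.

## Mutant combinatorics

Cleavage is attributed to the subunit engaged at each end: within a PEC an
end is cut iff its engaged subunit carries a functional DDE active site.
An S-NEC single-chain dimer spans the complex with one subunit at each
end, so one DDE→ADE subunit yields exclusively single-end cleavage
(linearized substrate) and a G462D dimer-interface subunit on either side
abolishes synapsis outright — the network simply loses its capture
channel. For the *hypothetical* double-dimer S-PD route, each end is
engaged by one randomly chosen subunit of a separate single-chain dimer
(`engagement_bias`, default 0.5) and the complex assembles only if both
engaged subunits have wild-type interfaces. Unbiased enumeration of the
four configurations gives 25% relative activity for a one-dead-interface
dimer. The classical expectation is quoted as an upper bound of 50%; the
combinatorics behind that figure are not fully specified, so this package
treats 50% strictly as a bound and reports the enumerated 25% as its
point prediction (`scripts/acceptance.R`, target `t5`).

## The invasion module

The generation-based invasion is a reconstruction: per generation each
element transposes independently with probability
$1 - e^{-r\,\Delta t}$, where $r$ comes from an exact first-passage
solution of the element-level chain at the mean-field free-transposase
concentration (trans-acting expression: `transposase_per_copy × copies`;
cis-acting: a constant local concentration), discounted by equilibrium
nonspecific sequestration. Each event adds a copy with
`duplication_probability` (default 1). A trans-acting inhibitor scales
$k_2$ competitively by $1/(1 + I/K_i)$; that mechanism is one choice among
several (reducing $k_1$, titrating protein) and is the only one
implemented.

Two deliberate design choices deserve emphasis:

* **Shared naked-end pool** (`shared_end_pool = TRUE`). In a multi-copy
  nucleus, a dimer bound at one end competes for naked ends drawn from the
  genome-wide pool, so the capture rate is additionally scaled by the
  naked-end fraction $k_{-1}/(k_{-1}+k_1 T)$. Without this term the
  per-element OPI tail falls exactly as $1/T$, total transposition per
  generation tends to a constant, and copy number grows linearly forever —
  no parameterization of the cis-only model can self-limit. With it the
  tail is $1/T^2$ and the S-NEC invasion approaches a plateau, which is
  the regulatory behaviour the module exists to reproduce. Reaction
  networks built by `build_network()` keep the conservative cis-partner
  default; the pool term is an invasion-level closure.
* **Horizon of 200 generations.** Past the OPI peak the mean copy number
  grows like $\sqrt{\text{generations}}$, so the per-generation increment
  decays slowly; the default horizon is set long enough that the
  self-limited regime, not the shoulder of the peak, is what the plateau
  statistic sees. The plateau criterion itself (mean increment over the
  final 10% of generations below 10% of the peak increment) is fixed, not
  tuned.

Copy loss, excision scars, host fitness costs and selection are all out of
scope; copy numbers are non-decreasing by construction.

## What the synthetic world does and does not establish

The generator emulates: the stated orderings of rate constants between the
bacterial-style and eukaryotic-style enzymes, the two measured Hsmar1-like
rates, exponential single-step dwell times, and cellular DNA
concentrations for nonspecific competition. It does not emulate sequence
heterogeneity, facilitated diffusion (sliding/hopping), DNA supercoiling,
crowding, gel- or colony-level observables, or expression noise. A green
test therefore establishes that the *model class with the pinned
parameters* reproduces the qualitative phenomena (pathway dominance, the
OPI dichotomy between architectures, the genome-size dichotomy with its
threshold behaviour, mutant phenotypes, invasion self-limitation) — not
that the parameter values are those of the real enzymes. Experimentally
measured effect sizes (fold-hyperactivity in cells, papillation
intensities) are deliberately outside the acceptance surface.

Specific scale-downs worth knowing about when reading the tests: the
pathway-dominance comparison runs in a 100 fL volume so that the lowest
dose-grid point still contains a few molecules (in the default 1 fL a
sub-0.1 nM concentration rounds to zero molecules and both pathways tie
at rate zero), and it sets $k_{ns}^{on}=0$ since sequestration acts on
both pathways identically. The S-NEC genome-size sweeps use the 4 Mb–400 Mb
range: beyond it the default sequestration pushes the effective
concentration *below* the OPI peak and the rate correctly turns over —
the model predicts an optimum, not an unbounded increase.

## Known limitations

* The uncensored-mean rate estimator is biased when censoring is heavy;
  tables carry the censoring fraction so users can judge.
* The CTMC oracle is limited to ~20 000 reachable states and refuses
  larger systems rather than approximating.
* `cis_acting` networks with more than one element are rejected (a truly
  private per-element pool is not expressible in one shared-species
  network); invasion handles the multi-copy cis case at the mean-field
  level instead.
* Natural-dimer subunit dissociation is one-way (no reassociation channel);
  at $6\times10^{-5}\,s^{-1}$ it is negligible on assay timescales, which
  is the point of modelling it at all.
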