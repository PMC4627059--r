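---
title: "Evolving allosteric signaling networks in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving allosteric signaling networks in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosig)
```

## What the package models

`evosig` simulates the evolution of protein signaling networks. The evolving
entity is a **binary-string genome**; a rule-based compiler translates it
into a concrete biochemical model -- a set of multi-domain, allosteric
proteins, the binding and catalysis rules among their reactive sites, and
the mass-action ODE system those rules imply. Fitness functions probe the
network's input-output behaviour (ultrasensitivity or adaptation), and two
evolutionary engines drive the genome through biologically motivated
mutation operators.

The package is organized along that pipeline:

1. **Genome codec** (`genome()`, `parse_genome()`, `serialize_genome()`,
   `decode_scaled()`),
2. **Network compiler** (`compile_network()` and the primitives `binds()`,
   `rate_from_profiles()`, `effective_profile()`, `allosteric_rates()`),
3. **Dynamics** (`build_odes()`, `simulate_to_steady_state()`,
   `run_protocol()`),
4. **Fitness** (`score_ultrasensitivity()`, `score_complexity()`,
   `combine_fitness()`, `score_adaptation()`, `score_genome()`),
5. **Mutation** (`mutate_genome()` and the individual operators),
6. **Evolution** (`fixation_probability()`, `random_walk_evolve()`,
   `roulette_select()`, `population_evolve()`),
7. **Workbench** (`signaling_seed_spec()`, `build_seed_genome()`,
   `prune_network()`, `saturation_params()`, exports, `run_cli()`).

## The genome and its translation

A genome is any finite string over {0, 1}. Protein-coding sections are
delimited by an 8-bit start code (`01111110`) and a 3-bit stop code
(`111`); inside a protein, domains are separated by a soft linker (`001`)
and reactive sites within a domain by a hard linker (`000`). Every
parameter is a fixed-width field; fields are read big-endian (first bit
most significant, an arbitrary convention fixed once). Parsing is **total**:
any separator pattern other than the three defined ones, or a truncated
field, aborts the candidate protein, the region remains untranslated
"junk", and scanning resumes right after the aborted start code. Junk is
preserved verbatim, so parse-then-serialize is bit-identical on any input
-- the property the mutation machinery relies on.

Bit fields map to real parameters by a linear scaling
(`lo + (hi - lo) v / (2^L - 1)`, used for the allosteric partition exponent
Phi on [0, 1]) or a log-linear scaling (`lo (hi/lo)^(v / (2^L - 1))`, used
for everything spanning decades). Default ranges follow measured
biochemistry for signaling proteins: concentrations and binding/catalytic
constants on [1e-3, 1e3] (uM, uM^-1 s^-1, s^-1), conformational transition
rates and the equilibrium-shift factor Gamma on [1e-2, 1e2]. Two notes on
deliberate choices:

* The layout provides a **single** basal R-T transition-rate field per
  domain, so the basal `k_RT = k_TR = r` and the basal equilibrium is 1;
  any equilibrium bias is carried by the Gamma factors, which can represent
  it without loss.
* The undefined site-type pattern `10` decodes to a binding site -- the
  inert default, so random or mutated genomes never fail to decode.

## From genome to reaction network

Whether two sites interact is decided by their 10-bit **binding profiles**:
binding occurs when the XOR of the two profiles has at least
`binding_threshold` ones (default 9 of 10 -- a strict threshold keeps
networks from becoming promiscuous and the state space from exploding).
Rules form between pairs of binding sites (plain binding) and between a
catalytic site and a modification site (catalysis); all other combinations
are inert.

Kinetics are pairwise too: the association and dissociation constants of a
bound pair are log-linear in the Hamming distance between the partners'
20-bit kf (kb) profiles, so identical profiles give the slowest rate and
complementary profiles the fastest. Conformation and modification state
enter through XOR **masks**: in the T conformation a site's rate profiles
are flipped by its conformational mask, and a modified msite's profiles by
its modification mask. An all-zero mask has no effect, so state dependence
is itself evolvable. Masks never touch the binding profile: who can bind is
state-independent, how fast is not. The catalytic rate is decoded directly
from the csite's 10-bit kp profile (after the conformational mask, of which
the first 10 bits apply, since masks are 20 bits wide in the layout).

Allostery follows the two-state MWC picture. Each occupied or modified
site on an allosteric domain multiplies the domain's R-T equilibrium
constant by its Gamma_i; the combined shift `G` is split between the two
transition rates by the domain's Phi: `k_RT' = k_RT G^Phi`,
`k_TR' = k_TR G^(Phi-1)`.

`compile_network()` enumerates species by breadth-first closure from the
initial monomer pool (every protein all-R, unmodified): conformational
flips, binding/unbinding, and catalysis through an explicit
enzyme-substrate complex. A catalytic site binds only the substrate state
it can act on (a kinase-like site binds the unmodified msite, a
phosphatase-like site the modified one) and converts on release --
Michaelis-Menten saturation emerges from the explicit complex, which is
what zero-order ultrasensitivity requires, while keeping the state space
bounded. Complexes are capped at `max_complex_size` monomers (default 2;
ring closure within a complex is not modeled) and enumeration aborts with
an explicit "network blow-up" error past `max_species` (default 2000)
rather than silently truncating; the fitness layer scores such genomes as
non-viable. Species are canonically ordered, so compilation is a pure
function of (bits, configuration) -- byte-identical outputs across runs.

## Dynamics and stimulus protocols

The ODE system is `dx/dt = S v(x)` with mass-action fluxes (a symmetric
`2X -> X2` binding carries flux `k [X]^2`). Steady states are found with
`deSolve`'s `lsodar`: one solver call per phase on a log-spaced time grid,
stopping at the root of the normalized-derivative criterion
`max_i |dx_i/dt| / (atol + |x_i|) < ss_tol`. Defaults: `rtol = 1e-6`,
`atol = 1e-9` uM, `ss_tol = 1e-6`, `t_max = 1e5` s -- stiff-safe values
that resolve the slow relaxation of nearly saturated modification cycles.
A per-interval step budget (`max_steps = 5000` on a 40-point log time
grid) caps the effort any single evaluation may consume, so one
pathologically stiff mutant cannot stall an evolution run. Solver failure,
budget exhaustion and non-convergence are never errors; they flow into the
scores as fitness 0.

A stimulus protocol clamps the **total** concentration of the input
protein at each phase boundary by rescaling its free (monomeric) forms; if
the new total is below the currently bound amount, free forms drop to zero,
bound complexes are scaled down proportionally, and their partner content
is released back to monomers in the state it held inside the complex, so
all other proteins stay exactly conserved. (Whether a cell "removes" bound
or free ligand is a modeling choice; clamping the free form first is the
least invasive one.) The staircase protocol for ultrasensitivity visits
four log-spaced levels up and back down (defaults 0.01, 0.1, 1, 10 uM --
the middle decades of the concentration range); the step protocol for
adaptation is baseline / step / baseline.

The scalar **output observable** is the summed concentration of
output-protein copies whose *first* modification site is modified,
counting copies inside complexes -- the natural phospho-readout for a
kinase/phosphatase target.

## Fitness

For ultrasensitivity, the staircase gives transition magnitudes
`D1, D2, D3` per direction (`D2` the middle step):

* amplitude `A = D2 / y_max` with `y_max` the total output-protein
  concentration;
* ultrasensitivity `U' = max(0, (3U - 1)/2)`, `U = D2 / (D1 + D2 + D3)`,
  so an equal-step (linear) response scores 0 and a pure middle-step
  switch scores 1.

`S_amp` and `S_ult` average the two directions. Complexity is counted
structurally, `C` = proteins + domains + sites + rules, and scored
`S_com = exp(-C / C0)` with `C0 = 100`. The combined fitness is the
weighted geometric mean
`F = (S_amp^wa * S_ult^wu * S_com^wc)^(1/(wa+wu+wc))`; any positively
weighted zero sub-score zeroes F. These sub-score forms are the package's
own documented defaults for the quantities scored (step differences and
structural counts); they are deliberately simple, monotone, and bounded in
[0, 1].

For adaptation, each step direction yields a peak deviation `dO_max` and a
residual deviation `dO_ss` from the pre-step steady output;
sensitivity `= dO_max / (O_pre + dO_max)` rewards responding at all,
precision `= 1 - dO_ss / dO_max` rewards returning to baseline, and the
adaptation fitness is the geometric mean of `sensitivity * precision` over
the two directions. In `score_genome(objective = "adaptation")` the two
direction terms enter the same weighted-geometric-mean combiner in place
of `S_amp`/`S_ult`, so the complexity pressure is applied identically in
both objectives.

## Mutation

Eight operators, applied in a fixed order (rearrangement, protein
duplication, protein deletion, domain duplication/deletion, shuffling,
point mutation) so a (parent, rates, seed) triple is perfectly
reproducible; every event is logged with enough detail that
`replay_mutations()` rebuilds the child bit-exactly.

Structural operators snap to whole reactive-site blocks: duplicated or
shuffled fragments stay parseable, a fragment starting at a domain head
carries the domain header (so duplicating a whole domain yields a new
identical domain, while a mid-domain fragment fuses into its neighbour by
a hard linker), deleting all sites of a domain removes the domain, and a
protein losing all sites disappears. Genome rearrangement works at the bit
level across protein boundaries and may well break reading frames -- the
total parser turns the damage into junk, which is the intended source of
gene loss and of raw material. Point mutations can likewise silence a gene
by corrupting its start code, or resurrect junk into a new gene.

A `protection_mask()` freezes chosen proteins against duplication,
deletion, domain operations, rearrangement overlap and HGT insertion, and
chosen bit spans against point mutation; evolution runs protect the input
and output proteins (and their start codes) so the scored function keeps
its anchors, while their kinetic parameters remain free to evolve.
Protected proteins are re-identified by bit content after restructuring
operators; rates are per bit (point), per protein (duplication, deletion,
domain operations, shuffling), per genome (rearrangement) and per
individual (HGT, population mode only).

Default rates (configurable) were fixed once at values that make point
mutations the common event (2 or 3 flips per replication of a
kilobase-scale genome, `point_rate = 0.002`) and structural events
occasional (0.5-1% per protein per replication; rearrangement 1% per
genome): frequent enough to explore topology on desk-scale runs, rare
enough that most children are kinetic variants of their parent.

## Evolution engines

**Random walk** (large population, low mutation rate): one resident
genotype; each attempt mutates it, scores the mutant, and accepts with
probability `alpha * P_fix`, where `P_fix = (1 - e^(-2s)) / (1 - e^(-4 Ne s))`
with `s = (w' - w)/w`, `Ne = 1e5` by default (prokaryote-scale; the
supported range runs to 1e8) and `alpha = 1e4` to make neutral fixations
(probability `1/(2Ne)`) affordable; `alpha * P_fix >= 1` is clipped with a
warning. The neutral limit `1/(2Ne)` is used below `|s| < 1e-12`, and the
deleterious branch is evaluated in log space (underflow to 0 rather than
overflow). A zero-fitness resident accepts any mutant with positive
fitness, since `s` is undefined at `w = 0`; two zero-fitness genotypes are
treated as neutral.

**Population mode** (quasi-species regime): `N` copies of the seed;
each generation every individual reproduces, mutates with a per-individual
probability (plus optional HGT from a random donor), and `N` survivors are
drawn with replacement with probability `p_i w_i / sum p_j w_j` by
cumulative-sum roulette -- the Wright-Fisher update whose expectation the
tests check against the closed form.

## The seed network and what the generator emulates

`signaling_seed_spec()` describes the canonical starting network: ligand L
(input, clamped), output protein T with one phosphorylation site, an
adaptor A whose allosteric domain binds L (Gamma = 10), a kinase K
(csite, polarity modify) and a phosphatase P (csite, polarity unmodify)
acting on T's site. Enzymes start abundant (10 uM) and the target low
(1 uM) -- the low-saturation regime -- and rate constants start at the
mid-range 1 s^-1 (phosphatase kp 0.5 s^-1, so the resting cycle is biased
toward the modified state). Crucially, the input is **not** connected to the
modification cycle at the start: the seed's fitness is zero and any
responsiveness, e.g. via shuffled binding sites that let L sequester or
regulate an enzyme, must evolve.

`build_seed_genome()` realizes a specification exactly: requested partners
get complementary binding profiles (two-coloring the constraint graph;
an odd complementarity cycle is reported as unrealizable), all other
profile pairs are redrawn until they stay below threshold, and rate
profiles are placed at the Hamming distances that decode to the requested
constants. What the generator does **not** emulate: real promoter-level
regulation, synthesis/degradation, spatial effects, and stochasticity --
passing tests say nothing about those. Deterministic mass action also
means results speak to the large-copy-number regime only.

## Numerical and design choices, in one place

* Bit order big-endian; v = 0 maps to `lo` for both scalings (both
  conventions fixed once; nothing downstream depends on the choice beyond
  consistency).
* Undefined 3-bit separators abort the protein (parser totality; point
  mutations can silence genes, matching the gene-silencing behaviour the
  encoding is meant to exhibit).
* Site-type `10` decodes as bsite (inert default).
* One rt-rate field: basal `k_RT = k_TR`; Gamma carries any bias.
* kp conformational mask: first 10 of 20 mask bits apply to the 10-bit kp
  profile.
* Binding threshold 9/10; `max_complex_size = 2`; `max_species = 2000`;
  blow-up is an explicit error scored as non-viable fitness.
* Input clamping rescales free forms and conserves all other proteins
  exactly (partner release in-state).
* Steady state by `lsodar` root-stopping on the normalized derivative;
  convergence is credited when the root is found (re-checking the strict
  inequality at the root would be a coin flip on floating-point noise).
* Pruning judges function: run it with a fitness whose complexity weight
  is zero, otherwise every deletion changes `S_com` by construction and no
  deletion can be fitness-neutral. `prune_network()` never removes the
  protected input/output proteins.
* Saturation diagnostics `K1`, `K2`: per catalytic rule on the output's
  first msite, `K = ((kb + kp)/kf) / S_tot` per enzyme conformational
  state; `K1` is the geometric mean over kinase-state pairs, `K2` over
  phosphatase-state pairs (the nested-mean reading of the composite
  parameter; grouping by enzyme first would coincide for enzymes with
  equal state counts).

## Scaled-down study sizes

The evolution case studies in the test suite are desk-scale versions of
week-long cluster experiments. The package's standing choices: the
ultrasensitivity study runs 3 replicate random walks of up to 3000
attempted mutations each (target fitness 0.8 with early stopping, weights
(1, 1, 0.1), `Ne = 1e5`, `alpha = 1e4`); the adaptation study runs 10
replicates of up to 400 attempts with a success threshold of `F >= 0.5`
on the adaptation objective ("high fitness" is not a printed constant
anywhere, so the package fixes it at half the maximal score, one
even-handed choice made once). Study runs use a species cap of 500:
functional networks in these studies stay well under 100 species, and the
tighter cap bounds the enumeration cost of doomed blow-up mutants, which
score 0 at any cap. Full-scale runs (budgets of 2e4 or more attempts per
replicate) are reproducible through `random_walk_evolve()` or the
`evolve` subcommand of the CLI; they take hours per replicate on one CPU.

## Known limitations

* State-space growth is exponential in allosteric domains and msites per
  complex; the caps make that failure explicit rather than cheap.
* The pairwise-complex cap (default 2) excludes scaffolding and chains;
  raising it is supported but enumeration and ODE size grow quickly.
* Fitness is deterministic; no stochastic (SSA) scoring hook is wired in.
* The sub-score formulas are package defaults chosen for monotonicity and
  boundedness; they are the natural reading of "score the middle-step
  amplitude, its dominance, and structural complexity", but other forms
  fit that description too, so they are isolated in `fitness.R` as
  swappable functions.
* Genome text files, reaction lists and GraphML exports are stable
  interfaces; the internal complex representation is not.
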