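# evosig

In silico evolution of biochemical signaling networks with explicit
protein domain structure and allostery.

## The problem

How do dynamic features of cell signaling — switch-like (ultrasensitive)
dose responses, adaptation to persistent stimuli — arise through evolution,
and what is the repertoire of network architectures that can implement
them? Answering this experimentally is hard; `evosig` lets you re-create
the process computationally. It is aimed at evolutionary systems
biologists exploring the origins of network motifs, and at synthetic
biologists using evolution as a design tool for circuits with a prescribed
input–output behaviour.

## The model

Networks are encoded on a **binary-string genome**. Protein-coding
sections (start code `01111110` … stop code `111`) carry domains separated
by soft linkers and reactive sites separated by hard linkers; every
parameter — concentrations, rate constants, allosteric factors — is a
fixed-width bit field scaled linearly or log-linearly onto measured
biochemical ranges. Whether two reactive sites interact is decided by the
complementarity (XOR popcount) of their 10-bit binding profiles against a
threshold; binding kinetics derive from Hamming distances between 20-bit
rate profiles. Domains are two-state allosteric units in the
Monod–Wyman–Changeux sense: each bound or modified site shifts the R⇌T
equilibrium by its factor Γᵢ, split between the transition rates by the
partition exponent Φ,

    k_RT' = k_RT · G^Φ,   k_TR' = k_TR · G^(Φ−1),   G = Π Γᵢ.

A rule-based compiler expands the genome into every reachable species and
mass-action reaction (conformational flips, binding, catalysis through
explicit enzyme–substrate complexes), and stiff ODE integration plus
staircase or step stimulus protocols yield the scores: amplitude and
ultrasensitivity of the dose response, or sensitivity and precision of an
adaptive transient, combined with a structural complexity penalty as a
weighted geometric mean

    F = (S_amp^ωa · S_ult^ωu · S_com^ωc)^(1/(ωa+ωu+ωc)).

Evolution proceeds either as a biased random walk — each mutant fixes with
probability α·P_fix, where Kimura's

    P_fix = (1 − e^(−2s)) / (1 − e^(−4·Ne·s)),   s = (w' − w)/w

— or as a fixed-size Wright–Fisher population with fitness-proportional
(roulette) selection. Mutation operators cover point mutations, protein
and domain duplication/deletion, domain shuffling, genome rearrangement
and horizontal gene transfer, all on the bitstring, all replayable from
their event logs.

See `vignettes/evosig-methods.Rmd` for the full model description and the
design decisions.

## Worked example

Build the canonical five-protein seed network — ligand L (input), output
T, adaptor A, kinase K, phosphatase P, where K and P act on T's
phosphorylation site and L binds only A — compile it, score it, and evolve
it toward an ultrasensitive dose response:

```r
library(evosig)

cfg  <- default_config(list(compiler = list(max_species = 500)))
seed <- build_seed_genome(signaling_seed_spec(), cfg, seed = 1)
net  <- compile_network(decode_proteins(parse_genome(seed), cfg), cfg)
net
#> <reaction_network> 11 species, 14 reactions, 3 rule(s)

score_genome(seed, cfg)
#> <fitness_report> objective=ultrasensitivity fitness=3.884e-06

mask <- protection_mask(
  proteins = c(1L, 2L),                      # freeze input + output genes
  bit_spans = list(list(protein = 1L, from = 0L, to = 8L),
                   list(protein = 2L, from = 0L, to = 8L)))
traj <- random_walk_evolve(
  seed, function(g) score_genome(g, cfg),
  mutation_rates(), mask,
  random_walk_config(Ne = 1e5, alpha = 1e4, target_fitness = 0.8,
                     max_attempts = 3000),
  seed = 3)
traj
#> <evolution_trajectory> 363 attempts, 62 accepted, fitness 3.884e-06 -> 0.8035
```

The seed starts with fitness ≈ 0 because the input is deliberately not
connected to the kinase/phosphatase cycle — responsiveness itself has to
evolve, typically through shuffled or mutated binding profiles that couple
L to the enzymes. The trajectory log records, per attempted mutation, the mutant
fitness, its sub-scores (`S_amp`, `S_ult`, `S_com`) and whether it fixed;
`saturation_params()` then quantifies how saturated the evolved kinases
and phosphatases are (the zero-order ultrasensitivity mechanism), and
`prune_network()` strips proteins that stopped contributing.

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "evosig.R", package = "evosig"))') \
    init --out run1 --seed 5
```

with subcommands `init`, `translate`, `score`, `mutate`, `evolve`,
`prune`.

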