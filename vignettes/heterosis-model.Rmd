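---
title: "Simulating heterosis and hybrid incompatibility in Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterosis and hybrid incompatibility in Boolean gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterosim)
```

## The model

`heterosim` simulates populations of diploid organisms whose genotype is a
Boolean gene regulatory network. Each locus carries two alleles; an allele
records the loci it can receive inputs from, the loci it can output to, and a
Boolean AND/OR/NOT expression that assigns the gene's ON/OFF state from the
states of its regulators. The executable *phenotype network* of a genome is
built by homozygote collapsing: a locus with two identical alleles is one
node (two identical nodes behave exactly like one under Boolean dynamics),
while a heterozygous locus contributes two nodes, and any gene regulated by a
heterozygous locus receives input from both allele nodes joined by an OR-gate.
A reference to a locus that has been lost from the genome evaluates as
constant OFF, so gene loss always leaves the network executable.

States are updated synchronously; iterating the update from a fixed initial
condition drives the network into an attractor — a fixed point or a state
cycle — which is the phenotype. Three designated *environment nodes* are
clamped and never updated; a combination of their states is an *environment*.

### Fitness

Three *modules* (highly interconnected subsets of loci) are each tied to one
environment. A perfectly adapted network switches the target module fully ON
and the other modules fully OFF in each environment. Fitness in one
environment is the mean activity of the target module minus the mean of the
other modules' mean activities, where a node's activity is its average state
over the attractor cycle; overall fitness is the average over the three
environments, giving a value between 1 (perfect response in every
environment) and -1 (exactly the wrong response). Two scoring conventions
were open and are fixed as follows:

* a heterozygous module locus contributes the mean of its two allele-node
  activities (one value per locus, keeping module scores comparable across
  heterozygosity levels);
* a module locus lost from the genome contributes activity 0 while the module
  keeps its nominal size in the denominator, so losing a required response
  gene is penalized rather than forgiven.

Cyclic attractors are scored by cycle-averaged activity — the minimal
scalarization consistent with defining the phenotype as "fixed point or state
cycle". The initial state for every fitness evaluation is all non-clamped
nodes OFF with the environment nodes at their clamp values; the dynamics are
deterministic, so this convention makes fitness a pure function of genome,
environments and modules. The three default environments are the one-hot
clamp combinations (1,0,0), (0,1,0), (0,0,1) mapped to modules 1–3: one-hot
vectors maximize the distinguishability of the conditions the network must
discriminate. All of these choices are configurable.

## Founder networks

Founders are generated by directed preferential attachment with triad
formation: each new node places `m` out-edges; the first targets an existing
node with probability proportional to in-degree + 1, and each subsequent
edge, with probability `p_triad`, instead targets a random out-neighbor of
the previous target, closing a directed feed-forward triangle. This yields
heavy-tailed degree distributions and tunable clustering on 25-node networks.
The last `n_env` nodes added become environment nodes; edges always point
from newer to older nodes, so they end up with out-going connections only,
and any in-edges are stripped defensively. Defaults `m = 2`, `p_triad = 0.6`
produce visible clustering at the default size (22 core + 3 environment
nodes); both are exposed in the configuration because no canonical values
exist for them.

Random logic is assigned per locus over exactly its in-neighbors: the input
set is split recursively into two non-empty groups joined by AND or OR
(equal probability), and each input is negated with probability 0.25.
Input-free loci receive a constant function drawn at creation, since
synchronous updating requires a rule for every node. Modules are detected by
greedy modularity maximization on the undirected projection of the core
subgraph, keeping the `k` largest communities with ties broken by smallest
member id — a deterministic rule, required for reproducible studies; loci
outside the `k` largest communities belong to no module.

## The evolutionary algorithm

A generation consists of fitness evaluation, survivor selection, and refill
to the configured population size (default 40) by mating. Gametes are formed
by independent reassortment — each locus contributes its maternal or paternal
entry with probability 1/2, including absences — and two gametes from two
distinct survivors form each offspring, which is then mutated (a germline
model: parents are immutable records). Mutation draws a Poisson number of
events per genome (default mean 0.3) and each event applies one of six
operators to a random allele: gain a regulatory input (wired into the logic
through a random gate), lose an input (structural removal from the
expression), rewrite a random logic subtree, toggle a NOT on one input,
duplicate an allele into a fresh hemizygous locus, or delete an allele.

Survivors (default 10 of 40) are chosen by a Metropolis–Hastings scheme: for
each survivor slot a uniformly drawn incumbent faces a sequence of uniformly
drawn challengers (as many proposals as the population size), each accepted
outright if at least as fit and otherwise with probability
`exp((F_challenger - F_incumbent) / temperature)`. Low-fitness individuals
therefore survive occasionally, which keeps the population from freezing on
local fitness peaks. The temperature is the one free knob of the selection
scheme. The default is `0.01`: on 25-node networks the fitness increments
that separate competing genotypes are of the order of a few hundredths (one
module gene responding correctly in one environment changes fitness by
roughly `1/(3 * module size)`), and the temperature must sit below those
increments for adaptive sweeps to fix reliably. With markedly weaker
selection (temperature 0.1) populations in this implementation plateau far
from the attainable optimum and neither appreciable hybrid vigor nor hybrid
incompatibility develops on desk-scale runs; the calibration is recorded here
because the original selection internals were not published in citable form.

## The experiments

* **Adaptation** (`adapt`): a population founded from one homozygous genome
  evolves for `n_adapt_generations` (default 1000); mean/max/min fitness are
  recorded per generation. Fitness starts near zero — an unadapted network's
  nodes are as likely to respond correctly as incorrectly, and the two cancel
  in the module averages.
* **Divergence and hybridization** (`run_divergence_experiment`): the adapted
  population is duplicated and the two copies evolve with no interbreeding.
  Every 20 generations, 80 hybrids are formed by mating one gamete from a
  random individual of each population; their fitness is recorded and the
  hybrids are discarded — they never breed back. Parent trajectories, hybrid
  sampling and mechanism scoring run on separate named RNG streams derived
  from the master seed, so measuring hybrids cannot perturb the parents and
  the whole experiment is bit-reproducible from the configuration and seed.
* **Hybrid intercross** (`cross_hybrid_generation`): a cohort of hybrids is
  closed on itself and evolved; the mean-fitness series tracks whether the
  heterotic advantage can be fixed by breeding hybrids to each other.

## Mechanism decomposition

For a hybrid genome, every heterozygous locus is scored by comparing the
complete network's fitness with the two homozygotes obtained by deleting
either allele. The effect is `F_complete - (F_hom_m + F_hom_p)/2`; it is
classed over-dominance when both homozygotes are less fit than the complete
network, dominance when positive otherwise, and under-dominance when
negative. Effects within 0.5% of the whole-network fitness are discarded as
numerical noise.

Epistasis is scored for every pair of heterozygous loci and both
cross-parental orientations (maternal allele of one locus against the
paternal allele of the other, and vice versa); same-parent pairs are present
in a parent too and are irrelevant for heterosis, and allelomorphic pairs
fall under the local effects. The expected fitness of the double heterozygote
under independence is multiplicative, `F_wo1 * F_wo2 / F_wo12`, and the
epistasis value is the difference `ep` between the complete network's fitness
and that prediction. `ep` above the noise threshold is positive epistasis;
below it, the pair is an *epistatic incompatibility* when both single
removals are fitter than the complete network (the joint presence of the two
alleles is what hurts) and negative epistasis otherwise. Numerical choices:

* the 0.5% noise threshold is reused for epistasis classification by analogy
  with the local effects (the source procedure states it only for the
  latter), as a symmetric guard;
* fitness here can be zero or negative, where the multiplicative expectation
  is undefined or misleading: when `|F_wo12| <= 1e-6` the additive prediction
  `F_wo1 + F_wo2 - F_wo12` is used instead and the row is flagged
  `degenerate`.

Because only pairs are scored, one interaction spanning three or more alleles
is counted once per cross-parental pair it touches; pair-class sums therefore
overestimate absolute epistatic contributions and are comparable only with
each other, never with the local-effect sums.

A *collapse* of hybrid fitness is detected as the first hybridization event
at which the hybrid mean falls more than `delta = 0.2` below the weaker
parent mean and stays there for `k = 2` consecutive events; both knobs are
configurable since the phenomenon is described qualitatively rather than
formalized in the source material. `pool_runs()` aligns several runs so their
collapse events coincide (by default at position 5) and averages every
numeric series position-wise, excluding runs without a detected collapse.

## What the simulation emulates — and what it does not

The generator's defaults are the study conditions: 22 + 3 node founders,
populations of 40 reduced to 10 survivors, hybridization of 80 hybrids at
20-generation intervals with parent means over 40 individuals each. The
synthetic populations emulate regulatory-network evolution under stabilizing
environments; they do not emulate spatial structure, linkage (reassortment is
fully independent), changing environments, or any specific organism's network
topology. Passing qualitative tests therefore shows that the mechanisms —
dominance, over-dominance, epistatic incompatibility — emerge from regulatory
logic under divergence, not that their relative magnitudes match any
particular biological system.

## Problem sizes used in the test suite

The packaged tests reproduce the qualitative phenomena at desk scale so the
whole suite runs in minutes on one CPU. Ten seeded studies on default-size
networks each adapt for 300 generations and then diverge for 600 generations
with hybridization every 20 generations, using cohorts of 30 hybrids and
parent samples of 20 individuals per event; mechanism decomposition is
computed on a 5-hybrid subsample at four events spanning each run (or a
window around the collapse where one is detected), which estimates the
population mechanism sums without the full quadratic cost. Intercross decay
is additionally demonstrated on a constructed over-dominant complementation
scenario — a regulator locus whose two alleles each sense one environment,
so the heterozygote responds in both and either homozygote in only one —
because in emergent desk-scale runs the hybrid swarm's continued adaptation
masks the segregation decay that the scenario isolates. The fitness collapse
is an emergent, stochastic event whose timing varies from tens to many
hundreds of generations after the split; desk-scale horizons catch it in a
minority of seeds, and the corresponding checks are majority-vote or
conditional on a detected collapse by design.

## Known limitations

* Attractor search is exact (hash-based cycle detection over the full state
  trajectory) and fast for the network sizes studied here, but cost grows
  with cycle length; pathological long-cycle networks are bounded by a step
  limit.
* Allele identity is structural (canonical logic string plus input set), so
  two independent mutations producing identical expressions count as the same
  allele — a reasonable convention that slightly underestimates
  heterozygosity.
* Duplicated loci receive fresh ids; two populations can in principle create
  colliding ids for independent duplications, which would then be treated as
  one locus in a hybrid. With the default rates this is rare.
* The asynchronous-updating variant is an extension point only; the
  implementation is synchronous throughout.
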