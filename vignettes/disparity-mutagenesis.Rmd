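---
title: "Disparity mutagenesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disparity mutagenesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispmut)
```

## The question

Direct parent–offspring sequencing puts the human mutation input at roughly
70 new mutations per diploid genome per generation, of which around 2.2 are
deleterious. Classic mutation-load arithmetic says a population paying
`L = 1 - exp(-U)` of its mean fitness per generation should not survive
`U = 2.2` (`L ≈ 0.89`), and Eigen's quasi-species theory says genetic
information is lost outright once the genome-wide error rate oversteps about
one mutation per replication. Yet mutation-rich lineages persist. The
disparity-mutagenesis hypothesis resolves the tension through the asymmetry
of semiconservative DNA replication: if copy errors fall predominantly on
the lagging-strand daughter, every division also produces a leading-strand
daughter that preserves the parental genotype exactly, so established
genotypes are never lost no matter how high the mutation rate. This package
implements the three desk-scale models that carry that argument, plus the
load arithmetic, so the claims can be recomputed and tested end to end.

## The replicore pedigree

`grow_pedigree()` expands a single replication unit (a *replicore*: one
origin, a leading- and a lagging-strand copy per division) deterministically
for `g` generations, so generation `g` holds exactly `2^g` genomes.
Mutations follow the infinite-sites idealization: every new substitution
hits a fresh site and is represented by a globally unique integer label; a
genotype is the inherited set of labels. There is no back-mutation, no
genome length and no selection — mutants are assumed neutral or mildly
deleterious and all survive, which is exactly the regime in which the
pedigree's combinatorics are the point.

Two replication modes are compared at equal total mutational input `d` per
replication (default `d = 2`):

* **disparity** — the leading daughter is an exact copy; the lagging
  daughter gains all `d` new labels;
* **parity** — each daughter gains `d/2` labels (`d` must be even).

Interpreting parity as *one new mutation in each daughter* (rather than one
shared between them) keeps the per-replication input identical across the
two modes, which is the comparison that matters; it is also why parity with
odd `d` is rejected rather than rounded.

The consequences are forced, and the tests verify them against exhaustive
enumeration of all `2^g` strand-choice paths: under disparity the census at
generation `g` has `choose(g, k)` genomes with `k·d` mutations, exactly one
genome stays mutation-free at every generation, all `2^g` genotypes are
distinct, and every genotype ever present persists at all later generations
(`genotype_persistence()`). Under parity every genome carries `(d/2)·g`
mutations and the ancestral genotype is gone after one replication.

Event labels are allocated in depth-first pre-order, leading daughter before
lagging, which makes `grow_pedigree()` bit-reproducible. The default node
budget (`max_generations = 20`, about two million nodes) is a memory guard,
not a model statement. Trees export to Newick through `ape`
(`as.phylo()` / `export_newick()`), with branch lengths equal to the number
of new mutations on each edge — 0 for every leading edge under disparity.

One point the pedigree deliberately leaves open: whether the physical
identity of the lagging strand alternates between daughters across
generations. The model only tracks *which daughter receives the new
mutations*, which is all that the census, persistence and distinctness
results require.

## The quasi-species engine

`solve_stationary()` computes Eigen's mutation–selection equilibrium on a
single-peak landscape: a binary genome of length `L` whose master sequence
has fitness `sigma > 1` while every other genotype has fitness 1. Because
that landscape is permutation-invariant, the `2^L` sequence space reduces to
`L + 1` Hamming error classes. Copying flips each base independently with
probability `mu`; the class-transition kernel convolves back-mutations among
the `i` incorrect sites (`Binomial(i, mu)`) with new errors among the
`L - i` correct ones (`Binomial(L - i, mu)`), exactly — the familiar
no-back-mutation formula is kept only as a test oracle. A binary alphabet is
used so that "error" simply means a flip; the threshold statements are
alphabet-agnostic.

The two-fidelity polymerase mixture enters as the kernel
`M = p·I + (1 - p)·B(mu)`: each replication event independently uses an
error-free polymerase with probability `p`. This per-event mixing is the
minimal reading of "a mixture of error-less and error-prone polymerases",
and it yields the closed-form check
`x0 = max(0, (sigma·Q - 1)/(sigma - 1))` with
`Q = p + (1 - p)(1 - mu)^L`, which the exact solution tracks to within
about 0.02 absolute for `L ≥ 50`.

Dynamics are the discrete-generation normalized update
`x' ∝ M (w ⊙ x)` rather than the continuous-time ODE; the fixed points
coincide up to time parameterization and the discrete map is simpler to
test. The stationary state is the dominant eigenvector of `M diag(w)`
(Perron–Frobenius), taken directly with `eigen()` and then polished by
iteration to a sup-norm fixed-point residual below `tol = 1e-12`; a plain
power-iteration solver is retained (`method = "power"`) and a test confirms
the two routes agree. The direct eigenpair is preferred because power
iteration alone slows down badly near the threshold, where the spectral gap
closes.

The error threshold is defined *operationally*: `find_error_threshold()`
bisects on `mu` for the point where the stationary master-class frequency
crosses `epsilon = 1e-3` (the sharp phase transition exists only as
`L → ∞`; both `epsilon` and the bisection tolerance `1e-5` are arguments).
Two results carry the argument:

* at `p = 0` the genome-wide critical rate `mu_c · L` approaches
  `ln(sigma)`; with `sigma = e` this is the classic rule of one mutation per
  genome per replication (`find_error_threshold(exp(1), 100)` returns
  0.999);
* for `p > 1/sigma` the master frequency is bounded below by
  `(sigma·p - 1)/(sigma - 1)` for every `mu`, so the threshold does not
  merely move up — it disappears. `threshold_phase_table()` tabulates this
  over `(sigma, p)` grids.

No primary source states the `sigma` or `L` behind the original mixture
simulations, so the defaults used in the tests and phase tables
(`sigma ∈ {2, e, 10}`, `L ∈ {50, 100}`) are this package's choices, made
once for desk-scale runtime; `sigma = e` is singled out because it is the
value at which the `ln σ` form reproduces the "<1 mutation per genome"
statement.

## The strand-asymmetric genetic algorithm

`run_ga()` is a DNA-type ("neo-Darwinian") genetic algorithm: genomes are
binary inclusion vectors over a 0/1 knapsack instance, and every genome
produces two daughters per generation, the leading copy mutated at
`mu_leading` per bit and the lagging copy at `mu_lagging`. Parity means
equal rates; disparity means a low-fidelity lagging channel (often with
`mu_leading = 0`). The double helix is abstracted to one bit-vector with two
copy channels — base-pair complementarity adds nothing to the fidelity
asymmetry, which is the only thing every in-scope claim depends on.

Choices the original account leaves open, fixed here once and recorded in
every run's metadata:

* **Fitness of an overweight genome is 0**, not a graded penalty; this makes
  extinction (no feasible genome) well-defined.
* **"Total mutation rate"** is read as the per-bit rate averaged over the
  two daughters, `(mu_leading + mu_lagging)/2`, so a 4% total is parity
  `(0.04, 0.04)` versus disparity `(0, 0.08)`.
* **Selection is truncation**: keep the top half of the `2N` daughters, ties
  broken stably by fitness, then parent index, then leading-before-lagging —
  reproducibility is part of the contract. `keep_fraction ≠ 0.5` refills to
  `N` by cycling survivors.
* **Founders are all-zero genomes** (the empty knapsack): feasible,
  deterministic, and maximally uncommitted. The empty genome scores 0, so
  all search progress is attributable to mutation plus truncation.
* **Extinction** is declared after 10 consecutive generations with zero
  feasible genomes (the original criterion is not stated).
* **No crossover or sex**; sexual-shuffling effects are out of scope here.

With `mu_leading = 0`, the faithful leading daughter of the current best
genome always survives truncation, so the best fitness is monotone
non-decreasing — "creation of diversity with a guarantee of principal" as a
provable invariant, verified over seeded runs. The exact optimum comes from
a standard dynamic program (`dp_optimum()`), itself checked against
exhaustive subset enumeration for `n ≤ 15`.

The historical headline numbers — parity extinction at a 2.32% total rate
versus disparity adaptation at 8% — are **not** reproduced quantitatively:
the instance size, population size and selection scheme behind them are not
on record. What the tests assert instead is the qualitative ordering under
this package's own conditions (20 items, `N = 200`, 500 generations,
matched instance and run seeds, average per-bit rate 0.04): disparity's
final best fitness is at least parity's in at least 80% of 20 seeds, and
disparity reaches the exact optimum within 500 generations in at least 80%
of seeds.

## Load arithmetic

`genetic_load()` is the closed form `L = 1 - exp(-U)`;
`mutations_per_generation()` and `cell_level_mutations()` are the two
mutation-budget products (rate × genome size × generation time; replicores ×
mutations per replicore). The human per-site rate is taken as `1e-9` per
year — the only value consistent with the quoted 60–75 mutations per
generation at a 3 Gb genome and 20–25-year generations — but the functions
take whatever rate they are given. Loads are displayed at two decimals
(`0.89`), matching how such values are conventionally reported. The
survival-multiplicativity identity
`1 - L(a + b) = (1 - L(a))(1 - L(b))` is tested exactly.

## Reproducibility and the runner

`parse_config()` resolves a YAML file plus command-line flags (flags win)
against per-subcommand schemas with documented defaults; unknown keys and
out-of-range values are rejected by name. `run_config_execute()` dispatches
to the engines and `write_results()` serializes every result as TSV (tab
separator, header row, `.` decimal), JSON metadata including the
round-trippable configuration and all seeds, and Newick for pedigrees.
Output files are write-once per run directory. Every stochastic component
takes an explicit seed and leaves the caller's RNG stream untouched; default
seeds are fixed, never time-based, so default invocations reproduce bit for
bit. A thin shell entry point ships at
`system.file("cli", "dispmut", package = "dispmut")`.

## What the synthetic conditions do and do not show

Everything here is generated internally: pedigrees are deterministic,
quasi-species states are exact linear-algebra solutions, and knapsack
instances are seeded uniform draws (weights and values on 1–100, capacity
half the total weight). These conditions isolate the mechanisms — genotype
guarantees from strand asymmetry, threshold shifts from fidelity mixtures,
optimization under matched mutational load — but they deliberately omit much
of real replication biology: Okazaki-fragment structure, polymerase
biochemistry, back-mutation at finite alleles (pedigree), finite-population
stochasticity and multi-peak or empirical fitness landscapes
(quasi-species), diploidy, recombination and environmental change (GA).
Passing tests therefore demonstrate the internal logic of the model at desk
scale, not its quantitative fit to any organism.

Problem sizes used throughout (pedigrees to `g = 12`, `L = 100` error
classes, GA at `N = 200` for 500 generations, 20 seeds) were chosen once as
comfortably desk-scale while large enough for the asymptotic statements
(`mu_c·L → ln σ`, binomial censuses) to hold at the stated tolerances.

```{r example}
find_error_threshold(sigma = exp(1), L = 100)
genetic_load(2.2)
```
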