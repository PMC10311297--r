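---
title: "Ensemble-objective RNA design: model, search, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-objective RNA design: model, search, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadesign)
```

## The problem

Inverse folding asks for an RNA sequence $x \in \{A,C,G,U\}^n$ whose
folding behaviour matches a given pseudoknot-free secondary structure
$y^\*$.  The classical success criterion is that $y^\*$ is a minimum
free energy (MFE) structure of $x$; the stricter *unique-MFE* (uMFE)
criterion additionally demands that every other structure in the
ensemble has strictly higher energy, i.e. there are no co-optimal
alternatives.  Optimizing the MFE criterion directly is awkward — it is
discrete, and a sequence can satisfy it while still spending most of
its Boltzmann ensemble elsewhere.  This package instead minimizes a
continuous *ensemble objective* and harvests MFE/uMFE solutions as
byproducts along the way.

Two objectives are available, both in $[0,1]$ and both zero exactly
when the ensemble is concentrated on the target:

* $f(x, y^\*) = 1 - p(y^\* \mid x)$, where
  $p(y \mid x) = e^{-\Delta G(x,y)/RT} / Q(x)$ is the equilibrium
  probability and $Q(x) = \sum_{y} e^{-\Delta G(x,y)/RT}$ the partition
  function;
* the normalized ensemble defect
  $\mathrm{NED}(x, y^\*) = \tfrac1n \mathbb{E}_{y \sim p(\cdot|x)}
  \, d(y^\*, y)$, the mean probability that a position is incorrectly
  structured, where
  $d(y', y'') = n - 2\,|\mathrm{pairs}(y') \cap \mathrm{pairs}(y'')| -
  |\mathrm{unpaired}(y') \cap \mathrm{unpaired}(y'')|$.

The defect never needs an ensemble enumeration: it equals
$n - 2 \sum_{(i,j) \in \mathrm{pairs}(y^\*)} p_{ij} -
\sum_{j \in \mathrm{unpaired}(y^\*)} q_j$
with $p_{ij}$ the base-pair probabilities and $q_j = 1 - \sum_i p_{ij}$,
and decomposes into positional defects $\epsilon_i$ ($1 - q_i$ for
unpaired target positions, $1 - p_{ij}$ for paired ones).  The
`test-objectives.R` suite verifies the expectation/marginal identity by
brute force on short sequences.

## The search

`design()` implements a structure-aware stochastic local search with a
*multifrontier*: a priority queue of the $k$ lowest-objective distinct
sequences seen over the whole history, not just the current incumbent.
Keeping suboptimal candidates matters because the ensemble objective
and the MFE criterion are not perfectly aligned — the eventual uMFE
solutions are often not the objective optimum.  Each iteration:

1. **Candidate sampling.** A frontier member is drawn with probability
   $\propto \exp((1 - f)/T)$.  At $T \to 0$ this is greedy; at
   $T \to \infty$, uniform.  Default $T = 1$.
2. **Position sampling.** A position of the chosen sequence is drawn
   with probability $\propto \exp(\epsilon_i / T')$, concentrating
   mutations on incorrectly structured positions.  $T' = 2T$ by
   default; the search is not very sensitive to this ratio.
3. **Structured mutation.** The selected position is mutated *jointly
   with its local motif* rather than alone (see below).
4. **Update.** The mutant is folded once, its objective cached, the
   frontier updated, and — independently of the objective — its
   MFE/uMFE status checked.  Sequences passing the criterion accumulate
   in `x_mfe` / `x_umfe` even when they never enter the frontier.

Runs stop when the best objective drops below `converge_eps`
(default 0.01), after `patience` (2000) non-improving iterations, or at
the budget `M` (5000).

### Targeted initialization

Initial sequences put `A` at every unpaired target position and an
independent uniform choice of `GC` or `CG` at every pair.  Helix sides
are therefore exactly complementary while two different helices of
length $h$ collide with probability $2^{-h}$, so the target is usually
favoured from the very first fold.  For a target with $p$ pairs only
$2^p$ such sequences exist; the search silently starts from all of them
when $2^p < k$.

### Structured mutation

Single-base (or single-pair) mutations ignore that folding energies are
functions of local motifs — stacks and loop mismatches — not of isolated
nucleotides.  The mutation operator therefore rewrites whole motifs,
classified from the *target* (never from a predicted structure, so
compatibility is preserved by construction):

| scenario | mutated positions | proposals |
|---|---|---|
| stack | pairs $(i,j),(i{+}1,j{-}1)$ | $6 \times 6 - 1 = 35$ |
| pair + double mismatch | pair $(i,j)$, bases $i{+}1, j{-}1$ | $6 \times 4 \times 4 - 1 = 95$ |
| stack + double mismatch | both pairs, bases $i{+}2, j{-}2$ | $6^2 4^2 - 1 = 575$ |
| 5′ / 3′ single mismatch | pair $(i,j)$, one inner base | $4 \times 6 - 1 = 23$ |
| unpaired double mismatch | pair $(i,j)$, bases $i{+}1, j{-}1$ | $4^2 \times 6 - 1 = 95$ |
| trivial (unpaired) | base $i$ | $3$ |
| trivial (paired fallback) | pair $(i,j)$ | $5$ |

Joint assignments are drawn uniformly with only the *identical* joint
assignment excluded, so individual positions may keep their base.  Where
scenario definitions could overlap for a paired position we prefer the
largest defined unit (stack + mismatch, then stack, then pair +
mismatch); irregular contexts — multiloop branch points whose inner
neighbour pairs elsewhere, loop interiors, exterior-adjacent bases —
fall back to the trivial move.  The trivial move excludes the current
base: re-proposing the same sequence would waste an $O(n^3)$
evaluation.

Design choices worth recording: frontier ties are broken by insertion
order (earlier entries win eviction contests), a new candidate must
*strictly* beat the worst member of a full frontier, "improvement" for
the patience counter means strict decrease of the frontier minimum, and
one RNG stream drives every stochastic stage in a fixed call order —
this keeps runs bit-for-bit reproducible under a seed and makes
ablations comparable.  Whether a mutant replaces its parent was an open
choice; the frontier-of-history definition implies coexistence, which
is what we implement.

### Ablation switches

Each ingredient can be disabled in `design_config()` without touching
the others: `use_targeted_init` (uniform random compatible
initialization instead), `use_boltzmann_sampling` (uniform candidate
*and* position draws), `use_structured_mutation` (traditional
single-base/single-pair moves), `multifrontier` (forces $k = 1$; this
is definitionally identical to `k = 1`, and the test suite checks
bitwise equality of the two runs), and `collect_byproducts` (only the
final best sequence is criterion-checked, so at most one solution can
be reported per run — the contrast with the full method's hundreds of
harvested solutions is checked in the acceptance tests).

## The built-in energy model, and why it exists

Published thermodynamic engines implement the full Turner
nearest-neighbour model; re-implementing it here would be both a large
undertaking and unverifiable from within the package.  Instead the
default backend is a deliberately small *nearest-pair model*: each pair
contributes an energy by type (CG/GC $-3$, AU/UA $-2$, GU/UG $-1$, toy
units), each stacked pair adds $-1$, hairpins enclose at least 3
unpaired bases, and $RT = 1$.  The constants are fixed package-wide and
were chosen so that G–C pairs and stacked helices dominate,
qualitatively mirroring the real stacking hierarchy.  The payoff is
that *every* ensemble quantity has an exact in-package oracle:
`enumerate_ensemble()` lists the complete ensemble of any sequence up
to length 16 by an independent recursion, and the McCaskill-style
inside–outside dynamic program (partition function, base-pair
probabilities), the MFE minimizer, the co-optimal count, and the
zero-slack traceback are all tested against it at relative tolerance
$10^{-9}$ on hundreds of random sequences.

The uMFE check counts co-optimal structures with zero energy slack —
the dynamic-programming analogue of enumerating all tied optima — never
an energy-gap heuristic.  Partition-function cells are rescaled per
nucleotide, so ensembles of kilobase-scale sequences stay in range
(log-scale quantities are exposed as `logQ`).  Energy ties are compared
at an absolute tolerance of $10^{-9}$, far below the model's 0.5-unit
energy granularity.

A second backend adapts the ViennaRNA command-line programs
(`RNAfold -p` for the ensemble, `RNAeval` for structure energies,
`RNAsubopt -e 0` for the full MFE set) behind the same four-function
contract, so designs can be run and scored under a realistic energy
model; extra engine flags (e.g. dangle options) pass through
unmodified.  The search code is backend-agnostic — the test suite runs
it against a mock backend to pin the contract.

## Synthetic targets

`random_structure()` generates valid pseudoknot-free targets of exact
length with controllable helix lengths (default 2–6 stacked pairs),
loop lengths (3–6), and multiloop branching probability (0.2) — ranges
typical of the hairpin/stem-loop/multiloop vocabulary of curated design
benchmarks.  Hairpins always enclose $\ge 3$ unpaired bases so every
target is foldable under both backends.  What the generator does *not*
emulate: the adversarial motifs that make the hardest curated puzzles
hard (isolated pairs flanked by long symmetric internal loops,
repeated near-identical helices), or the base-composition statistics
of natural structural RNAs.  Passing tests on these targets therefore
demonstrate correctness of the machinery and the qualitative behaviour
of the search, not benchmark-level difficulty.

## Validation scale and expectations

The test and acceptance workloads are sized for a laptop-class single
core: oracle equivalence on 200 random sequences of length 5–14,
sampling-distribution checks at $10^4$ draws (tolerance $\pm 0.015$,
several binomial standard deviations), the worked 20-nt two-hairpin
target at 500 iterations, and an end-to-end benchmark of eight
synthetic 50-nt targets at 1500 iterations each.  Under those
conditions the toy-model search typically solves all eight targets by
both criteria, harvests on the order of $10^2$–$10^3$ distinct MFE
solutions per solved target, and reaches mean target probabilities
around 0.5–0.6 — the qualitative signature of the method (many
byproduct solutions, high ensemble concentration), at a scale where
every number can be recomputed in seconds.

## Known limitations

* The toy model has no loop-length free energies, dangles, or coaxial
  stacking; its ensembles are far more permissive than Turner-model
  ensembles, which makes synthetic targets easier to solve.
* The ViennaRNA adapter shells out per evaluation; for long sequences
  or large budgets the process-spawn overhead dominates.
* Pseudoknots are out of scope throughout (the notation, the dynamic
  programs, and the generator all assume properly nested pairings).
* `mfe_structures()` enumerates the complete co-optimal set and will
  refuse (with an error) pathological inputs whose tie count exceeds
  the traceback cap; the uMFE check is unaffected since it only counts.
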