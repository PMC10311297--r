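# rnadesign

Inverse RNA folding: given a pseudoknot-free secondary structure
`y*` in dot-bracket notation, find sequences `x` over `{A,C,G,U}` that
fold into it.  The package is aimed at people who need *many*
successful designs per target — e.g. to add downstream sequence
constraints or to build training sets — rather than a single sequence.

## Method

Rather than optimizing the discrete MFE criterion directly, the search
minimizes a continuous **ensemble objective**, either

* `1 − p(y* | x)`, with `p(y|x) = exp(−ΔG(x,y)/RT) / Q(x)` the
  equilibrium probability of the target, or
* the **normalized ensemble defect**
  `NED(x, y*) = (1/n) E_y[d(y*, y)]`, the mean probability that a
  position is incorrectly structured, computed from the base-pair
  probability matrix as
  `NED = (n − 2 Σ_{(i,j)∈pairs(y*)} p_ij − Σ_{j∈unpaired(y*)} q_j)/n`,

and treats sequences satisfying the MFE criterion (`y*` is a minimum
free energy structure of `x`) or the stricter uMFE criterion (`y*` is
the *only* one) as **byproducts**: every sequence evaluated during the
search is criterion-checked and harvested on success.  The search
itself is structure-aware and multifrontier:

* a priority queue keeps the `k` best distinct sequences seen so far
  (default `k = 10`);
* candidates are drawn with probability `∝ exp((1 − f)/T)` and mutation
  positions with probability `∝ exp(ε_i / T')`, where `ε_i` is the
  positional defect (`T = 1`, `T' = 2T`);
* mutations rewrite whole local motifs — stacks, stack+mismatch,
  loop mismatches — jointly (6 pair types per pair, 4 bases per
  unpaired position, current joint assignment excluded), preserving
  target compatibility by construction;
* initial sequences put `A` at unpaired positions and a random `GC`/`CG`
  at each pair, making helix sides complementary from the start.

Folding goes through a pluggable backend: a built-in, exactly tested
nearest-pair energy model (with full-ensemble enumeration, a
McCaskill-style inside–outside partition function, and zero-slack
co-optimal MFE tracing), or the ViennaRNA command-line programs for the
realistic Turner model.

## Worked example

Design the 20-nt two-hairpin target:

```r
library(rnadesign)
y <- "(((...)))..(((...)))"
res <- design(y, design_config(seed = 0, max_iters = 500))
res
#> Design result for (((...)))..(((...)))
#>   500 iterations (max_iters), 510 evaluations
#>   best objective 0.118865 (prob), |X_MFE| = 414, |X_uMFE| = 387
```

In 500 iterations the run evaluated 510 sequences and 387 of them are
uMFE solutions — the target is their unique minimum-energy structure
under the toy model.  The best frontier member leaves ~12% of the
ensemble off-target; the harvested solutions are verifiable
individually:

```r
head(res$x_umfe, 3)
#> [1] "CGGAAACCGAACCGAAACGG" "CCCAAAGGGAACGGAAACCG" "GCGAAACGCAACGCAAAGCG"
check_criterion(res$x_umfe[1], y)
#> $satisfies_mfe
#> [1] TRUE
#> $satisfies_umfe
#> [1] TRUE
prob_of_structure(res$x_umfe[1], y)
#> [1] 0.8634
```

Ensemble quantities are available directly; for `"GAAAC"` the
two-structure ensemble gives `Q = 1 + e^3 ≈ 21.086` and a hairpin-pair
probability `p_15 = e^3/(1+e^3) ≈ 0.9526`:

```r
s <- partition_function("GAAAC")
c(s$Q, s$bpp[1, 5])
#> [1] 21.0855369  0.9525741
```

`run_design()` processes whole puzzle files (with per-puzzle FASTA
output, a TSV metrics report, and union/average aggregation over
repeated runs), `evaluate_designs()` scores externally produced
sequences under the same metrics, and `inst/cli/rnadesign.R` exposes
`design`, `eval` and `make-fixtures` subcommands for shell use:

```sh
Rscript inst/cli/rnadesign.R make-fixtures --n-puzzles 5 --length 50 --seed 1 --out puzzles.txt
Rscript inst/cli/rnadesign.R design --puzzles puzzles.txt --objective prob --seed 1 --out out/
```

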