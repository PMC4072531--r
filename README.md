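# sirphylo

Phylogenetics from tandem **sequence-informed repeat** domains.

Some proteins carry an array of short, fixed-length repeat domains whose
copy number evolves by duplication and loss while each copy's sequence
diverges — the 50-residue WHEP domains in the linker of the bifunctional
glutamyl-prolyl tRNA synthetase (EPRS) are the canonical case. Each repeat
array is therefore two characters in one: the per-class **count vector** is
a rare, discrete genome-level character, and the repeat **sequences** carry
ordinary phylogenetic signal. `sirphylo` is for molecular evolutionists who
want to exploit both: it detects the repeats, builds repeat-level trees
under several algorithms with cross-algorithm branch support, collapses
class-count profiles into a most-parsimonious species tree, and predicts
the repeat architectures of unobserved intermediate ancestors.

## What's inside

* **Repeat detection** — windowed (Pustell-style) dot-matrix comparison
  against reference domains (PAM250, window 11, two stringencies),
  anchor-based linker extraction, automatic fixed-length boundary calling,
  and flagging of degenerate repeats detectable only at low stringency.
* **Alignment** — deterministic affine-gap Needleman–Wunsch (Gotoh) in
  C++, percent identity with documented denominator modes, progressive
  multiple alignment on an NJ guide tree.
* **Trees** — neighbor joining on maximum-likelihood Dayhoff distances;
  WAG+Γ maximum likelihood (Felsenstein pruning, 4 discrete gamma
  categories, SPR hill-climbing); BIC model selection; a minimal Bayesian
  MCMC with majority-rule consensus after a 0.25 burn-in; branches
  supported by 2 or 3 of the algorithms annotate as `*` / `**`.
* **Species collapse** — k-medoids (or manual-anchor) assignment of repeat
  units to classes; species as class-count profiles; exact Dreyfus–Wagner
  minimum Steiner tree over the Hanan grid under unit-cost duplication /
  loss / innovation steps, with predicted (unobserved) intermediate
  profiles.
* **Simulator** — forward repeat birth–death evolution along a species
  tree with tiered substitution rates (slow flanks, moderate domains, fast
  spacers) and a machine-readable truth log, so the entire pipeline is
  testable against ground truth.

The model core is this edit system on count profiles: a species with
counts $u = (u_a, u_b, \dots)$ reaches $v$ in
$d(u,v) = \sum_c |u_c - v_c|$ unit steps (duplication $+1$ on a class with
$u_c \ge 1$, loss $-1$, innovation $+1$ into an empty class), and the
putative species tree is the minimum-total-cost Steiner tree connecting
the observed profiles in that lattice.

## Worked example: collapsing five profiles

Five species-level profiles over three repeat classes — an
ichthyosporean-like `(a:1)`, a filasterean-like `(a:2)`, a
choanoflagellate-like `(a:1,b:1,c:1)`, a basal-metazoan-like `(b:1)` and a
bilaterian-like `(c:1)`:

```r
library(sirphylo)
P <- matrix(0L, 5, 3,
            dimnames = list(c("ichthyosporean", "filasterean",
                              "choanoflagellate", "basal_metazoan",
                              "bilaterian"), c("a", "b", "c")))
P["ichthyosporean", "a"] <- 1L
P["filasterean", "a"] <- 2L
P["choanoflagellate", ] <- c(1L, 1L, 1L)
P["basal_metazoan", "b"] <- 1L
P["bilaterian", "c"] <- 1L
class(P) <- c("sir_profiles", "matrix")

cc <- collapse_to_species_tree(P, root_hint = "ichthyosporean")
print(cc)
#> Collapsed species tree: 7 nodes (2 predicted), total cost 6 (exact, rooted)
cc$edges
#>                 parent child    event
#> ichthyosporean   1,0,0 2,0,0   dup(a)
#> ichthyosporean1  1,0,0 1,1,0 innov(b)
#> 1                1,1,0 1,1,1 innov(c)
#> 11               1,1,1 0,1,1  loss(a)
#> 12               0,1,1 0,1,0  loss(c)
#> 13               0,1,1 0,0,1  loss(b)
predict_missing_intermediates(cc)
#>      id n_incident_edges  nearest_species distance
#> 1 1,1,0                2   ichthyosporean        1
#> 2 0,1,1                3 choanoflagellate        1
```

Reading the output: the cheapest history (6 single-domain events) starts
from the single ancestral `a` domain, duplicates it in the filasterean
lineage, founds classes `b` and `c` on the way to the choanoflagellate
architecture, and passes through a **predicted ancestor `0,1,1`** — a
species carrying one `b`-like and one `c`-like domain but no `a` — from
which the basal-metazoan and bilaterian profiles each derive by one loss.
An observed profile at unit distance from a predicted node (here, e.g., a
hydrozoan-like `(b:1,c:2)` would be one `dup(c)` away from `0,1,1`) is the
kind of "missing link" this analysis is designed to surface.

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study on simulated
data, writing their tables under `results/`:

1. `01_simulate.R` — generate the 8-species reference dataset (FASTA +
   truth tables).
2. `02_detect_repeats.R` — extract linkers, call repeat boundaries, score
   detection against truth.
3. `03_repeat_trees.R` — align units; NJ tree for classification; NJ/ML/
   Bayesian comparison with `*`/`**` support on a subset.
4. `04_species_tree.R` — classes, profiles, parsimony collapse, predicted
   intermediates, and the Robinson–Foulds comparison with the true tree.

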