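---
title: "Phylogenetics from tandem repeat domains: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetics from tandem repeat domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirphylo)
```

## The scientific problem

Some multi-domain proteins carry a tandem array of short, fixed-length
repeat domains whose copy number changes by duplication and loss while their
sequences diverge. The canonical example is the linker of the bifunctional
glutamyl-prolyl tRNA synthetase (EPRS), where a variable number of
50-residue WHEP domains sits between two deeply conserved catalytic
domains. Such repeats are doubly informative characters: the *count* of
repeats per class behaves like a rare genome-level character (a duplication
or deletion is a discrete, heritable event), while the *sequence* of each
repeat carries ordinary phylogenetic signal. The linker is also easy to
delimit, because the flanking catalytic domains barely change.

`sirphylo` implements that workflow end to end:

1. **Detection** — find the linker between two conserved anchors, dot-plot
   it against curated reference domains, and call fixed-length unit
   boundaries.
2. **Repeat-level trees** — align the units and infer trees by neighbor
   joining (Dayhoff ML distances), WAG+Gamma maximum likelihood with SPR
   search, and a minimal Bayesian MCMC; annotate branches by how many of
   the three algorithms agree (`*` = 2, `**` = 3).
3. **Species collapse** — cluster units into sequence classes on the repeat
   tree, summarize each species as a class-count profile, and connect the
   profiles by the most parsimonious tree of single-domain duplication,
   loss and class-founding (innovation) steps, predicting unobserved
   intermediate profiles.
4. **Simulation** — a forward generator of repeat birth-death evolution
   with tiered substitution rates supplies ground truth for all of the
   above.

## Detection model

The dot matrix slides an ungapped window (default 11 residues, odd) along
both sequences and scores each center pair with a substitution matrix
(default PAM250, the classic choice for distant homology). A pair is marked
when its window score reaches a fraction (default 0.5, "high stringency";
0.3, "low stringency") of the maximum attainable score for that window
pair. We normalize by the *smaller* of the two windows' perfect self-match
scores; normalizing by the query window alone would make self-comparisons
asymmetric, and symmetry is a property users rightly expect of a dot plot.

Boundary calling exploits the fixed unit length: each maximal diagonal run
of marks against a reference domain nominates one full-coverage placement
of a `domain_length` (default 50) window, scored by its total ungapped
substitution score. The same stringency fraction is applied again at the
unit scale — a placement must reach the fraction of the maximum attainable
domain score — which suppresses units nominated by a single lucky window in
otherwise unrelated sequence. Overlaps are resolved by score (ties: earlier
start), ordinals run from the N terminus, and units found only at the low
stringency are flagged degenerate. Degenerate units are reported but
excluded from class profiles by default, mirroring how atypical,
highly-diverged repeats are usually excluded from groupings.

Because no gaps are modeled inside units, a unit whose interior acquired an
indel will shift its diagonal; such units typically surface at low
stringency as degenerate calls. This is a known limitation, accepted
because linker repeat arrays evolve overwhelmingly by whole-unit gain/loss
and substitution.

## Alignment

Pairwise global alignment is Needleman-Wunsch with affine gaps (a gap of
length L costs `gap_open + L * gap_extend`; defaults 10 and 0.5 with
BLOSUM62). Traceback ties are resolved deterministically — diagonal, then
up, then left — so results are bit-reproducible. The multiple alignment is
progressive: a neighbor-joining guide tree on pairwise score distances
(d = 1 − S_ab / min(S_aa, S_bb)), midpoint-rooted, then profile-profile
merges with the same affine kernel over frequency-vector column scores.
End gaps are free during profile merges only: units of unequal length
should overhang, not drag terminal residues inward. Iterative refinement
is deliberately absent; an import adapter accepts any externally produced
aligned FASTA instead.

## Substitution models and likelihood

Two empirical amino-acid models are embedded by reference: Dayhoff (1978)
and WAG (Whelan & Goldman 2001), with their published stationary
frequencies. The rate matrix is built from exchangeabilities and
frequencies and normalized to one expected substitution per site per unit
time, so branch lengths are expected substitutions per site. Among-site
rate variation uses the standard k equal-probability discrete gamma
categories (default k = 4), each category carrying the mean of its slice of
Gamma(alpha, alpha); the category mean is exactly 1 by construction. Note
that at very large alpha the extreme category means still deviate from 1 by
about 1.27 / sqrt(alpha) (k = 4) — that is a property of the exact
construction, not numerical error.

Likelihoods use Felsenstein pruning with the gamma mixture averaged at
equal weights; gaps, `X` and `*` are missing data (partial likelihood 1).
Transition matrices come from the spectral decomposition of the reversible
rate matrix. ML pairwise distances maximize the likelihood of the observed
residue pair counts over t in [1e-8, 10] with pairwise deletion of gapped
columns; entries hitting the cap are flagged saturated.

## Tree inference

*Neighbor joining* follows Saitou-Nei with two determinism rules: Q-ties
break toward the lexicographically smallest label pair, and negative branch
lengths are clamped to zero with the deficit moved to the sister branch
(preserving the joined pair's path length). Additive matrices are recovered
exactly.

*Maximum likelihood* starts from the NJ tree on ML distances (the
conventional "default starting tree"), then hill-climbs over the full SPR
neighborhood. Each neighbor is first screened with one quick
branch-optimization cycle; the best few (default 3) are refined with full
coordinate-wise Brent optimization (1-D tolerance 1e-6), and a move is
accepted only if it improves the log-likelihood by more than 1e-4. The
final likelihood is never below the starting one. Screening trades a small
risk of missing the best neighbor for a large constant-factor speedup; on
4-5 leaf problems the search provably has the whole topology space within
reach, and recovery tests back the 6-taxon behavior.

*Model selection* scores each candidate (Dayhoff/WAG x uniform/Gamma-4 by
default) on its own NJ starting topology by BIC = −2 lnL + p log(n
columns), p counting branches plus one for a free gamma shape; ties go to
fewer parameters.

*Bayesian MCMC* is a deliberately minimal Metropolis-Hastings sampler:
random NNI for topology, a multiplier proposal for branch lengths
(exponential(10) prior), a reflected sliding window for alpha (uniform
prior on [0.05, 50]), majority-rule consensus over post-burn-in samples
(default burn-in fraction 0.25 of samples) with bipartition posteriors
attached. It makes no claim of matching any particular reference sampler's
posteriors — only the consensus/burn-in contract and seed reproducibility
are promised.

*Cross-algorithm support* counts, for every internal bipartition of a
primary tree, how many of the three trees contain it; counts of 2 and 3
serialize as `*` and `**`. With a rooted primary, the two root edges carry
the same unrooted split, which is labeled once.

## Species collapse

Each species is a vector of unit counts per sequence class. Classes come
either from manual clade anchors (smallest containing clade; clades must be
disjoint and cover all leaves) or k-medoids on the repeat tree's patristic
distances; class labels `a`, `b`, `c`, ... are assigned by each group's
alphabetically smallest member, making labels deterministic.

The collapse connects the observed profiles by a minimum-total-cost tree in
the unit-step lattice, where one step is a duplication (+1 to a non-empty
class), a loss (−1), or an innovation (+1 founding an empty class), all at
unit cost. Candidate ancestral profiles (Steiner points) are restricted to
the Hanan grid — the cartesian product of observed per-class counts — and
the exact optimum is found by Dreyfus-Wagner dynamic programming for up to
`max_exact_terminals` (default 6) distinct profiles, with a
shortest-path-insertion heuristic above (flagged in the output).

Minimum Steiner trees are frequently non-unique, and the ties matter
scientifically. Three choices resolve them:

* an infinitesimal (1e-6) penalty on edges touching the all-zero profile
  keeps equal-cost solutions from routing through repeat-less ancestors
  (observed repeat-less species are unaffected — the penalty only breaks
  ties);
* multi-step edges expand into unit-step chains gains-first, so chains
  never pass through transient repeat-less states;
* for exact instances, a bounded enumeration of co-optimal Steiner node
  sets prefers the tree minimizing convergent class origins (a Dollo-style
  single-origin preference), then fewest predicted nodes, then a
  deterministic key.

The integer total cost always equals the unconstrained optimum (tested
against a brute-force oracle); only the choice among co-optimal trees is
affected. Nodes whose profile matches no observed species are flagged
predicted. `predict_missing_intermediates()` can additionally enumerate
every profile lying on *some* minimal path of a segment (the L1 box between
its endpoints) — the drawn chain is just one of many equally parsimonious
histories, and a predicted intermediate should not depend on that arbitrary
choice.

### What count-profile parsimony can and cannot recover

The collapse uses class-count profiles only; within-class subtree topology
is reported alongside but not used as a constraint. This bounds the
information available: with three classes and stochastic count evolution,
different histories often produce profile sets whose cheapest connecting
tree is *not* congruent with the species tree (the minimum Steiner cost
can undercut the cost of the same profiles constrained to the true
topology). In our recovery experiments the acceptance script measures
exactly this: single-unit boundary detection and per-species counts are
recovered essentially perfectly, while full 8-taxon species-topology
recovery from 3-class counts alone is rare. The honest conclusion, which
matches how such characters are used in practice, is that repeat-class
profiles excel at *placing* individual branching events (which clade shares
a duplication) and at *predicting* intermediate architectures, but a
handful of count characters cannot by themselves resolve a complete
8-taxon topology. Resolving that would require joining the repeat tree's
sequence signal to the count signal — explicitly out of scope for this
version's collapse.

## The synthetic-data generator

`sim_config()` describes the study conditions: a species tree (given as
Newick, or simulated by a crown birth-death process, conditioned on the
species count by rejection), per-domain rates of tandem duplication, loss
and class-founding duplication, and sequence evolution under WAG with three
rate tiers — conserved flanks (relative rate 0.1), domains (1), spacers
(5) — scaled by `subs_scale` (default 0.15 expected substitutions per site
per unit time at tier 1). Root classes diverge from a common ancestral
domain by `class_divergence` (default 0.8 subs/site); an innovation's
founding copy receives `burst_factor` extra expected substitutions at
birth. Duplications insert the copy next to its parent with a freshly drawn
spacer (uniform length 10-40); indels inside domains are not simulated, so
boundary calling is tested under substitution divergence only. The event
log, unit genealogy and slice-exact coordinates are emitted alongside the
FASTA, and replaying the log reproduces every leaf architecture.

`sim_config_easy()` is the fixed preset used by the recovery experiments:
a balanced 8-species tree with long internal branches (1.3) and short tips
(0.5), three pre-diverged root classes, `lambda_dup = 0.4`,
`lambda_loss = 0.1`, `lambda_innov = 0.03`, `burst_factor = 0.3`,
`subs_scale = 0.1`. These values keep domain divergence inside the
detector's range (root-to-leaf about 0.23 subs/site), keep per-species
counts bounded so exact collapse stays computable, and concentrate
count-change events on internal branches. What the generator does *not*
emulate: domain-internal indels, gene conversion between repeats,
rate variation among lineages, and alignment ambiguity from length-variable
units — so passing recovery tests demonstrate correctness of the machinery
under the model, not robustness to every feature of real linkers.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere; ordinals are 1-based.
* FASTA ids are the first whitespace token; writes wrap at 60 columns.
* Newick output prints branch lengths to six decimals; internal labels are
  reserved for support (stars or numbers).
* Stops (`*`) are never silently stripped; sequences with internal stops
  are rejected rather than guessed at (frame-choice errors must surface).
* All stochastic components (simulator, MCMC, k-medoids seeding) are
  reproducible from a single integer seed; alignment, NJ and search are
  deterministic outright.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with tight oracles: exhaustive
likelihood checks on 4-5 leaf trees and 4-6 column alignments; exhaustive
topology enumeration against SPR search on 4-5 leaves with 100-column
alignments; 50-replicate planted-repeat detection; 100-200 random Steiner
instances against the brute-force oracle; and 12-20 full pipeline
replicates under `sim_config_easy()`. Each quantity is recomputed from
scratch by `scripts/acceptance.R`, which reports the measured values as
JSON.
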