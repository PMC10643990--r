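---
title: "Methods: modeling neighboring intein dynamics with inteinkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling neighboring intein dynamics with inteinkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inteinkit)
```

## The question and the model

Inteins are self-splicing protein elements whose homing endonuclease (HEN)
domain lets them invade intein-free alleles of their host gene. When two
insertion sites of the *same* gene are both intein-prone — as with sites
a and d of the haloarchaeal *mcm* helicase — the natural question is
whether the two elements move independently (one gain or loss at a time)
or whether a single gene-conversion event can carry both at once
("co-homing").

`inteinkit` phrases this as a model-selection problem on a phylogeny. The
joint occupancy of the two sites is one of four states, with a fixed index
order:

| index | state | meaning |
|---|---|---|
| 1 | `--` | neither site invaded |
| 2 | `-D` | only site d invaded |
| 3 | `A-` | only site a invaded |
| 4 | `AD` | both sites invaded |

The character evolves along the rooted extein tree as a continuous-time
Markov chain. Two nested, all-rates-different models are compared:

* **no_cohoming**: the eight single-step transitions
  `-- ↔ -D`, `-- ↔ A-`, `-D ↔ AD`, `A- ↔ AD`, each with its own rate;
* **cohoming**: the same eight plus the two double transitions
  `-- ↔ AD`.

Each allowed transition gets one free rate (no hidden rate classes), so
k = 8 versus k = 10. Rates are in expected transitions per unit branch
length; the branch lengths of the input tree set the time scale, and no
separate calibration is applied. Disallowed cells of the rate matrix Q are
structural zeros, and each diagonal entry is minus its row sum.

The tip-state likelihood is computed by the pruning algorithm (post-order
dynamic programming over partial likelihood vectors), with two properties
worth noting:

* **polytomies** are handled natively — the product at a node simply runs
  over all children, so multifurcating inputs are never arbitrarily
  resolved;
* **per-edge rescaling** of partial likelihoods (with an accumulated log
  scale) keeps deep trees and extreme rates from underflowing.

Model fit is summarized with the corrected Akaike criterion,
`AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, with the **taxon count as n**, and
competing models are reported with their relative likelihood
`exp((AICc_min - AICc_i)/2)`.

### Root prior

The likelihood requires a distribution over root states. The reference
implementations of Mk-type models differ in their defaults and the choice
is rarely printed, so it is an explicit, recorded option here:
`"flat"` (1/4 each; the default), `"equilibrium"` (the stationary
distribution of the fitted Q), or a user vector. Every fit and report
records which prior was used. With informative data the choice moves lnL
by well under a log unit, but it is part of the model and should travel
with the numbers.

### Optimization

Rates are optimized in log space with box constraints (defaults
`[1e-9, 1e5]`; the wide upper bound deliberately leaves room for
effectively instantaneous transitions, mirroring the raised search bound
such analyses need when a transition is near-saturated on short branches).
`nlminb` is run from multiple starts: one data-driven start (about one
event per tip over the total tree length) plus seeded log-uniform draws
between the bounds; all restart optima are kept in the result so a flat
or multi-modal likelihood surface is visible rather than hidden. Because
the co-homing model nests the single-homing model, the pipeline
additionally warm-starts the richer model at the reduced model's optimum
with the two extra rates at the lower bound — this makes the nesting
inequality `lnL(cohoming) >= lnL(no_cohoming)` hold for the *reported*
optima, not just in theory.

A caveat surfaced by testing: with zero-variation data (all tips in one
state) the gain rates collapse to zero but the loss rates are
unidentifiable, and under a flat prior the likelihood supremum is ln(1)
rather than ln(1/4) (enormous loss rates funnel every root state into the
observed one). The pipeline therefore flags zero-variation data instead
of pretending the fitted rates mean anything.

### Matrix exponentials

`P(t) = exp(Qt)` is computed by eigendecomposition, accepted only when the
decomposition reconstructs Q to a relative 1e-12 (complex pairs are
handled and the real part taken); otherwise the code falls back to
scaling-and-squaring (`Matrix::expm`). `t = 0` returns the exact identity
so zero-length branches are exact, and entries are clamped to [0, 1]
against roundoff. For a whole tree the decomposition is done once and all
edge matrices are produced with a single matrix product, which is what
makes 1000-tip maximum-likelihood fits take seconds rather than minutes.

## MAD rooting

Unrooted input trees are rooted by minimal ancestor deviation. For a
candidate root position and a tip pair (i, j), the induced ancestor is the
point a on the i–j path nearest the root, and its relative deviation from
the pair midpoint is `r_ij = |2 d(a,i)/d(i,j) - 1|`. For pairs on one side
of the candidate branch this reduces to `|d(i,u) - d(j,u)| / d(i,j)` with
u the branch endpoint on their side; for pairs spanning the branch the
optimal position along the branch has a closed form (a weighted least
squares in 1/d(i,j)^2), clamped to the branch. The branch/position with
the minimal root-mean-square deviation wins; exact ties are resolved to
the first branch in a deterministic postorder and flagged (`tie = TRUE`,
plus a message), never silently. Tip pairs at zero patristic distance are
excluded with a warning, all-zero-length trees are rejected, and
zero-length candidate branches collapse to a point (ρ = 0).

## Occupancy statistics

`count_patterns()` tallies all 2^S presence/absence patterns over the
table's S sites; `expected_independent()` computes the expected counts
under independent invasion from the per-site marginal frequencies.
Expected counts are kept as reals, never rounded. Mini-inteins (elements
without a detectable HEN) count as *present* — they are inteins, just
immobile — with the full/mini flag carried separately. A chi-square
comparison is available but labeled exploratory: it ignores the
phylogenetic non-independence of taxa, which is exactly what the Markov
model is for.

## Insertion-site flanks

Flank windows are counted in **residues, not alignment columns**: from the
insertion point the code walks outward skipping gaps until w residues per
side are collected (default w = 20). The alternative (columns) would make
the profiles depend on how gappy the alignment happens to be around the
site. Insertion-point coordinates in site annotation files are 0-based,
half-open `[start, end)` column intervals; a sequence counts as invaded
when at least 50% of its block columns are non-gap (configurable — the
threshold makes occupancy calls robust to ragged block ends). Logo columns
report Shannon entropy and information content
`IC = log2(20) - H - 19/(2 ln 2 · n)` with the standard small-sample
correction, clamped at zero. Note the correction makes IC depend on
coverage: a single-residue column at n = 2 has IC 0 after correction, so
"IC is maximal iff single-residue" only holds at fixed coverage.

## PSSM detection of inteins and HEN blocks

PSSMs are plain log-odds matrices in bits,
`s(p, aa) = log2((c + α b) / ((n_p + α) b))`, built from user-supplied (or
synthetic) conserved-block alignments with pseudocount mass α = 1 and a
uniform background by default — both configurable and recorded in the PSSM
metadata, since the original analyses do not publish theirs. Every window
of a protein is scored; the default reporting threshold is 60% of a PSSM's
maximum attainable (consensus) score, all scores are emitted so thresholds
can be re-applied post hoc, and ambiguity codes score 0. Overlapping
windows of one PSSM merge to the best offset; hits from different PSSMs
within 150 residues (the default merge gap — conserved blocks of one
intein are far closer to each other than two distinct inteins are) merge
into a single intein call. A call containing at least one LAGLIDADG HEN
block hit is a *full* intein, otherwise a *mini* intein. Group summaries
use intein counts (not gene counts) as denominators of the %-with-HEN
columns.

The R API reports hit coordinates 1-based (`start`/`end`), following
R/Bioconductor convention.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known ground truth:

* **trees** from a seeded birth–death process (`ape::rphylo`), branch
  lengths in time units;
* **occupancy histories** by exact Gillespie simulation along each branch
  (exponential waiting times at rate −Q[s,s], jumps proportional to
  Q[s,·]), with the complete event list recorded so tip states can be
  replayed and verified event by event;
* **annotated alignments**: a master extein scaffold with i.i.d. residues
  from a haloarchaea-like composition (acid-shifted), per-row point
  substitutions (default 5%), intein blocks filled for invaded rows and
  all-gap otherwise, and the +1 residue drawn per invasion status —
  default: invaded always serine, uninvaded proline with probability 0.9 —
  reproducing the serine/proline dichotomy of invasion-prone sites;
* **proteomes** with planted full/mini inteins assembled from synthetic
  conserved blocks (three splicing blocks, four LAGLIDADG-style HEN
  blocks; constructed sequences, not curated natural ones) at recorded
  positions.

One master seed expands into per-component sub-seeds, so components can be
regenerated independently and all outputs are bit-reproducible.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequence evolution along the tree (alignment
rows are scaffold + noise, not phylogenetically correlated), alignment
error, rate variation across lineages, gene transfer of exteins, and any
dependence between the two sites beyond what the Markov model itself
induces. Parameter-recovery results on these fixtures certify the
estimator, not the realism of the model for any particular dataset.

## Problem sizes and tolerances used by the checks

The shipped checks use sizes chosen to give each property real exercise:
pruning vs exhaustive enumeration on 100 random trees of 3–6 tips
(tolerance 1e-10); the nesting inequality on 20 simulated 40-tip datasets
(slack 1e-6); rate recovery on ten 1000-tip simulations with rates in
[0.5, 2] (criterion: per-rate median relative error below 50%); AICc model
selection on ten 500-tip datasets simulated without co-homing (criterion:
the single-homing model preferred at least 8 of 10 times); MAD recovery on
fifty 20-tip clock-like trees (criterion: at least 95%) plus grid-search
agreement on 6-tip trees; and planted-intein recovery of 13/13 elements
with correct full/mini categories. `scripts/acceptance.R` recomputes all
of these from one seed.

## Known limitations

* No ancestral-state reconstruction, hidden-rate classes, Bayesian
  fitting, or joint models over more than two sites.
* Missing or ambiguous tip states are rejected, not marginalized.
* The exploratory chi-square ignores phylogeny (by design; see above).
* Tree inference and alignment construction are out of scope: trees and
  alignments are consumed, not estimated.
* With few taxa or invariant data the per-transition rates are weakly
  identified; inspect the restart table and the zero-variation flag
  before interpreting individual rates.
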