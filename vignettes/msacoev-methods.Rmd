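---
title: "Simulated MSA evolution and differential-binary coevolution detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated MSA evolution and differential-binary coevolution detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msacoev)
```

## The problem

Pairs of protein positions under a shared structural or functional
constraint accumulate compensatory substitutions: they coevolve.  A
detector working from a multiple sequence alignment (MSA) alone must
separate this signal from two confounders — the phylogenetic correlation
that shared ancestry imprints on *every* pair of columns, and stochastic
covariation from finite sampling.  Because the true coevolving pairs of
a real family are unknown, `msacoev` evaluates detectors on alignments
evolved in silico, where an internal observer records every
co-segregating pair of changes exactly.

## The evolution model

A single ancestor (drawn per position from a profile, by default
uniform over the 20 amino acids) is copied down a tree specified by
`branching`: level 1 creates `branching[1]` copies; each later level
appends `branching[k]` copies of every current sequence.  Within each
level every lineage undergoes `cycles[k]` cycles of:

1. **Point mutation** — each non-covarion position mutates with
   probability `mut_prob`, redrawing from the profile (a redraw of the
   same residue is silent and not counted).
2. **Covarion firing** — each covarion pair fires with probability
   `cov_prob`, drawing a residue *couple* jointly from its 21×21 pair
   distribution.  The default pair model places equal mass on
   `cov_states` (8) residue couples, so a coupled pair carries about
   log2(8) = 3 bits of mutual information at equilibrium; real
   covarying columns similarly visit several residue combinations.
   A fire that reproduces the current couple changes nothing and is not
   counted.
3. **Recombination** — with probability `rec_prob` the lineage receives
   one zone (chosen uniformly among the zones delimited by the
   `crossovers` points, half-open intervals) from a random donor in the
   current population.

Alignment length is fixed (no indels) and there is no fitness model:
the simulator is a null-plus-covarions generator, not a selection
model.  The final population is subsampled uniformly without
replacement to `n_seq` sequences; the rows are returned in the random
draw order, which is what "unsorted" means for the resorting
diagnostics below.

### Ground-truth bookkeeping

Per cycle and lineage, let `M` be the positions changed by point
mutation, `C` the covarion pairs whose residues changed, and `R` the
positions changed by recombination.  Then

- `mutCOV` += 1 for every unordered pair within `M`;
- `covCOV` += 1 for every changed covarion pair and for every cross
  pair between positions of *distinct* covarion pairs changed in the
  same cycle (two pairs changing together credit six entries);
- `recCOV` += 1 for every pair within `R` and for every pair mixing a
  position of `M` with one of `R`;
- `totCOV` accumulates every increment.

A position changed by mutation and then overwritten by recombination in
the same cycle is attributed to recombination only, so each pair
increment lands in exactly one component matrix and
`totCOV = mutCOV + covCOV + recCOV` holds after every cycle (the run
records the residual after each cycle; it is identically zero).  Pairs
mixing a covarion position with `M` or `R` positions are not counted —
covarion credit is reserved for the forced-coupling mechanism.  The
event log allows the four matrices to be reconstructed independently
(`replay_events()`), which the test suite uses as an audit.

## The differential binary methods

The resorting step orders rows by a greedy nearest-neighbour chain on
Hamming distance, seeded at the two most similar sequences (modes
seeding at a fixed row, or scanning every row as seed and keeping the
smallest total, are provided).  Exact minimization is a travelling
salesman path and is deliberately not attempted; ties break to the
lowest original index so the ordering is deterministic.  The
differential binary translation writes 0 where a cell equals the cell
above and 1 otherwise, first row all zeros; gap-to-gap is "no change"
and gap-to-residue is a change (the gap is a first-class 21st symbol).

Three detectors build on this encoding:

- **dbZPX2**: MI matrix of the binary columns, merged with their
  covariance matrix (ordinary least squares rescaling of the covariance
  onto the MI scale, then the elementwise mean), then ZPX2.
- **dgbZPX2**: the covariance term instead comes from the global
  differential binary matrix — each position expands to a 21-column
  one-hot block carrying the *new* symbol at changed cells — collapsed
  back to position resolution by the Frobenius norm of each 21×21
  covariance block.  The text this design follows does not state
  whether the original implementation one-hots the new symbol, the old
  one, or a signed difference; the new symbol is the natural reading of
  a "differential" encoding that reintroduces the change type, and a
  plain one-hot (no differencing) is available behind the `onehot`
  flag for comparison.
- **nbZPX2**: the resorted alignment masked by the binary matrix (0
  where unchanged, the new residue where changed — a 22-symbol
  alphabet), scored by MI then ZPX2.

ZPX2 computes per-row Z-scores of the symmetric input (mean and
population standard deviation over each row's off-diagonal entries;
zero-spread rows give Z = 0), multiplies `Z[i,j] * Z[j,i]`, and squares.
The square discards the sign, so a pair with strongly *negative*
cross-product ranks as high as a positive one; a signed variant
(`signed = TRUE`) is provided for users who care about the direction.
ZPX2 is applied directly to the merged (or nb-MI) matrix; an optional
`apc_first` flag inserts the average product correction first, off by
default because the composite pipelines are defined without it.

Amino-acid MI and OMES exclude gapped rows pairwise (gap-driven MI is a
known artifact), while the binary and normal/binary pipelines treat
every symbol as informative — the encoding has already folded gaps into
change events.  MI uses plug-in frequencies without pseudocounts.  The
diagonal of every finished score matrix is set to the off-diagonal
minimum so self-pairs never enter a ranking.

## Evaluation

`recovery_curve()` ranks a detector's pairs by descending score (ties
lexicographic), credits each ranked pair with its `covCOV` count, and
accumulates.  The ideal-observer curve — the `covCOV` values in their
own descending order — bounds every detector from above, which the test
suite asserts.  `contact_recall()` scores a detector against a
structure: centroids are the unweighted mean of all non-hydrogen atoms
(a side-chain-only mode exists; the backbone-included default is the
more conservative reading of "residue centroid"), contacts are centroid
pairs strictly closer than 8 Å, and recall among the top-L pairs is
reported under a separation filter implemented as |i−j| ≥ s+1 for "at
least s intervening positions", applied to numerator and denominator
alike.  `merge_curves()` fits each curve with PCHIP (shape-preserving,
monotone inputs give monotone interpolants), resamples on a common
normalized grid of 100 points, and reports the pointwise mean and plain
standard deviation — the transparent spread choice; a weighted scheme
can be slotted in where the standard deviation is computed.

## Study conditions and what the tests show

Two presets encode the study conditions used throughout the tests.

`kdo8ps_like_config()` mirrors a 280-residue family: 300 sequences, 28
covarion pairs (10% of positions, at the benchmark ratio), 9
recombination zones with the crossover points of the reference family,
and a copy-tree of 5 deep subfamilies of 60 sequences.  Deep branches
run 280 mutation cycles at `mut_prob = 0.021` (about 6 expected draws
per position, i.e. saturated between-subfamily divergence, as between
distant homologs of a real family), terminal branches 5 cycles (about
80% within-subfamily identity, as between close homologs).

`tree_family_config()` is the recombination-free variant (150
positions, 5 subfamilies of 120, subsampled to 600) used to
characterize the resorting diagnostics: across seeded replicates the
resorted differential binary translation shows lower mean column
entropy, lower mean MI, and higher mean joint entropy than the
translation in as-produced (random) row order.  This behaviour is a
genuine window, not a tautology: the joint entropy can only rise while
the marginal entropies fall if the unsorted binary matrix is strongly
row-correlated, which requires the bimodal adjacency structure of a
clustered family — near-duplicate neighbours within subfamilies,
saturated divergence between them.  Outside that regime (shallow
families, homogeneous divergence, heavy recombination) the joint
entropy falls together with the entropy, and the diagnostic is
reported for what it is.  Recombination is excluded from this preset
because the property concerns purely tree-structured signal; the
recombination machinery is exercised by the bookkeeping tests instead.

Problem sizes in the test suite (20 replicates at 300×280 for recovery
comparisons, 20 at 600×150 for the resorting diagnostics, 20 at 100×150
for additivity, oracle comparisons at 8×6) were chosen to characterize
the methods at the study scale while keeping a full run of the suite in
the minutes range.

What passing these tests does *not* show: the simulator has no indels,
no selection, no rate heterogeneity beyond the profile, and its
covarion model is perfectly coupled; real families are messier on all
four axes.  The simulator's purpose is a controlled null with known
coevolution, not a generative model of Pfam.

## Numerical notes

- All entropies are in bits; plug-in estimates, no bias correction.
- Z-score rows with zero spread yield zero, not NaN; degenerate
  regression in the MI/COV merge falls back to the MI matrix with a
  warning; the average product correction returns its input unchanged
  (with a warning) when the grand mean is zero.
- Relative entropy excludes gaps from column frequencies, returns 0 for
  all-gap columns, and errors if the background assigns zero
  probability to an observed residue.  The background defaults to
  uniform 1/20 and is configurable.
- Non-canonical residue letters (B, J, O, U, X, Z) map to the gap
  symbol: the alphabet is exactly 20 amino acids plus gap, and an
  ambiguity code carries no usable identity for these methods.
- Alignment-to-structure mapping is by explicit residue-number offset;
  the package does not attempt to align sequences to structures.
- Seeded runs are bit-reproducible: one seed drives ancestor, covarion
  placement and dynamics, mutation, recombination and subsampling.
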