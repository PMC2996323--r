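---
title: "Rejected-substitution scoring and constrained-element detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rejected-substitution scoring and constrained-element detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerpr)
```

## The model

gerpr quantifies evolutionary constraint at single columns of a multiple
sequence alignment in **rejected substitutions (RS)**.  A supplied neutral
phylogeny `T` relates the aligned species; its branch lengths are expected
substitutions per neutral site, so the sum of all branch lengths (the
*phylogenetic scope*) is the expected number of substitutions a neutral site
accumulates across the whole tree.

For each alignment column, species carrying a gap or an ambiguity code are
projected out of the tree.  The site-specific neutral rate `n` is the total
branch length of the projected tree.  A single **rescaling factor** `r` is
then fitted by maximum likelihood: every branch of the projected tree is
multiplied by `r`, and the likelihood of the observed leaf nucleotides

    L(r) = Pr(c_1, ..., c_k | T_r)

is computed by Felsenstein's pruning algorithm under the HKY85 substitution
model.  The column's estimated evolutionary rate is `r n`, and

    RS = n - r n = n (1 - r)

Positive RS means a substitution deficit (constraint); negative RS a
surplus.  Because maximum likelihood can estimate arbitrarily large `r`, the
estimate is capped at `r = 3`, so RS is bounded in `[-2n, +n]`.  Columns
with fewer than 3 ungapped species cannot form a tree and are left unscored
(the rates output carries `0.000000 0.000000` for them; internally a
`scored = FALSE` flag, not the zeros, is authoritative).

Implementation notes:

* The HKY85 rate matrix is normalized so that the expected number of
  substitutions per unit branch length is one at stationarity.  Without this
  normalization, branch lengths would not be interpretable as neutral
  substitution counts and `r` would absorb an arbitrary constant.
* Transition probabilities `p_ab(t)` come from a one-time eigendecomposition
  of the symmetrized rate matrix (the model is time reversible, so the
  symmetrized matrix has a real spectrum).
* Gapped species are *marginalized* in the pruning recursion (their partial
  likelihood vector is all ones).  Under a reversible model this equals the
  likelihood on the explicitly projected tree for every `r`, because `r`
  rescales all branches uniformly; the unit tests verify this equivalence
  against an exhaustive-enumeration oracle.
* Ambiguity codes (N and the IUPAC letters) are treated exactly like gaps
  and projected out.  This keeps the neutral-rate definition (sum of
  retained branches) consistent; marginalizing a partially informative code
  would retain its branches in `n` while contributing almost no signal.
* `L(r)` is maximized on `[0, 3]` with Brent's method on the negative
  log-likelihood, absolute tolerance `1e-4` on `r` — scores are later
  discretized to 0.1 RS, so finer precision is wasted.  The endpoints are
  evaluated explicitly and returned exactly when they beat the interior
  optimum, so invariant columns give `r = 0` (RS `= n`) and maximally
  discordant columns give `r = 3` (RS `= -2n`).  For a non-invariant column
  `L(0) = 0`; the optimizer works in log space and treats it as `-Inf`.

### Known property: skew of per-column estimates

A single column carries little information, so the per-column ML estimate
of `r` is noisy and right-skewed.  On the package's 16-leaf, scope-5.8 test
tree the *median* of the estimates sits on the generating value, but the
*mean* carries a positive bias that peaks around `r = 1` (about +0.13 at
2000 columns; about +0.01 at `r = 0.2`, +0.05 at `r = 0.5`, +0.08 at
`r = 2`, where the cap at 3 removes part of the upper tail).  The test
suite reproduces these numbers, and an independent phylogenetics library
gives the same mean at `r = 1`, so this is a property of the estimator, not
of the implementation.  Consumers averaging RS scores over many positions
should be aware that the neutral background average is slightly negative
for this reason.

## Constrained-element detection

Element detection operates on the per-position (neutral rate, RS) track and
is independent of how the scores were produced.

**Regions.**  The track is split into regions of approximately
`chunk_size` (default 2,000,000) positions, with boundaries placed in long
unscored runs (at least `shallow_run` positions, default 10) nearest each
size multiple; where no such run exists the split falls at the exact
multiple.  Elements never span region boundaries.

**Null model.**  Within a region the null is the empirical distribution of
discretized RS scores:

* Scores are discretized to multiples of `tol` (default 0.1 RS), rounding
  half away from zero.
* Runs of at least `shallow_run` consecutive *shallow* positions (neutral
  rate below `shallow_cutoff`, default 0.5 substitutions/site) are excluded
  outright — such stretches reflect missing data, not evolution — and act
  as hard breaks for candidate elements, like unscored runs.
* Shallow positions that survive (isolated ones) are penalized by
  `0.5 * (shallow_cutoff - n)`, capped at 0.5 RS, both in the histogram and
  in candidate scores.  The cap never binds at the defaults; it guards
  user-supplied cutoffs above 1.  Penalizing only the null would *lower* it
  and so reward shallow predictions, the opposite of the intent.
* One pseudocount (`prior_weight`) is added to every bin so no score has
  probability zero.
* The histogram's support is the observed score range of the region, not a
  fixed theoretical grid.  This makes p-values exactly invariant under a
  uniform additive shift of all scores by a multiple of `tol` (the null and
  every candidate score translate together); with a fixed absolute support
  the prior mass would redistribute and break the invariance.  Shifts that
  are not multiples of `tol` perturb p-values only through discretization
  rounding.
* A *preliminary pass* of the full detector with false-positive cutoff 0
  identifies clearly constrained intervals, which are excluded from the
  final histogram so strong signal does not contaminate the null.  One
  round only; further iteration changes little and costs a full pass.

**p-values.**  A candidate of length `L` and score `S` gets the p-value
`Pr(sum of L i.i.d. null draws >= S)`, computed by iterated convolution of
the discretized null (a dynamic program over lengths, with tails cached per
`L`).  Far-below-the-mean bins whose cumulative probability stays under
1e-30 are trimmed as the support grows; every queried score sits at or
above zero, so reported p-values are exact to within that budget.  The unit
tests pin the DP to brute-force enumeration at small `L`.

**Candidates.**  Every segment of contiguous columns is in principle a
candidate.  The search is restricted to segments that start at the first
position of a maximal run of non-negative effective RS and end at the last
position of such a run (endpoints non-negative and not extendable outward);
candidates may span negative stretches between runs, which is what lets a
codon-patterned exon with weak third positions come out as one element
rather than fragments.  Length is bounded by `[min_length, max_length]`
(defaults 4 and 2000), and candidates must score at least
`q * L * median_neutral_rate` (default `q = 0.05`), a permissive linear
pruning of hopeless candidates.  The tests check empirically that this
pruning never removes a candidate whose p-value would have been accepted.

**Selection and error control.**  Candidates are accepted greedily from
smallest to largest p-value — ties favor the longer element, then the
leftmost — discarding overlaps with previously accepted elements.
Analytic multiple-testing correction across overlapping candidates is not
attempted; instead `n_shuffles` (default 5) permuted copies of the region
(scores shuffled uniformly among usable positions; unscored positions and
long shallow runs stay in place) are run through the identical machinery,
and the mean number of null predictions at or below a p-value threshold
estimates the expected false predictions.  Acceptance stops when estimated
false predictions divided by accepted predictions first exceeds
`fp_cutoff` (default 5%, counted in number of predictions).  The same
tables give the expected false *bases* and the detection-saturation curve
`B(c)`, `F(c)`, `B*(c) = B(c) - F(c)`, whose maximum estimates the total
detectable constrained bases in the track.

The false-positive cutoff is applied per region; pooled tables are
reported.  All shuffles derive their streams deterministically from one
seed, so every result is bit-for-bit reproducible.

## The synthetic-data generator

`simulate_alignment()` draws columns independently from exactly the
generative model the scorer assumes: root state from the stationary
frequencies, then evolution down each branch with the branch length
multiplied by the column's true `r`.  Constraint is planted through a
piecewise `r` profile (`constraint_profile()`), optionally codon-patterned
(positions 1–2 at `r`, position 3 at `r3`).  Gaps are injected
independently per species and column (never in the reference).

Defaults (chosen once, as study conditions): a balanced 16-leaf tree with
equal branch lengths scaled to scope 5.8 substitutions/site, mirroring the
depth of a mammal-wide alignment; HKY85 with transition/transversion ratio
2.0 and mildly AT-rich frequencies (A/T 0.3, C/G 0.2); gap rate 0.1.

What passing tests on these data do **not** show about real alignments:
real gaps are autocorrelated (lineage-specific deletions, assembly holes),
real neutral rates vary along the genome (the score distribution is not
homogeneous within a region), alignment error produces column patterns no
substitution model generates, and real constraint boundaries are not sharp.
The detector's p-values inherit the i.i.d.-within-region assumption.

## Problem sizes used in the checks

The packaged checks run at desk scale: oracle comparisons on 3–4 leaf trees
(about 100 random column/rescaling pairs) and 5-bin histograms with
lengths up to 6; rate recovery at 2000 columns per setting; null
calibration and planted-element recovery on 100 kb tracks (10 planted
blocks of 50–500 bp at `r <= 0.3`); the codon-pattern comparison on 20 kb
tracks with a 150 bp block.  `scripts/acceptance.R` recomputes all of these
from scratch for any seed.

## Known limitations

* Only HKY85 ships, though the model interface is pluggable; no
  context-dependent or codon models, and no gap/indel modeling (projection
  avoids the biases of explicit gap models at the cost of some information
  loss).
* The neutral tree is taken as given; branch lengths are never re-estimated
  from the data.
* p-values assume score homogeneity and independence within a region; the
  shuffle-based estimate is the only error control.
* The greedy tie-break favors longer elements, which can merge two nearby
  strong elements separated by weakly constrained sequence into one
  prediction; the per-position scores remain available to split such cases
  downstream.
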