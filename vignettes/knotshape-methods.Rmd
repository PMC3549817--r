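---
title: "Consensus shape and pseudoknotted structure prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus shape and pseudoknotted structure prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotshape)
```

## The problem

Homologous non-coding RNAs conserve their secondary structure more strongly
than their sequence, and for many families that structure includes
pseudoknots — pairs i–j and i'–j' with i < i' < j < j', which most
thermodynamic folders either forbid or restrict to fixed topologies. Given a
set of homologous ncRNA sequences and, for each, a *folding ensemble* (the
optimal and suboptimal structures a de novo folder proposes, with free
energies), `knotshape` answers two questions:

1. **Which abstract shape does the family share?** An abstract shape retains
   the adjacency and nesting of helices but forgets helix and loop lengths,
   so the exponentially large folding space collapses onto a small set of
   shape classes. This is the shape-ranking half of the pipeline
   (`predict_shape`).
2. **Which concrete structure inside that shape class is the consensus?**
   One candidate structure per sequence is selected to maximize joint
   sequence-plus-structure similarity, the selections are aligned, and
   column-wise majority pairs form the consensus (`knotstructure`).

The fold-then-align strategy needs no input alignment, which matters for
families whose sequence identity is too low for alignment-first methods.

## Structures, pseudoknot orders, and shapes

Structures are pair tables with 1-based, closed coordinates. Every pair
carries a *pseudoknot order*: order 0 is a maximum-cardinality mutually
non-crossing subset of the pairs (the nested page), and each remaining pair
takes the lowest order k ≥ 1 whose class it does not cross. The order-0
subset is found by an interval dynamic program over the pairs (each position
belongs to at most one pair, so the DP is quadratic); ties are broken towards
the subset containing the 5'-most pair and then the lexicographically
smallest pair list, making `annotate_crossing` deterministic. External
folding tools rarely annotate crossing classes in their output, so adapter
output is always re-annotated through this mechanism.

On output the package always writes the Rfam letter dialect — `(` `)` for
order 0 and `A/a`, `B/b`, … for orders 1, 2, … — while the parser also
accepts `[]`, `{}`, `<>` as crossing classes (numbered by first appearance)
because several tools emit those.

Shapes are computed at levels 1, 3 and 5:

* a **stack** is a maximal run of directly stacked pairs of one order;
* a **helix** merges consecutive stacks separated only by unpaired positions
  (bulges and internal loops) on both strands, orders matching;
* **level 5** emits one `[`/`]` or letter pair per helix, **level 3** one per
  stack (a split pseudoknot helix repeats its letter, e.g. `[AA]aa` at level
  3 versus `[A]a` at level 5), **level 1** adds a `_` for every maximal
  unpaired region, termini included.

Neither the merge rule nor the letter-assignment order is forced by the
definitions alone; we fix them (merge across pure bulges/internal loops;
letters `A`, `B`, … by first opening position; distinct crossing helices get
distinct letters) so that H-type families render `[A]a` and split-helix
frameshift elements render `[AA]aa` at level 3, the patterns used for
pseudoknot families in the Rfam-derived literature. Levels 2 and 4 exist in
the wider abstract-shape literature but are not implemented.

```{r shapes}
s <- parse_dotbracket("(((...AAAA...)))...aaaa")
c(level5 = shape_of(s, 5), level3 = shape_of(s, 3), level1 = shape_of(s, 1))
```

## Shape classes, features, and the ranking model

All candidate structures of all sequences are pooled and partitioned by
shape (`group_by_shape`). For a class P over N input sequences the four
model features are

* `F1 = |P.LX|`, the number of sequences with at least one structure in P;
* `F2 = |P.LS|`, the number of structures in P;
* `F3`, the mean free energy of the structures in P;
* `F4`, the mean over P's member sequences of each sequence's ensemble MFE —
  deliberately the minimum over *all* of that sequence's candidates, not
  only those inside P, so F4 measures how stable P's supporters are overall.

Features are min–max normalized to [0, 1]; the parameters are fitted on the
training data, stored in the model, and re-applied with clipping at
prediction time, so test families of different sizes and energy scales land
on the training scale. A constant feature maps to 0.5 (no information, no
influence after centering).

Candidate features are ranked by **F-score**, the ratio of between-class mean
separation to within-class variance; its denominator is floored at 1e-12 so
a perfectly separating feature keeps a large finite score instead of
dividing by zero. Feature subsets are then grown by **sequential forward
search**: each round trial-adds the remaining features in descending F-score
order, keeps the addition with the best 5-fold cross-validation accuracy,
and stops at the first round with no improvement — the simplest stopping
rule consistent with greedy forward selection. Folds are stratified by
family so that shape classes of one family never straddle a training/test
split. The SVM is a linear-kernel maximum-margin classifier (fit via
`e1071`, i.e. libsvm); its cost constant is grid-searched over
2^-5, 2^-3, …, 2^5, a standard geometric grid, ties going to the smaller
(more regularized) C.

A trained model scores any class as the signed hyperplane distance
`sc = w · x + b`. Candidate shapes are reported in descending sc; ties break
by larger F1, then shape string. When no class lands on the positive side —
e.g. a family far from the training regime — the top-scoring shape is still
reported, with a warning, since downstream structure prediction always needs
a shape.

## Grammar strings and the consensus procedure

A *grammar string* encodes a (sequence, structure) pair position-by-position:
each symbol carries the nucleotide and a structural role (unpaired, or the
opening/closing side of a pair of order k). Two grammar strings are compared
by global alignment (Needleman–Wunsch, linear gap penalty, implemented in
C++) under the scheme: role and nucleotide match +2, role-only match +1,
role mismatch −1, gap −2, all configurable via a key=value file. Similarity
is the raw score normalized by the alignment length, terminal gaps included.
Pseudoknot roles compare equal only on identical order, which preserves
crossing topology through the consensus step. This positional encoding is a
deliberately transparent formalism with the properties the pipeline needs —
joint sequence+structure alignability, pseudoknot capable; the scoring
scheme being configurable lets users approximate richer grammar-based
encodings.

`select_representatives` implements the constrained clustering: every
candidate structure with the predicted shape starts as a singleton cluster;
same-sequence candidate pairs are fixed at −∞ similarity; cluster-to-cluster
similarity is the arithmetic mean of member pairwise similarities (UPGMA run
on similarities, merging the maximum, rather than on distances); and
whenever a structure of sequence X joins the merged cluster, every other
candidate of X leaves the pool. The procedure stops when one cluster holds
exactly one structure per covered sequence. Merge ties break on the
lexicographically smallest (sequence id, ensemble rank) member. The merge
history is the guide tree for the progressive profile alignment (mean
pairwise column scores; a gap against a symbol scores the gap penalty, two
gaps score zero; gaps propagate to all profile members).

The consensus is read off the alignment columns: a column pair (p, q) is
kept when the fraction of rows pairing p with q exceeds the support
threshold (default 0.5, strictly greater — a majority rule; at 1.0 the
consensus is the intersection of the rows). A column claimed by two kept
pairs goes to the higher support, then to the 5'-most partner. Orders are
re-annotated on the kept set, and the consensus maps back to each sequence
by dropping that row's gap columns; per-sequence structures are re-annotated
too, because dropping pairs can orphan an order-k pair from its lower-order
witness. Sequences that never fold into the predicted shape receive no
prediction and are listed separately rather than being forced into the
consensus. The candidate pool per sequence is capped at the optimal plus 10
suboptimal structures by default, matching the regime in which folding
ensembles are typically sampled (an energy-range cutoff around 5%); the cap
is configurable. Only the final representatives are aligned — the greedy
clustering is a heuristic and is not guaranteed to find the representative
set with maximum mean similarity, but its first merge is always the global
best cross-sequence pair, and the constraint (never two structures of one
sequence in a cluster) holds at every step by construction.

## The synthetic-family generator and the toy folder

Real training data for the ranking model comes from curated families whose
reference structures are known; those corpora are not bundled here. The
package instead ships a generator (`generate_family`) whose defaults define
the study conditions used by the tests and the acceptance script: N = 10
sequences of L = 80 nt, mutation rate 0.1 per site (pairwise identities in
the 80–90% range typical of curated family sets), 5 decoys per sequence,
energy noise sd 0.5 kcal/mol, decoy energies within 5% of the MFE. The
planted structure (H-type-like pseudoknot optional) is complementarity-
consistent with a random ancestor; mutations at paired sites are
compensatory. Decoys are drawn from a family-level pool — homologs misfold
similarly, so decoy classes accumulate members across sequences — but every
decoy's shape differs from the planted shape at the configured level, and
the planted structure is the MFE candidate of every ensemble. Those two
contract properties are what make the recovery thresholds (planted shape at
rank 1 in ≥ 90% of replicates; consensus sensitivity and PPV ≥ 0.8)
generator-design properties rather than empirical tuning: F1/F2 favor and
F3/F4 disfavor the planted class by construction.

What the generator does *not* emulate: energy models correlated with
structure plausibility (decoy energies are independent noise), folding
ensembles whose suboptimal structures share most of their pairs with the
optimum, indels between family members (all sequences have equal length),
and families whose true structure is absent from some ensembles. Passing
the recovery tests therefore demonstrates the machinery — grouping,
features, ranking, constrained clustering, alignment, consensus — not
performance on curated data; for real use, retrain the model on labeled
families produced by a real folder through the adapter interface.

`toy_fold` exists so the package can exercise the full fold-then-predict
path without an external tool: a Nussinov-style dynamic program maximizing
(pairs + 0.5 per stacked adjacent pair), hairpin loops ≥ 3 nt, Watson–Crick
and GU wobble pairs, reported energy = −score on an arbitrary fixed scale.
Suboptimal structures within a percentage window of the optimum are
enumerated through an unambiguous grammar decomposition with best-first
expansion, so the enumeration is exact, deterministic, and duplicate-free.
It never emits pseudoknots; pseudoknotted test families come from the
generator's planted structures. No acceptance quantity depends on the toy
energy scale.

## Numerical and degenerate-input choices

* F-score requires ≥ 2 instances per class (sample variances); a zero
  denominator returns numerator/1e-12.
* Sensitivity and PPV with zero denominators are reported as `NA`
  (undefined), never 0; pair matching is exact (i, j) identity with
  pseudoknot order ignored and no helix-slip tolerance.
* Alignment traceback ties break diagonal > up > left; model files serialize
  doubles as `%.17g` text so a reloaded model scores bit-identically.
* A single-sequence shape class skips clustering and returns that sequence's
  lowest-energy candidate.
* All randomness (fold assignment, generator) is seed-controlled; identical
  inputs and seeds reproduce outputs byte-for-byte.

## Problem sizes

The bundled default model is trained on 100 generated families (about 400
shape classes); the test suite and the acceptance script use the same
training size plus 50 replicate families for recovery measurements, which
keeps a full run in the tens of seconds on one CPU. Complexity grows mildly:
shape grouping is linear in total structures, and the clustering is cubic in
the number of sequences with quadratic pairwise alignments in sequence
length, so families of 15–20 sequences at a few hundred nt remain practical.

## Known limitations

* The consensus is defined on alignment columns; families with long
  insertions relative to each other dilute support and can drop weakly
  covered helices.
* The greedy constrained clustering can be suboptimal for adversarial
  similarity matrices (the exhaustive representative search is factorial and
  intentionally not attempted).
* Shape strings trust the structure's pseudoknot-order annotation; they
  never re-run crossing analysis.
* The default model is a synthetic-data artifact for out-of-the-box use and
  sanity checks, not a substitute for training on curated families.
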