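---
title: "Three-taxon analysis of DNA supermatrices: methods and design"
author: "tritax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-taxon analysis of DNA supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritax)
library(ape)
```

## The method

Three-taxon analysis (3TA) recasts a character matrix as the collection of
its minimal relational claims.  A three-taxon statement (3TS) `ij|k` asserts
that taxa *i* and *j* are more closely related to each other than either is
to taxon *k*.  Given a DNA alignment and a polarity standard — an
*operational outgroup* sequence — every column is read as evidence: each
nucleotide state `s` that differs from the outgroup state and is shared by
two or more taxa generates, for every pair of `s`-bearing taxa and every
taxon scored with a different nucleotide, one statement.  The full matrix of
statements is the Williams–Siebert (WS) binary representation of the DNA
matrix: expanded, each statement is one binary character with `1` at *i* and
*j*, `0` at *k* and at an implicit all-plesiomorphic outgroup terminal, and
`?` everywhere else.  Every such character is parsimony-informative by
construction.

The statement matrix is analysed by ordinary uniform-weight parsimony.  On a
tree rooted at the operational outgroup a statement is *accommodated* — costs
one step — exactly when the most recent common ancestor of *i* and *j* is a
proper descendant of the most recent common ancestor of *i*, *j* and *k*;
otherwise it costs two.  Hence for `N` statements the tree length `L` lies in
`[N, 2N]`, and because every statement has minimum 1 and maximum 2 steps the
ensemble indices collapse to closed forms,

$$\mathrm{CI} = N/L, \qquad \mathrm{RI} = (2N - L)/N,$$

which the package computes without ever materializing the expanded binary
matrix (`tsEnsembleCiRi()`).  `tsLength()` evaluates the accommodation rule
directly; its equivalence with summed Fitch lengths over the expanded
columns is the central correctness property of the scorer and is
property-tested against an independent exhaustive-assignment oracle.

## Operational outgroup

The polarity standard is the 50% majority-rule consensus of a designated set
of outgroup taxa (`consensusSequence()`).  Frequencies are taken over
*applicable* symbols only — the four nucleotides; gaps, `?`, `N`, and
(by default) partial IUPAC ambiguities are excluded from the denominator,
with an `ambiguity = "fractional"` option that splits an ambiguity's weight
equally among its component nucleotides.  A column emits its modal state
when the mode is unique and reaches the threshold; ties and sub-threshold
modes yield `?`, and `?`-polarity columns contribute no statements.  This is
deliberately conservative: a tied consensus is treated as no polarity
information rather than as an ambiguity code.

## The zeros set

The wording "binary representation" leaves open which taxa are scored `0`
in a recoding.  The package implements both readings and defaults to
`zeros = "absence"`: the zeros are all scored taxa lacking the derived state,
including bearers of other derived states, which is the straightforward
presence/absence reading.  The alternative `zeros = "plesiomorphic"`
restricts the zeros to taxa carrying the outgroup state.  In recovery
simulations the two conventions performed indistinguishably, so the default
follows the simpler reading.

## Parsimony engine

Conventional DNA matrices are scored by Fitch parsimony generalized to
polytomies (Hartigan's bottom-up rule) in compiled code, with gaps and `?`
treated as missing (the full nucleotide set) and partial IUPAC codes as
their component sets.  Binary statement characters are "ordered" Wagner
characters, which for two states is step-identical to Fitch; the engine
scores them through the accommodation rule instead of expansion.

`mpSearch()` is a heuristic search: greedy random-addition starting trees
followed by steepest-descent branch swapping (`nni`, the default `spr`, or
`tbr` — SPR with rerooting of the pruned clade at each of its tips, i.e. a
limited-reconnection TBR).  Equally optimal distinct trees are pooled up to
a cap per replicate and deduplicated by topology.  For statement matrices
the operational outgroup leaf is always placed in the starting triple so
polarity is defined throughout the addition sequence.  Searches are
deterministic given `seed` and leave the caller's RNG state untouched.
Defaults (10 addition replicates, 10 trees per replicate, SPR) are
desk-scale choices; production analyses of the kind the method targets have
historically used on the order of a thousand addition replicates with full
TBR, and the parameters accept such values.  `exactSearch()` enumerates all
unrooted topologies (at most nine leaves) and is the oracle against which
the heuristic is tested.

`jackknifeSupport()` deletes a fixed fraction of characters per replicate —
alignment columns for DNA, expanded statement occurrences (honouring
multiplicities) for statement matrices — reruns the search, and reports the
percentage of replicates whose strict consensus contains each clade.  The
conventional deletion fraction for parsimony jackknifing, 37% (≈ 1/e), is
the default.

## Robinson–Foulds comparison and combination

`rfDistance()` counts the symmetric difference of bipartition sets (unrooted
mode) or rooted cluster sets; with `mode = "auto"` rooted clusters are used
when both trees are rooted.  `strictConsensus()`/`majorityConsensus()`
follow strict counting rules: a majority clade must occur in *more* than the
threshold fraction, ties excluded.

The RF *median* consensus — the tree minimizing the summed RF distance to a
profile of trees — is computed exactly at any size rather than by heuristic
search.  The total distance decomposes linearly over the candidate's
clusters: a cluster in more than half of the inputs lowers the sum, one in
fewer raises it, one in exactly half is neutral, and all majority clusters
are mutually compatible.  The optimum is therefore the majority-rule
consensus; because exactly-half clusters are score-neutral, ties are broken
toward resolution by greedily adding compatible half-frequency clusters in
deterministic order.  `rfMedian()` reports the score from an explicit
re-evaluation against the inputs, and the tests compare it with a
brute-force enumeration over all compatible cluster sets.

The RF *supertree* (`rfSupertree()`) minimizes the summed RF distance
between each input and the supertree restricted to that input's leaves.
Restriction makes the problem genuinely hard, so exactness is promised only
for small leaf unions: up to 7 union leaves every topology (polytomies
included) is enumerated by recursive leaf addition; beyond that a greedy
construction (largest input as backbone, score-minimizing insertion of the
remaining leaves ordered by occurrence frequency) is refined by leaf
reinsertion and edge-contraction moves.  Ties prefer the most resolved
candidate, then a canonical ordering, so output is deterministic.  When all
inputs share one leaf set the supertree problem *is* the median problem and
the exact median is returned.

## Synthetic data

The generator (`simConfig()`, `simulateTree()`, `evolveSequences()`)
emulates the structure of a multi-locus plastid supermatrix: about ten loci
of several hundred aligned columns, a few designated outgroup taxa, patchy
per-taxon locus coverage padded as `?` on concatenation, and occasional
short gap runs.  Specific choices, and why:

* **Tree prior.** A pure-birth ingroup tree rescaled to a crown depth of
  0.05 expected substitutions per site — the shallow divergence typical of
  plastid loci among congeners.  Successive speciations are separated by a
  minimum interval of 5% of the crown depth: unconditioned pure-birth trees
  contain internal edges so short that fewer than one substitution is
  expected across an entire desk-scale matrix, and no method can recover
  such edges; the generator deliberately excludes them so that recovery
  failures reflect the method, not unresolvable trees.  A consequence of
  rescaling is that the birth rate influences only the relative node
  heights, not the absolute divergence.
* **Outgroups.** Outgroup taxa attach as a basal ladder just below the
  ingroup root, at 0.6–1.0× the crown depth.  Strongly divergent outgroups
  corrupt the majority-rule polarity on a small fraction of columns, and a
  single mispolarized column spawns on the order of $n_1^2 n_0$ spurious
  statements; the generator therefore emulates outgroups chosen close
  enough to polarize reliably, which is precisely what the consensus-of-
  several-outgroups device is for.
* **Substitution model.** Jukes–Cantor only.  Richer models belong to the
  likelihood analyses that are outside this package's scope, and parsimony
  scoring is agnostic to the exchangeability structure; JC suffices to
  exercise every pipeline stage and admits a closed-form p-distance check.
* **Missingness.** Per-taxon, per-locus dropout at 0.15 (each taxon keeps
  at least one locus), mirroring the patchy locus tables of
  database-assembled supermatrices; gap runs of mean length ~4 open at rate
  0.01 per site.

What passing the recovery tests does **not** show about real data: real
supermatrices contain alignment error, rate heterogeneity, non-stationary
composition, and genuinely unresolvable short internodes, none of which the
generator produces.  The recovery results certify the pipeline's internal
consistency under its own assumptions, not the statistical behaviour of 3TA
on empirical matrices.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout the partition map.
* `-` and `?` are distinct at I/O but both missing to the parsimony engine;
  there is no fifth-state option.
* A consensus threshold must lie in (0, 1]; statement encoding skips
  columns whose outgroup symbol is not a plain nucleotide.
* `ensembleCiRi()` returns `NA` with a warning when every character is
  constant or uninformative (zero denominator).
* Search and jackknife validate their parameters and are seed-deterministic;
  equally optimal trees are deduplicated by canonical split sets.
* An alignment with fewer than four taxa cannot be searched; exhaustive
  enumeration refuses more than nine leaves and points to `mpSearch()`.

## Worked example

```{r example}
cfg <- simConfig(nTaxa = 14, nLoci = 4, locusLengths = 300, nOutgroup = 3,
                 seed = 101)
tree <- simulateTree(cfg)
aln <- evolveSequences(tree, cfg)
aln

res <- runGlobal3ta(aln, outgroupTaxa = c("og1", "og2", "og3"),
                    searchParams = list(nAdditionReplicates = 2), seed = 1)
str(res$manifest[c("nStatements", "length", "violations", "ci", "ri")])

## the closed-form identity RI = (2N - L)/N always holds for 3TS searches
with(res$manifest, all.equal(ri, (2 * nStatements - length) / nStatements))
```

## Problem sizes used in the tests

Unit and acceptance tests run at deliberately small scales chosen so each
oracle stays exhaustive: Fitch against brute-force assignment enumeration on
5–8-leaf trees; encoder count laws on 4–10-taxon toys; heuristic-vs-exact
searches on 7-taxon matrices (945 topologies; 10,395 with the statement
outgroup); median and supertree oracles on 6-leaf profiles where all
compatible cluster sets can be enumerated; and recovery on twenty simulated
20-taxon, 4,000-column supermatrices.  These sizes are the package's own
validation design: every stochastic check is seeded and reproducible.

## Known limitations

* The supertree search is heuristic beyond 7 union leaves; scores are
  upper bounds there.
* Uniform statement weighting only; fractional weighting schemes are out of
  scope.
* 3TA itself is known to be sensitive to homoplasy concentrated near the
  polarity standard: mispolarized columns inject quadratically many false
  statements.  The operational-outgroup consensus mitigates but does not
  remove this; with distant, sparse outgroups expect the statement optimum
  to drift from the conventional-parsimony topology.
* The NEXUS dialect is minimal (DATA/TAXA/CHARACTERS/TREES, interleaving);
  SETS and ASSUMPTIONS blocks are ignored with a warning.
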