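---
title: "Phylogenetics of binary AFLP matrices: models, tests and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetics of binary AFLP matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflphylo)
```

# The problem

AFLP fingerprinting scores thousands of anonymous, dominant genomic
fragments as present/absent bands per individual. For recent, rapid
radiations — the motivating system is the *Xenotilapia* lineage of Lake
Tanganyika cichlids, where maternal-only and biparental mouthbrooding
co-occur among close relatives — such genome-wide binary characters carry
more phylogenetic signal than any single locus. `aflphylo` implements the
full analysis chain for such matrices: fragment-sharing distances and
neighbor joining, Fitch parsimony with constrained heuristic search,
bootstrap bipartition support, a tree-length skewness randomization, the
Shimodaira–Hasegawa (SH) topology test, a homoplasy excess screen for
hybridization, and ancestral reconstruction of a discrete life-history
trait by unordered parsimony and by the one-parameter Markov (Mk1) model.
A seeded synthetic generator supplies matrices with known ground truth so
that every stage is testable without raw data.

# Models and procedures

## Nei–Li distance and neighbor joining

For two band profiles the similarity is the fragment-sharing coefficient
$F = 2 n_{xy} / (n_x + n_y)$, counting presences only: shared *absence* of
a band is not evidence of common ancestry for dominant markers. The
default distance is the bounded form $D = 1 - F$, which matches the scale
of a drawn phylogram; the divergence-corrected $-\ln F$ is available via
`variant = "log"`. Missing cells are deleted pairwise, and a profile left
with zero bands is an error rather than a silent 0 or 1.

Neighbor joining follows the standard $Q$-criterion with rate-corrected
pendant lengths. Two numerical choices are pinned down for
reproducibility: ties in $Q$ are broken toward the lexicographically
smallest pair of cluster labels (a cluster is labelled by its smallest
leaf), and a negative pendant length is clamped to zero with the deficit
moved to its sister so the pair's sum is preserved (at the terminal
three-way join negatives are simply clamped). On additive matrices the
implementation reproduces the generating tree and its branch lengths to
$10^{-9}$.

## Parsimony scoring and search

Per-locus parsimony steps are computed by a unit-cost two-state Sankoff
dynamic program (compiled kernel), which is exact on multifurcations and
treats missing cells as fully ambiguous; the total is invariant to
rooting. The heuristic search uses random-addition starting trees followed
by nearest-neighbor-interchange hill climbing, optionally under a
topological constraint (used for the "each care state is monophyletic"
hypotheses). NNI rather than the more aggressive rearrangements is a
deliberate complexity control: the search is validated on problem sizes
where NNI provably suffices (exhaustive checks at $n = 4$, perfect
recovery on clean simulated matrices), and equally best topologies are
retained up to a configurable cap because an engine must tolerate ties
even when a single tree is the expected outcome.

## Bootstrap support and the g1 randomization

Bootstrap resamples loci (columns) with replacement, rebuilds the tree per
replicate, and maps split frequencies onto the full-data reference tree;
the mean support is averaged over the reference tree's internal nodes,
matching how a mean bootstrap value is read off a published figure.
Hierarchical structure is tested by scoring uniformly random labeled
topologies (sequential addition with a uniformly chosen attachment edge)
and taking the moment skewness $g_1 = m_3 / m_2^{3/2}$ (divisor $n$) of
the length distribution: strongly negative skewness means few trees are
nearly as short as the best ones, i.e. tree-like signal. The package
reports $g_1$ itself; significance against published critical-value tables
is left to the user because those tables are external to the data.

## SH test

Topologies are compared on per-locus score vectors with RELL resampling:
loci are resampled, per-topology totals are centered by their own
resample mean, and the p-value of topology $k$ is the fraction of
resamples in which the centered best-versus-$k$ difference reaches the
observed difference; the best topology has difference 0 and $p = 1$ by
construction. The default backend scores loci by parsimony steps, staying
inside the maximum-parsimony framework; a likelihood backend (symmetric
two-state model, one rate optimized per topology on the tree's own branch
lengths) is provided as the statistically orthodox alternative. Full
per-topology branch-length optimization is intentionally out of scope.

## Homoplasy excess screen

A hybrid's mosaic genome destabilizes bootstrap support for clades
ancestral to its parents; removing it makes that support jump. The screen
bootstraps the full matrix, then re-bootstraps with each taxon removed in
turn, and records, for every baseline reference split that stays
non-trivial on the reduced taxon set,
$\Delta = \mathrm{support}_{-t} - \mathrm{support}_{\mathrm{full}}$.
A (taxon, split) pair is flagged when its $\Delta$ is a boxplot-rule
outlier ($> Q_3 + 1.5\,\mathrm{IQR}$) across removals *and* rises by at
least 10 points (configurable). The published applications of this test
screen qualitatively for support increases; the explicit rule makes the
screen testable. Fewer than 100 replicates triggers a recorded stability
warning. Note one deliberate subtlety: the full-analysis support is taken
as observed (with the candidate taxon still in the analysis), because
computing it on restricted replicate trees would remove precisely the
destabilization the screen is looking for.

## Ancestral states

`collapseWeakNodes()` contracts internal edges whose support falls below a
threshold (default 50%), turning topological uncertainty into polytomies.
`fitchMPR()` then enumerates every binary resolution of each polytomy
(degree cap 8, i.e. at most 10,395 resolutions per node), computes
most-parsimonious reconstructions with unordered states, and reports
per-direction transition counts. Two summaries are given. The headline
`min`/`max` is the range over resolutions of the per-resolution
delayed-transformation (DELTRAN) count: ambiguity is resolved toward
parallel changes near the tips, which is the convention under which one
counts *independent origins* of a state on a traced reconstruction. The
`mprMin`/`mprMax` columns give the extremes over all most-parsimonious
assignments, which can be wider because equally parsimonious histories may
replace several parallel gains with one deep gain plus reversals; on the
packaged topology the all-MPR range for maternal-to-biparental is 1–5
while the origins count is 3–5. Both endpoints of the headline range come
with explicit witnesses (a resolution plus a full node-state assignment
that is itself most parsimonious).

The Mk1 model is the symmetric $k$-state chain,
$P(\text{stay}, t) = 1/k + (1 - 1/k) e^{-k\alpha t/(k-1)}$, with a uniform
root prior. The single rate is fitted by bounded maximization on the log
scale; marginal ancestral probabilities come from the standard down/up
pass, and nodes whose best marginal falls below 0.75 (configurable) are
reported as equivocal — on saturated traits essentially every node is,
reproducing the situation where likelihood declines to resolve what
parsimony narrates. When the input phylogram carries Nei–Li branch
lengths those are used; trees without lengths get unit lengths with a
warning.

Species-level reconstruction uses `collapseToSpecies()`, which verifies
that each multi-individual species is monophyletic (erroring with the
offenders named) and keeps one representative tip per species.

## Published-topology reconstruction

`xenotilapiaSpeciesTree()` encodes the species topology described in the
source study's results: the rooted outgroup ladder
((nasuta, ventralis), (furcifer, ((macrops, stappersii), ingroup))); the
(leptura, tenuidentata) clade sister to the remaining lineage; the
(melanogenys, ochrogenys) pair sister to the
bathyphila/boulengeri/sima/flavipinnis assemblage whose internal
arrangement is a polytomy; and the unresolved
ornatipinnis/spiloptera/papilio lineage as the assemblage's sister. Two
reading notes: the text's outgroup sentences admit an alternative
arrangement of *Cyathopharynx* relative to the *Ophthalmotilapia* cherry,
which cannot change the care-state reconstruction because all outgroups
are maternal; and the pair-sister reading of "clusters with a large
assemblage consisting of ..." is required — putting the pair *inside* a
five-way polytomy would let the assemblage's maternal members coalesce and
alter the transition counts. With Table 1 care states this yields a
maternal ancestral state and 3–5 maternal-to-biparental origins:

```{r published}
asr <- fitchMPR(xenotilapiaSpeciesTree(), xenotilapiaSpeciesCareStates(),
                direction = c("Maternal Mouthbrooder",
                              "Biparental Mouthbrooder"))
asr@transitions
```

# The synthetic generator

`simulationConfig()` fixes the study conditions the generator emulates: 16
species with per-species sampling (3, 1, 1, 1, 3, 3, 1, 1, 1, 2, 4, 3, 2,
2, 4, 5) totalling 37 individuals, 3,588 scored characters, and roughly
two thirds of loci polymorphic (0.69, the published 2,478/3,588). The
species tree is pure-birth, rescaled to unit depth; conspecific
individuals attach as shallow cherries/polytomies at 2% of tree depth (the
study gives no within-species divergence, so this default is a flagged
guess that reproduces species-monophyletic clustering). Each locus evolves
as an asymmetric band gain/loss chain — loss twice as fast as gain, the
dominant-marker expectation — whose gain rate is calibrated *exactly* (by
pruning, `expectedPolymorphicFraction()`) so the expected **observed**
polymorphic fraction matches the target; the calibration integrates the
scoring-noise flip probability (default 2% per cell, in the range reported
for AFLP scoring error) into the tip emissions, since empirical
polymorphism counts are post-scoring. Fragment-size homoplasy is modeled
statistically as random bin merging (logical OR of randomly chosen locus
pairs, default probability 1%) rather than by simulating electrophoresis.
Hybrids are injected as per-locus mosaics of two parents.

What the generator deliberately does not emulate: coalescent
gene-tree/species-tree discordance, primer bias, non-independence among
fragments co-migrating from the same region, and any peak-calling
artifacts beyond the flip-noise model. Tests passing on these synthetics
therefore validate the *algorithms* under the stated generating model, not
the field behavior of AFLP data.

# Numerical and design choices

- **Seeds.** Every stochastic function takes a seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from one root
  seed (`deriveSeed()`) so stages can be rerun in isolation and whole runs
  are byte-reproducible.
- **Tie-breaks.** NJ joins the lexicographically smallest tied pair;
  DELTRAN resolves a root tie toward the first alphabet state; the
  heuristic search takes the first improving NNI neighbor.
- **Degenerate inputs.** Zero-band profiles, zero-variance length
  distributions, outgroups that are not monophyletic, leaves without trait
  states, and polytomies beyond the enumeration cap are all hard errors
  with the offender named, never silent values.
- **Tree container.** Trees are ape `phylo` objects throughout rather than
  a bespoke class, for interoperability with the ecosystem's tooling; the
  package adds split canonicalization, support-threshold contraction and
  outgroup rooting with even stem splitting on top.
- **Problem sizes.** The validation suite runs at desk scale, chosen once:
  g1 on 18-taxon/300-locus matrices with 10,000 random topologies; SH on
  10-species/500-locus noise-free matrices (5 seeds); Mk1 rate recovery on
  a fixed 16-leaf pure-birth tree with 500 characters over 20 seeds.
  The homoplasy screen's two properties are demonstrated under their own
  conditions (see below): specificity on strongly tree-like
  10-species/2,400-locus matrices at 600 replicates, sensitivity on
  14-species/2,000-locus matrices with an injected 50/50 mosaic of two
  distant cherry tips at 500 replicates. Tree simulations for these checks
  are conditioned on a minimum internal edge length (0.04–0.05 of tree
  depth), mirroring data sets whose nodes are almost all resolved above
  50%. Replicate counts are configuration, with the reference analysis's
  heavier values (10,000 bootstrap replicates, 1,000,000 random trees)
  reachable by setting them.

# Known limitations

- The homoplasy excess screen inherits the known behavior of support-based
  outlier rules, in both directions. On matrices with weakly supported
  short internodes, taxon removal can shift support for reasons other than
  reticulation (rogue-taxon effects), producing structural false
  positives. Conversely, a 50/50 mosaic hybrid under neighbor joining is
  often placed *stably* at an intermediate edge, destabilizing nothing —
  in that case no removal-based screen can see it, because the signature
  the test relies on (bistable placement depressing bootstrap support)
  never arises. Simulations in the test suite demonstrate both regimes;
  the screen's specificity and sensitivity are therefore validated under
  separate, documented conditions. Flags call for inspection, not a
  verdict of hybridization.
- The SH likelihood backend optimizes a single rate per topology but not
  branch lengths; rankings agree with the parsimony backend on clean data,
  p-values may differ on borderline cases.
- TBR rearrangements and exact branch-and-bound search are not provided;
  for matrices much beyond a few dozen taxa the NNI search should be
  treated as a local optimizer.
- Dominant-marker genotype inference (allele frequencies from band
  presence) is intentionally absent: bands are treated as phylogenetic
  characters only.
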