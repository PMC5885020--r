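---
title: "Delineating and dissecting phage groups with phagani: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and dissecting phage groups with phagani: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Lytic dsDNA phages of enterobacteria fall into tight clusters of highly
similar genomes separated by wide gaps in average nucleotide identity (ANI).
If such clusters are natural evolutionary units, their members should
exchange core genes with each other (homologous recombination) while genes
should cross cluster boundaries only rarely. `phagani` implements the full
chain of analyses needed to test this on a genome sample:

1. fragment-based ANI (ANIb) with alignment coverage for all genome pairs;
2. group delineation at an ANI discontinuity, with "satellite" lineages at
   intermediate identity and high-ANI/low-coverage pairs flagged as
   candidate horizontal transfers;
3. ortholog families and core genomes per group;
4. recombination inside groups: the pairwise homoplasy index (PHI) per core
   gene and a SNP-density clonal-frame scan over the concatenated core;
5. congruence among per-gene distance matrices (CADM / Mantel), a
   progressive procedure that adds satellites and a neighbouring group, and
   frequency-weighted consensus splits from gene trees.

Because real genome collections are external downloads, the package ships a
synthetic phage-genome evolution simulator with a complete truth log; every
stage is validated against that truth.

## ANIb and coverage

A query genome is tiled into non-overlapping fragments (default 500 bp; a
trailing fragment is kept iff at least half the fragment length — behaviour
of published ANIb tools is undocumented here, so it is config-exposed). Each
fragment is locally aligned to the target on both strands. Scoring is
blastn-like: match +1, mismatch −2, a gap of length L costs 5 + 2L, all
config-exposed. A hit qualifies when identity ≥ 30 % over ≥ 70 % of the
fragment, the published ANIb rule; ANI is the unweighted mean identity over
qualifying hits (fragments have uniform length, so length weighting would
change nothing material) and coverage is the fraction of the query inside
qualifying fragments.

Two alignment routes share the scoring: exact affine-gap Smith–Waterman with
traceback for targets up to 10 kb, and a seeded route (exact 11-mer seeds,
per-diagonal best-segment scan) for genome-scale targets. The seeded route
is gapless; on indel-free within-group comparisons it is effectively exact,
and the package's correctness contract is score equality with exhaustive
Smith–Waterman on small instances, which the test suite checks against an
independent implementation (Biostrings).

With +1/−2 scoring, a full-length fragment alignment has positive expected
score up to one mismatch in three: the aligner stops reporting qualifying
full-length hits near 67 % identity, which matches the empirical ~63 % floor
of ANIb reported for phage genome comparisons. A consequence worth knowing:
at ~25 % nucleotide divergence, fully homologous genomes still align
end-to-end, so between-group coverage in the synthetic world is near 1
unless gene content differs. Genuinely non-alignable backgrounds require
roughly 40 % divergence; the default study design places its distant donor
group there so that an implanted ~10 kb transfer reproduces the
high-ANI/low-coverage signature of a horizontal transfer event.

Local alignment trims mismatching fragment ends, which biases per-fragment
identity upward by roughly 0.1–0.3 percentage points at 5–10 % divergence.
This is inherent to ANIb (blast does the same) and stays inside the ±0.5 pp
recovery tolerance the tests enforce.

## Groups, satellites, transfer candidates

Groups are connected components (size ≥ 2) of the graph with an edge where
symmetrized ANI ≥ 92 % — the discontinuity boundary — and coverage ≥ 0.5 in
both directions. The coverage condition prevents a single long transferred
tract from fusing two groups; 0.5 mirrors the dot-plot convention of
requiring similarity over half the genome. ANI is directional; the
symmetrized value is the arithmetic mean of the two directions. Whether the
original delineation used one direction, a mean, or a coverage condition is
not documented, so all three choices are config-exposed.

A genome is a satellite of a group when its best symmetrized ANI to the
group lies in [85, 92): close enough to be clearly related, too divergent
for membership. The relation is per group, so one genome can be a satellite
of two groups. Transfer candidates are ordered pairs with ANI ≥ 92 % but
coverage ≤ 0.2 — near-identical DNA confined to a small genome fraction.

## Pangenomes

Proteins are compared by local alignment under BLOSUM62 (gap open 10,
extension 1 per residue); two genes join the same family when amino-acid
identity ≥ 50 % and the alignment covers ≥ 50 % of both proteins (the
published rule leaves open which protein must be covered; "both" is the
default and the alternatives are config-exposed). Families are connected
components (single linkage). Chaining is a documented risk of single
linkage; at the synthetic scale used here families are well separated and
the tests verify exact recovery. An amino-acid 5-mer prefilter limits the
alignment work; a shared 5-mer is essentially guaranteed for pairs near the
50 % identity threshold and rare between unrelated proteins.

The core genome is the set of families present in every genome; single-copy
core families (exactly one member per genome) provide the per-gene
alignments. Since synthetic evolution is indel-free, stacking the member
genes of a family yields an alignment directly; no MSA step is needed, which
is why the simulator avoids indels by default (an indel-free world makes
positional homology exact, at the cost of realism — see Limitations).

## Phylogenetic primitives

TN93 distances distinguish the two transition types from transversions with
unequal base frequencies; frequencies per pair are the mean of the two
sequences' frequencies (a common convention; the tests verify agreement
with ape's implementation to 1e−9 and the Jukes–Cantor collapse in the
symmetric limit). Gaps and N are handled by pairwise deletion by default
(complete deletion is config-exposed); pairs whose log argument is
non-positive are flagged saturated/infinite, and genes containing such
pairs are dropped from congruence analyses with a warning.

Trees are neighbour-joining (ape) with taxa sorted lexicographically first,
so results are independent of input order; negative branch lengths are
clamped to zero with the deficit moved to an adjacent branch.

Fitch parsimony assigns variant columns to branches. The tree is traversed
from its stored basal multifurcation rather than from a midpoint root: a
midpoint root splits the longest branch in two, and singleton substitutions
belonging to exactly that branch (the signature of a divergent implanted
tract) then end up ambiguously assigned. At the basal node the root state is
chosen by the Hartigan max-count rule, which keeps the assignment's total
change count equal to the parsimony score (verified against phangorn on
enumerated small trees); remaining ambiguity is resolved by retaining the
parent state, pushing changes rootward.

## PHI — the pairwise homoplasy index

For informative sites (≥ 2 states each in ≥ 2 taxa), the refined
incompatibility of a site pair is the cyclomatic number E − V + C of their
partition-intersection graph: the minimum number of extra mutations, beyond
each site's own parsimony bound, needed to place both sites on one tree
(verified against exhaustive parsimony over all small topologies). PHI is
the mean refined incompatibility over site pairs at most w = 100 alignment
positions apart (window in alignment positions, as in PhiPack; config
exposed). Under recombination, incompatibility grows with genomic distance,
so a low near-pair mean signals recombination. The null permutes the
positions of the informative sites, keeping their state vectors; p =
(1 + #{phi_perm ≤ phi_obs}) / (n_perm + 1). The permutation null is exact
and seed-reproducible; since state vectors are fixed, all pair scores are
precomputed once and permutations only re-index them, so 1000 permutations
cost milliseconds.

At low diversity the test is conservative — few informative sites mean a
discrete statistic and tied permutation values, inflating p. This matches
the known behaviour of the test and the original caveat that it loses power
when diversity is low. The suite therefore checks type-I control at the
5 %-diversity study conditions (rejection rate within [0.03, 0.07]) and
p-value uniformity at 10 % diversity where homoplasy is dense; genes with
fewer than two informative sites are reported untestable rather than
significant.

## Clonal-frame scan

A deliberately simplified SNP-density procedure in the spirit of Gubbins,
replacing maximum likelihood with NJ + Fitch and the likelihood window test
with a binomial scan: per branch, candidate windows are maximal runs of ≥ 3
branch SNPs with inter-SNP gaps ≤ 100 columns; a run of k SNPs spanning l
columns is recombinant when

n_branch_snps × P(Binom(l, background density) ≥ k − 1) < α / n_branches,

i.e. a scan-style Bonferroni over the possible anchoring SNPs and over the
branches scanned. A naive per-candidate Bonferroni is badly anticonservative
here (the number of *potential* windows, not of observed candidates, drives
the multiplicity), which direct null simulation confirms; with the
correction above, ≥ 90 % of clonal replicates yield zero tracts. Detected
tracts are trimmed to their outermost SNPs, masked (set to missing) in the
descendant taxa, and the scan iterates (≤ 5 rounds) so masked tracts stop
distorting the tree and densities. The clonal frame of a branch is
1 − recombinant columns / alignment columns, reported per branch with the
min–max range across branches, the reporting style used for group tables.
Which aggregation the original analysis printed is ambiguous; per-branch
min–max is documented here. Terminal-branch tracts are attributable to a
single genome; with heavy star-like intragroup recombination, conversions
between close relatives carry few SNPs and are undetectable in principle,
so tract recovery is validated on an implanted divergent tract (2 kb at
10 % divergence: recovered with ≥ 90 % reciprocal overlap and a branch
clonal-frame estimate within ±0.02 of truth).

## Congruence

Per-gene TN93 matrices over the shared taxa feed the CADM test: Kendall's W
over rank-transformed unfolded matrices with a permutation null (the ape
implementation, the same route the original analysis used; W = 1 means all
gene trees agree). All matrices are permuted (no reference matrix); the
reference variant is available in ape. The a-posteriori battery computes
Spearman Mantel correlations for every gene pair with a one-tailed
permutation p; the package's own Mantel (rank re-indexing per permutation)
replaces a generic implementation purely for speed and is tested against
vegan's statistic. No multiple-testing correction is applied to the battery
by default — the reported quantity is the raw significant fraction.

The progressive procedure starts from a group, then adds its satellites,
then the most similar other group; at each step the shared single-copy
families are re-derived, matrices rebuilt, and CADM re-run. On the default
synthetic design, W and the significant-Mantel fraction rise strictly along
the trajectory, while pooling the NJ gene trees shows one full-weight split
separating the groups and only partial-weight splits inside them —
recombination scrambles intragroup gene trees but gene flow does not cross
the boundary.

Consensus splits pool the nontrivial bipartitions of all gene trees; a
split's weight is its occurrence frequency (each tree counts once), and
splits under `min_freq = 0.1` are dropped (the original network threshold
is unknown; config-exposed). Export is a SplitsTree-compatible NEXUS splits
block; layout/rendering is out of scope.

## The simulator

`sim_config()`/`group_design()` describe an ancestral genome (default 50 kb,
60 genes of 300–3000 bp placed on both strands with start/stop codons and
no internal stops) and a set of groups. Divergence parameters are expected
substitutions per site on an HKY clock (κ = 2 by default so TN93 estimation
has something non-trivial to recover; base frequencies follow the
configured GC). Members radiate from their group ancestor on a star with
multiplicative branch jitter in [0.75, 1.25], so without recombination all
gene trees estimate the same star and differ only by noise. Satellites
branch at 0.10–0.14 expected substitutions/site — inside the intermediate
9–15 % band, with the ends avoided so that realized ANI stays strictly
inside [85, 92) after the slight upward bias of local alignment.
Recombination is applied after substitution as copy-paste of homologous
donor tracts (geometric lengths, uniform donors, random global event
order); intergroup transfers use a fixed tract length (default ~10 kb,
mirroring a single observed long-transfer event) so the coverage signature
is reproducible. Group-specific gene content is modelled as whole-gene
deletions in a group's ancestor; realized pairwise divergence is recorded
by direct site counting over shared homologous positions, and every event
is logged with recipient, donor, coordinates and type.

The default study design (three groups of 8/6/5 members at 4–5 % within,
two satellites, stems placing neighbouring groups ~25 % and the donor group
~40 % apart, gene conversion in every group, 3 genes deleted in group B and
a rare 10 kb C→A transfer) is the sampled-population stand-in used by the
acceptance checks.

What the simulator does *not* emulate: insertions/deletions within genes
(an optional small-indel mode exists but is excluded from validation, since
downstream alignments assume positional homology), gene duplication, mobile
elements, codon-level selection, and realistic modular mosaicism. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not performance on real phage collections; with real
data, a proper MSA step (e.g. mafft) must replace the stacking of
equal-length genes.

## Numerical choices and problem sizes

* Permutation counts default to 999 (CADM), 1000 (PHI), 199 (Mantel
  battery); the pipeline uses 499/499/199 and the tests 99–499. These are
  resolution choices, not statistical tuning: all tests fix seeds and
  derive per-stage seeds from one root seed, so any stage can be re-run in
  isolation and full pipeline reruns are byte-identical.
* The test suite and the acceptance script run the full default design
  (21 genomes × 50 kb, all stages, ≈ 6 minutes) once, plus a reduced
  9-genome/12 kb design for determinism checks, PHI calibration at
  200 × 1 kb replicates, and the clonal-frame null at 50 × 30 kb
  replicates. These sizes were chosen as the smallest at which the binomial
  error bands in the acceptance criteria are meaningful.
* Groups with fewer than 4 members skip PHI/CADM (the tests are untestable
  there, and group tables follow the "more populous groups" convention);
  the threshold is config-exposed.
* PHI significance for the per-group gene count uses raw p < 0.05 (no
  multiple-testing correction), matching how such counts are convention-
  ally reported; Benjamini–Hochberg is a one-liner away via `p.adjust` on
  the per-gene table.

## Known limitations

* The seeded aligner reports gapless fragment hits; with real (indel-rich)
  genomes its identities would be slight underestimates near gaps. The
  exact route is available up to 10 kb targets and the fragment length
  keeps DP costs bounded if `exact_max` is raised.
* Single-linkage families can chain through promiscuous domains on real
  proteins.
* The clonal-frame scan detects only SNP-dense tracts: conversion between
  very close relatives is invisible to any SNP-density method, so per-group
  tract recall on heavily recombining simulations is low even though the
  implant benchmark is sharp; the PHI test carries the per-gene burden
  there.
* CADM's global p only rejects "total incongruence"; a significant p with
  small W (the typical within-group outcome) means *some* matrices agree,
  not that histories are clonal.
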