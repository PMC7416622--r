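---
title: "Inferring, dating and placing whole-genome duplications"
author: "wgdtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring, dating and placing whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

# The problem

An ancient whole-genome duplication (WGD, paleopolyploidy) leaves three
complementary signatures in a modern genome:

1. an excess of duplicated gene pairs of similar age, visible as a peak in
   the distribution of synonymous divergence (Ks) across the paranome;
2. co-linear (syntenic) segments — runs of duplicated genes in conserved
   order — whose stacking depth reflects the duplication multiplicity
   (depth 2 after one round, depth 4 after two);
3. gene-tree topologies in which duplicate pairs of several descendant
   species coalesce to a single duplication node, which can be placed on a
   branch of the species phylogeny.

`wgdtrace` implements all three lines of evidence as a single tested
pipeline, together with a genome-evolution simulator that produces datasets
with *known* WGD age, branch, retention and anchor pairs, so every stage can
be validated end to end against ground truth.

# Synonymous divergence (Ks)

Pairwise Ks and Ka are estimated with the Nei–Gojobori (1986) counting
method. Synonymous/nonsynonymous *sites* are counted per codon (each of the
nine single-base changes contributes 1/3 of a site; changes into stop codons
count as nonsynonymous). *Differences* between a codon pair are averaged over
all shortest mutational pathways (1, 2 or 6 orderings); pathways through
stop codons are excluded, and a codon pair whose pathways are all blocked is
skipped entirely. Proportions are corrected for multiple hits with the
Jukes–Cantor transform $K = -\tfrac34 \ln(1 - \tfrac43 p)$; a non-positive
log argument marks the estimate as saturated (reported `Inf`, flagged).

This is a deliberate design choice over maximum-likelihood codon models
(e.g. the Goldman–Yang model): NG86 is deterministic, fast, and exactly
checkable against an independent enumeration oracle, which the test suite
exploits over all 61 × 61 codon pairs. The cost is a known mild
*underestimate* of divergence at high Ks; for locating peaks at Ks ≲ 2 this
bias is immaterial, and the subfamily/anchor cutoff at Ks = 5 removes the
regime where it matters. Real-data use assumes pre-aligned codon sequences
(the simulator evolves sequences without indels, so alignment is the
identity there).

# The node-weighted paranome age distribution

A family of $n$ genes contributes $n(n-1)/2$ pairwise Ks values but only
$n-1$ duplication events, so raw pair counts over-weight large families.
The correction used here:

* families are connected components of the within-genome similarity graph
  at E-value ≤ 1e−10 (a deterministic stand-in for Markov clustering — the
  weighting, which is the method's substance, is independent of the
  clustering backend);
* families are split into subfamilies whose pairwise Ks never exceeds 5,
  read as *complete linkage* (the stricter all-pairs interpretation;
  single linkage is available via an argument), with saturated pairs
  treated as exceeding the bound;
* each subfamily gets an average-linkage (UPGMA) tree on its Ks matrix.
  The tree's only role is to group pairs by duplication node; on the
  approximately ultrametric within-genome data UPGMA is adequate and fully
  deterministic (members are sorted before clustering so ties always break
  the same way). An NJ-based alternative is provided;
* every internal node is a duplication node; a node with child clades $L$
  and $R$ contributes all $m = |L||R|$ cross-clade pairs, each with weight
  $1/m$, so each event carries total mass exactly 1 and a subfamily of $n$
  members carries mass $n-1$. The mass identities are asserted exactly in
  the tests, and the distribution is invariant to duplicated input rows.

Peaks are located by weighted Gaussian KDE (Silverman's rule on the
weighted sample, with the effective sample size $(\sum w)^2/\sum w^2$;
evaluation grid step 0.01 over the data range), and dated with a percentile
bootstrap over resampled entries (weights travel with their entries).
Windows such as the 0.6–1.4 interval used to select pairs under a WGD peak
are closed on both ends.

```{r ks-demo}
m <- matrix(c(0, 0.2, 1.0, 0.2, 0, 1.2, 1.0, 1.2, 0), 3, 3,
            dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
weightNodeKs(subfamilyTree(m), m, "demo")
```

# Co-linear segments, depth and multiplicity patterns

Homology edges are first cleaned with a c-score filter: an edge's bit-score
divided by the larger of the two genes' best bit-scores must reach 0.5.
Match points (gene pairs projected onto gene-order ranks) are then chained
per scaffold pair with a sparse dynamic program: a chain may step from one
match to the next if both rank gaps are positive and at most 25, with a
consistent direction (forward or inverted); the score is +10 per anchor and
−1 per skipped rank. Maximal-scoring chains are extracted greedily (each
match belongs to at most one segment) until the best remaining chain falls
below the anchor floor. The floor is a preset — 5 for fragmented assemblies
and self-comparisons, 10–15 for chromosome-level dot plots — and raising it
can only remove segments, never add them (asserted as a property test).
These chaining parameters are package defaults chosen to recover segments
of ≥5 anchors through moderate fractionation; they are exposed as arguments.
In a self-comparison the identity diagonal is masked and each unordered
segment pair is reported once.

Overlapping segment intervals (closed rank intervals; a shared rank counts
as overlap, bookended intervals do not merge) union into broader regions.
Two depth conventions are provided:

* `duplicationDepth(..., includeSelf = FALSE)` — the raw count of segment
  intervals covering a rank (recomputable by brute force, used by the
  oracle tests);
* `includeSelf = TRUE` — the dot-plot margin convention, which counts the
  reference region itself as one of the stacked co-linear segments. A
  region retained in four copies is covered by segments to its three
  sister copies and reported at depth 4, directly reflecting copy
  multiplicity after two WGD rounds. This is the convention used in the
  validation checks, because copy number is the quantity the profile is
  meant to display.

Recursive profile-based detection of highly degenerated segments is *not*
implemented: depth beyond pairwise segments arises only from overlapping
pairwise segments. This is a documented limitation; with heavy
fractionation the profile approach can recover older duplications that
pairwise chaining misses.

Cross-genome multiplicity is summarised per merged region: the number of
distinct partner-genome regions aligned to it, yielding patterns such as
4:1 (two rounds in one lineage, none in the other) or 2:2 (a shared WGD).

# Orthologs and relative timing

Orthologs are reciprocal best hits under the cross-species cutoff
E ≤ 1e−5 applied in both directions; the best hit maximises bit-score with
ties broken by lower E-value, then lexicographically smallest partner id so
results are deterministic. The ortholog Ks distribution (unit weights,
saturated pairs excluded with a count) dates the speciation; comparing it
with the anchor-pair distribution orders WGD against speciation. The
decision rule — disjoint 90% bootstrap peak CIs decide the order,
overlapping CIs return "indistinguishable" — is this package's
formalisation of the usual visual peak comparison and is labelled as such
in the output. It assumes comparable substitution rates in the lineages
compared; no rate correction is applied.

# Placing duplications on the species tree

Families used for placement must carry at least one anchor pair with
Ks ≤ 5, at most 300 genes, and at least one outgroup gene; families bridged
by an anchor are merged first (the anchor is evidence the clustering split
one family). Gene trees are neighbour joining on Poisson-corrected
amino-acid distances $-\ln(1-p)$ (saturated distances capped at the largest
finite value + 1), with support from resampling codon columns: each
replicate re-estimates distances and the NJ topology, and a branch's
support is the percentage of replicates containing its bipartition.
Supports are attached to branches via canonical bipartition keys, so they
survive re-rooting unchanged. NJ replaces ML tree search deliberately: the
placement logic needs coalescence order, not branch-length optimality, and
NJ is consistent on additive distances and orders of magnitude faster; a
rooted tree with externally computed supports can be supplied instead.

Trees are rooted on the outgroup when its genes form a clade on some
rooting, else by midpoint (ties broken deterministically). Each internal
node is LCA-mapped to the species tree. A node whose child clades share a
species is a *duplication* node; a paralog-free node whose map is a strict
ancestor of every child's map is a *speciation* node (congruence with the
species phylogeny formalised as the standard LCA-reconciliation
criterion); the rest are *dubious*. Multifurcating
species trees are allowed; strictness is evaluated on the multifurcation
as given.

An anchor pair whose coalescent node is a duplication node defines an event
interval: the coalescent node's species map is the lower bound and the
first speciation ancestor's map the upper bound. Tracing continues *past*
dubious nodes (the number crossed is recorded per placement); anchors whose
trace reaches the root without a speciation node get a root-open interval
and are reported in an unbounded bin rather than forced onto a branch. When
the interval is a single species-tree branch, the event is assigned to it;
per-branch counts of anchor pairs and families are reported at bootstrap
thresholds 50 and 80, and the count at 80 can never exceed the count at 50.

# The simulator and what it does (not) emulate

`simulateDataset()` evolves gene families down a species tree whose branch
lengths are *per-lineage* expected Ks; WGD ages and divergence times in
configurations are quoted in *pairwise* Ks, so an event of age 1.0 sits at
per-lineage depth 0.5 above the tips and its surviving duplicate pairs show
pairwise Ks near 1.0. At an event every scaffold is duplicated and each
gene copy is retained with the event's retention probability; retained
duplicates can be lost later at a per-Ks-unit fractionation rate; tip
genomes receive random inversions; a small-scale (tandem) duplication rate
is available. Homology is a similarity proxy — bit-score
$(1-p)\times$ protein length and E-value $10^{-\mathrm{bit}/10}$ floored at
1e−180 — sufficient because downstream methods use only score ranks, an
E-value cutoff and c-score ratios.

Sequences evolve by a proposal process: a uniform random site gets a
uniform random different base; proposals creating internal stops are
rejected, synonymous proposals are always accepted, nonsynonymous ones with
probability omega (default 0.2). Mutation continues until the NG86
synonymous-difference count against the branch parent reaches a
Poisson-drawn target. The target mean is calibrated as
$S \cdot \tfrac34(1 - e^{-4k/3})$ — the Jukes–Cantor *forward* expectation
of observed differences after $k$ substitutions per synonymous site —
rather than $S \cdot k$ itself: targeting the raw count at $S_k$ would make
the raw proportion equal $k$ and the corrected estimate overshoot (0.82 for
a target of 0.5). With the calibrated target the corrected Ks tracks the
requested age (Monte-Carlo: mean within a few percent for Ks ≤ 1.5) and JC
distances compose additively across branch segments, so multi-branch paths
also land on their configured divergences. Unreachable targets (short or
saturated sequences) are capped and counted in the ground truth.

Deliberate simplifications, and what they imply for the tests: no indels
(alignment is the identity — real data need pre-aligned input), a single
global omega with no among-site or among-lineage rate variation, no
transposable elements or intergenic structure, and clean similarity scores
without alignment noise. Passing the recovery tests therefore demonstrates
the *inference machinery* is correct under the model's assumptions; it does
not certify robustness to alignment error, rate heterogeneity or assembly
artefacts in real genomes.

# Validation scenarios and problem sizes

The package validates itself on four simulated scenarios (sizes chosen to
keep a full run inside a few minutes on one core):

* *peak recovery*: 500 families, one WGD at Ks 1.0 with 30% retention,
  20 replicate seeds — the weighted KDE peak must fall in [0.85, 1.15] in
  at least 90% of replicates;
* *placement recovery*: three ingroup species and an outgroup, WGD on the
  ingroup stem (Ks 0.9, 30% retention), 40 families, 20 seeds, 100
  bootstrap replicates per gene tree — at least 90% of support-≥80
  placements must land on the true stem branch;
* *depth/multiplicity*: two WGD rounds at full retention give modal
  self-comparison depth 4 and a 4:1 cross-genome pattern against a lineage
  without WGD;
* *CI calibration*: the nominal 90% bootstrap peak CI covers the true mode
  of a unimodal sample in at least 80 of 100 replicates (mode estimation
  bias makes exact nominal coverage unattainable; the margin reflects
  that).

The algorithmic cores are additionally checked against independent
brute-force oracles: exhaustive pathway enumeration for NG86 (all 61 × 61
codon pairs, tolerance 1e−9), exhaustive chain search for the collinearity
DP, double-loop RBH, neighbourhood-expansion components, and greedy
complete-linkage merging.

# Known limitations

* NG86 underestimates Ks in the saturation regime; estimates near the
  Ks = 5 cutoff are indicative only.
* Connected components can lump families that share promiscuous domains;
  the 300-gene cap and the c-score filter mitigate but do not remove this.
* Pairwise-only synteny misses highly degenerated segments that
  profile-based recursive search would recover.
* The relative-timing rule inherits the equal-rates assumption of all
  Ks-peak comparisons.
* The simulator's clean homology scores make family reconstruction easier
  than with real BLAST output.
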