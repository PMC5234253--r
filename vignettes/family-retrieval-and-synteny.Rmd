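---
title: "Retrieving a gene family across a whole-genome duplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving a gene family across a whole-genome duplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

## The problem

Budding yeasts of the family Saccharomycetaceae descend from an ancient
whole-genome duplication (WGD). A gene that was single-copy before the event
may survive as an ohnolog pair afterwards — two paralogues that can diverge in
sequence, length and function, as the Haa1/Cup2 transcription-factor pair did:
both retain the same ~124-aa N-terminal copper-fist DNA-binding domain, but
Cup2 lost most of its transactivation region and shrank to roughly a third of
Haa1's length. Given a set of pre-WGD ("protoploid") and post-WGD proteomes
with their gene orders, `wgdtrace` answers three questions:

1. **Which proteins belong to the family?** Homology is transitive at a fixed
   significance level, so the family is retrieved as the connected component of
   a seed protein in an all-vs-all similarity network thresholded on e-value.
2. **What is each member's role?** Post-WGD members split into full-length
   (Haa1-type) and size-reduced (Cup2-type) orthologues by protein length;
   pre-WGD members carry the single ancestral copy.
3. **Which post-WGD copies belong to the same sub-lineage?** Sequence alone
   cannot reliably separate ohnologs that diverged immediately after the WGD;
   conserved gene neighbourhoods (synteny) can.

## Network retrieval and the e-value sweep

All translated ORFs are aligned all-against-all with exact affine-gap
Smith–Waterman (BLOSUM62, gap open 11 / extend 1 — the classic blastp
defaults) and each local score $S$ for sequences of lengths $m, n$ receives a
Karlin–Altschul e-value

$$E = K\,m\,n\,e^{-\lambda S}, \qquad \lambda = 0.267,\ K = 0.041,$$

the published constants for gapped BLOSUM62 statistics. Both constants and
the gap costs are exposed in `alignment_params()`. Hits with $E \le 10$ are
stored; directed hits collapse onto undirected edges keyed by the minimum
e-value of the two directions, the permissive, order-independent choice.

`retrieve_cluster()` performs breadth-first traversal from the seed over
edges with $E \le 10^{x}$; `sweep_thresholds()` repeats this for every integer
exponent $x \in [-60, -1]$. Because relaxing the threshold only adds edges,
member sets nest and the retrieval curve is non-decreasing — both properties
are tested against an independent connected-components oracle. Flat runs of
the curve (`detect_plateaus()`, tolerance 0 by default since a "range" is
otherwise in the eye of the beholder) indicate stable family boundaries.
`auto_plateau_cut()` suggests the most permissive exponent of the widest
plateau that still excludes the next merge — the widest shelf before another
protein set would join. It is a logged suggestion, deliberately overridable,
because the reference analyses of this kind fix the cut by expert judgement
(e.g. keeping a 51-member family while excluding a remotely similar
copper-fist relative that merges two decades later).

On full all-vs-all runs a shared-word prefilter (`filter_word = 5`) skips
pairs that share no exact 5-mer, a blast-style seeding heuristic; every pair
that is aligned is aligned exactly. `filter_word = NULL` gives exact mode.
The prefilter only thins hits near the report ceiling; edges anywhere near
the sweep thresholds come from pairs that always share words.

## Role assignment

Roles use the two criteria that separate the published clusters: protein
length and pre/post-WGD taxonomy. Post-WGD members shorter than
`length_cutoff` (default 450 aa) are Cup2-type; the default splits the
empirical gap between the short cluster (221–356 aa) and every full-length
cluster (≥ 525 aa) roughly midway. Pre-WGD members are the single protoploid
copies. An explicitly designated outgroup id can be excluded; there is no
automatic outgroup detection. A neighbor-joining tree on global-alignment
identity distances (`pairwise_distances()`, `nj_tree()` via `ape::nj`) stands
in for Bayesian/ML phylogenetics at desk scale; its Newick output can seed
external samplers, which this package does not run. On additive matrices NJ
provably recovers the generating topology, which the tests assert via
Robinson–Foulds distance.

## Synteny scoring

For each family member the 15 genes on either side (`neighbour_k`, the
window width used in the reference analysis; gene positions are ordinal
ranks, not base pairs, and strand is ignored) are labelled with their
similarity-cluster membership. For two query genes, each family label present
in both windows contributes one shared neighbour pair — the closest instance
when a label repeats, ties broken upstream for determinism. The edge strength
sums a per-pair product of three $[0,1]$ factors mirroring the three lines of
evidence named for this analysis:

* closeness, $c = 1/\max(|o_a|, |o_b|)$ — immediate neighbours weigh most;
* neighbour similarity, $s = \min(1, -\log_{10} E_{ab} / 60)$, from the
  stored network edge between the two neighbours or an on-demand alignment
  when the hit table does not cover the pair (defaulting $s$ to 1 would erase
  this criterion except in exact-identity simulations);
* cluster rarity, $r = 2/|\text{cluster}|$ — a shared label from a two-member
  family is maximally informative; matches from large families arise by
  chance more easily.

Sub-lineages are the connected components of the strong-edge subgraph
(`strength >= strong_cutoff`), each annotated with its majority role. The
default `strong_cutoff = 0.3` was calibrated on the bundled simulator:
within-sub-lineage edges score roughly 0.35–2 (the spread reflects whether
pre/post track clusters merge at the chosen cut, which changes cluster
rarity), while cross-WGD and pre-versus-post edges stay below about 0.15;
0.3 sits inside that gap with about a two-fold margin either side. Flanks are
scored jointly — the analysis does not require support on both sides of the
query, a point the underlying method descriptions leave open.

## What the simulator emulates — and what it does not

`simulate_genomes()` generates the study conditions end to end with ground
truth: a species tree with six protoploid and six post-WGD leaves; one
ancestral scaffold of 30 single-copy background genes (250–400 aa) around a
620-aa query gene (echoing the ~622-aa protoploid average) whose first 124
residues — the DNA-binding domain — are absolutely conserved; full gene-order
doubling onto paired scaffolds at the WGD; per-leaf Bernoulli retention of
each duplicated copy (`retention_prob = 0.9`, never losing both copies of a
family); truncation of the track-B query copy into 221–356 aa, the published
size range of the short cluster; and optional Poisson gene-order shuffling
(off by default).

Branch lengths matter. Crown depth is 0.25 within either clade against stem
lengths of 0.70/0.80, so orthologues within a sub-lineage remain clearly
alignable while cross-clade and cross-duplication neighbour pairs have only
marginal similarity (e-values around $10^{-1}$–$10^{-15}$). This is the regime
the method is for: if the stems are shallow, plain sequence similarity
separates the sub-lineages and synteny is redundant; the defaults were chosen,
using the package's own e-value machinery, so that synteny is necessary and
sufficient.

Deliberate simplifications, which bound what green tests prove about real
data: substitutions are uniform across the 19 alternative residues (no rate
matrix, no site heterogeneity); the conserved domain is perfectly conserved
rather than slowly evolving; indels are geometric with mean length 2;
retention is i.i.d. per leaf rather than phylogenetically shared, so sister
species lose copies independently; there is one scaffold, not a karyotype;
and no gene conversion. Real proteomes add fragments, annotation errors and
domain shuffling that the simulator does not model.

## Numerical and degenerate-input choices

* Exponent grid: integer steps, $-60$ to $-1$; `retrieve_cluster` validates
  the range.
* Stored e-values are capped below at the smallest positive double when an
  external hit table reports 0.
* Plateau tolerance 0 by default; exposed because published "ranges" are
  read off a plot.
* `auto_plateau_cut` with a single plateau returns its permissive end; ties
  between equally wide plateaus resolve toward the more stringent one.
* Windows truncate at scaffold ends and never cross scaffolds; ORFs missing
  from a gene-order table are placed on a per-genome `unplaced` scaffold in
  input order (how unanchored ORFs were treated in the reference analysis is
  unstated; this is our convention).
* Empty promoter sequences scan to an empty hit list; an `N` in a promoter
  matches no motif element.
* Motif runs report every feasible run length and every overlapping offset,
  matching the exhaustive oracle.
* `apply_truncation` is a no-op on sequences already at or below the target
  maximum and refuses ranges that would invade the conserved prefix.

## Problem sizes used by the tests

The test-suite simulations use the default 12-leaf / 30-family configuration
for end-to-end parameter recovery (about 520 ORFs and 10⁴ stored hits) and
reduced 4- and 6-leaf variants for unit and determinism checks; property
tests use up to 100 random graphs of up to 200 nodes and 1000 random 200-bp
promoter sequences. These sizes exercise every code path while keeping a full
run on one CPU within a few minutes; `scripts/acceptance.R` re-runs the
default configuration from scratch and reports what it recovers.

## Known limitations

* The e-value stand-in applies Karlin–Altschul statistics to exact
  Smith–Waterman scores with per-pair search space $m \times n$; blastp's
  composition-based statistics and effective-search-space corrections are out
  of scope, so absolute e-values differ from blastp's even though their
  ordering is faithful. Full-scale replication of a published network should
  import blastp tabular output via `read_hit_table()`.
* Only seed-anchored retrieval is provided — no global clustering of the
  whole proteome set, and no genome-wide ancestral gene-order reconstruction.
* Majority-role annotation of a sub-lineage can be undecided on chimeric
  single-gene lineages (an early-branching species whose lone copy shares
  neighbours with both tracks); the partition itself is still reported.
* Bayesian/ML tree inference, multiple alignment and database lookups of
  motif annotations are external to the package by design.
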