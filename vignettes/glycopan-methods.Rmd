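---
title: "Methods: inferring core and accessory nucleotide-sugar pathways in a genome set"
author: "glycopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring core and accessory nucleotide-sugar pathways in a genome set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopan)
```

## The scientific question

Bacteria build their extracellular glycans — capsules, lipopolysaccharide,
biofilm polysaccharides — from activated monosaccharides called
nucleotide-sugars (UDP-glucose, GDP-mannose, dTDP-rhamnose, ...). Within a
genus, some nucleotide-sugar biosynthesis pathways are conserved in
essentially every genome (*core*), while others occur only in subsets of
strains (*accessory*). Whether an accessory pathway's scattered distribution
reflects vertical descent with repeated loss or repeated independent
acquisition can be read from two signals: the minimum number of gain/loss
events its presence/absence pattern implies on the species tree, and the
degree to which the genus' sequences for the pathway's gene families are
monophyletic within broader gene-family trees.

`glycopan` implements this analysis as a reusable pipeline for sets of
related (draft) genomes such as metagenome-assembled genomes (MAGs) of one
genus, together with a synthetic-data generator that makes every stage
testable without external databases.

## Pipeline stages and their assumptions

### Genome and evidence screening

Genomes are filtered on completeness and contamination estimates (defaults:
keep completeness ≥ 90%, contamination ≤ 5%). A genome violating *either*
bound is removed; although quality rules are sometimes written as a
conjunction of defects, keeping a 50%-complete genome because it is clean
would undermine the prevalence estimates, so the disjunctive reading is
used. Both thresholds are configurable.

Homology evidence is consumed as HMMER 3.x `--domtblout` tables, one per
genome, searched against KO-style profile collections. A hit passes when
the family has a database-recommended bitscore threshold and the
full-sequence bitscore reaches it; families without a recommended threshold
fall back to an E-value cutoff (default 1e-20) combined with a query-cover
threshold (default 75%). *Query cover* is defined as the fraction of the
HMM profile length spanned by the domain alignments, because the profile is
the query in `hmmsearch`; multiple domains of one ORF are merged by the
union of their profile spans, with score and E-value taken from the
full-sequence columns. Families backed by fewer than 200 known sequences
are excluded as poorly supported models. When one family matches several
ORFs, only the highest-bitscore hit is kept, with ties broken by lower
E-value and then lexicographic ORF id so results are deterministic.

Gene families present in at least 90% of genomes (inclusive) are labelled
core, detected families below that accessory.

### Pathway presence on a reference network

The reference network is a directed reaction graph from central-carbon
entry points (fructose-6-phosphate, ribulose-5-phosphate,
sedoheptulose-7-phosphate) to nucleotide-sugar products, supplied as a YAML
file. Each reaction is gated by gene families with the usual
KEGG-module-style semantics: OR over isoenzyme alternatives, AND within a
complex. The package ships a curated default transcription of the standard
bacterial routes (`inst/extdata/nucleotide_sugar_network.yaml`); it is
curation, intended to be reviewed and edited for the organism group at
hand.

A pathway to a sugar is *detected* in a genome when two criteria hold
simultaneously: (i) some route from a source metabolite to the sugar is at
least 75% complete, and (ii) the terminal enzyme producing the sugar is
present. Completeness is operationalized as the maximum over all simple
(cycle-free) routes of the fraction of route *reactions* whose gene
requirement is satisfied. This reduces to the intuitive "3 of 4 steps"
reading on linear pathways and is well defined on branched networks; an
alternative reading (connected-component reachability) was considered and
rejected because it can assign high completeness to fragments that do not
lie on any producing route. Counting reactions rather than genes was
chosen so that isoenzyme redundancy does not inflate completeness. Route
enumeration is exhaustive depth-first search with a configurable depth cap
(default 15), which is safe because curated nucleotide-sugar networks have
tens of reactions.

Sugars detected in strictly more than 90% of genomes are core; the strict
inequality at sugar level versus the inclusive one at gene level follows
the respective conventions exactly and both are configurable.

### Gain/loss events on the species tree

Each sugar's detection pattern is a binary character on the marker-gene
species tree (the marker defaults to the polyphosphate kinase family
K00937, *ppk1*; the tree is rooted on a user-supplied outgroup, and
genomes outside the clade spanned by two reference leaves can be
discarded). The minimum number of state changes is computed by unit-cost
dynamic programming over ancestral states (Fitch small parsimony; the
Sankoff-style recursion generalizes it exactly to multifurcating nodes, so
polytomies need no arbitrary resolution). Gains and losses are counted
jointly, with no root-state prior and no gain/loss asymmetry. For binary
trees the count is invariant to root placement, which the test suite
checks.

### Monophyly in gene-family trees

For each gene family, the genus' sequences sit among background database
sequences in a gene tree. The monophyly score is the size of the largest
clade consisting *only* of target sequences divided by the number of
targets, with clades taken in the rooting-invariant bipartition sense:
score 1 means perfect monophyly, lower scores mean several independent
lineages. Clades containing any non-target sequence never count, however
target-rich. Families whose target LCA has support below 80% are excluded
from group summaries as phylogenetically unreliable; the comparison is
inclusive at the threshold, the support scale (fraction vs percent) is
auto-detected, and the LCA is located after midpoint rooting by default
(`rooting = "as-read"` is available). An LCA that coincides with the root
carries no support and is likewise excluded, as are families without
background sequences.

### Permutation tests

Core and accessory groups are compared on event counts, monophyly scores
and kingdom-wide sugar prevalence with an independent-samples permutation
test using the difference of group medians, two-sided via the absolute
statistic: p = P(|median(A\*) − median(B\*)| ≥ |observed|) under random
relabelings preserving group sizes (default 100000). When the number of
distinct regroupings is at most the permutation budget the test switches
to exhaustive enumeration and the p-value is exact; in sampled mode the
add-one estimator (b+1)/(n+1) is used, which never returns zero. A
different two-sided convention — doubling the smaller one-sided p, as some
software defaults do — can differ when group sizes are unequal because the
permutation distribution of the median difference is then asymmetric; the
absolute-statistic definition is used here and verified bit-for-bit
against brute-force enumeration. No multiple-testing correction is applied
across the three tests, matching common practice for this design; users
comparing many groups should adjust externally.

Medians and interquartile ranges are reported with linear-interpolation
quantiles (R type 7) throughout.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a single-genus MAG study so
the whole pipeline can be exercised with known ground truth:

* a Yule-split species tree with 61 curated genomes plus an outgroup leaf,
  supports drawn from U(0.85, 1);
* 9 core sugars whose characters start present at the root and are lost
  with per-branch probability 0.005, and 12 accessory sugars starting
  absent with per-branch gain and loss probabilities 0.08 — simple
  per-branch flip (CFN-style) dynamics rather than rate×length Markov
  processes, which is deliberate: it is sufficient to generate the
  polyphyletic patterns the analysis detects and keeps every event
  enumerable in the truth record;
* a linear reference network of 3 reactions per sugar, each gated by a
  dedicated gene family co-present with the sugar's character;
* per-genome domtblout-dialect hit tables (including the *ppk1* marker, a
  deliberately under-supported decoy family, and a mix of
  bitscore-thresholded and fallback-filtered families), plus a
  CheckM-style quality table in which 3 extra genomes fail both quality
  bounds;
* gene trees of 40 background leaves per family in which the target
  sequences are implanted as one clade (core families) or 2–4 clades
  (accessory), each attached at a distinct background leaf so the
  monophyly truth is exactly (largest clade)/(total targets);
* kingdom-wide prevalence drawn from Beta(8, 2) for core and Beta(2, 5)
  for accessory sugars, reproducing the expected separation.

All randomness derives from one master seed through named substreams, so
each stage is independently reproducible. What the generator does *not*
emulate: sequence-level evolution, annotation error structure (hits are
clean once thresholds pass), correlated loss of neighbouring genes, and
realistic horizontal-transfer donors. Passing end-to-end tests therefore
demonstrates correctness of the inference machinery given its inputs, not
robustness to annotation noise in real data.

## Numerical choices and degenerate inputs

* Bitscore ties in best-hit selection: lower E-value, then lexicographic
  ORF id.
* Coverage from inclusive 1-based domtblout coordinates; unions of
  overlapping or adjacent spans merge.
* Route enumeration depth cap 15 (configurable); networks are validated at
  load time (undeclared metabolites, missing terminal reactions,
  unreachable products, self-loops all error).
* `fitch_changes` requires a complete binary character and errors on
  missing leaves; constant characters give 0.
* Exact permutation mode engages automatically when C(n_a+n_b, n_a) ≤
  n_permutations; statistic comparisons use a relative 1e-12 tolerance so
  floating-point ties count as ties.
* Empty core or accessory groups abort summaries and tests with
  informative errors rather than returning NaN.

## Problem sizes used in the shipped checks

The package's own validation runs at sizes chosen to make brute-force
oracles exhaustive: parsimony against all internal labelings on 200 trees
of ≤ 7 leaves; monophyly against all bipartition sides on 200 trees of
≤ 30 leaves; permutation sampling against full enumeration for 50 datasets
with ≤ 10000 regroupings; null calibration over 2000 datasets of 9 vs 12
values at 2000 permutations; the pathway rule against independent
route enumeration over all 2^10 gene-presence combinations of a 12-reaction
branched toy network; and 20 end-to-end replicates at the full study
geometry (61 genomes, 21 sugars).

One caveat the validation surfaced: with the generator's low core loss
rate, core event counts are nearly all zero, and the median-difference
statistic then has a 1–2% tie probability under relabeling (any regrouping
that captures most of the zeros reproduces the observed difference).
Median-difference p-values for the event comparison therefore hover around
0.01 at this geometry even when the dichotomy is obvious, which is a
granularity property of the statistic at small group sizes, not an error;
the monophyly and kingdom-prevalence comparisons, whose values are less
degenerate, test sharply significant.

## Known limitations

* The default reference network is curation; organism-specific isoenzymes
  or alternative routes must be added by the user, and pathway calls are
  only as good as the network and the annotation evidence.
* Presence of a family is "≥ 1 surviving hit"; copy number and operon
  context are ignored.
* Parsimony counts are lower bounds on true event numbers and carry no
  branch-length information.
* The monophyly score does not distinguish transfer into the genus from
  transfer out of it, and depends on the background sequence sample.
* Permutation tests operate at the unit supplied (sugar or family); when
  several families report on the same pathway their values are not
  independent, and the tests make no correction for that.
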