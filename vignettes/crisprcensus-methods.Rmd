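---
title: "Methods: models, thresholds and design choices in crisprcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in crisprcensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcensus)
```

crisprcensus implements the computational machinery behind the current
evolutionary classification of CRISPR–Cas systems: 2 classes, 7 types and
46 subtypes. It does not run homology searches, array detectors or tree
inference; those tools' outputs (profile-hit tables, array calls,
similarity matrices, Newick trees) are its inputs. What the package owns
is everything downstream: locus assembly, subtype classification and
completeness calls, dendrogram construction and constrained profile
merging, the module-shuffling tally, and phylogenetically weighted census
statistics. This vignette explains the models, the thresholds, and the
choices we made where the procedure was genuinely open.

## The classification registry

The taxonomy is shipped as versioned, diffable JSON
(`inst/extdata/registry_2025.json` and `registry_2020.json`). Each
subtype definition carries the effector-module gene inventory
(`required_all`, including the subtype's signature family), alternative
sets (`required_any`), disqualifying families (`forbidden`), and two
dispensability flags: `adaptation_optional` (type VII and most type III
and IV subtypes do not need cas1/cas2 to be complete) and
`array_optional` (no CRISPR array has been found in III-G loci, and type
IV loci frequently lack them). Variants (I-F3 CAST, IV-A2, V-M, ...) are
children of subtypes and are not counted among the 46; variants can be
promoted as they are characterised.

Two transcription decisions deserve a flag. First, the current inventory
has eight type I subtypes but the eighth is defined only in the extended
subtype figures; we carry it as `I-H` with a registry note. Second, the
15-subtype composition of type V is not closed in the running text: we
take the ten 2020 subtypes (V-A..V-I, V-K) plus the five rare subtypes
enumerated with the other poorly represented lineages (V-L, V-N, V-O,
V-P, V-Q), and keep V-J and V-M as variants. Both points are notes in the
registry file, so a future transcription can amend them without touching
code.

```{r registry}
reg <- load_registry("2025")
registry_counts(reg)$per_type
length(diff_registries(reg, load_registry("2020"))$added)
```

## Annotation: one non-overlapping hit set per protein

Profile hits are filtered at e-value `r pipeline_config()$evalue_max`
(inclusive) and then reduced, per protein, to a non-overlapping set of
best-scoring hits. "Best-scoring" is read as greedy culling by descending
bit score — the standard reading for profile-hit assignment — rather than
maximum-weight interval scheduling: a hit is accepted iff it overlaps
every accepted hit by at most `overlap_tolerance` residues (default 0,
configurable, since partial-overlap handling is not specified by the
source procedure). Score ties are broken by lower e-value, longer
interval, then profile id, making the assignment deterministic. Whether
the e-value filter precedes the culling is likewise unstated; we filter
first, which can only remove hits that would lose the culling anyway at
equal tolerance.

Abundance counting against a clustered protein database reuses the same
culling per target protein, with an additional query-coverage floor of
0.75 (inclusive), and credits each surviving hit to the subtype of the
query profile's provenance (`family@subtype` profile ids); untagged
profiles are reported under `unassigned` rather than dropped.

## Locus assembly, directon trimming, classification

Neighbourhoods of up to ten genes on each side are taken around every
gene with a core cas hit (cas1–cas14, including the lettered and fused
families), truncated at contig ends; overlapping or adjacent
neighbourhoods merge into one locus, and assembly is set-based, so seed
order cannot matter. Merged neighbourhoods are not re-extended from the
merged span (single pass). Arrays within ten genes of a member are
attached. Gene order is by rank, not base-pair distance.

Boundary trimming interprets "the directions at the locus margins" as
*directons* — maximal runs of consecutive co-oriented genes, the standard
operon proxy; the literal reading (directions) prescribes nothing
computable. Each margin is moved to the boundary of the directon
containing the outermost cas-annotated gene (or array-adjacent gene):
co-oriented flanks are pulled in, unannotated margin genes beyond the
strand switch are trimmed, and interior unannotated genes are retained.

Classification scores every subtype from the locus's family evidence:
subtype-specific evidence (a hit from a profile tagged with the subtype,
or a family that is the unique signature of exactly one subtype) counts
2, every required family present counts 1, and a forbidden family
disqualifies (III-E, for instance, forbids cas10). The weights are
configurable; the source procedure classifies by "type- and
subtype-specific profiles" without stating arithmetic, so the weights
encode only "signatures dominate". A subtype needs at least one piece of
signature evidence to be eligible; otherwise the locus is
`unclassified`. Exact ties are broken by the number of required families
matched and otherwise *recorded as conflicts* — pairs like III-C/III-H or
IV-B/IV-C share gene inventories and are separable only by
subtype-tagged profiles, which mirrors the manual curation the original
analysis applied. Completeness requires all `required_all` families, one
member of each `required_any` set, and the adaptation module and an
attached array only where the registry marks them non-optional.

## Dendrograms and the profile-merge loop

Profile similarity scores are converted to distances by
`d = -ln(S_AB / min(S_AA, S_BB))`, clamped to `[1e-9, 1]` before the log:
cross-scores occasionally exceed a self-score in practice, and the clamp
floor keeps zero or negative scores finite. UPGMA is implemented
in-package with an explicit lexicographic tie rule and node heights equal
to half the merge distance, so trees are ultrametric and reproducible;
`stats::hclust(method = "average")` serves as an independent cross-check
in the tests, together with a naive agglomerator that recomputes average
distances from the original matrix. The "tree depth cutoff" of 0.8 is
read as a threshold on node height in these log-distance units — the only
interpretation consistent with cutting a dendrogram built from
`-ln(relative score)`; `cut_at_depth()` returns the maximal subtrees
whose root height does not exceed the cutoff, and partitions nest across
depths. Hybrid trees are built by `graft()`, which replaces backbone tips
by rooted subtrees while conserving leaf labels.

The profile-update loop (`nj_merge()`) is named after the
neighbour-joining step of the original pipeline but is deliberately *not*
canonical NJ tree building: following the procedure's own description, at
each iteration the closest pair of clusters under the current distance
matrix is proposed, a merge oracle evaluates the merged profile, and the
merge is accepted only if it retains more than 98% of the original member
sequences (strict) and gains at most ten new false positives
(inclusive). In the original pipeline the oracle is a PSI-BLAST search
with a rebuilt profile; here it is a pluggable deterministic callable,
and the merged cluster's score row is the cluster-size-weighted mean of
its parents' rows (UPGMA-consistent), its self-score likewise. An
exemption from the false-positive rule (used for families with abundant
homologues outside CRISPR–Cas loci, such as Cas3 and CARF) is the
oracle's responsibility, not a package flag: an oracle may simply report
zero false positives for such families. Rejected pairs are marked
unmergeable; the loop ends when no unmarked pair remains, after at most
`n - 1` accepted merges, and every decision is logged.

## Census: tree-based weights and prevalence

To correct for the massively uneven sampling of prokaryotic clades,
genomes are weighted by branch-proportional (Gerstein–Sonnhammer–Chothia
style) apportionment: each edge's length is shared equally among its
descendant leaves and a leaf's weight is the sum of its shares,
normalised to 1. The original analysis cites an external weighting scheme
without reproducing it; GSC apportionment is the canonical tree-based
choice for this purpose, is exactly testable (hand-apportioned cases,
clade-extraction oracle), and matches the stated goal of down-weighting
oversampled clades. Weighted prevalence of a predicate ("carries a
complete system of type X") is the weight of carrier genomes over the
group's total weight; with uniform weights it reduces to plain counting.
The subtype-fraction heat-map statistic weights *loci*, not genomes: each
complete locus inherits its genome's weight — so two same-subtype loci in
one genome both count, following the figure-legend definition literally —
and taxon rows are normalised to 1. Temperature-stratified prevalence
recomputes weights on the subtree of genomes with known optimal growth
temperature; the class bounds (psychrophile < 20 °C, mesophile 20–45,
thermophile 45–80, hyperthermophile > 80 °C) are configurable defaults,
since the classes are named but not bounded in the source.

```{r census}
tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
compute_weights(tree)
```

## Module-shuffling estimate

Proteins are clustered greedily (longest first, coverage measured on the
representative) at two levels: strict (0.9 identity, 0.9 coverage) and
permissive (0.5, 0.33). For every locus containing cas1 and an effector
gene (cas8 — including the lettered large subunits and Cas10d — cas9,
cas10 or cas12; cas13/cas14 excludable by default, includable by flag), a
pair links the cas1 strict cluster to the effector's permissive cluster.
The counting unit of "a recombination event was registered" is ambiguous;
we count, per strict cas1 cluster, the number of distinct permissive
effector clusters minus one (floored at zero) — a conservative spanning
estimate, with a per-effector-gene variant behind `per_pair = TRUE`.
Identical loci across near-identical genomes are not deduplicated
(documented; the tally is an estimate, not an exact event count).

## The synthetic-data generator

`simulate_genomes()` emits every input dialect with planted truth:
single-contig genomes, a planted locus per carrier genome (subtypes
cycled from a configurable list defaulting to twelve lineages including
VII, III-E and III-G), decoy genes on both flanks, and arrays where the
subtype requires them. Incomplete loci are created by removing one
required element (a shared effector-core gene where possible, else the
adaptation module, else the array), so the classification signal
survives while the completeness flag flips. True hits carry
subtype-tagged profiles with e-values log-uniform on `[1e-30, 1e-5]` and
query coverage Beta(8, 2); decoy hits use non-cas profiles with e-values
log-uniform on `[1e-3, 1]`, placing them above the 1e-4 filter. Type IV
loci are emitted with an adaptation module even though it is optional,
because locus assembly anchors on core cas1–cas14 genes and csf1 is not
core — an adaptation-less type IV locus would be invisible to the
assembler here, as it is to a cas-anchored assembly generally.
Coordinates use fixed 300-bp genes and 50-bp gaps for readability; rank,
not distance, drives assembly, so this is cosmetic.

What the generator does *not* emulate matters for interpreting green
tests: there are no sequences, no partial or frame-shifted genes, no
tandem loci sharing one neighbourhood, no cross-reacting profiles
(decoys never hit cas families), and noise never removes a true
signature hit. Passing the closed loop therefore demonstrates the
correctness of the plumbing and the decision rules under the stated
noise model — not robustness to adversarial real-world annotation noise,
which in the original analysis required manual curation.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes that exercise every rule: oracle equivalence on 200 random
matrices (n ≤ 8), 500 random hit sets (≤ 10 hits) and 100 random pair
sets; closed-loop recovery on 50 genomes across 12 subtypes; census
recovery on 500 genomes with a coalescent tree, checked within three
binomial standard errors of the planted carrier rate; merge-rule
enforcement over 20 adversarial oracle runs on 8 clusters. Tolerances:
matrix symmetry and weight sums at 1e-9 relative; distance-clamp floor
1e-9; tie comparisons at 1e-12. Degenerate inputs are defined behaviour:
single-leaf trees get weight 1, zero-total-length trees fall back to
uniform weights, empty hit tables flow through every filter, and a
single cluster is returned unchanged by the merge loop with an empty
log.

## Known limitations

Variant-level assignment (e.g. recognising a CAST within I-F) is out of
scope: variants are registry metadata, and `variant` is reported as `NA`.
Tandem loci produce one merged locus with a conflict list rather than
two systems. Subtype pairs with identical gene inventories (III-C/III-H,
IV-B/IV-C) require subtype-tagged profiles to separate. The
census statistics assume the genome tree covers the census genomes;
bacteria and archaea are expected to be weighted on their separate
marker trees and combined by census proportion, which is the caller's
composition rather than a baked-in rule.
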