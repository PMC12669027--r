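# crisprcensus

Assembly, classification and census of CRISPR–Cas genomic loci.

CRISPR–Cas systems — the adaptive immune systems of bacteria and archaea
— are classified into an evolutionary taxonomy of 2 classes, 7 types and
46 subtypes, defined by the gene composition of their effector modules.
Surveying them across thousands of genomes takes a pipeline:
profile-search hits must be reduced to per-protein annotations,
annotations assembled into *cas* loci, loci classified against subtype
signature rules and called complete or not, profile families organised
into similarity dendrograms, and the resulting counts corrected for the
massively uneven phylogenetic sampling of sequenced genomes. This
package implements that downstream machinery for computational
microbiologists who already have search output (PSI-BLAST/MMseqs2-style
hit tables, CRISPR array calls, HHsearch-style score matrices, genome
trees) and need reproducible classification and census statistics. It
runs no homology searches itself, and a synthetic-data generator with
planted ground truth makes the whole pipeline testable offline.

## The core models

**Classification.** A versioned registry encodes each subtype's
effector-module inventory: required families (including the subtype
signature, e.g. *cas14* for type VII, *cas7-11e* for III-E), forbidden
families (III-E forbids *cas10*), and whether the adaptation module
(*cas1*/*cas2*) and the CRISPR array are dispensable. Loci are
neighbourhoods of up to 10 genes around each core *cas* gene
(*cas1*–*cas14*), merged when they touch, trimmed to directon
boundaries; each subtype *s* is scored

```
score(s) = 2 · #{subtype-specific evidence} + 1 · #{required families present}
```

with forbidden matches disqualifying, ties surfaced as conflicts, and a
locus *complete* iff all required effector-module genes of its subtype
are present (plus adaptation/array where non-optional).

**Dendrograms.** Profile scores `S` become distances
`d(A,B) = −ln(S_AB / min(S_AA, S_BB))`, clamped to `[1e-9, 1]`; UPGMA
with a deterministic tie rule builds ultrametric dendrograms (node
height = half merge distance), cut at a node-height depth (default 0.8);
within-cluster trees can be grafted onto backbone tips. An iterative
merge loop joins the closest cluster pair only when a merge oracle
reports retention > 0.98 of original sequences and ≤ 10 new false
positives.

**Census.** Genome weights are branch-proportional
(Gerstein–Sonnhammer–Chothia) apportionments of the genome tree,
normalised to 1. Weighted prevalence of a predicate within a group is
`Σ w(carriers) / Σ w(group)`; the taxon × subtype fraction matrix
weights each complete locus by its genome's weight and normalises rows.

**Recombination.** Module shuffling between adaptation and effector
modules is estimated conservatively: per strict (0.9/0.9) *cas1*
cluster, the number of distinct permissive (0.5/0.33) effector clusters
it co-occurs with, minus one.

## Worked example

Simulate a small cohort with planted loci, run annotation → assembly →
classification, and compute weighted census statistics:

```r
library(crisprcensus)

reg <- load_registry("2025")
reg
#> CRISPR-Cas classification registry, version 2025
#>   2 classes, 7 types, 46 subtypes; 74 gene families

sim   <- simulate_genomes(reg, n_genomes = 6, seed = 11, noise = "default")
annot <- annotate_proteins(sim$hits)                  # e-value filter + culling
loci  <- assemble_neighborhoods(sim$genes, annot, sim$arrays)
loci  <- trim_boundaries(loci, sim$genes, reg)        # directon margins
loci  <- classify_loci(loci, reg)
loci[, c("locus_id", "subtype", "complete")]
#>      locus_id subtype complete
#> 1 g001:ctg1:1     I-B     TRUE
#> 2 g002:ctg1:1     I-E     TRUE
#> 3 g003:ctg1:1     I-F    FALSE
#> 4 g004:ctg1:1    II-A     TRUE
#> 5 g005:ctg1:1   III-A     TRUE
#> 6 g006:ctg1:1   III-B     TRUE
```

Each row is one assembled locus with its subtype call; `g003`'s I-F
locus was planted incomplete (a required effector gene removed) and is
flagged accordingly. Census statistics weight genomes by their placement
in the genome tree, down-weighting oversampled clades:

```r
w <- compute_weights(simulate_tree(6, "coalescent", seed = 11))
round(w, 3)
#>  g005  g003  g006  g001  g002  g004
#> 0.356 0.123 0.096 0.096 0.123 0.204

weighted_prevalence(sim$genomes, loci, w)
#>   group   prevalence weight_total
#> 1 taxon1          1        0.453
#> 2 taxon2          1        0.219
#> 3 taxon3          0        0.123
#> 4 taxon4          1        0.204
```

`prevalence` is the weighted fraction of genomes in each taxon carrying
a complete system — taxon3's only genome carries the incomplete I-F
locus, so its prevalence is 0. `subtype_fraction_matrix()` produces the
taxon × subtype heat-map values the same way, weighting loci instead of
genomes.

A thin command-line front door over the same functions ships in
`inst/cli/crisprcensus.R`
(`crisprcensus.R {registry-validate,registry-diff,annotate,classify,dendro,census,recomb,simulate}`).

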