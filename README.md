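# lsgkit

Discovery and characterization of lineage-specific genes (LSGs) —
genes with no detectable homolog outside a taxonomic group — from an
annotated genome.

Given a focal proteome and an ordered set of homology databases, the
package classifies every gene by sequential elimination:

1. **outgroup genomes** (protein databases searched BLASTp-style,
   nucleotide databases tBLASTn-style via six-frame translation): a
   significant hit makes the gene an **EC** (evolutionarily conserved);
2. **non-lineage transcript sets**: a hit ⇒ EC;
3. **lineage transcript sets**: a hit ⇒ provisional **CSG**
   (lineage-specific gene with relatives inside the lineage); no hit
   anywhere ⇒ provisional **ORPHAN**;
4. optional **curated protein databases**: provisional LSGs with a hit
   are reassigned to EC.

Significance is the classical local-alignment model: Smith–Waterman
affine-gap alignment (BLOSUM62; gap open 11, extend 1) scored with
Karlin–Altschul statistics, *E* = *K·m·n·e^(−λS)* (λ = 0.267,
*K* = 0.041), thresholded strictly at *E* < 10⁻⁵. Exact per-stage
bookkeeping is kept in a stage ledger whose survivor and final counts
are re-derived and cross-checked by `reconcile_ledger()`.

Downstream of classification the package computes genic features (exon
counts, lengths, GC of exons/introns/gene/CDS and the three codon
positions) with one-way ANOVA between gene classes, chromosome
distributions with Spearman's rank test (exact permutation p for
n ≤ 9), RPKM expression with the two-rule tissue-preferential filter,
and qPCR 2^−ΔΔCt fold changes with stress-responsiveness calls. A
synthetic-corpus generator (`simulate_corpus()`) emits every input with
planted ground truth, so the whole cascade is testable without any
external database.

Intended users: researchers identifying orphan/taxonomically-restricted
genes in newly annotated genomes who want a transparent, hermetically
testable reference implementation of the classification cascade and its
downstream statistics.

## Worked example

```r
library(lsgkit)

corpus <- simulate_corpus(simulation_config(seed = 42))
res <- run_pipeline(corpus$proteome, corpus$tiers)
print(res$ledger)
#> <stage_ledger>
#>   input genes          60
#>   - outgroup genomes   18 eliminated -> 42 remain
#>   - non-lineage PUTs   9 eliminated -> 33 remain
#>   - lineage PUTs       20 provisional CSG / 13 provisional orphan
#>   - curated screen     3 reassigned EC (0 CSG + 3 orphan)
#>   final: 30 EC, 20 CSG, 10 orphan (30 LSGs)

table(truth = corpus$truth$category, called = res$outcomes$category)
#>         called
#> truth    CSG EC ORPHAN
#>   CSG     20  0      0
#>   EC       0 30      0
#>   ORPHAN   0  0     10
```

The ledger narrates the cascade: of 60 genes, 18 were eliminated as
conserved by the outgroup-genome tier and 9 more by the non-lineage
transcript tier; 20 of the 33 survivors found lineage homologs
(provisional CSGs); the curated screen reassigned 3 provisional orphans
to EC (those genes' only planted homologs live in the curated database).
Every planted label is recovered. The genic features then separate the
classes as planted — conserved genes are longer with more exons, LSGs
are GC-richer:

```r
ft <- features_table(corpus$models, corpus$genome)
anova_by_class(ft, res$outcomes$category)
#>          feature     F        p
#> 1     exon_count  12.0 4.53e-05
#> 2    gene_length  25.1 1.53e-08
#> 3 protein_length  55.4 4.29e-14
#> 4        gc_gene 105.4 7.04e-20
#> 5         gc_cds 747.5 1.27e-41
```

A command-line wrapper with `simulate`, `classify`, `features`,
`expression` and `qpcr` subcommands is installed at
`system.file("scripts", "lsgkit", package = "lsgkit")`; see its header
for usage. The methods vignette (`vignettes/lsg-discovery.Rmd`)
documents the model, the conventions, and what the synthetic benchmarks
do and do not demonstrate.

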