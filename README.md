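# peaklink

Batch tools for linking ATAC-seq accessible chromatin to genes in
regeneration time courses.

In injury/regeneration studies — e.g. the zebrafish retina after optic
nerve crush, sampled at 0, 2, 4, 7 and 12 days post injury — chromatin
accessibility (ATAC-seq peak calls) and transcription (RNA-seq time
courses) are profiled in parallel, and the analytical glue between them is
the question: *which genes could this patch of open chromatin regulate?*
peaklink answers it reproducibly, offline, from standard files.

## What it computes

**Peaklets.** Each peak call with `p < 10⁻¹⁰` is reduced to a 500 bp window
`[mode − 250, mode + 250)` anchored on the mode (summit) of its signal,
clipped at contig ends. Accessibility is quantified by counting fragments
that share ≥ 1 base with the window.

**Proximal/distal classification.** For a peaklet with mode *m* and a
transcript with TSS *t* on the same contig, with *d* = |*m* − *t*|:

- *proximal* — the peaklet interval contains the TSS, or *d* ≤ 1 kb;
- *distal* — *d* ≤ 100 kb and not proximal;
- *none* — otherwise.

All (peaklet, transcript) pairs with a label are kept — the correspondence
is many-to-many. Peaklets within 50 bp of an exon that cover no TSS can be
flagged and removed. Results export as CSV (per record), BED4 and FASTA
(per unique peaklet, for motif scanners).

**Expression.** TPM normalisation, `log2(TPM+1)`, log fold change vs a
baseline column, row Z-scores; K-means row clusters (seeded, multi-start)
with complete-linkage/Euclidean ordering within clusters; heatmap
rendering.

**GO over-representation.** True-path propagation over the is_a/part_of
DAG, then per term the one-sided hypergeometric tail
p = P(X ≥ k), X ~ Hypergeom(N, K, n), reported at raw p < 0.05
(classic, plus the elim variant that removes genes of significant children
before testing ancestors).

**Cross-species projection.** Gene lists from other organisms map into the
reference transcript space through a homology TSV (all one-to-many hits
kept), filter by DE status (FDR < 5%, strict), and compare as 2–4-way Venn
partitions.

**Synthetic fixtures.** `simulate_fixture()` generates a coherent toy
genome/annotation/peaks/fragments/expression/DE/GO/homology bundle with
known ground-truth labels, deterministically per seed — every module is
testable with exact expected answers and no downloads.

## Worked example

```r
library(peaklink)
library(dplyr)

fx  <- simulate_fixture(fixture_spec(seed = 42), out_dir = "demo")
ann <- read_annotation(fx$paths[["annotation"]], contig_lengths = fx$paths[["sizes"]])
peaklets <- derive_peaklets(read_narrowpeak(fx$paths[["peaks"]]), ann$contig_lengths)
peaklets
#> # A tibble: 120 × 7
#>   peaklet_id contig start   end  mode source_p_value truncated
#>   <chr>      <chr>  <int> <int> <int>          <dbl> <lgl>
#> 1 chr1:2449  chr1    2199  2699  2449       1.34e-14 FALSE
#> 2 chr1:3267  chr1    3017  3517  3267       4.26e-14 FALSE
#> 3 chr1:6977  chr1    6727  7227  6977       6.77e-15 FALSE
```

132 peaks were generated; the 12 with p-values above 10⁻¹⁰ are filtered,
and each surviving peak yields one 500 bp peaklet named by its summit.

```r
records <- build_correspondence(peaklets, ann, remove_exonic = TRUE)
count(records, link_class)
#> # A tibble: 2 × 2
#>   link_class     n
#> 1 distal       944
#> 2 proximal      30
export_records(records, fx$paths[["genome"]], "linked")  # CSV + BED + FASTA
```

974 peaklet–transcript links survive the exonic filter; distal links
dominate because each peaklet can sit within 100 kb of many TSSs while at
most a couple are within 1 kb.

```r
z  <- transform_expression(fx$tpm, "zscore_log_tpm")
cl <- cluster_expression(z, k = 3, seed = 1)
glance(cl)
#> # A tibble: 1 × 6
#>   n_rows n_cols     k tot_withinss totss prop_within
#> 1     30      5     3        0.108  108.     0.00100
```

The three planted temporal shapes are recovered essentially perfectly
(within-cluster variance 0.1% of total). Finally, GO enrichment of the
planted DE genes against all expressed genes:

```r
prop  <- propagate_annotations(fx$gene2go, fx$ontology)
truth <- fx$ground_truth$transcripts
fisher_enrichment(unique(truth$gene_id[truth$de]), unique(truth$gene_id),
                  prop, fx$ontology)
#> # A tibble: 4 × 7
#>   term_id    name               namespace annotated significant expected p_value
#> 1 GO:0009888 tissue development BP                9           9      2.7 6.99e-8
#> 2 GO:0031099 regeneration       BP                9           9      2.7 6.99e-8
#> ...
```

The 9 DE genes were planted on the regeneration term; it and its ancestors
are the only terms below the 5% reporting threshold (expected count under
the null: 2.7 of 9).

## Vignette

`vignettes/peak-gene-linkage.Rmd` documents the models, parameter choices,
degenerate-input rules, and what the synthetic generator does and does not
emulate.
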