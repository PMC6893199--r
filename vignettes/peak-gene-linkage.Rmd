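---
title: "Linking accessible chromatin to genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking accessible chromatin to genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaklink)
```

## The problem

In regeneration time courses — the motivating system is the zebrafish retina
after optic nerve crush, sampled at 0, 2, 4, 7 and 12 days post injury (dpi)
— ATAC-seq peak calls describe where chromatin is open and RNA-seq describes
which transcripts respond. peaklink connects the two: it reduces each
significant peak to a fixed-width "peaklet", asks which transcription start
sites (TSSs) each peaklet could plausibly regulate, and exports the
resulting many-to-many peaklet–gene table together with the sequence and
coordinate files that downstream motif analysis needs. Around that core it
provides the supporting analyses such a study uses: time-course expression
transforms and clustering, GO over-representation against an
expressed-transcript universe, and projection of gene lists from other
species through homology tables.

## Coordinates

Every coordinate inside the package is 0-based half-open `[start, end)`.
GTF/GFF3 files are 1-based closed; the conversion happens once, inside
`read_annotation()` and `write_gtf()`, and nowhere else. Interval
containment of a point (e.g. "does the peaklet cover the TSS?") uses
half-open membership: `tss >= start & tss < end`. Abutting intervals share
no base and do not overlap.

## Peaklets

A peak call enters the pipeline with a p-value and either a summit offset
(narrowPeak column 10) or a per-base signal vector. `derive_peaklets()`
keeps peaks with `p_value < p_threshold` and anchors a 500 bp window on the
mode of the signal:

* the mode is the summit position, or the **leftmost** argmax of the signal
  when only a signal vector is available — plateaus are broken
  deterministically;
* the window is `[mode - 250, mode + 250)`, i.e. the even width is split
  symmetrically with the extra base on neither side;
* windows are clipped at contig boundaries and flagged `truncated` — the
  only case in which a peaklet is narrower than 500 bp;
* ids are `contig:mode`, so they are stable across runs and self-locating.

The default `p_threshold` is `1e-10`. The filter this threshold implements
is conventionally written `p < 10e-10` in some pipelines, a notation that
literally reads as `1e-9`; we document the ambiguity and expose the value as
an argument rather than deciding silently. Accessibility per peaklet is
quantified by `count_overlaps()`: a fragment counts when it shares at least
one base with the peaklet (no minimum-overlap fraction; provided intervals
are counted as-is, with no duplicate removal).

## Proximal and distal classification

For a peaklet and a transcript on the same contig, with `d = |mode - tss|`:

* **proximal** — the peaklet interval contains the TSS, or `d <= 1000`;
* **distal** — `d <= 100000` and the pair is not proximal;
* **none** — otherwise.

The two clauses of the proximal rule are deliberately different: distance is
measured from the peaklet *mode* (the best single-base estimate of where the
accessibility signal sits), while TSS overlap uses the full interval. The
three labels partition every pair: exactly one applies. Distances in the
output are signed, positive downstream of the TSS on the gene's strand,
which is the orientation motif work cares about.

TSSs are per-transcript, not per-gene: a peaklet near a gene with two
alternative starts yields two records, and gene-level questions are answered
by taking the union over the gene's transcripts. This is the finest-grained
choice; collapsing to a canonical TSS would discard information the
correspondence table can represent.

`build_correspondence()` keeps **all** (peaklet, transcript) pairs with a
proximal or distal label — one peaklet may serve several genes and one gene
may receive dozens of peaklets. Internally candidates are found with an
interval overlap query (GenomicRanges) and then classified exactly; the test
suite checks this against an exhaustive all-pairs scan on hundreds of random
fixtures.

### The exonic filter

A peaklet within 50 bp of an exon (overlap and abutment count as distance 0)
that does not itself cover any TSS is flagged exonic; `remove_exonic = TRUE`
drops its records to enrich for non-genic regulatory chromatin. The test is
a property of the peaklet, not of the pair: it uses the genome-wide merged
exon union and the genome-wide TSS set, so a peaklet is either exonic
everywhere or nowhere.

### Exports

`export_records()` writes the CSV (one row per record), a BED4 and a FASTA
of unique peaklets. Entries are deduplicated by peaklet id — a peaklet
linked to three genes appears three times in the CSV but once in the
BED/FASTA, since motif scanners should not see the same sequence multiple
times. FASTA sequences are forward-strand slices; their lengths always equal
the BED interval widths.

## Expression transforms and clustering

`compute_tpm()` is the standard transcripts-per-million: per sample,
`rate = count / length_kb`, scaled so each column sums to 10^6 (all-zero
columns stay zero). `transform_expression()` then provides `log2(TPM + 1)`,
per-row `log2` fold change against a named baseline column (the baseline
column becomes exactly 0), and row Z-scores of either log-scale measure. The
pseudocount is 1 for both logs — it keeps zeros at zero and is the common
default; Z-scores are taken on log-scale values, and a zero-variance row
maps to all zeros rather than NaN.

Row clustering is K-means (`stats::kmeans`, Hartigan–Wong) with 10 random
restarts under a fixed seed, keeping the best within-cluster sum of squares;
this gives deterministic, quality-stable results without a bespoke
initialisation scheme. Labels are relabelled by descending cluster size
(ties by first row index) so label 1 is always the largest cluster and a
fixed seed yields bit-identical assignments. Within each cluster, rows are
ordered by the leaf order of a complete-linkage dendrogram on Euclidean
distances — the plain agglomerative order, with no optimal-leaf reordering,
since metric and linkage are the specified contract. Columns may optionally
be clustered the same way; by default they stay in time-course order.
Columns are expected to be one summary per time point (replicates collapsed
upstream, e.g. by their mean).

`cluster_expression()` packages all of this with `tidy()` / `glance()` /
`autoplot()` methods, and `render_heatmap()` writes the banded heatmap.

## GO over-representation

Annotations are propagated by the true-path rule: a gene annotated to a term
is annotated to every ancestor, each ancestor counted once per gene no
matter how many paths reach it (`propagate_annotations()` takes the
transitive closure over `is_a` and, by default, `part_of` links; a flag
restricts to `is_a`). `fisher_enrichment()` then tests each term one-sided
for over-representation: with `N` universe genes, `K` annotated, `n` study
genes and `k` annotated study genes, `p = P(X >= k)` for
`X ~ Hypergeom(N, K, n)` — Fisher's exact test for enrichment. Terms are
reported at raw `p < 0.05`, unadjusted; enriched-term lists at this
threshold are screening output, to be read in the context of the query list,
and an optional BH column is available for users who want it.

Two method variants are provided. `classic` tests every term independently;
it is exactly the closed form above and is verified in the tests against
draw-by-draw enumeration for small universes. `elim` iterates terms
bottom-up and removes the genes of significantly enriched children (cutoff
0.01) before testing their ancestors, which suppresses the parent–child
redundancy classic testing produces. Decorrelation schemes that reweight
rather than remove genes exist; classic and elim bracket their behaviour and
both are fully specified here.

The universe should be the expressed genes; by default genes without any
annotation are dropped from it (`drop_unannotated = FALSE` keeps them, which
only deflates p-values uniformly). Enrichment runs in gene space —
transcript-level queries should be collapsed to genes first.

## Cross-species projection

`map_genes()` expands source-species gene ids through a static homology
table (a BioMart-style TSV) into all their reference transcripts:
one-to-many homologies are all kept — prioritising a "best" hit would
require similarity data the table does not carry — and unmapped ids are
returned verbatim so nothing disappears silently. Input id lists follow a
paste-box contract (`tokenize_ids()`: whitespace, comma or semicolon
separated). `subset_de()` filters to transcripts with `fdr < 0.05`
(strictly) at a named timepoint or at any timepoint, and
`overlap_partition()` tabulates every region of a 2–4 set Venn partition,
with region counts summing to the union size by construction.

## The synthetic generator

`simulate_fixture()` exists so the entire pipeline is testable offline with
known answers. It emulates the *shapes* of the real data: a small genome
(default two 400 kb contigs), 30 single-transcript genes with 2–4 exons in a
150 kb gene region, 120 significant peaks whose summits are placed to
realise intended labels, fragments piled around summits, a five-timepoint
(0/2/4/7/12 dpi) expression table with 3 planted temporal shapes (ramp up,
ramp down, transient; amplitude 3 on the log2 scale, noise sd 0.1), a DE
table with 30% of transcripts planted below FDR 5% at every post-injury
timepoint, an 11-term GO DAG containing a diamond, and homology tables for
two query species.

Summit placement keeps guard bands around the classification boundaries:
proximal summits within 800 bp of their partner TSS, distal ones 2.5–90 kb
from the partner and at least 2.5 kb from every TSS, background ones more
than 102 kb from every TSS. Inside those bands the intended label is
unambiguous, so the closure test — generate, derive peaklets, classify,
compare to truth — must recover 100% of labels; the boundary cases
themselves (distances 999/1000/1001, 99999/100000/100001) are exercised
separately with hand-placed intervals. Each file type draws from its own
RNG stream derived from the master seed, so adding a file type never
perturbs the others, and a fixed seed reproduces the bundle byte for byte.

What the generator does **not** emulate: read-level noise and alignment
artefacts, overlapping or multi-isoform gene structure, signal-dependent
peak shapes, batch effects, or biologically structured GO annotation.
Passing tests demonstrate the algorithms' correctness on their contracts,
not performance characteristics on real libraries.

## Numerical and degenerate-input choices

* Mode ties: leftmost argmax. Even-width windows: `[mode - 250, mode + 250)`.
* TSS containment: half-open. FDR and p-value report thresholds: strict `<`.
* All-zero TPM columns and zero-variance Z-score rows map to zeros, never
  NaN.
* K-means is seeded and multi-start; k greater than the row count is an
  error, k = 1 is allowed.
* Empty record sets export valid empty files; empty universes and unknown
  timepoints are errors that name the valid options.
* The test suite and the examples here run on deliberately small problems —
  tens of genes, low hundreds of peaks, 100-replicate oracle comparisons —
  sizes at which exhaustive oracles are feasible and the whole suite runs in
  about a minute.

## Limitations

* Differential expression and differential accessibility are consumed as
  input tables; no testing is re-implemented.
* No peak calling, motif scanning, or enhancer-activity prediction — the
  FASTA/BED exports are the hand-off to those tools.
* Homology projection is only as good as the supplied table; no ortholog
  inference is attempted.
* The proximal/distal windows (±1 kb, ±100 kb) are conventions, not
  biology; both are arguments.
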