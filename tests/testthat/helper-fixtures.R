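# Small in-code fixture builders shared across tests.

# Wrap a TSS table (transcript_id, gene_id, contig, strand, tss) into an
# annotation whose spans reproduce those TSSs exactly (span-only models).
annotation_from_tss <- function(tx, contig_lengths = NULL) {
  tx$start <- ifelse(tx$strand == "-", tx$tss - 499L, tx$tss)
  tx$end <- ifelse(tx$strand == "-", tx$tss + 1L, tx$tss + 500L)
  suppressWarnings(peaklink::annotation(tx, contig_lengths = contig_lengths))
}

# A three-transcript / two-gene GTF written to a temp file.
write_tiny_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    'chr1\tsrc\ttranscript\t101\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tsrc\texon\t501\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tsrc\ttranscript\t1\t1000\t.\t-\t.\tgene_id "gA"; transcript_id "tA2";',
    'chr1\tsrc\texon\t1\t300\t.\t-\t.\tgene_id "gA"; transcript_id "tA2";',
    'chr1\tsrc\texon\t801\t1000\t.\t-\t.\tgene_id "gA"; transcript_id "tA2";',
    'chr2\tsrc\ttranscript\t2001\t4000\t.\t+\t.\tgene_id "gB"; transcript_id "tB1";',
    'chr2\tsrc\texon\t2001\t2500\t.\t+\t.\tgene_id "gB"; transcript_id "tB1";',
    'chr2\tsrc\texon\t3001\t4000\t.\t+\t.\tgene_id "gB"; transcript_id "tB1";'
  )
  writeLines(lines, path)
  path
}

# One-row peaklet at a given mode with a standard 500bp interval.
peaklet_at <- function(mode, contig = "chr1", half = 250L) {
  tibble::tibble(
    peaklet_id = paste0(contig, ":", mode), contig = contig,
    start = mode - half, end = mode + half, mode = mode,
    source_p_value = 1e-12, truncated = FALSE
  )
}
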