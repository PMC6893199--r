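# Proximal/distal classification, the exonic filter, the many-to-many
# correspondence, and the CSV/BED/FASTA exports.

test_that("classify_link honors TSS containment and mode-distance windows", {
  model_at <- function(tss, contig = "chr1") {
    tibble::tibble(contig = contig, tss = tss)
  }
  # TSS inside the interval -> proximal even though the distance rule alone
  # would also say so
  expect_equal(classify_link(peaklet_at(1200), model_at(1200)), "proximal")
  p <- tibble::tibble(contig = "chr1", start = 950L, end = 1450L, mode = 1200L)
  expect_equal(classify_link(p, model_at(1300)), "proximal")
  # mode 900bp away, interval not covering the TSS
  expect_equal(classify_link(peaklet_at(2000), model_at(1100)), "proximal")
  expect_equal(classify_link(peaklet_at(60000), model_at(10000)), "distal")
  expect_equal(classify_link(peaklet_at(160000), model_at(10000)), "none")
  expect_equal(classify_link(peaklet_at(1200), model_at(1200, "chr9")), "none")
})

test_that("exonic flag requires exon adjacency within the margin and no TSS inside", {
  exons <- tibble::tibble(contig = "chr1", start = 1000L, end = 2000L)
  tss <- tibble::tibble(contig = "chr1", tss = 5300L)

  near <- peaklet_at(2280, half = 250)        # gap 2030 - 2000 = 30bp
  expect_true(flag_exonic(near, exons, tss))
  far <- peaklet_at(2310, half = 250)         # gap 60bp > margin
  expect_false(flag_exonic(far, exons, tss))
  overlapping_with_tss <- peaklet_at(5300, half = 4000)  # covers exon and TSS
  expect_false(flag_exonic(overlapping_with_tss, exons, tss))
  abutting <- peaklet_at(2250, half = 250)    # [2000, 2500): distance 0
  expect_true(flag_exonic(abutting, exons, tss))
})

test_that("one peaklet links to several genes and gene_subset filters records", {
  tx <- tibble::tibble(
    transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"), contig = "c1",
    strand = "+", tss = c(10000L, 90000L)
  )
  ann <- annotation_from_tss(tx, contig_lengths = c(c1 = 200000))
  pk <- peaklet_at(50000, contig = "c1")  # 40kb from both TSSs
  rec <- build_correspondence(pk, ann)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$gene_id, c("gA", "gB"))
  expect_true(all(rec$link_class == "distal"))

  only_a <- build_correspondence(pk, ann, gene_subset = "gA")
  expect_equal(only_a$gene_id, "gA")
  expect_warning(build_correspondence(pk, ann, gene_subset = c("gA", "gZ")),
                 "gZ")
})

test_that("signed distance is positive downstream of the TSS on the gene strand", {
  tx <- tibble::tibble(
    transcript_id = c("tP", "tM"), gene_id = c("gP", "gM"),
    contig = c("c1", "c2"), strand = c("+", "-"), tss = c(10000L, 10000L)
  )
  ann <- annotation_from_tss(tx, contig_lengths = c(c1 = 50000, c2 = 50000))
  pk <- dplyr::bind_rows(peaklet_at(12000, "c1"), peaklet_at(12000, "c2"))
  rec <- build_correspondence(pk, ann)
  expect_equal(rec$distance[rec$gene_id == "gP"], 2000)
  expect_equal(rec$distance[rec$gene_id == "gM"], -2000)  # upstream on '-'
})

test_that("build_correspondence equals the exhaustive all-pairs oracle and exonic removal shrinks output", {
  for (seed in 1:5) {
    set.seed(seed)
    fx <- random_linkage_fixture(n_peaklets = 80, n_transcripts = 30)
    ann <- annotation_from_tss(fx$tss)
    rec <- build_correspondence(fx$peaklets, ann)
    want <- oracle_correspondence(fx$peaklets, tss_table(ann))
    got <- as.data.frame(rec[order(rec$peaklet_id, rec$transcript_id),
                             c("peaklet_id", "transcript_id", "link_class")])
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)

    kept <- build_correspondence(fx$peaklets, ann, remove_exonic = TRUE)
    expect_lte(nrow(kept), nrow(rec))
    key <- function(r) paste(r$peaklet_id, r$transcript_id)
    expect_true(all(key(kept) %in% key(rec)))
  }
})

test_that("shrinking proximal_bp can demote proximal links to distal but never to none", {
  tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1", contig = "c1",
                       strand = "+", tss = 10000L)
  ann <- annotation_from_tss(tx, contig_lengths = c(c1 = 100000))
  pk <- peaklet_at(10900, "c1")  # mode 900bp from TSS, interval not covering it
  wide <- build_correspondence(pk, ann, proximal_bp = 1000L)
  narrow <- build_correspondence(pk, ann, proximal_bp = 500L)
  expect_equal(wide$link_class, "proximal")
  expect_equal(narrow$link_class, "distal")
})

test_that("export writes one deduplicated BED/FASTA entry per peaklet and a CSV row per record", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 50000), collapse = "")))
  tx <- tibble::tibble(transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"),
                       contig = "c1", strand = "+", tss = c(10000L, 12000L))
  ann <- annotation_from_tss(tx, contig_lengths = c(c1 = 200000))
  pk <- peaklet_at(11000, "c1")  # proximal to both genes
  rec <- build_correspondence(pk, ann)
  expect_equal(nrow(rec), 2)

  prefix <- tempfile()
  paths <- export_records(rec, genome, prefix)
  bed <- read_bed(paths[["bed"]])
  expect_equal(nrow(bed), 1)
  expect_equal(c(bed$start, bed$end), c(10750, 11250))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(length(fa), 1)
  expect_equal(unname(Biostrings::width(fa)), bed$end - bed$start)
  expect_equal(names(fa), bed$name)
  # forward-strand slice contract
  expect_equal(as.character(fa[[1]]),
               as.character(Biostrings::subseq(genome[["c1"]], 10751, 11250)))
  back <- read_correspondence(paths[["csv"]])
  expect_equal(as.data.frame(back), as.data.frame(rec))

  expect_error(export_records(dplyr::mutate(rec, contig = "cX"), genome, tempfile()),
               "cX")
})

test_that("exporting an empty record set yields valid empty files", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  empty <- build_correspondence(
    peaklet_at(1e6, "cZ"),
    annotation_from_tss(tibble::tibble(transcript_id = "t1", gene_id = "g1",
                                       contig = "c1", strand = "+", tss = 1000L),
                        contig_lengths = c(c1 = 2000, cZ = 2e6))
  )
  expect_equal(nrow(empty), 0)
  paths <- export_records(empty, genome, tempfile())
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read_correspondence(paths[["csv"]])), 0)
  expect_equal(length(Biostrings::readDNAStringSet(paths[["fasta"]])), 0)
})
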