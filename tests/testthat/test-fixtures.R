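# The synthetic-data generator: determinism, ground-truth consistency, and
# the confusion report.

test_that("identical seeds give byte-identical file bundles", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  spec <- fixture_spec(seed = 5, n_genes = 10, n_peaks = 20)
  f1 <- simulate_fixture(spec, d1)
  f2 <- simulate_fixture(spec, d2)
  f3 <- simulate_fixture(fixture_spec(seed = 6, n_genes = 10, n_peaks = 20), d3)
  for (nm in names(f1$paths)) {
    expect_identical(readLines(f1$paths[[nm]]), readLines(f2$paths[[nm]]),
                     label = paste("file", nm))
  }
  expect_false(identical(readLines(f1$paths[["peaks"]]),
                         readLines(f3$paths[["peaks"]])))
})

test_that("files on disk re-parse into the in-memory objects", {
  dir <- tempfile()
  fx <- simulate_fixture(fixture_spec(seed = 9, n_genes = 8, n_peaks = 16), dir)
  ann <- read_annotation(fx$paths[["annotation"]])
  expect_equal(dplyr::arrange(ann$transcripts, transcript_id),
               dplyr::arrange(fx$annotation$transcripts, transcript_id))
  np <- read_narrowpeak(fx$paths[["peaks"]])
  expect_equal(np$summit_offset, fx$peaks$summit_offset)
  expect_equal(np$p_value, fx$peaks$p_value, tolerance = 1e-12)
  onto <- read_obo(fx$paths[["obo"]])
  expect_setequal(onto$terms$term_id, fx$ontology$terms$term_id)
  expect_equal(nrow(read_gene2go(fx$paths[["gene2go"]])), nrow(fx$gene2go))
  expect_equal(read_homology(fx$paths[["homology"]]), fx$homology)
  de <- read_de_table(fx$paths[["de"]])
  expect_equal(de$fdr, fx$de$fdr, tolerance = 1e-12)
})

test_that("fraction_proximal = 1 makes every derived peaklet proximal to its partner", {
  fx <- simulate_fixture(fixture_spec(seed = 2, n_genes = 10, n_peaks = 30,
                                      fraction_proximal = 1, fraction_distal = 0,
                                      fraction_background = 0))
  pk <- derive_peaklets(fx$peaks, fx$annotation$contig_lengths)
  rec <- build_correspondence(pk, fx$annotation)
  truth <- fx$ground_truth$peaks[fx$ground_truth$peaks$label == "proximal", ]
  key <- paste(paste0(truth$contig, ":", truth$mode), truth$partner_transcript)
  rec_key <- paste(rec$peaklet_id, rec$transcript_id)
  hit <- rec$link_class[match(key, rec_key)]
  expect_equal(hit, rep("proximal", nrow(truth)))
})

test_that("de_fraction = 0 leaves no transcript significant at any timepoint", {
  fx <- simulate_fixture(fixture_spec(seed = 4, n_genes = 10, n_peaks = 10,
                                      de_fraction = 0))
  expect_equal(subset_de(fx$ground_truth$transcripts$transcript_id, fx$de,
                         timepoint = "ANY"),
               character(0))
})

test_that("truth_report detects a summit shifted out of its intended class", {
  fx <- simulate_fixture(fixture_spec(seed = 12, n_genes = 10, n_peaks = 30))
  pk <- derive_peaklets(fx$peaks, fx$annotation$contig_lengths)
  rec <- build_correspondence(pk, fx$annotation)
  clean <- truth_report(fx$ground_truth$peaks, rec, pk)
  off <- clean[clean$n > 0 &
                 !(paste(clean$intended, clean$observed) %in%
                     c("proximal proximal", "distal distal",
                       "background background", "filtered missed")), ]
  expect_equal(sum(off$n), 0)

  # push one proximal summit ~2kb away: it must migrate to distal. Pick a
  # peak whose shifted mode stays clear of every other TSS, so the intended
  # migration is unambiguous.
  truth <- fx$ground_truth$peaks
  tss <- tss_table(fx$annotation)
  shift <- NA
  for (i in which(truth$label == "proximal")) {
    for (cand in c(2000L, -2000L, 3000L, -3000L)) {
      new_mode <- truth$mode[i] + cand
      d <- abs(tss$tss[tss$contig == truth$contig[i]] - new_mode)
      if (min(d) > 1300 && min(d) <= 99000) { shift <- cand; break }
    }
    if (!is.na(shift)) break
  }
  expect_false(is.na(shift))
  peaks2 <- fx$peaks
  j <- which(paste0(peaks2$contig, ":", peaks2$start + peaks2$summit_offset) ==
               paste0(truth$contig[i], ":", truth$mode[i]))[1]
  peaks2$summit_offset[j] <- peaks2$summit_offset[j] + shift
  peaks2$start[j] <- min(peaks2$start[j], peaks2$start[j] + shift)
  peaks2$end[j] <- max(peaks2$end[j], peaks2$end[j] + shift)
  peaks2$summit_offset[j] <- truth$mode[i] + shift - peaks2$start[j]
  truth$mode[i] <- truth$mode[i] + shift  # coordinates move, intended label does not
  pk2 <- derive_peaklets(peaks2, fx$annotation$contig_lengths)
  rec2 <- build_correspondence(pk2, fx$annotation)
  shifted <- truth_report(truth, rec2, pk2)
  expect_gte(shifted$n[shifted$intended == "proximal" &
                         shifted$observed == "distal"], 1)
})

test_that("planted expression clusters are recovered exactly at the planted k", {
  fx <- simulate_fixture(fixture_spec(seed = 7, n_genes = 18, n_peaks = 10,
                                      n_clusters = 3))
  z <- transform_expression(fx$tpm, "zscore_log_tpm")
  got <- kmeans_rows(z, k = 3, seed = 1)
  truth <- fx$ground_truth$transcripts
  tab <- table(got$cluster[match(truth$transcript_id, got$transcript_id)],
               truth$cluster)
  # one-to-one correspondence: each recovered cluster maps to one planted one
  expect_equal(sum(apply(tab, 1, max)), nrow(truth))
})

test_that("invalid fixture specs are rejected", {
  expect_error(fixture_spec(fraction_proximal = 0.7, fraction_distal = 0.7,
                            fraction_background = 0), "sum to 1")
  expect_error(fixture_spec(n_clusters = 9), "n_clusters")
})
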