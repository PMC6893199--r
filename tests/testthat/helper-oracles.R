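# Independent brute-force oracles. These deliberately avoid the package's
# interval-tree / vectorized code paths: plain exhaustive scans and
# enumerations against which the implementation is checked.

# All-pairs peaklet x transcript classifier: every pair is inspected with
# scalar rules, no candidate pruning.
oracle_correspondence <- function(peaklets, tss, proximal_bp = 1000,
                                  distal_bp = 100000) {
  rows <- list()
  for (i in seq_len(nrow(peaklets))) {
    for (j in seq_len(nrow(tss))) {
      if (peaklets$contig[i] != tss$contig[j]) next
      d <- abs(peaklets$mode[i] - tss$tss[j])
      contains <- tss$tss[j] >= peaklets$start[i] && tss$tss[j] < peaklets$end[i]
      cls <- if (contains || d <= proximal_bp) "proximal"
             else if (d <= distal_bp) "distal" else NA_character_
      if (is.na(cls)) next
      rows[[length(rows) + 1L]] <- data.frame(
        peaklet_id = peaklets$peaklet_id[i],
        transcript_id = tss$transcript_id[j],
        link_class = cls, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peaklet_id = character(), transcript_id = character(),
                      link_class = character())
  }
  out[order(out$peaklet_id, out$transcript_id), , drop = FALSE]
}

# Per-base boolean-mask union of intervals on one contig of given length.
oracle_mask_union <- function(starts, ends, contig_length) {
  mask <- logical(contig_length)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  data.frame(start = begins[r$values] - 1L, end = stops[r$values])
}

# Pairwise overlap counting by double loop (half-open intervals).
oracle_count_overlaps <- function(peaklets, fragments) {
  vapply(seq_len(nrow(peaklets)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(fragments))) {
      if (peaklets$contig[i] == fragments$contig[j] &&
          max(peaklets$start[i], fragments$start[j]) <
            min(peaklets$end[i], fragments$end[j])) {
        n <- n + 1L
      }
    }
    n
  }, integer(1))
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)  # w.l.o.g. the first K universe elements carry the term
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# Complete-linkage agglomeration from scratch: returns the list of cluster
# partitions after each merge (clusters as sorted id vectors).
oracle_complete_linkage <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- max(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  partitions
}

# Partition sequence implied by an hclust merge matrix, same shape as above.
hclust_partitions <- function(hc, n) {
  clusters <- lapply(seq_len(n), identity)
  node <- list()
  partitions <- list()
  members <- function(x) if (x < 0) -x else node[[x]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- members(hc$merge[s, 1]); b <- members(hc$merge[s, 2])
    merged <- sort(c(a, b))
    node[[s]] <- merged
    drop <- vapply(clusters, function(cl) all(cl %in% merged), logical(1))
    clusters <- c(clusters[!drop], list(merged))
    partitions[[s]] <- lapply(clusters, sort)
  }
  partitions
}

canonical_partition <- function(p) {
  lapply(p, function(step) {
    step <- lapply(step, sort)
    step[order(vapply(step, `[`, 0, 1))]
  })
}

# Per-element membership tabulation for Venn regions.
oracle_overlap_counts <- function(sets) {
  ids <- unique(unlist(sets))
  keys <- vapply(ids, function(id) {
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(keys)
}

# Random linkage fixture: a handful of transcripts and mode-anchored
# peaklets scattered over short contigs.
random_linkage_fixture <- function(n_peaklets, n_transcripts,
                                   contigs = c("c1", "c2"),
                                   contig_length = 400000L) {
  tss_pos <- sample(1000:(contig_length - 1000), n_transcripts)
  tx <- tibble::tibble(
    transcript_id = sprintf("t%03d", seq_len(n_transcripts)),
    gene_id = sprintf("g%03d", ceiling(seq_len(n_transcripts) / 2)),
    contig = sample(contigs, n_transcripts, replace = TRUE),
    strand = sample(c("+", "-"), n_transcripts, replace = TRUE),
    tss = tss_pos
  )
  mode <- sample(250:(contig_length - 250), n_peaklets)
  pk <- tibble::tibble(
    peaklet_id = paste0("pk", seq_len(n_peaklets)),
    contig = sample(contigs, n_peaklets, replace = TRUE),
    start = mode - 250L, end = mode + 250L, mode = mode,
    source_p_value = 1e-12, truncated = FALSE
  )
  list(peaklets = pk, tss = tx)
}
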