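# Deterministic synthetic-data generator: a coherent toy genome, annotation,
# peak calls, fragments, expression and DE tables, ontology and homology
# table, with known ground-truth linkage labels so every stage of the
# pipeline can be verified offline. Summits are placed with guard bands
# around the proximal/distal boundaries, so intended labels are unambiguous;
# boundary behaviour itself is exercised with hand-placed intervals in the
# tests, not here.

#' Specify a synthetic fixture
#'
#' @param seed Master RNG seed. Each file type draws from its own stream
#'   derived from this seed, so adding one file type never perturbs the
#'   others.
#' @param n_contigs,contig_length Genome shape. Contigs must be long enough
#'   to hold a gene region plus a background region beyond the distal
#'   window.
#' @param n_genes Number of genes (one transcript each, 2-4 exons,
#'   non-overlapping).
#' @param n_peaks Number of significant peaks, split by the label fractions.
#' @param fraction_proximal,fraction_distal,fraction_background Intended
#'   label mix; must sum to 1. Proximal summits land within 800bp of a TSS,
#'   distal ones 2.5-90kb from their partner (and >= 2.5kb from every TSS),
#'   background ones > 102kb from every TSS.
#' @param filtered_fraction Extra peaks with p-values above the
#'   significance threshold, emitted to exercise the filter; default 0.1.
#' @param timepoints Time-point labels; the first is the baseline.
#' @param n_clusters Planted expression-profile clusters (distinct temporal
#'   shapes: ramp up, ramp down, transient, late/early spikes).
#' @param amplitude,noise_sd Log2-scale template amplitude and Gaussian
#'   noise sd of the expression profiles.
#' @param de_fraction Fraction of transcripts planted as differentially
#'   expressed (FDR < 0.05 at every post-baseline timepoint).
#' @param fragments_per_peak Mean fragments simulated per significant peak.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, contig_length = 400000L,
                         n_genes = 30L, n_peaks = 120L,
                         fraction_proximal = 0.4, fraction_distal = 0.4,
                         fraction_background = 0.2, filtered_fraction = 0.1,
                         timepoints = c("0dpi", "2dpi", "4dpi", "7dpi", "12dpi"),
                         n_clusters = 3L, amplitude = 3, noise_sd = 0.1,
                         de_fraction = 0.3, fragments_per_peak = 20) {
  fr <- c(fraction_proximal, fraction_distal, fraction_background)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    abort("label fractions must be non-negative and sum to 1")
  }
  stopifnot(n_contigs >= 1, n_genes >= 1, n_peaks >= 1, n_clusters >= 1,
            n_clusters <= 5, length(timepoints) >= 2, de_fraction >= 0,
            de_fraction <= 1, contig_length >= 280000)
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks), fraction_proximal = fraction_proximal,
    fraction_distal = fraction_distal, fraction_background = fraction_background,
    filtered_fraction = filtered_fraction, timepoints = timepoints,
    n_clusters = as.integer(n_clusters), amplitude = amplitude,
    noise_sd = noise_sd, de_fraction = de_fraction,
    fragments_per_peak = fragments_per_peak
  ), class = "fixture_spec")
}

# gene region occupies [10k, 150k); background summits start 102kb past the
# last TSS so they are > distal_bp + guard from every TSS
.gene_region_hi <- 150000L
.bg_guard <- 102000L

#' Generate a synthetic data bundle with ground truth
#'
#' Produces, deterministically for a given seed, a toy genome (random ACGT),
#' a GTF annotation, narrowPeak peak calls whose summits realize intended
#' proximal/distal/background labels, fragment intervals, a time-course
#' expression table with planted profile clusters, a DE table with planted
#' FDRs, a small GO DAG with gene annotations (differentially expressed
#' genes are planted on a dedicated term, so enrichment is recoverable), and
#' a homology table for two query species.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, all pieces are written as
#'   plain-text files (genome.fa, chrom.sizes, genes.gtf, peaks.narrowPeak,
#'   fragments.bed, tpm.tsv, de.tsv, go.obo, gene2go.tsv, homology.tsv) and
#'   their paths returned under `$paths`.
#' @return List with the in-memory objects (`genome`, `annotation`, `peaks`,
#'   `fragments`, `tpm`, `de`, `ontology`, `gene2go`, `homology`) and
#'   `ground_truth` (`$peaks`: intended label and partner per peak;
#'   `$transcripts`: planted DE status and cluster per transcript).
#' @export
simulate_fixture <- function(spec = fixture_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  contigs <- paste0("chr", seq_len(spec$n_contigs))
  clen <- setNames(rep(spec$contig_length, spec$n_contigs), contigs)

  # --- genome ---------------------------------------------------------------
  set.seed(spec$seed + 1L)
  genome <- Biostrings::DNAStringSet(vapply(contigs, function(ct) {
    paste(sample(c("A", "C", "G", "T"), spec$contig_length, replace = TRUE),
          collapse = "")
  }, character(1)))

  # --- annotation -----------------------------------------------------------
  set.seed(spec$seed + 2L)
  tx_rows <- vector("list", spec$n_genes)
  ex_rows <- vector("list", spec$n_genes)
  cursor <- setNames(rep(10000L, spec$n_contigs), contigs)
  for (i in seq_len(spec$n_genes)) {
    ct <- contigs[((i - 1L) %% spec$n_contigs) + 1L]
    span_len <- sample(2000:5000, 1)
    gap <- sample(1500:4000, 1)
    start <- unname(cursor[ct]) + gap
    end <- start + span_len
    if (end > .gene_region_hi) {
      abort("gene region overflow: reduce n_genes or raise contig_length")
    }
    cursor[ct] <- end
    strand <- sample(c("+", "-"), 1)
    tid <- sprintf("t%03d", i)
    gid <- sprintf("g%03d", i)
    tx_rows[[i]] <- tibble(transcript_id = tid, gene_id = gid, contig = ct,
                           start = start, end = end, strand = strand)
    # 2-4 exons: alternate exon/intron segments across the span
    n_ex <- sample(2:4, 1)
    cuts <- sort(sample(seq(start + 50L, end - 50L), 2L * (n_ex - 1L)))
    bounds <- c(start, cuts, end)
    ex_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ex_end <- bounds[seq(2, length(bounds), by = 2)]
    ex_rows[[i]] <- tibble(transcript_id = tid, contig = ct,
                           start = as.integer(ex_start), end = as.integer(ex_end))
  }
  ann <- annotation(dplyr::bind_rows(tx_rows), dplyr::bind_rows(ex_rows),
                    contig_lengths = clen)
  tss <- tss_table(ann)
  tss_by_contig <- split(tss, tss$contig)

  # --- peaks ----------------------------------------------------------------
  set.seed(spec$seed + 3L)
  n_prox <- round(spec$fraction_proximal * spec$n_peaks)
  n_dist <- round(spec$fraction_distal * spec$n_peaks)
  n_bg <- spec$n_peaks - n_prox - n_dist
  labels <- sample(rep(c("proximal", "distal", "background"),
                       c(n_prox, n_dist, n_bg)))
  min_tss_dist <- function(ct, pos) {
    tt <- tss_by_contig[[ct]]
    if (is.null(tt) || nrow(tt) == 0) return(Inf)
    min(abs(tt$tss - pos))
  }
  place_summit <- function(label) {
    for (attempt in 1:2000) {
      if (label == "background") {
        ct <- sample(contigs, 1)
        tt <- tss_by_contig[[ct]]
        lo <- if (is.null(tt) || nrow(tt) == 0) 300L
              else as.integer(max(tt$tss) + .bg_guard)
        if (lo > clen[ct] - 300L) next
        pos <- sample(lo:(clen[ct] - 300L), 1)
        if (min_tss_dist(ct, pos) > .bg_guard) {
          return(list(contig = ct, mode = pos, partner = NA_character_))
        }
      } else {
        partner <- tss[sample(nrow(tss), 1), ]
        offset <- if (label == "proximal") sample(-800:800, 1)
                  else sample(c(-1, 1), 1) * sample(2500:90000, 1)
        pos <- partner$tss + offset
        if (pos < 300L || pos > clen[partner$contig] - 300L) next
        d <- min_tss_dist(partner$contig, pos)
        ok <- if (label == "proximal") abs(offset) <= 800 else d >= 2500
        if (ok) {
          return(list(contig = partner$contig, mode = as.integer(pos),
                      partner = partner$transcript_id))
        }
      }
    }
    abort(paste0("could not place a ", label, " summit; contig too crowded"))
  }
  placed <- purrr::map(labels, place_summit)
  n_filtered <- ceiling(spec$filtered_fraction * spec$n_peaks)
  filtered <- purrr::map(rep("background", n_filtered), place_summit)
  all_placed <- c(placed, filtered)
  all_labels <- c(labels, rep("filtered", n_filtered))
  mk_peak <- function(p, lab, i) {
    left <- sample(200:800, 1); right <- sample(200:800, 1)
    start <- max(0L, p$mode - left)
    end <- min(clen[p$contig], p$mode + right)
    neglog10_p <- if (lab == "filtered") stats::runif(1, 2, 8)
                  else stats::runif(1, 12, 15)
    tibble(name = sprintf("peak%04d", i), contig = p$contig,
           start = as.integer(start), end = as.integer(end),
           summit_offset = as.integer(p$mode - start),
           neglog10_p = neglog10_p, label = lab,
           partner_transcript = p$partner, mode = p$mode)
  }
  peaks_full <- dplyr::bind_rows(purrr::imap(all_placed, function(p, i) {
    mk_peak(p, all_labels[i], i)
  }))
  peaks <- peaks_full |>
    dplyr::mutate(p_value = 10^(-.data$neglog10_p)) |>
    dplyr::select("contig", "start", "end", "name", "p_value", "summit_offset")
  truth_peaks <- peaks_full |>
    dplyr::select("name", "contig", "mode", "label", "partner_transcript")

  # --- fragments ------------------------------------------------------------
  set.seed(spec$seed + 4L)
  sig <- peaks_full[peaks_full$label != "filtered", ]
  frag_rows <- purrr::map(seq_len(nrow(sig)), function(i) {
    n <- stats::rpois(1, spec$fragments_per_peak)
    if (n == 0) return(NULL)
    centre <- sig$mode[i] + sample(-300:300, n, replace = TRUE)
    len <- sample(50:150, n, replace = TRUE)
    start <- pmax(0L, centre - len %/% 2L)
    tibble(contig = sig$contig[i], start = as.integer(start),
           end = as.integer(pmin(clen[sig$contig[i]], start + len)))
  })
  n_bg_frag <- 2L * spec$n_peaks
  bg_ct <- sample(contigs, n_bg_frag, replace = TRUE)
  bg_start <- vapply(bg_ct, function(ct) sample(0:(clen[ct] - 200L), 1), integer(1))
  fragments <- dplyr::bind_rows(
    dplyr::bind_rows(frag_rows),
    tibble(contig = bg_ct, start = as.integer(bg_start),
           end = as.integer(bg_start + sample(50:150, n_bg_frag, replace = TRUE)))
  ) |> dplyr::arrange(.data$contig, .data$start)

  # --- expression -----------------------------------------------------------
  set.seed(spec$seed + 5L)
  tp <- spec$timepoints
  nt <- length(tp)
  x <- seq(-1, 1, length.out = nt)
  shapes <- list(up = x, down = -x, transient = 1 - 2 * abs(x),
                 late = ifelse(x > 0.5, 1, -0.5),
                 early = ifelse(x < -0.5, 1, -0.5))
  shapes <- shapes[seq_len(spec$n_clusters)]
  cluster_of <- sort(rep_len(seq_len(spec$n_clusters), spec$n_genes))
  log_expr <- t(vapply(seq_len(spec$n_genes), function(i) {
    5 + spec$amplitude * shapes[[cluster_of[i]]] +
      stats::rnorm(nt, sd = spec$noise_sd)
  }, numeric(nt)))
  dimnames(log_expr) <- list(ann$transcripts$transcript_id, tp)
  tpm <- expr_tibble(2^log_expr, transform = "tpm")

  # --- DE table -------------------------------------------------------------
  set.seed(spec$seed + 6L)
  n_de <- round(spec$de_fraction * spec$n_genes)
  de_ids <- sort(sample(ann$transcripts$transcript_id, n_de))
  de <- tidyr::expand_grid(transcript_id = ann$transcripts$transcript_id,
                           timepoint = tp[-1]) |>
    dplyr::mutate(
      log_fc = purrr::map2_dbl(.data$transcript_id, .data$timepoint, function(id, t) {
        log_expr[id, t] - log_expr[id, tp[1]]
      }),
      fdr = ifelse(.data$transcript_id %in% de_ids,
                   stats::runif(dplyr::n(), 0.0005, 0.045),
                   stats::runif(dplyr::n(), 0.055, 0.99))
    )
  truth_transcripts <- tibble(
    transcript_id = ann$transcripts$transcript_id,
    gene_id = ann$transcripts$gene_id,
    de = ann$transcripts$transcript_id %in% de_ids,
    cluster = cluster_of
  )

  # --- ontology + annotations ----------------------------------------------
  set.seed(spec$seed + 7L)
  onto <- fixture_ontology()
  leaf_terms <- setdiff(onto$terms$term_id, unique(onto$parents$parent_id))
  regen_term <- "GO:0031099"
  other_leaves <- setdiff(leaf_terms, regen_term)
  gene2go <- dplyr::bind_rows(
    tibble(gene_id = truth_transcripts$gene_id[truth_transcripts$de],
           term_id = regen_term),
    tibble(gene_id = truth_transcripts$gene_id,
           term_id = sample(other_leaves, spec$n_genes, replace = TRUE))
  ) |> dplyr::distinct()

  # --- homology -------------------------------------------------------------
  set.seed(spec$seed + 8L)
  n_hom <- ceiling(0.8 * spec$n_genes)
  hom_targets <- truth_transcripts[sort(sample(spec$n_genes, n_hom)), ]
  homology <- dplyr::bind_rows(
    tibble(source_species = "mus_musculus",
           source_gene_id = sprintf("ENSMUSG%011d", seq_len(n_hom)),
           target_gene_id = hom_targets$gene_id,
           target_transcript_id = hom_targets$transcript_id),
    tibble(source_species = "petromyzon_marinus",
           source_gene_id = sprintf("PMZ%06d", seq_len(n_hom)),
           target_gene_id = rev(hom_targets$gene_id),
           target_transcript_id = rev(hom_targets$transcript_id))
  )
  # a couple of one-to-many homologies (first mouse gene hits two targets)
  if (n_hom >= 2) {
    homology <- dplyr::bind_rows(homology, tibble(
      source_species = "mus_musculus",
      source_gene_id = sprintf("ENSMUSG%011d", 1L),
      target_gene_id = hom_targets$gene_id[2],
      target_transcript_id = hom_targets$transcript_id[2]
    ))
  }

  bundle <- list(
    spec = spec, genome = genome, annotation = ann, peaks = peaks,
    fragments = fragments, tpm = tpm, de = de, ontology = onto,
    gene2go = gene2go, homology = homology,
    ground_truth = list(peaks = truth_peaks, transcripts = truth_transcripts)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(genome = "genome.fa", sizes = "chrom.sizes",
               annotation = "genes.gtf",
               peaks = "peaks.narrowPeak", fragments = "fragments.bed",
               tpm = "tpm.tsv", de = "de.tsv", obo = "go.obo",
               gene2go = "gene2go.tsv", homology = "homology.tsv")
    paths <- setNames(file.path(out_dir, paths), names(paths))
    Biostrings::writeXStringSet(genome, paths[["genome"]])
    readr::write_tsv(tibble(contig = names(clen), length = unname(clen)),
                     paths[["sizes"]], col_names = FALSE, progress = FALSE)
    write_gtf(ann, paths[["annotation"]])
    np <- peaks_full |>
      dplyr::mutate(score = 0L, strand = ".", signal = 1,
                    neglog10_q = .data$neglog10_p) |>
      dplyr::select("contig", "start", "end", "name", "score", "strand",
                    "signal", "neglog10_p", "neglog10_q", "summit_offset")
    readr::write_tsv(np, paths[["peaks"]], col_names = FALSE, progress = FALSE)
    readr::write_tsv(fragments, paths[["fragments"]], col_names = FALSE,
                     progress = FALSE)
    readr::write_tsv(tpm, paths[["tpm"]], progress = FALSE)
    readr::write_tsv(de, paths[["de"]], progress = FALSE)
    write_obo(onto, paths[["obo"]])
    readr::write_tsv(gene2go, paths[["gene2go"]], col_names = FALSE,
                     progress = FALSE)
    readr::write_tsv(homology, paths[["homology"]], progress = FALSE)
    bundle$paths <- paths
  }
  bundle
}

# Small fixed BP ontology (11 terms) with a diamond: GO:0031099 is_a both
# GO:0048589 and GO:0009888, which share the ancestor GO:0032502.
fixture_ontology <- function() {
  terms <- tibble(
    term_id = c("GO:0008150", "GO:0032502", "GO:0009987", "GO:0048589",
                "GO:0009888", "GO:0031099", "GO:0007049", "GO:0006950",
                "GO:0008283", "GO:0016265", "GO:0045087"),
    name = c("biological_process", "developmental process",
             "cellular process", "developmental growth",
             "tissue development", "regeneration", "cell cycle",
             "response to stress", "cell population proliferation", "death",
             "innate immune response"),
    namespace = "BP"
  )
  parents <- tibble(
    term_id = c("GO:0032502", "GO:0009987", "GO:0048589", "GO:0009888",
                "GO:0031099", "GO:0031099", "GO:0007049", "GO:0006950",
                "GO:0008283", "GO:0016265", "GO:0045087"),
    parent_id = c("GO:0008150", "GO:0008150", "GO:0032502", "GO:0032502",
                  "GO:0048589", "GO:0009888", "GO:0009987", "GO:0008150",
                  "GO:0009987", "GO:0008150", "GO:0006950"),
    relation = "is_a"
  )
  ontology(terms, parents)
}

#' Write an ontology as OBO 1.2
#'
#' @param onto An [ontology] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  ns_map <- c(BP = "biological_process", CC = "cellular_component",
              MF = "molecular_function")
  stanzas <- purrr::map_chr(seq_len(nrow(onto$terms)), function(i) {
    t <- onto$terms[i, ]
    par <- onto$parents[onto$parents$term_id == t$term_id, ]
    isa <- par$parent_id[par$relation == "is_a"]
    part <- par$parent_id[par$relation == "part_of"]
    paste(c("[Term]", paste0("id: ", t$term_id), paste0("name: ", t$name),
            paste0("namespace: ", ns_map[[t$namespace]]),
            if (length(isa) > 0) paste0("is_a: ", isa),
            if (length(part) > 0) paste0("relationship: part_of ", part),
            ""), collapse = "\n")
  })
  writeLines(c("format-version: 1.2", "", stanzas), path)
  invisible(path)
}

#' Confusion table of intended vs observed peaklet labels
#'
#' Compares the generator's intended labels with what the pipeline observed.
#' A peak's observed label is the best class among its correspondence
#' records (`proximal` beats `distal`), `background` when its peaklet exists
#' but links to no transcript, and `missed` when no peaklet was derived
#' (expected for `filtered` peaks).
#'
#' @param truth Ground-truth peak tibble (`$ground_truth$peaks` from
#'   [simulate_fixture()]).
#' @param records Correspondence tibble from [build_correspondence()].
#' @param peaklets Peaklet tibble from [derive_peaklets()].
#' @return Tibble `(intended, observed, n)` over the full label grid.
#' @export
truth_report <- function(truth, records, peaklets) {
  pk_id <- paste0(truth$contig, ":", truth$mode)
  best <- records |>
    dplyr::group_by(.data$peaklet_id) |>
    dplyr::summarise(
      observed = ifelse(any(.data$link_class == "proximal"), "proximal", "distal"),
      .groups = "drop"
    )
  observed <- dplyr::case_when(
    pk_id %in% best$peaklet_id ~ best$observed[match(pk_id, best$peaklet_id)],
    pk_id %in% peaklets$peaklet_id ~ "background",
    .default = "missed"
  )
  tidyr::expand_grid(intended = unique(truth$label),
                     observed = c("proximal", "distal", "background", "missed")) |>
    dplyr::left_join(
      tibble(intended = truth$label, observed = observed) |>
        dplyr::count(.data$intended, .data$observed),
      by = c("intended", "observed")
    ) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}
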