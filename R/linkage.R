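# Peaklet-to-gene linkage: proximal/distal classification against transcript
# TSSs, the exonic filter, and the many-to-many correspondence table with its
# CSV/BED/FASTA exports.

# Vectorized classification for aligned peaklet/TSS vectors.
# proximal: the peaklet interval contains the TSS (half-open membership) or
#           the mode is within proximal_bp of the TSS;
# distal:   the mode is within distal_bp and the pair is not proximal;
# none:     otherwise (incl. different contigs, handled by callers).
link_class <- function(start, end, mode, tss, proximal_bp = 1000L,
                       distal_bp = 100000L) {
  stopifnot(proximal_bp > 0, distal_bp > proximal_bp)
  d <- abs(mode - tss)
  contains <- tss >= start & tss < end
  dplyr::case_when(
    contains | d <= proximal_bp ~ "proximal",
    d <= distal_bp ~ "distal",
    .default = "none"
  )
}

#' Classify one peaklet against one gene model
#'
#' A peaklet is *proximal* to a transcript when its interval contains the TSS
#' or its mode lies within `proximal_bp` of the TSS; *distal* when the mode
#' lies within `distal_bp` but the pair is not proximal; `"none"` otherwise
#' (including different contigs). Distances are measured from the peaklet
#' mode; TSS containment uses the full interval with half-open membership.
#'
#' @param peaklet One-row peaklet tibble (columns `contig`, `start`, `end`,
#'   `mode`).
#' @param model One-row transcript tibble (columns `contig`, `tss`).
#' @param proximal_bp Proximal window half-width in bp (default 1000).
#' @param distal_bp Distal window half-width in bp (default 100000).
#' @return `"proximal"`, `"distal"` or `"none"`.
#' @export
classify_link <- function(peaklet, model, proximal_bp = 1000L,
                          distal_bp = 100000L) {
  if (peaklet$contig[1] != model$contig[1]) return("none")
  link_class(peaklet$start[1], peaklet$end[1], peaklet$mode[1], model$tss[1],
             proximal_bp, distal_bp)
}

#' Flag exonic peaklets
#'
#' A peaklet is exonic when it lies within `margin_bp` of an exon (overlap or
#' abutment counts as distance 0) **and** its interval contains no TSS. The
#' test is genome-wide: the merged exon union and the full TSS set, not just
#' the linked gene's. Exonic peaklets can be excluded to enrich for
#' non-genic regulatory chromatin.
#'
#' @param peaklets Peaklet tibble.
#' @param exons Merged exon intervals, e.g. from [exon_union()].
#' @param tss Tibble with columns `contig`, `tss` (all TSS positions), e.g.
#'   from [tss_table()].
#' @param margin_bp Maximum gap to an exon in bp; default 50.
#' @return Logical vector along the peaklet rows.
#' @export
flag_exonic <- function(peaklets, exons, tss, margin_bp = 50L) {
  if (nrow(peaklets) == 0) return(logical(0))
  contigs <- unique(c(peaklets$contig, exons$contig, tss$contig))
  gr_p <- GenomicRanges::GRanges(
    factor(peaklets$contig, levels = contigs),
    IRanges::IRanges(peaklets$start + 1L, peaklets$end)
  )
  near_exon <- rep(FALSE, nrow(peaklets))
  if (nrow(exons) > 0) {
    gr_e <- GenomicRanges::GRanges(
      factor(exons$contig, levels = contigs),
      IRanges::IRanges(exons$start + 1L, exons$end)
    )
    hits <- GenomicRanges::distanceToNearest(gr_p, gr_e)
    near_exon[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(hits)$distance <= margin_bp
  }
  has_tss <- rep(FALSE, nrow(peaklets))
  if (nrow(tss) > 0) {
    gr_t <- GenomicRanges::GRanges(
      factor(tss$contig, levels = contigs),
      IRanges::IRanges(tss$tss + 1L, width = 1L)
    )
    has_tss <- GenomicRanges::countOverlaps(gr_p, gr_t) > 0
  }
  near_exon & !has_tss
}

#' Build the many-to-many peaklet-to-gene correspondence
#'
#' Pairs every peaklet with every transcript whose TSS classifies it as
#' proximal or distal. One peaklet may link to many transcripts and one
#' transcript may receive many peaklets; all pairs are kept. The signed
#' `distance` is `mode - tss`, orientation-adjusted so that positive means
#' downstream of the TSS on the gene's strand.
#'
#' @param peaklets Peaklet tibble from [derive_peaklets()].
#' @param ann An [annotation] object.
#' @param remove_exonic Drop records whose peaklet is exonic-flagged
#'   (see [flag_exonic()]); default `FALSE`.
#' @param gene_subset Optional character vector of gene ids; records are
#'   restricted to these genes (ids absent from the annotation raise a
#'   warning). Use this to focus on, e.g., differentially expressed genes.
#' @param proximal_bp,distal_bp Classification windows; see [classify_link()].
#' @param exonic_margin_bp Margin for the exonic flag; default 50.
#'
#' @return Tibble sorted by (contig, mode, transcript_id) with columns
#'   `peaklet_id`, `contig`, `start`, `end`, `mode`, `transcript_id`,
#'   `gene_id`, `link_class`, `distance`, `exonic`.
#' @export
build_correspondence <- function(peaklets, ann, remove_exonic = FALSE,
                                 gene_subset = NULL, proximal_bp = 1000L,
                                 distal_bp = 100000L, exonic_margin_bp = 50L) {
  stopifnot(inherits(ann, "annotation"))
  tss <- tss_table(ann)
  empty <- tibble(peaklet_id = character(), contig = character(),
                  start = integer(), end = integer(), mode = integer(),
                  transcript_id = character(), gene_id = character(),
                  link_class = character(), distance = integer(),
                  exonic = logical())
  if (!is.null(gene_subset)) {
    absent <- setdiff(gene_subset, unique(tss$gene_id))
    if (length(absent) > 0) {
      warn(paste0("gene_subset id(s) absent from annotation: ",
                  paste(head(absent, 10), collapse = ", ")))
    }
  }
  if (nrow(peaklets) == 0 || nrow(tss) == 0) return(empty)

  # Candidate pairs: TSS within the distal window of the mode or inside the
  # peaklet interval; exact classification is then applied per pair.
  contigs <- unique(c(peaklets$contig, tss$contig))
  win_start <- pmin(peaklets$start, peaklets$mode - distal_bp)
  win_end <- pmax(peaklets$end, peaklets$mode + distal_bp + 1L)
  gr_win <- GenomicRanges::GRanges(
    factor(peaklets$contig, levels = contigs),
    IRanges::IRanges(win_start + 1L, win_end)
  )
  gr_tss <- GenomicRanges::GRanges(
    factor(tss$contig, levels = contigs),
    IRanges::IRanges(tss$tss + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(gr_win, gr_tss)
  if (length(hits) == 0) return(empty)

  pi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  cls <- link_class(peaklets$start[pi], peaklets$end[pi], peaklets$mode[pi],
                    tss$tss[ti], proximal_bp, distal_bp)
  keep <- cls != "none"
  pi <- pi[keep]; ti <- ti[keep]; cls <- cls[keep]

  exonic <- flag_exonic(peaklets, exon_union(ann), tss, exonic_margin_bp)
  rec <- tibble(
    peaklet_id = peaklets$peaklet_id[pi],
    contig = peaklets$contig[pi],
    start = peaklets$start[pi],
    end = peaklets$end[pi],
    mode = peaklets$mode[pi],
    transcript_id = tss$transcript_id[ti],
    gene_id = tss$gene_id[ti],
    link_class = cls,
    distance = as.integer((peaklets$mode[pi] - tss$tss[ti]) *
                            ifelse(tss$strand[ti] == "-", -1L, 1L)),
    exonic = exonic[pi]
  )
  if (remove_exonic) rec <- rec[!rec$exonic, , drop = FALSE]
  if (!is.null(gene_subset)) rec <- rec[rec$gene_id %in% gene_subset, , drop = FALSE]
  dplyr::arrange(rec, .data$contig, .data$mode, .data$transcript_id)
}

#' Export a correspondence table as CSV, BED and FASTA
#'
#' Writes three files under a common prefix: `<prefix>.csv` with one row per
#' (peaklet, transcript) record; `<prefix>.bed` (BED4) and `<prefix>.fa` with
#' one entry per *unique* peaklet (deduplicated across records, named by
#' peaklet id). FASTA sequences are forward-strand genome slices of the
#' peaklet interval, so sequence length equals interval width. The FASTA
#' feeds motif scanners (e.g. the MEME suite) downstream.
#'
#' @param records Correspondence tibble from [build_correspondence()].
#' @param genome Path to a genome FASTA or a [Biostrings::DNAStringSet].
#' @param out_prefix Output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
export_records <- function(records, genome, out_prefix) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  paths <- c(csv = paste0(out_prefix, ".csv"),
             bed = paste0(out_prefix, ".bed"),
             fasta = paste0(out_prefix, ".fa"))
  readr::write_csv(records, paths[["csv"]], progress = FALSE)
  uniq <- records |>
    dplyr::distinct(.data$peaklet_id, .data$contig, .data$start, .data$end) |>
    dplyr::arrange(.data$contig, .data$start, .data$peaklet_id)
  readr::write_tsv(uniq[, c("contig", "start", "end", "peaklet_id")],
                   paths[["bed"]], col_names = FALSE, progress = FALSE)
  if (nrow(uniq) > 0) {
    missing_contig <- setdiff(unique(uniq$contig), names(genome))
    if (length(missing_contig) > 0) {
      abort(paste0("contig(s) missing from genome: ",
                   paste(missing_contig, collapse = ", ")))
    }
    seqs <- Biostrings::subseq(genome[uniq$contig],
                               start = uniq$start + 1L, end = uniq$end)
    names(seqs) <- uniq$peaklet_id
  } else {
    seqs <- Biostrings::DNAStringSet()
  }
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  invisible(paths)
}

#' Re-read an exported correspondence CSV
#'
#' @param path Path to a CSV written by [export_records()].
#' @return Correspondence tibble with the column types of
#'   [build_correspondence()].
#' @export
read_correspondence <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    peaklet_id = "c", contig = "c", start = "i", end = "i",
                    mode = "i", transcript_id = "c", gene_id = "c",
                    link_class = "c", distance = "i", exonic = "l"
                  ))
}
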