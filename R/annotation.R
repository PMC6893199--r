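# Gene-model layer: strand-aware transcript models with TSS coordinates and
# merged exon intervals. All coordinates inside the package are 0-based
# half-open [start, end); GTF/GFF3 1-based closed coordinates exist only at
# the file boundary.

#' Build an annotation object from transcript and exon tables
#'
#' An annotation holds one gene model per transcript: its genomic span, its
#' strand-aware transcription start site (TSS: `start` on `+`, `end - 1` on
#' `-`; unstranded transcripts are treated like `+`), and its exons merged
#' into disjoint sorted intervals. This is the in-memory currency consumed by
#' [build_correspondence()], [tss_table()] and [exon_union()].
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `contig`, `start`, `end` (0-based half-open) and `strand`
#'   (`"+"`, `"-"` or `"*"`).
#' @param exons Optional tibble with columns `transcript_id`, `contig`,
#'   `start`, `end`. Exons are merged per transcript; a transcript with no
#'   exons keeps a span-only model (with a warning).
#' @param contig_lengths Optional named numeric vector of contig lengths.
#'   When absent, lengths are inferred as the maximum feature end per contig.
#'
#' @return An object of class `annotation`: a list with tibbles
#'   `$transcripts` (incl. a `tss` column), `$exons`, and the named vector
#'   `$contig_lengths`.
#' @export
annotation <- function(transcripts, exons = NULL, contig_lengths = NULL) {
  transcripts <- as_tibble(transcripts)
  required <- c("transcript_id", "gene_id", "contig", "start", "end", "strand")
  missing_cols <- setdiff(required, names(transcripts))
  if (length(missing_cols) > 0) {
    abort(paste0("transcripts is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    dups <- unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)])
    abort(paste0("duplicated transcript_id(s): ", paste(head(dups, 5), collapse = ", ")))
  }
  if (any(transcripts$start < 0) || any(transcripts$end <= transcripts$start)) {
    abort("transcript spans must satisfy 0 <= start < end")
  }

  transcripts <- transcripts |>
    dplyr::mutate(
      strand = ifelse(.data$strand %in% c("+", "-"), .data$strand, "*"),
      tss = ifelse(.data$strand == "-", .data$end - 1L, .data$start)
    )

  if (is.null(exons) || nrow(exons) == 0) {
    exons <- tibble(transcript_id = character(), contig = character(),
                    start = integer(), end = integer())
  } else {
    exons <- as_tibble(exons)[, c("transcript_id", "contig", "start", "end")]
    unknown <- setdiff(exons$transcript_id, transcripts$transcript_id)
    if (length(unknown) > 0) {
      abort(paste0("exons reference unknown transcript(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    exons <- merge_intervals_by(exons, c("transcript_id", "contig"))
  }

  no_exons <- setdiff(transcripts$transcript_id, unique(exons$transcript_id))
  if (length(no_exons) > 0 && nrow(transcripts) > 0) {
    warn(paste0(length(no_exons), " transcript(s) lack exons; keeping span-only models: ",
                paste(head(no_exons, 5), collapse = ", ")))
  }

  if (is.null(contig_lengths)) {
    ends <- dplyr::bind_rows(
      transcripts[, c("contig", "end")],
      exons[, c("contig", "end")]
    )
    contig_lengths <- tapply(ends$end, ends$contig, max)
    contig_lengths <- setNames(as.numeric(contig_lengths), names(contig_lengths))
  } else {
    contig_lengths <- setNames(as.numeric(contig_lengths), names(contig_lengths))
    missing_contig <- setdiff(transcripts$contig, names(contig_lengths))
    if (length(missing_contig) > 0) {
      abort(paste0("contig_lengths lacks contig(s): ",
                   paste(missing_contig, collapse = ", ")))
    }
    too_long <- transcripts$end > contig_lengths[transcripts$contig]
    if (any(too_long)) {
      abort(paste0("transcript(s) extend beyond their contig: ",
                   paste(head(transcripts$transcript_id[too_long], 5), collapse = ", ")))
    }
  }

  structure(
    list(transcripts = transcripts, exons = exons, contig_lengths = contig_lengths),
    class = "annotation"
  )
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> ", nrow(x$transcripts), " transcripts, ",
      length(unique(x$transcripts$gene_id)), " genes, ",
      length(x$contig_lengths), " contig(s)\n", sep = "")
  invisible(x)
}

# Merge intervals (0-based half-open tibble with start/end) within groups
# given by `keys`; returns disjoint sorted intervals. Abutting intervals
# ([0,10) + [10,20)) are merged, matching IRanges reduce on closed coords.
merge_intervals_by <- function(df, keys) {
  if (nrow(df) == 0) return(df)
  key <- do.call(paste, c(df[keys], sep = "\r"))
  ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  merged <- IRanges::reduce(S4Vectors::split(ir, factor(key, levels = unique(key))))
  lens <- S4Vectors::elementNROWS(merged)
  flat <- unlist(merged, use.names = FALSE)
  key_rows <- rep(seq_along(lens), lens)
  key_df <- df[match(names(merged), key), keys, drop = FALSE]
  out <- dplyr::bind_cols(
    key_df[key_rows, , drop = FALSE],
    tibble(start = IRanges::start(flat) - 1L, end = IRanges::end(flat))
  )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)), .data$start)
}

#' Parse a GTF or GFF3 annotation into gene models
#'
#' Reads standard Ensembl-style annotation through [rtracklayer::import()] and
#' assembles one strand-aware gene model per transcript. File coordinates
#' (1-based closed) are converted to the package-internal 0-based half-open
#' convention at this boundary. Only transcript and exon features are used;
#' other feature types are ignored.
#'
#' @param path Path to a GTF (attributes `gene_id`/`transcript_id`) or GFF3
#'   (`ID`/`Parent` chains) file.
#' @param dialect `"auto"` (by file extension), `"gtf"` or `"gff3"`.
#' @param contig_lengths Optional path to a `.fai` or `chrom.sizes` file
#'   (contig name and length in the first two columns), or a named numeric
#'   vector. When absent, contig lengths are inferred as the maximum feature
#'   end per contig.
#'
#' @return An [annotation] object.
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3"),
                            contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  if (is.character(contig_lengths) && length(contig_lengths) == 1) {
    sizes <- readr::read_tsv(contig_lengths, col_names = FALSE,
                             show_col_types = FALSE, progress = FALSE)
    contig_lengths <- setNames(as.numeric(sizes[[2]]), as.character(sizes[[1]]))
  }

  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  if (dialect == "gtf") {
    tx_id <- as.character(mc$transcript_id)
    gene_id <- as.character(mc$gene_id)
  } else {
    # GFF3: transcripts carry ID and Parent=gene; exons carry Parent=transcript
    ids <- as.character(mc$ID)
    parent <- vapply(as.list(mc$Parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    is_tx <- type %in% c("mRNA", "transcript")
    tx_gene <- setNames(parent[is_tx], ids[is_tx])
    tx_id <- ifelse(is_tx, ids, parent)
    gene_id <- ifelse(is_tx, parent, unname(tx_gene[parent]))
  }

  keep_tx <- type %in% c("mRNA", "transcript")
  keep_ex <- type == "exon"
  if (!any(keep_tx) && !any(keep_ex)) {
    abort("no transcript or exon features found in annotation")
  }

  to_tbl <- function(idx) {
    tibble(
      transcript_id = tx_id[idx],
      gene_id = gene_id[idx],
      contig = as.character(GenomicRanges::seqnames(gr)[idx]),
      start = GenomicRanges::start(gr)[idx] - 1L,
      end = GenomicRanges::end(gr)[idx],
      strand = as.character(GenomicRanges::strand(gr)[idx])
    )
  }

  exons <- to_tbl(which(keep_ex))
  transcripts <- to_tbl(which(keep_tx))
  if (nrow(transcripts) == 0) {
    # exon-only file: infer spans from exon extents
    transcripts <- exons |>
      dplyr::group_by(.data$transcript_id, .data$gene_id, .data$contig, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  } else {
    # a transcript feature may lack exon children; spans come from the feature
    transcripts <- transcripts[!is.na(transcripts$transcript_id), ]
  }
  transcripts <- transcripts[, c("transcript_id", "gene_id", "contig",
                                 "start", "end", "strand")]

  annotation(transcripts, exons[, c("transcript_id", "contig", "start", "end")],
             contig_lengths = contig_lengths)
}

#' Write an annotation back to GTF
#'
#' Emits one `transcript` line and one `exon` line per (merged) exon for each
#' model, converting internal 0-based half-open coordinates back to the GTF
#' 1-based closed convention. Round-trips through [read_annotation()].
#'
#' @param ann An [annotation] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  fmt_line <- function(contig, feature, start, end, strand, gene_id, transcript_id) {
    sprintf("%s\tpeaklink\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            contig, feature, start + 1L, end, ifelse(strand == "*", ".", strand),
            gene_id, transcript_id)
  }
  tx <- ann$transcripts
  ex <- dplyr::left_join(ann$exons,
                         tx[, c("transcript_id", "gene_id", "strand")],
                         by = "transcript_id")
  lines <- c(
    fmt_line(tx$contig, "transcript", tx$start, tx$end, tx$strand,
             tx$gene_id, tx$transcript_id),
    if (nrow(ex) > 0)
      fmt_line(ex$contig, "exon", ex$start, ex$end, ex$strand,
               ex$gene_id, ex$transcript_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Genome-wide union of exon intervals
#'
#' Merges the exons of all transcripts into disjoint sorted intervals per
#' contig — the exon set used by the exonic-peaklet filter.
#'
#' @param ann An [annotation] object.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open),
#'   sorted by contig then start.
#' @export
exon_union <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  if (nrow(ann$exons) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  merge_intervals_by(ann$exons[, c("contig", "start", "end")], "contig")
}

#' Table of transcription start sites
#'
#' One row per transcript with its strand-aware TSS (0-based coordinate of
#' the first transcribed base), in deterministic (contig, tss, transcript_id)
#' order.
#'
#' @param ann An [annotation] object.
#' @return Tibble with columns `transcript_id`, `gene_id`, `contig`, `tss`,
#'   `strand`.
#' @export
tss_table <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  ann$transcripts |>
    dplyr::select("transcript_id", "gene_id", "contig", "tss", "strand") |>
    dplyr::arrange(.data$contig, .data$tss, .data$transcript_id)
}
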