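# Cross-species projection: map gene lists from a source organism into the
# reference transcript space through a homology table, subset by
# differential-expression status, and tabulate multi-set (Venn) overlaps.

#' Read a homology mapping table
#'
#' Tab-separated with columns `source_species`, `source_gene_id`,
#' `target_gene_id`, `target_transcript_id` (e.g. a BioMart export); one row
#' per homology pair, one-to-many allowed in both directions.
#'
#' @param path Path to the TSV.
#' @return Tibble with those four columns.
#' @export
read_homology <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Tokenize a pasted id list
#'
#' Splits on any mix of whitespace, commas and semicolons (the paste-box
#' contract); case is preserved and empty tokens dropped.
#'
#' @param text Character vector of raw input.
#' @return Character vector of ids.
#' @export
tokenize_ids <- function(text) {
  ids <- unlist(strsplit(paste(text, collapse = "\n"), "[,;[:space:]]+"))
  ids[nzchar(ids)]
}

#' Map source-species gene ids into the reference transcript space
#'
#' Many-to-many expansion: every target transcript of every input gene is
#' returned. Duplicate input ids are counted once; ids with no homology row
#' are returned verbatim in `unmapped`.
#'
#' @param ids Character vector of source gene ids (pre-tokenized or raw —
#'   raw text is passed through [tokenize_ids()]).
#' @param homology Homology tibble from [read_homology()].
#' @param species Source species name; must occur in the table.
#' @return List with `mapped` (tibble `source_gene_id`, `target_gene_id`,
#'   `target_transcript_id`) and `unmapped` (character vector).
#' @export
map_genes <- function(ids, homology, species) {
  available <- unique(homology$source_species)
  if (!species %in% available) {
    abort(paste0("species \"", species, "\" not in homology table; available: ",
                 paste(available, collapse = ", ")))
  }
  ids <- unique(tokenize_ids(ids))
  hom <- homology[homology$source_species == species, , drop = FALSE]
  mapped <- hom[hom$source_gene_id %in% ids,
                c("source_gene_id", "target_gene_id", "target_transcript_id")]
  mapped <- dplyr::distinct(as_tibble(mapped))
  list(mapped = dplyr::arrange(mapped, .data$source_gene_id,
                               .data$target_transcript_id),
       unmapped = setdiff(ids, mapped$source_gene_id))
}

#' Read a differential-expression result table
#'
#' Tab-separated with columns `transcript_id`, `timepoint`, `log_fc`, `fdr`.
#'
#' @param path Path to the TSV.
#' @return Tibble with those columns; `fdr` must lie in \[0, 1\].
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(transcript_id = "c",
                                                timepoint = "c",
                                                log_fc = "d", fdr = "d"))
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE)) {
    abort("fdr values must lie in [0, 1]")
  }
  de
}

#' Subset transcripts by differential-expression status
#'
#' Keeps transcripts with `fdr < fdr_threshold` (strict) at the named
#' timepoint, or at one or more timepoints when `timepoint = "ANY"`.
#'
#' @param transcripts Character vector of transcript ids.
#' @param de DE tibble from [read_de_table()].
#' @param fdr_threshold Strict FDR cutoff; default 0.05.
#' @param timepoint A timepoint label present in `de`, or `"ANY"`.
#' @return Character vector, a subset of `transcripts`.
#' @export
subset_de <- function(transcripts, de, fdr_threshold = 0.05,
                      timepoint = "ANY") {
  if (!identical(timepoint, "ANY")) {
    labels <- unique(de$timepoint)
    if (!timepoint %in% labels) {
      abort(paste0("unknown timepoint \"", timepoint, "\"; available: ",
                   paste(labels, collapse = ", ")))
    }
    de <- de[de$timepoint == timepoint, , drop = FALSE]
  }
  hits <- unique(de$transcript_id[de$fdr < fdr_threshold])
  transcripts[transcripts %in% hits]
}

#' Venn partition of 2-4 named gene sets
#'
#' Counts the elements in every region of the Venn partition: one row per
#' non-empty membership pattern (2^m - 1 rows for m sets), so the counts sum
#' to the size of the union.
#'
#' @param sets Named list of 2 to 4 character vectors over a common id
#'   space.
#' @return Tibble with one logical column per set, a `region` label (set
#'   names joined by `&`), and the element count `n`.
#' @export
overlap_partition <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 4) abort("overlap_partition supports 2 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named")
  }
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, names(sets)))
  patterns <- as.matrix(do.call(expand.grid, rep(list(c(TRUE, FALSE)), m)))
  colnames(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  n <- apply(patterns, 1, function(p) {
    if (length(all_ids) == 0) return(0L)
    sum(apply(membership, 1, function(row) all(row == p)))
  })
  out <- as_tibble(patterns)
  out$region <- apply(patterns, 1, function(p) paste(names(sets)[p], collapse = "&"))
  out$n <- as.integer(n)
  dplyr::arrange(out, dplyr::desc(rowSums(dplyr::across(dplyr::all_of(names(sets))))),
                 .data$region)
}
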