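# Peaklet derivation: significance-filtered fixed-width accessibility windows
# anchored on the mode (summit) of each peak's signal.

#' Read ENCODE narrowPeak peak calls
#'
#' narrowPeak is BED6+4; column 8 holds -log10(p) and column 10 the summit
#' offset from the region start. The p-value is converted back to its linear
#' scale here; a summit offset of -1 (summit not called) becomes `NA`.
#'
#' @param path Path to a narrowPeak file.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, `signal_value`, `p_value`, `q_value`,
#'   `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "signal_value", "neglog10_p", "neglog10_q", "summit_offset")
  df <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(
                          contig = "c", start = "i", end = "i", name = "c",
                          score = "d", strand = "c", signal_value = "d",
                          neglog10_p = "d", neglog10_q = "d", summit_offset = "i"
                        ))
  df |>
    dplyr::mutate(
      p_value = 10^(-.data$neglog10_p),
      q_value = 10^(-.data$neglog10_q),
      summit_offset = ifelse(.data$summit_offset < 0, NA_integer_, .data$summit_offset)
    ) |>
    dplyr::select("contig", "start", "end", "name", "score", "strand",
                  "signal_value", "p_value", "q_value", "summit_offset")
}

#' Derive significance-filtered 500bp peaklets
#'
#' For each peak call passing the p-value filter, a fixed-width window (500bp
#' by default) is anchored on the mode of the peak signal: the window is
#' `[mode - width/2, mode + width/2)`, clipped to the contig. The mode comes
#' from `summit_offset` when present, otherwise from the leftmost argmax of a
#' per-base `signal` vector (a list column of numeric vectors over the
#' region). Peaklet ids are `contig:mode`, unique and deterministic.
#'
#' @param peaks Tibble with columns `contig`, `start`, `end`, `p_value`, and
#'   `summit_offset` and/or `signal`.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param p_threshold Retain only peaks with `p_value < p_threshold`.
#'   Default `1e-10`.
#' @param width Peaklet width in bp; default 500.
#'
#' @return Tibble with columns `peaklet_id`, `contig`, `start`, `end`, `mode`,
#'   `source_p_value`, `truncated` (TRUE when clipped at a contig boundary,
#'   the only case where the width is < `width`).
#' @export
derive_peaklets <- function(peaks, contig_lengths, p_threshold = 1e-10,
                            width = 500L) {
  peaks <- as_tibble(peaks)
  has_summit <- "summit_offset" %in% names(peaks)
  has_signal <- "signal" %in% names(peaks)
  if (!has_summit && !has_signal) {
    abort("peaks need a summit_offset column or a signal list-column")
  }
  missing_contig <- setdiff(unique(peaks$contig), names(contig_lengths))
  if (length(missing_contig) > 0) {
    abort(paste0("contig_lengths lacks contig(s): ",
                 paste(missing_contig, collapse = ", ")))
  }

  kept <- peaks[peaks$p_value < p_threshold, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble(peaklet_id = character(), contig = character(),
                  start = integer(), end = integer(), mode = integer(),
                  source_p_value = double(), truncated = logical()))
  }

  mode <- rep(NA_integer_, nrow(kept))
  if (has_summit) {
    ok <- !is.na(kept$summit_offset)
    bad <- which(ok & (kept$summit_offset < 0 |
                       kept$summit_offset >= kept$end - kept$start))
    if (length(bad) > 0) {
      abort(paste0("summit_offset outside region for peak row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    mode[ok] <- kept$start[ok] + kept$summit_offset[ok]
  }
  if (has_signal) {
    need <- which(is.na(mode))
    for (i in need) {
      sig <- kept$signal[[i]]
      if (is.null(sig) || length(sig) == 0) next
      if (length(sig) != kept$end[i] - kept$start[i]) {
        abort(paste0("signal length does not match region length for peak row ", i))
      }
      mode[i] <- kept$start[i] + which.max(sig) - 1L  # leftmost argmax
    }
  }
  if (anyNA(mode)) {
    bad <- which(is.na(mode))
    lab <- if ("name" %in% names(kept)) kept$name[bad] else as.character(bad)
    abort(paste0("peak(s) with neither summit nor signal: ",
                 paste(head(lab, 5), collapse = ", ")))
  }

  half <- width %/% 2L
  clen <- unname(contig_lengths[kept$contig])
  beyond <- mode >= clen
  if (any(beyond)) {
    abort(paste0("summit position beyond contig end for peak(s) at ",
                 paste(head(paste0(kept$contig[beyond], ":", mode[beyond]), 5),
                       collapse = ", "),
                 "; check that contig lengths match the peak calls"))
  }
  start <- pmax(0L, mode - half)
  end <- pmin(as.integer(clen), mode + (width - half))
  out <- tibble(
    peaklet_id = paste0(kept$contig, ":", mode),
    contig = kept$contig,
    start = as.integer(start),
    end = as.integer(end),
    mode = as.integer(mode),
    source_p_value = kept$p_value,
    truncated = (end - start) < width
  )
  dplyr::arrange(out, .data$contig, .data$mode)
}

#' Count fragments overlapping each peaklet
#'
#' A fragment counts toward a peaklet when the two half-open intervals share
#' at least one base; abutting intervals do not overlap.
#'
#' @param peaklets Peaklet tibble from [derive_peaklets()].
#' @param fragments Tibble of aligned-fragment intervals with columns
#'   `contig`, `start`, `end` (0-based half-open).
#' @return Tibble `(peaklet_id, count)` in peaklet order.
#' @export
count_overlaps <- function(peaklets, fragments) {
  if (nrow(peaklets) == 0) {
    return(tibble(peaklet_id = character(), count = integer()))
  }
  if (nrow(fragments) == 0) {
    return(tibble(peaklet_id = peaklets$peaklet_id,
                  count = integer(nrow(peaklets))))
  }
  contigs <- unique(c(peaklets$contig, fragments$contig))
  gr_p <- GenomicRanges::GRanges(
    factor(peaklets$contig, levels = contigs),
    IRanges::IRanges(peaklets$start + 1L, peaklets$end)
  )
  gr_f <- GenomicRanges::GRanges(
    factor(fragments$contig, levels = contigs),
    IRanges::IRanges(fragments$start + 1L, fragments$end)
  )
  tibble(peaklet_id = peaklets$peaklet_id,
         count = GenomicRanges::countOverlaps(gr_p, gr_f))
}

#' Read a BED file of intervals
#'
#' Minimal BED reader for fragment files and peaklet BED4: the first three
#' columns are `contig`, `start`, `end` (already 0-based half-open in BED),
#' with an optional fourth `name` column.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  as_tibble(df[, seq_len(min(4, ncol(df)))])
}

#' Write peaklets as BED4
#'
#' @param peaklets Peaklet tibble from [derive_peaklets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklets_bed <- function(peaklets, path) {
  readr::write_tsv(peaklets[, c("contig", "start", "end", "peaklet_id")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
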