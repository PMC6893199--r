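# Time-course expression: TPM normalization, log / fold-change / Z-score
# transforms, K-means row clustering with within-cluster hierarchical
# ordering, optional sample clustering, and the heatmap.

# Accepts either a numeric matrix with rownames or a tibble whose first
# column holds transcript ids; returns a named numeric matrix.
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("expression matrix needs rownames")
    return(x)
  }
  x <- as.data.frame(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1]])
  m
}

expr_tibble <- function(m, id_col = "transcript_id", transform = NULL) {
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), as_tibble(m))
  if (!is.null(transform)) attr(out, "transform") <- transform
  out
}

#' Read an expression table
#'
#' First column transcript ids, remaining columns numeric with a header row
#' of time-point labels. Delimiter is inferred from the extension
#' (`.csv` vs tab-separated otherwise).
#'
#' @param path Path to a TSV/CSV expression table.
#' @return Tibble, first column `transcript_id`.
#' @export
read_expression <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv
            else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "transcript_id"
  df
}

#' Transcripts-per-million normalization
#'
#' Per sample: `rate = count / length_kb`, `TPM = rate / sum(rate) * 1e6`, so
#' every non-degenerate column sums to one million. An all-zero column stays
#' all-zero.
#'
#' @param counts Tibble (first column transcript ids) or matrix of
#'   non-negative counts, transcripts x samples.
#' @param lengths Transcript lengths in bp: a named numeric vector or a
#'   two-column tibble (`transcript_id`, `length`). Every transcript must
#'   have a length.
#' @return Tibble of TPM values with a `transform = "tpm"` attribute.
#' @export
compute_tpm <- function(counts, lengths) {
  m <- as_expr_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  }
  missing_len <- setdiff(rownames(m), names(lengths))
  if (length(missing_len) > 0) {
    abort(paste0("length missing for transcript(s): ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  len_kb <- lengths[rownames(m)] / 1000
  if (any(len_kb <= 0)) abort("transcript lengths must be positive")
  if (any(m < 0)) abort("counts must be non-negative")
  rate <- m / len_kb
  col_tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(col_tot > 0, col_tot, 1), "/") * 1e6
  expr_tibble(tpm, transform = "tpm")
}

#' Transform an expression matrix for visualization
#'
#' Starting from TPM values, computes `log_tpm = log2(TPM + pseudocount)`,
#' `log_fc = log2((TPM + pc) / (TPM_baseline + pc))` per row against the
#' named baseline column, or row Z-scores of either log-scale measure
#' (`(x - mean) / sd` across columns; a constant row maps to all zeros).
#'
#' @param tpm Tibble (first column transcript ids) or matrix of TPM values.
#' @param mode One of `"log_tpm"`, `"log_fc"`, `"zscore_log_tpm"`,
#'   `"zscore_log_fc"`.
#' @param baseline Baseline column name, required for the fold-change modes
#'   (e.g. `"0dpi"`).
#' @param pseudocount Added before taking logs; default 1 keeps zeros at
#'   zero.
#' @return Tibble of transformed values; the transform is recorded in the
#'   `transform` attribute.
#' @export
transform_expression <- function(tpm,
                                 mode = c("log_tpm", "log_fc",
                                          "zscore_log_tpm", "zscore_log_fc"),
                                 baseline = NULL, pseudocount = 1) {
  mode <- match.arg(mode)
  m <- as_expr_matrix(tpm)
  needs_fc <- mode %in% c("log_fc", "zscore_log_fc")
  if (needs_fc) {
    if (is.null(baseline)) abort("log fold-change requires a baseline column")
    if (!baseline %in% colnames(m)) {
      abort(paste0("baseline column not found: ", baseline))
    }
    v <- log2(sweep(m + pseudocount, 1, m[, baseline] + pseudocount, "/"))
  } else {
    v <- log2(m + pseudocount)
  }
  if (startsWith(mode, "zscore")) {
    mu <- rowMeans(v)
    s <- apply(v, 1, sd)
    v <- sweep(v, 1, mu, "-")
    v <- sweep(v, 1, ifelse(s > 0, s, 1), "/")
    v[s == 0, ] <- 0
  }
  expr_tibble(v, transform = mode)
}

#' K-means clustering of expression rows
#'
#' Seeded multi-start K-means (`stats::kmeans`, 10 restarts, best
#' within-cluster sum of squares kept), deterministic for a given seed.
#' Cluster labels are relabeled by descending cluster size, ties broken by
#' the first row index in the cluster, so label 1 is always the largest
#' cluster.
#'
#' @param x Expression tibble or matrix.
#' @param k Number of clusters, `1 <= k <= nrow`.
#' @param seed Integer RNG seed.
#' @param nstart Number of random restarts; default 10.
#' @return Tibble `(transcript_id, cluster)` plus attributes `tot_withinss`
#'   and `totss`.
#' @export
kmeans_rows <- function(x, k, seed = 1L, nstart = 10L) {
  m <- as_expr_matrix(x)
  if (k < 1 || k > nrow(m)) {
    abort(paste0("k must be between 1 and the number of rows (", nrow(m), ")"))
  }
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  # deterministic relabeling: by size desc, then first occurrence
  first_idx <- vapply(seq_len(k), function(cl) match(cl, km$cluster), integer(1))
  ord <- order(-tabulate(km$cluster, k), first_idx)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- tibble(transcript_id = rownames(m),
                cluster = relabel[km$cluster])
  attr(out, "tot_withinss") <- km$tot.withinss
  attr(out, "totss") <- km$totss
  out
}

#' Order rows within clusters by hierarchical clustering
#'
#' Within each cluster, rows follow the leaf order of a complete-linkage
#' dendrogram on Euclidean distances; clusters are concatenated in label
#' order, so rows of a cluster stay contiguous.
#'
#' @param x Expression tibble or matrix.
#' @param assignment Tibble `(transcript_id, cluster)` from [kmeans_rows()].
#' @return Character vector of transcript ids in display order.
#' @export
order_within_clusters <- function(x, assignment) {
  m <- as_expr_matrix(x)
  if (!setequal(assignment$transcript_id, rownames(m))) {
    abort("assignment must cover exactly the rows of the matrix")
  }
  unlist(lapply(sort(unique(assignment$cluster)), function(cl) {
    ids <- assignment$transcript_id[assignment$cluster == cl]
    if (length(ids) < 3) return(ids)
    hc <- hclust(dist(m[ids, , drop = FALSE]), method = "complete")
    ids[hc$order]
  }), use.names = FALSE)
}

#' Hierarchically cluster samples (columns)
#'
#' Complete linkage on Euclidean distances between columns; deterministic
#' leaf order.
#'
#' @param x Expression tibble or matrix with at least two value columns.
#' @return Character vector of column labels in dendrogram leaf order.
#' @export
cluster_columns <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2) abort("need at least 2 columns to cluster samples")
  hc <- hclust(dist(t(m)), method = "complete")
  colnames(m)[hc$order]
}

#' Cluster an expression matrix for heatmap display
#'
#' Convenience wrapper tying the pieces together: K-means row clusters
#' ([kmeans_rows()]), within-cluster hierarchical row ordering
#' ([order_within_clusters()]), and optionally hierarchically clustered
#' columns ([cluster_columns()]). The result has [tidy()], [glance()] and
#' [ggplot2::autoplot()] methods and feeds [render_heatmap()].
#'
#' @inheritParams kmeans_rows
#' @param cluster_cols Also reorder columns by hierarchical clustering;
#'   default `FALSE` (time-course order is usually meaningful).
#' @return An object of class `expression_clustering`.
#' @export
cluster_expression <- function(x, k, seed = 1L, nstart = 10L,
                               cluster_cols = FALSE) {
  m <- as_expr_matrix(x)
  assignment <- kmeans_rows(m, k, seed = seed, nstart = nstart)
  row_order <- order_within_clusters(m, assignment)
  col_order <- if (cluster_cols) cluster_columns(m) else colnames(m)
  structure(
    list(values = m, assignment = assignment, row_order = row_order,
         col_order = col_order, k = k, seed = seed,
         transform = attr(x, "transform"),
         tot_withinss = attr(assignment, "tot_withinss"),
         totss = attr(assignment, "totss")),
    class = "expression_clustering"
  )
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat("<expression_clustering> ", nrow(x$values), " transcripts x ",
      ncol(x$values), " time points, k = ", x$k, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname cluster_expression
#' @param x An `expression_clustering` object.
#' @param ... Unused.
#' @export
tidy.expression_clustering <- function(x, ...) {
  x$assignment |>
    dplyr::mutate(order = match(.data$transcript_id, x$row_order)) |>
    dplyr::arrange(.data$order)
}

#' @rdname cluster_expression
#' @export
glance.expression_clustering <- function(x, ...) {
  tibble(n_rows = nrow(x$values), n_cols = ncol(x$values), k = x$k,
         tot_withinss = x$tot_withinss, totss = x$totss,
         prop_within = x$tot_withinss / x$totss)
}

#' @rdname cluster_expression
#' @param object An `expression_clustering` object.
#' @export
autoplot.expression_clustering <- function(object, ...) {
  long <- as_tibble(object$values, rownames = "transcript_id") |>
    tidyr::pivot_longer(-"transcript_id", names_to = "time_point",
                        values_to = "value") |>
    dplyr::left_join(object$assignment, by = "transcript_id") |>
    dplyr::mutate(
      transcript_id = factor(.data$transcript_id, levels = rev(object$row_order)),
      time_point = factor(.data$time_point, levels = object$col_order)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_point, .data$transcript_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  name = object$transform %||% "value") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Render a clustered expression heatmap to file
#'
#' @param clustering An `expression_clustering` object.
#' @param out_path Output image path (`.png` or `.pdf`).
#' @param width,height Device size in inches.
#' @param dpi Resolution for raster output.
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(clustering, out_path, width = 7, height = 7,
                           dpi = 150) {
  if (nrow(clustering$values) == 0 || ncol(clustering$values) == 0) {
    abort("cannot render a heatmap of an empty matrix")
  }
  p <- autoplot.expression_clustering(clustering)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
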