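# GO over-representation: a minimal OBO reader, true-path annotation
# propagation over the is_a/part_of DAG, and one-sided Fisher
# (hypergeometric) tests of a study set against an expressed-gene universe.

#' Build an ontology graph
#'
#' @param terms Tibble with columns `term_id`, `name`, `namespace`
#'   (`"BP"`, `"CC"` or `"MF"`).
#' @param parents Tibble with columns `term_id`, `parent_id`, `relation`
#'   (`"is_a"` or `"part_of"`). The graph must be acyclic and every parent
#'   must be a known term.
#' @return An object of class `ontology`.
#' @export
ontology <- function(terms, parents) {
  terms <- as_tibble(terms)
  parents <- as_tibble(parents)
  unknown <- setdiff(unique(c(parents$term_id, parents$parent_id)), terms$term_id)
  if (length(unknown) > 0) {
    abort(paste0("parent link references unknown term(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  onto <- structure(list(terms = terms, parents = parents), class = "ontology")
  # acyclicity: the full closure must never contain a term as its own ancestor
  anc <- term_ancestors(onto)
  self_anc <- names(anc)[vapply(names(anc), function(t) t %in% anc[[t]], logical(1))]
  if (length(self_anc) > 0) {
    abort(paste0("ontology graph contains a cycle through: ",
                 paste(head(self_anc, 5), collapse = ", ")))
  }
  onto
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", nrow(x$terms), " terms (",
      paste(names(table(x$terms$namespace)), table(x$terms$namespace),
            sep = ":", collapse = ", "),
      "), ", nrow(x$parents), " parent links\n", sep = "")
  invisible(x)
}

#' Read a GO ontology in OBO 1.2 format
#'
#' Parses `[Term]` stanzas: `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of`. Obsolete terms are skipped. Namespaces are
#' abbreviated to BP/CC/MF.
#'
#' @param path Path to an OBO file.
#' @return An [ontology] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) abort("no [Term] stanzas found in OBO file")
  boundaries <- c(stanza_starts, length(lines) + 1L)
  ns_map <- c(biological_process = "BP", cellular_component = "CC",
              molecular_function = "MF")
  terms <- vector("list", length(stanza_starts))
  parents <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    chunk <- lines[(boundaries[i] + 1L):(boundaries[i + 1L] - 1L)]
    chunk <- chunk[cumsum(startsWith(chunk, "[")) == 0]  # stop at next stanza
    field <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      sub("\\s*!.*$", "", sub(paste0("^", key, ":\\s*"), "", v))
    }
    if (any(field("is_obsolete") == "true")) next
    id <- field("id")[1]
    if (is.na(id)) next
    terms[[i]] <- tibble(term_id = id, name = field("name")[1] %||% NA_character_,
                         namespace = unname(ns_map[field("namespace")[1]]))
    isa <- field("is_a")
    rel <- field("relationship")
    part <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of")])
    parents[[i]] <- dplyr::bind_rows(
      if (length(isa) > 0) tibble(term_id = id, parent_id = isa, relation = "is_a"),
      if (length(part) > 0) tibble(term_id = id, parent_id = part,
                                   relation = "part_of")
    )
  }
  ontology(dplyr::bind_rows(terms), dplyr::bind_rows(parents))
}

#' Read gene-to-GO annotations
#'
#' Either a two-column TSV (gene id, term id; a header row is detected by a
#' non-`GO:` second field) or GAF 2.x (`!` comments; columns 2 and 5).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return Tibble `(gene_id, term_id)` of direct annotations, deduplicated.
#' @export
read_gene2go <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble(gene_id = vapply(parts, `[`, "", 2),
                  term_id = vapply(parts, `[`, "", 5))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble(gene_id = vapply(parts, `[`, "", 1),
                  term_id = vapply(parts, `[`, "", 2))
    if (nrow(out) > 0 && !grepl("^GO:", out$term_id[1])) out <- out[-1, ]
  }
  dplyr::distinct(out)
}

# Full ancestor sets (excluding self) for every term, memoized over a
# topological traversal. `relations` restricts which edge types to follow.
term_ancestors <- function(onto, relations = c("is_a", "part_of")) {
  par <- onto$parents[onto$parents$relation %in% relations, , drop = FALSE]
  parent_of <- split(par$parent_id, factor(par$term_id, levels = onto$terms$term_id))
  anc <- new.env(parent = emptyenv())
  get_anc <- function(id, seen = character()) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% seen) return(character())  # cycle guard; validated elsewhere
    ps <- parent_of[[id]]
    res <- unique(c(ps, unlist(lapply(ps, get_anc, seen = c(seen, id)))))
    anc[[id]] <- res
    res
  }
  setNames(lapply(onto$terms$term_id, get_anc), onto$terms$term_id)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Annotation to a term implies annotation to all its ancestors; each gene
#' counts once per term regardless of how many paths lead there. The
#' operation is idempotent.
#'
#' @param gene2go Tibble `(gene_id, term_id)` of direct annotations.
#' @param onto An [ontology] object.
#' @param relations Edge types to follow; default both `is_a` and
#'   `part_of`.
#' @return Tibble `(gene_id, term_id)` of the transitive closure,
#'   deduplicated. Unknown term ids are skipped with a warning.
#' @export
propagate_annotations <- function(gene2go, onto,
                                  relations = c("is_a", "part_of")) {
  gene2go <- as_tibble(gene2go)
  if (nrow(gene2go) == 0) return(tibble(gene_id = character(), term_id = character()))
  unknown <- setdiff(unique(gene2go$term_id), onto$terms$term_id)
  if (length(unknown) > 0) {
    warn(paste0("skipping annotation(s) to unknown term(s): ",
                paste(head(unknown, 5), collapse = ", ")))
    gene2go <- gene2go[!gene2go$term_id %in% unknown, , drop = FALSE]
  }
  anc <- term_ancestors(onto, relations)
  closure <- anc[gene2go$term_id]
  n_anc <- lengths(closure)
  dplyr::distinct(tibble(
    gene_id = c(gene2go$gene_id, rep(gene2go$gene_id, n_anc)),
    term_id = c(gene2go$term_id, unlist(closure, use.names = FALSE))
  ))
}

#' GO term over-representation by Fisher's exact test
#'
#' One-sided over-representation p-value per term from the hypergeometric
#' upper tail: with `N` universe genes of which `K` carry the term, and `n`
#' study genes of which `k` carry it, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`. Terms are reported at raw `p < p_report`
#' (default 5%) with no multiplicity adjustment, sorted by ascending p; an
#' optional Benjamini-Hochberg column can be added. The `elim` method
#' iterates terms bottom-up and removes the genes of significantly enriched
#' children (at `elim_cutoff`) before testing their ancestors, reducing the
#' parent-child redundancy of the classic test.
#'
#' @param study Character vector of study gene ids. Genes outside the
#'   universe are dropped with a warning.
#' @param universe Character vector of background gene ids (e.g. all
#'   expressed genes).
#' @param annotations Propagated annotations from [propagate_annotations()].
#' @param onto Optional [ontology]; supplies term names/namespaces and is
#'   required for `method = "elim"` and for `namespace` filtering.
#' @param p_report Report terms with raw `p < p_report`; default 0.05. Use 1
#'   to keep every tested term.
#' @param method `"classic"` or `"elim"`.
#' @param elim_cutoff Child-significance cutoff for `elim`; default 0.01.
#' @param namespace Optional restriction to `"BP"`, `"CC"` or `"MF"`.
#' @param drop_unannotated Restrict the universe to genes with at least one
#'   annotation (default `TRUE`).
#' @param adjust Add a `p_adjust` (BH) column; default `FALSE`.
#'
#' @return Tibble with columns `term_id`, `name`, `namespace`, `annotated`
#'   (genes with the term in the universe), `significant` (in the study),
#'   `expected`, `p_value`, sorted by `p_value`.
#' @export
fisher_enrichment <- function(study, universe, annotations, onto = NULL,
                              p_report = 0.05,
                              method = c("classic", "elim"),
                              elim_cutoff = 0.01, namespace = NULL,
                              drop_unannotated = TRUE, adjust = FALSE) {
  method <- match.arg(method)
  if (length(universe) == 0) abort("universe is empty")
  universe <- unique(universe)
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " study gene(s) outside the universe dropped: ",
                paste(head(outside, 5), collapse = ", ")))
    study <- intersect(study, universe)
  }
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  if (!is.null(onto)) {
    keep_terms <- onto$terms$term_id
    if (!is.null(namespace)) {
      keep_terms <- onto$terms$term_id[onto$terms$namespace %in% namespace]
    }
    ann <- ann[ann$term_id %in% keep_terms, , drop = FALSE]
  }
  if (drop_unannotated) universe <- intersect(universe, unique(ann$gene_id))
  study <- intersect(study, universe)
  if (length(universe) == 0) abort("universe is empty after annotation filtering")

  genes_by_term <- split(ann$gene_id, ann$term_id)
  N <- length(universe)
  n <- length(study)

  if (method == "classic") {
    rows <- purrr::map(names(genes_by_term), function(t) {
      g <- genes_by_term[[t]]
      K <- length(g)
      k <- sum(g %in% study)
      tibble(term_id = t, annotated = K, significant = k,
             expected = n * K / N,
             p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
    })
    res <- dplyr::bind_rows(rows)
  } else {
    if (is.null(onto)) abort("method = \"elim\" requires an ontology")
    anc <- term_ancestors(onto)
    term_ids <- intersect(onto$terms$term_id, names(genes_by_term))
    # bottom-up: a term is tested before any of its ancestors
    depth <- vapply(anc[term_ids], length, integer(1))
    term_ids <- term_ids[order(-depth)]
    removed <- new.env(parent = emptyenv())
    res <- dplyr::bind_rows(purrr::map(term_ids, function(t) {
      g <- genes_by_term[[t]]
      g_eff <- setdiff(g, removed[[t]])
      K <- length(g_eff)
      k <- sum(g_eff %in% study)
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      if (p < elim_cutoff) {
        for (a in intersect(anc[[t]], names(genes_by_term))) {
          removed[[a]] <- unique(c(removed[[a]], g))
        }
      }
      tibble(term_id = t, annotated = K, significant = k,
             expected = n * K / N, p_value = p)
    }))
  }

  if (!is.null(onto)) {
    res <- dplyr::left_join(res, onto$terms, by = "term_id")
  } else {
    res$name <- NA_character_
    res$namespace <- NA_character_
  }
  res <- res |>
    dplyr::select("term_id", "name", "namespace", "annotated", "significant",
                  "expected", "p_value") |>
    dplyr::arrange(.data$p_value, .data$term_id)
  if (adjust) res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res[res$p_value < p_report, , drop = FALSE]
}
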