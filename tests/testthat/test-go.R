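# Ontology parsing, true-path propagation, and Fisher over-representation.

diamond_ontology <- function() {
  # root <- A; A <- B, A <- C; B <- D, C <- D (two paths from D to A)
  ontology(
    tibble::tibble(term_id = c("GO:R", "GO:A", "GO:B", "GO:C", "GO:D"),
                   name = c("root", "a", "b", "c", "d"), namespace = "BP"),
    tibble::tibble(term_id = c("GO:A", "GO:B", "GO:C", "GO:D", "GO:D"),
                   parent_id = c("GO:R", "GO:A", "GO:A", "GO:B", "GO:C"),
                   relation = "is_a")
  )
}

test_that("OBO round-trip preserves terms and parent links", {
  onto <- diamond_ontology()
  path <- tempfile(fileext = ".obo")
  write_obo(onto, path)
  back <- read_obo(path)
  expect_equal(dplyr::arrange(back$terms, term_id),
               dplyr::arrange(onto$terms, term_id))
  expect_equal(dplyr::arrange(back$parents, term_id, parent_id),
               dplyr::arrange(onto$parents, term_id, parent_id))
})

test_that("ontology constructor rejects cycles and unknown parents", {
  terms <- tibble::tibble(term_id = c("GO:X", "GO:Y"), name = c("x", "y"),
                          namespace = "BP")
  expect_error(ontology(terms, tibble::tibble(term_id = "GO:X",
                                              parent_id = "GO:Z",
                                              relation = "is_a")),
               "unknown")
  expect_error(ontology(terms, tibble::tibble(term_id = c("GO:X", "GO:Y"),
                                              parent_id = c("GO:Y", "GO:X"),
                                              relation = "is_a")),
               "cycle")
})

test_that("propagation follows the true-path rule, counts diamonds once, and is idempotent", {
  onto <- diamond_ontology()
  g2g <- tibble::tibble(gene_id = "gene1", term_id = "GO:D")
  prop <- propagate_annotations(g2g, onto)
  # the leaf annotation implies every ancestor up to the root, each once
  expect_setequal(prop$term_id[prop$gene_id == "gene1"],
                  c("GO:D", "GO:B", "GO:C", "GO:A", "GO:R"))
  expect_equal(nrow(prop), 5)
  prop2 <- propagate_annotations(prop, onto)
  expect_equal(dplyr::arrange(prop2, gene_id, term_id),
               dplyr::arrange(prop, gene_id, term_id))

  expect_equal(nrow(propagate_annotations(
    tibble::tibble(gene_id = character(), term_id = character()), onto)), 0)
  expect_warning(propagate_annotations(
    tibble::tibble(gene_id = "g", term_id = "GO:NOPE"), onto), "unknown")
})

test_that("parent annotation counts are at least child counts after propagation", {
  fx <- simulate_fixture(fixture_spec(seed = 8, n_genes = 20, n_peaks = 10))
  prop <- propagate_annotations(fx$gene2go, fx$ontology)
  counts <- table(prop$term_id)
  for (i in seq_len(nrow(fx$ontology$parents))) {
    child <- fx$ontology$parents$term_id[i]
    parent <- fx$ontology$parents$parent_id[i]
    c_child <- if (child %in% names(counts)) counts[[child]] else 0
    c_parent <- if (parent %in% names(counts)) counts[[parent]] else 0
    expect_gte(c_parent, c_child)
  }
})

test_that("enrichment p-values equal the closed-form hypergeometric tail", {
  # N = 20 universe genes, K = 5 with the term, study of n = 5 hits all of
  # them: p = 1 / C(20,5) = 1/15504
  universe <- paste0("g", 1:20)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:5), term_id = "GO:T"),
    tibble::tibble(gene_id = universe, term_id = "GO:ALL")
  )
  res <- fisher_enrichment(paste0("g", 1:5), universe, ann)
  row <- res[res$term_id == "GO:T", ]
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row$annotated, 5)
  expect_equal(row$significant, 5)
  expect_equal(row$expected, 5 * 5 / 20)

  # study = universe: every term has p = 1, nothing reported at 5%
  expect_equal(nrow(fisher_enrichment(universe, universe, ann)), 0)
  full <- fisher_enrichment(universe, universe, ann, p_report = 1.01)
  expect_true(all(full$p_value == 1))

  # k = 0 terms have p = 1 and are never reported
  res0 <- fisher_enrichment(paste0("g", 6:10), universe, ann)
  expect_false("GO:T" %in% res0$term_id)
})

test_that("enrichment matches exhaustive draw enumeration for small universes", {
  for (seed in 1:5) {
    set.seed(seed)
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    universe <- paste0("g", seq_len(N))
    ann <- tibble::tibble(gene_id = paste0("g", seq_len(K)), term_id = "GO:T")
    study <- sample(universe, n)
    res <- fisher_enrichment(study, universe, ann, p_report = 1.01,
                             drop_unannotated = FALSE)
    k <- sum(paste0("g", seq_len(K)) %in% study)
    expect_equal(res$p_value[res$term_id == "GO:T"],
                 oracle_hyper_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("study genes outside the universe are dropped with a warning; empty universe errors", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"), term_id = "GO:T")
  expect_warning(fisher_enrichment(c("g1", "gX"), c("g1", "g2"), ann,
                                   p_report = 1.01),
                 "outside")
  expect_error(fisher_enrichment("g1", character(), ann), "empty")
})

test_that("elim removes the genes of significant children before testing ancestors", {
  onto <- diamond_ontology()
  universe <- paste0("g", 1:40)
  # all 8 study genes carry the leaf GO:D; its ancestors inherit them
  g2g <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:8), term_id = "GO:D"),
    tibble::tibble(gene_id = universe, term_id = "GO:R")
  )
  prop <- propagate_annotations(g2g, onto)
  study <- paste0("g", 1:8)
  classic <- fisher_enrichment(study, universe, prop, onto, p_report = 1.01)
  elim <- fisher_enrichment(study, universe, prop, onto, p_report = 1.01,
                            method = "elim")
  pc <- function(res, t) res$p_value[res$term_id == t]
  expect_equal(pc(elim, "GO:D"), pc(classic, "GO:D"))  # leaf unaffected
  # parents lose the leaf's genes under elim, so their p-values collapse to 1
  expect_lt(pc(classic, "GO:B"), 1e-6)
  expect_equal(pc(elim, "GO:B"), 1)
  expect_equal(pc(elim, "GO:A"), 1)
})

test_that("gene2go readers handle plain TSV and GAF", {
  tsv <- tempfile(); writeLines(c("g1\tGO:0000001", "g2\tGO:0000002"), tsv)
  expect_equal(read_gene2go(tsv)$gene_id, c("g1", "g2"))
  gaf <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               paste(c("DB", "g1", "SYM", "", "GO:0000001", "REF", "IEA",
                       "", "P", "", "", "protein", "taxon:7955", "20190101",
                       "ZFIN", "", ""), collapse = "\t")), gaf)
  got <- read_gene2go(gaf, format = "gaf")
  expect_equal(got, tibble::tibble(gene_id = "g1", term_id = "GO:0000001"))
})
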