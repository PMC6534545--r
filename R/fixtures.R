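#' Generate a random GO-like DAG with annotations
#'
#' Draws a rooted random DAG shaped like a small slice of the Gene
#' Ontology: terms are laid on a random topological order, the first
#' `n_roots` terms are roots, every later term receives between 1 and
#' `max_parents` parents among the earlier terms, and direct gene
#' annotations are attached leaf-heavily (every leaf gets at least one
#' gene; internal terms are annotated directly with probability
#' `direct_annotation_rate`), mimicking GO's curation pattern. After
#' [propagate_annotations()] the parent-superset invariant holds by
#' construction.
#'
#' @param n_terms,n_genes,n_roots counts (`n_roots >= 1`).
#' @param max_parents maximum parents per non-root term (>= 1).
#' @param direct_annotation_rate probability an internal term carries a
#'   direct annotation.
#' @param genes_per_leaf upper bound on genes drawn per direct
#'   annotation event.
#' @param seed integer seed; the same seed reproduces the same DAG.
#' @return list with `dag` (an [ontology_dag()]), `direct` (a
#'   `direct_annotations`) and `ann` (the propagated `annotation_map`).
#' @export
random_godag <- function(n_terms = 30, n_genes = 100, n_roots = 1,
                         max_parents = 3, direct_annotation_rate = 0.3,
                         genes_per_leaf = 4, seed = 1) {
  stopifnot(n_roots >= 1, max_parents >= 1, n_terms >= n_roots)
  local_seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  genes <- sprintf("g%04d", seq_len(n_genes))
  edges <- list()
  for (i in seq_len(n_terms)) {
    if (i <= n_roots) next
    k <- sample.int(min(max_parents, i - 1L), 1L)
    pa <- if (i - 1L == 1L) ids[1] else ids[sample.int(i - 1L, k)]
    edges[[length(edges) + 1L]] <- data.frame(child = ids[i], parent = pa,
                                              stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(child = character(), parent = character())
  dag <- ontology_dag(ids, edges = edges)

  lf <- leaves(dag)
  pairs <- list()
  draw <- function(term) {
    k <- sample.int(genes_per_leaf, 1L)
    data.frame(gene = genes[sample.int(n_genes, min(k, n_genes))],
               term = term, stringsAsFactors = FALSE)
  }
  for (t in lf) pairs[[length(pairs) + 1L]] <- draw(t)
  for (t in setdiff(ids, lf)) {
    if (stats::runif(1) < direct_annotation_rate) {
      pairs[[length(pairs) + 1L]] <- draw(t)
    }
  }
  direct <- structure(list(pairs = unique(do.call(rbind, pairs)), taxon = NULL),
                      class = "direct_annotations")
  ann <- propagate_annotations(dag, direct)
  list(dag = dag, direct = direct, ann = ann)
}

#' Hand-checkable worked fixtures
#'
#' Small named DAG/annotation bundles with documented expected outputs,
#' used throughout the tests and examples:
#'
#' * `chain3` — chain A <- B <- C (C deepest), one gene at C.
#' * `diamond` — A <- {B, C} <- D with four distinct gene sets;
#'   refinement leaves it untouched.
#' * `refine_chain` — chain A <- B <- C all annotated with the same
#'   single gene; refinement collapses it to the deepest term C.
#' * `buoyant4` — root R (4 genes directly + descendants) with children
#'   A and B, A with child C; node sizes R:5, A:4, C:2, B:1. The
#'   buoyant leveling is [R], [A], [C, B]: B (size 1) may not sit above
#'   C (size 2), unlike in the root-bound layout.
#' * `star` — root R with children c1..c5, each with 3 grandchildren;
#'   exercises the focus expansion cap (full closure = 21 nodes).
#'
#' @return named list of bundles, each with `dag`, `direct`, `ann`.
#' @export
worked_fixtures <- function() {
  bundle <- function(ids, edges, pairs) {
    dag <- ontology_dag(ids, edges = edges)
    direct <- structure(list(pairs = pairs, taxon = NULL),
                        class = "direct_annotations")
    list(dag = dag, direct = direct, ann = propagate_annotations(dag, direct))
  }
  pairs <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(gene = m[, 1], term = m[, 2], stringsAsFactors = FALSE)
  }
  list(
    chain3 = bundle(c("A", "B", "C"),
                    data.frame(child = c("B", "C"), parent = c("A", "B")),
                    pairs("g1", "C")),
    diamond = bundle(c("A", "B", "C", "D"),
                     data.frame(child = c("B", "C", "D", "D"),
                                parent = c("A", "A", "B", "C")),
                     pairs("g1", "D", "g2", "B", "g3", "C", "g4", "A")),
    refine_chain = bundle(c("A", "B", "C"),
                          data.frame(child = c("B", "C"), parent = c("A", "B")),
                          pairs("g1", "C")),
    buoyant4 = bundle(c("R", "A", "B", "C"),
                      data.frame(child = c("A", "B", "C"),
                                 parent = c("R", "R", "A")),
                      pairs("g1", "C", "g2", "C",
                            "g3", "A", "g4", "A",
                            "g5", "B")),
    star = {
      kids <- sprintf("c%d", 1:5)
      gkids <- as.vector(outer(kids, 1:3, function(k, j) paste0(k, "x", j)))
      ids <- c("R", kids, gkids)
      edges <- rbind(data.frame(child = kids, parent = "R"),
                     data.frame(child = gkids,
                                parent = rep(kids, times = 3)))
      bundle(ids, edges,
             data.frame(gene = paste0("g_", gkids), term = gkids,
                        stringsAsFactors = FALSE))
    })
}
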