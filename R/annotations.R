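#' Propagate annotations up the DAG (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor
#' of that term. Propagation computes, for each term, the union of its
#' direct genes with the gene sets of all its descendants, in a single
#' children-first topological pass; unions are order-free so the result
#' does not depend on traversal details. After propagation every parent's
#' gene set is a superset of each child's — the invariant the buoyant
#' layout relies on.
#'
#' @param dag an [ontology_dag()].
#' @param direct a `direct_annotations` object, or a data.frame with
#'   columns `gene` and `term`.
#' @return an `annotation_map`: list with `genes_of` (named list of
#'   character gene vectors, one per term, sorted), and `universe`
#'   (character vector of all annotated genes).
#' @examples
#' dag <- ontology_dag(c("A", "B"), edges = data.frame(child = "B", parent = "A"))
#' ann <- propagate_annotations(dag, data.frame(gene = "g1", term = "B"))
#' ann$genes_of$A  # "g1" by the true-path rule
#' @export
propagate_annotations <- function(dag, direct) {
  pairs <- if (inherits(direct, "direct_annotations")) direct$pairs else direct
  pairs <- unique(data.frame(gene = as.character(pairs$gene),
                             term = as.character(pairs$term),
                             stringsAsFactors = FALSE))
  unknown <- !(pairs$term %in% dag$term_ids)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) to unknown terms skipped")
    pairs <- pairs[!unknown, , drop = FALSE]
  }
  direct_of <- split(pairs$gene, factor(pairs$term, levels = dag$term_ids))
  genes_of <- stats::setNames(vector("list", length(dag$term_ids)), dag$term_ids)
  for (id in topo_children_first(dag)) {
    ch <- children_of(dag, id)
    genes_of[[id]] <- sort(unique(c(direct_of[[id]],
                                    unlist(genes_of[ch], use.names = FALSE))))
  }
  structure(list(genes_of = genes_of,
                 universe = sort(unique(pairs$gene))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  sz <- lengths(x$genes_of)
  cat(sprintf("annotation_map: %d terms, %d genes in universe, sizes %d..%d\n",
              length(x$genes_of), length(x$universe),
              if (length(sz)) min(sz) else 0L, if (length(sz)) max(sz) else 0L))
  invisible(x)
}

#' Node sizes (annotated gene counts)
#'
#' The number of genes annotated to each term after propagation — the
#' "node size" the layouts and filters operate on.
#'
#' @param ann an `annotation_map`.
#' @param terms optional term ids (default: all).
#' @return named integer vector.
#' @export
term_sizes <- function(ann, terms = NULL) {
  sz <- lengths(ann$genes_of)
  if (is.null(terms)) sz else sz[terms]
}

#' Check the annotation superset invariant
#'
#' Verifies that `genes_of(parent)` contains `genes_of(child)` for every
#' edge; returns invisibly or fails naming the offending edge.
#'
#' @param dag an `ontology_dag`.
#' @param ann an `annotation_map` covering `dag`'s terms.
#' @return TRUE, invisibly.
#' @export
check_superset_invariant <- function(dag, ann) {
  for (i in seq_len(nrow(dag$edges))) {
    ch <- dag$edges$child[i]; pa <- dag$edges$parent[i]
    if (!all(ann$genes_of[[ch]] %in% ann$genes_of[[pa]])) {
      stop("annotation superset invariant violated on edge ",
           ch, " -> ", pa)
    }
  }
  invisible(TRUE)
}

# restrict an annotation_map to a term subset (universe unchanged)
restrict_annotation <- function(ann, terms) {
  structure(list(genes_of = ann$genes_of[terms], universe = ann$universe),
            class = "annotation_map")
}

# canonical per-term gene-set keys for fast identity comparison
gene_set_keys <- function(ann) {
  vapply(ann$genes_of, function(g) paste(g, collapse = "\r"), character(1))
}
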