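#' Remove annotation-redundant parents from a DAG
#'
#' A parent annotated to exactly the same gene set as one of its children
#' is redundant for hypothesis testing: its test statistic duplicates the
#' child's and only inflates the multiplicity burden. Refinement
#' iteratively removes such parents, reconnecting each removed parent's
#' parents to its children so that ancestry among surviving terms is
#' preserved. Removal proceeds deepest-parent first (longest root
#' distance, ties by term id) and cascades until no redundant parent
#' remains, so the output is a fixed point: refining twice equals
#' refining once.
#'
#' @param dag an [ontology_dag()].
#' @param ann an `annotation_map` propagated over `dag`.
#' @return the refined `ontology_dag`.
#' @examples
#' dag <- ontology_dag(c("A", "B", "C"),
#'                     edges = data.frame(child = c("B", "C"), parent = c("A", "B")))
#' ann <- propagate_annotations(dag, data.frame(gene = "g1", term = "C"))
#' refine_dag(dag, ann)$term_ids  # only "C" survives
#' @export
refine_dag <- function(dag, ann) {
  keys <- gene_set_keys(ann)
  repeat {
    if (!nrow(dag$edges)) break
    redundant <- unique(dag$edges$parent[keys[dag$edges$parent] ==
                                         keys[dag$edges$child]])
    if (!length(redundant)) break
    depth <- root_bound_levels(dag)$level_of
    redundant <- redundant[order(-depth[redundant], redundant)]
    dag <- drop_with_reconnect(dag, redundant[1])
  }
  dag
}

#' Filter a DAG by node size
#'
#' Keeps the terms whose propagated annotation count lies in
#' `[min_size, max_size]`, removing overly generic or overly specific
#' terms. Removed terms are bridged: each removed term's parents are
#' connected to its children, so ancestry among the kept terms is
#' preserved just as in [refine_dag()].
#'
#' @param dag an [ontology_dag()].
#' @param ann an `annotation_map` over `dag`.
#' @param min_size,max_size inclusive bounds on the annotated gene count
#'   (`max_size = Inf` for no upper bound).
#' @return the filtered `ontology_dag`.
#' @export
filter_by_size <- function(dag, ann, min_size = 0, max_size = Inf) {
  stopifnot(min_size >= 0, min_size <= max_size)
  sz <- term_sizes(ann, dag$term_ids)
  drop <- dag$term_ids[sz < min_size | sz > max_size]
  for (term in drop) dag <- drop_with_reconnect(dag, term)
  dag
}
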