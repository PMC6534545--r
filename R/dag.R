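#' Construct an ontology DAG
#'
#' The central graph container: terms as nodes, directed child-to-parent
#' edges of the "is a" kind. Edges always point rootward, so a term's
#' ancestors are reached by following edges and its descendants by walking
#' them backwards. The constructor validates acyclicity and referential
#' integrity.
#'
#' @param term_ids character vector of unique term identifiers.
#' @param term_names optional named character vector (names = term ids)
#'   of human-readable labels; missing labels default to the id.
#' @param edges two-column data.frame (or matrix) with columns `child`
#'   and `parent`, each row one child-to-parent edge. May have zero rows.
#' @return an object of class `ontology_dag` with components `term_ids`,
#'   `term_names`, and `edges` (a data.frame of character columns
#'   `child`, `parent`).
#' @examples
#' dag <- ontology_dag(c("A", "B", "C"),
#'                     edges = data.frame(child = c("B", "C"),
#'                                        parent = c("A", "B")))
#' roots(dag)
#' @export
ontology_dag <- function(term_ids, term_names = NULL, edges = NULL) {
  term_ids <- as.character(term_ids)
  if (anyDuplicated(term_ids)) {
    stop("duplicate term ids: ",
         paste(unique(term_ids[duplicated(term_ids)]), collapse = ", "))
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges[["child"]]),
                        parent = as.character(edges[["parent"]]),
                        stringsAsFactors = FALSE)
    bad <- !(edges$child %in% term_ids) | !(edges$parent %in% term_ids)
    if (any(bad)) {
      stop("edges reference unknown terms: ",
           paste(unique(c(edges$child[bad], edges$parent[bad])), collapse = ", "))
    }
    if (any(edges$child == edges$parent)) stop("self-loop edge detected")
    edges <- unique(edges)
    rownames(edges) <- NULL
  }
  nm <- stats::setNames(term_ids, term_ids)
  if (!is.null(term_names)) {
    known <- intersect(names(term_names), term_ids)
    nm[known] <- as.character(term_names[known])
  }
  dag <- structure(list(term_ids = term_ids, term_names = nm, edges = edges),
                   class = "ontology_dag")
  if (length(term_ids) && nrow(edges)) {
    g <- as_igraph(dag)
    if (!igraph::is_dag(g)) stop("relations contain a cycle; not a DAG")
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d edges, %d root(s)\n",
              length(x$term_ids), nrow(x$edges), length(roots(x))))
  invisible(x)
}

#' @export
summary.ontology_dag <- function(object, ...) {
  lv <- root_bound_levels(object)
  cat(sprintf("ontology_dag: %d terms, %d edges\n",
              length(object$term_ids), nrow(object$edges)))
  cat(sprintf("roots: %s\n", paste(roots(object), collapse = ", ")))
  cat(sprintf("depth (longest root path): %d\n",
              if (length(lv$levels)) length(lv$levels) - 1L else 0L))
  invisible(object)
}

# child -> parent directed igraph; vertex order follows term_ids
as_igraph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                vertices = data.frame(name = dag$term_ids))
}

#' Roots and leaves of a DAG
#'
#' Roots are terms with no parent; leaves terms with no child.
#' @param dag an `ontology_dag`.
#' @return character vector of term ids.
#' @export
roots <- function(dag) {
  setdiff(dag$term_ids, dag$edges$child)
}

#' @rdname roots
#' @export
leaves <- function(dag) {
  setdiff(dag$term_ids, dag$edges$parent)
}

#' Parents or children of a term
#' @param dag an `ontology_dag`.
#' @param term a term id present in `dag`.
#' @return character vector of immediate parents (resp. children).
#' @export
parents_of <- function(dag, term) {
  dag$edges$parent[dag$edges$child == term]
}

#' @rdname parents_of
#' @export
children_of <- function(dag, term) {
  dag$edges$child[dag$edges$parent == term]
}

#' Ancestors and descendants of a term
#'
#' Reachability along the child-to-parent edges, including the term itself
#' (a term counts among its own ancestors and descendants, matching the
#' convention used for highlight counting in silhouettes).
#'
#' @param dag an `ontology_dag`.
#' @param term a term id present in `dag`.
#' @return character vector of term ids.
#' @export
ancestors_of <- function(dag, term) {
  if (!term %in% dag$term_ids) stop("unknown term: ", term)
  if (!nrow(dag$edges)) return(term)
  g <- as_igraph(dag)
  names(igraph::subcomponent(g, term, mode = "out"))
}

#' @rdname ancestors_of
#' @export
descendants_of <- function(dag, term) {
  if (!term %in% dag$term_ids) stop("unknown term: ", term)
  if (!nrow(dag$edges)) return(term)
  g <- as_igraph(dag)
  names(igraph::subcomponent(g, term, mode = "in"))
}

# Topological order of term ids: every child precedes its parents.
# Kahn-style via igraph; deterministic for a given dag.
topo_children_first <- function(dag) {
  if (!nrow(dag$edges)) return(dag$term_ids)
  g <- as_igraph(dag)
  names(igraph::topo_sort(g, mode = "out"))
}

# All-nodes strict descendant index sets, as a named list of character
# vectors. DP over a parents-before-processed order (children last), so a
# single pass suffices; intended for the small graphs this package handles.
strict_descendants <- function(dag) {
  ids <- dag$term_ids
  desc <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) desc[[id]] <- character()
  # children-first order: when we reach a node all its children are done
  for (id in topo_children_first(dag)) {
    ch <- children_of(dag, id)
    if (length(ch)) {
      desc[[id]] <- unique(c(ch, unlist(desc[ch], use.names = FALSE)))
    }
  }
  desc
}

# Induce the subgraph on a set of term ids (edges with both endpoints kept).
induce_on <- function(dag, keep) {
  keep <- intersect(dag$term_ids, keep)  # preserve original term order
  e <- dag$edges[dag$edges$child %in% keep & dag$edges$parent %in% keep, ,
                 drop = FALSE]
  ontology_dag(keep, dag$term_names[keep], e)
}

# Remove one term, reconnecting each of its parents to each of its
# children; shared by refinement and size filtering so ancestry among
# surviving terms is preserved.
drop_with_reconnect <- function(dag, term) {
  pa <- parents_of(dag, term)
  ch <- children_of(dag, term)
  e <- dag$edges[dag$edges$child != term & dag$edges$parent != term, ,
                 drop = FALSE]
  if (length(pa) && length(ch)) {
    e <- rbind(e, expand.grid(child = ch, parent = pa,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
  }
  keep <- setdiff(dag$term_ids, term)
  ontology_dag(keep, dag$term_names[keep], unique(e))
}
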