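#' Anchor specifications
#'
#' An anchor is a term chosen to select a subDAG, playing one of three
#' roles: a `root` anchor contributes its descendants, a `leaf` anchor
#' its ancestors, a `waypoint` anchor both. Anchors can also be written
#' compactly as `"TERM:ROLE"` tokens (the command-line form).
#'
#' @param terms character vector of term ids, or `"TERM:ROLE"` tokens
#'   when `roles` is missing.
#' @param roles character vector (recycled) of roles, each one of
#'   `"root"`, `"leaf"`, `"waypoint"`.
#' @return an `anchor_spec` data.frame with columns `term` and `role`.
#' @examples
#' anchor_spec(c("GO:1", "GO:2"), c("root", "leaf"))
#' anchor_spec(c("GO:1:waypoint"))
#' @export
anchor_spec <- function(terms, roles = NULL) {
  if (is.null(roles)) {
    parts <- regmatches(terms, regexpr(":(root|leaf|waypoint)$", terms))
    if (length(parts) != length(terms)) {
      stop("anchor tokens must end in :root, :leaf or :waypoint")
    }
    roles <- sub("^:", "", parts)
    terms <- sub(":(root|leaf|waypoint)$", "", terms)
  }
  roles <- rep_len(as.character(roles), length(terms))
  bad <- !roles %in% c("root", "leaf", "waypoint")
  if (any(bad)) stop("unknown anchor role: ", paste(unique(roles[bad]), collapse = ", "))
  structure(data.frame(term = as.character(terms), role = roles,
                       stringsAsFactors = FALSE),
            class = c("anchor_spec", "data.frame"))
}

#' Induce a context subDAG from anchors
#'
#' The context graph is the reference DAG narrowed to the terms
#' semantically related to the anchors: the union, over anchors, of
#' descendants (root role), ancestors (leaf role) or both (waypoint),
#' each set including the anchor itself. Edges are those of the input
#' DAG with both endpoints retained.
#'
#' @param dag an [ontology_dag()].
#' @param spec an [anchor_spec()].
#' @return an `ontology_dag`; the anchors are kept in the
#'   `"anchors"` attribute so that focus extraction can default to them.
#' @export
induce_context <- function(dag, spec) {
  missing <- setdiff(spec$term, dag$term_ids)
  if (length(missing)) stop("unknown anchor term(s): ", paste(missing, collapse = ", "))
  keep <- character()
  for (i in seq_len(nrow(spec))) {
    t <- spec$term[i]
    keep <- c(keep, switch(spec$role[i],
      root = descendants_of(dag, t),
      leaf = ancestors_of(dag, t),
      waypoint = c(ancestors_of(dag, t), descendants_of(dag, t))))
  }
  ctx <- induce_on(dag, unique(keep))
  attr(ctx, "anchors") <- spec
  ctx
}

#' Extract a focus subDAG from a context graph
#'
#' The focus graph is the small subDAG actually drawn in detail. Focus
#' anchors take role `waypoint` or `leaf`; when no anchors are given the
#' context anchors are reused in leaf role. The focus always contains
#' all context-internal ancestors of the anchors. A waypoint anchor
#' additionally contributes its immediate children, and its full
#' descendant closure only when that closure is small: at most
#' `expansion_cap` terms. To keep the display tractable the number of
#' anchors is capped at `max_anchors`.
#'
#' @param context an `ontology_dag`, typically from [induce_context()].
#' @param focus_anchors an [anchor_spec()] with roles in
#'   `{waypoint, leaf}`, or NULL to default to the context anchors as
#'   leaf anchors.
#' @param max_anchors maximum number of focus anchors accepted.
#' @param expansion_cap node-count threshold above which a waypoint
#'   anchor's descendants beyond its immediate children are not shown.
#' @return an `ontology_dag` with the focus anchors in the `"anchors"`
#'   attribute.
#' @export
focus_subdag <- function(context, focus_anchors = NULL, max_anchors = 10,
                         expansion_cap = 50) {
  if (is.null(focus_anchors)) {
    ctx_anchors <- attr(context, "anchors")
    if (is.null(ctx_anchors)) stop("no focus anchors given and context has none")
    focus_anchors <- anchor_spec(ctx_anchors$term, "leaf")
  }
  if (any(focus_anchors$role == "root")) {
    stop("focus anchors must have role waypoint or leaf")
  }
  if (nrow(focus_anchors) > max_anchors) {
    stop("too many focus anchors: ", nrow(focus_anchors),
         " given, at most ", max_anchors, " allowed")
  }
  outside <- setdiff(focus_anchors$term, context$term_ids)
  if (length(outside)) {
    stop("focus anchor(s) outside the context: ", paste(outside, collapse = ", "))
  }
  keep <- character()
  for (i in seq_len(nrow(focus_anchors))) {
    t <- focus_anchors$term[i]
    keep <- c(keep, ancestors_of(context, t))
    if (focus_anchors$role[i] == "waypoint") {
      closure <- descendants_of(context, t)
      keep <- c(keep, if (length(closure) <= expansion_cap) closure
                      else c(t, children_of(context, t)))
    }
  }
  foc <- induce_on(context, unique(keep))
  attr(foc, "anchors") <- focus_anchors
  foc
}
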