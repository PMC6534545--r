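#' Leveled layouts of an ontology DAG
#'
#' A leveled layout assigns every term to a horizontal level (0 at the
#' top, where the roots sit) such that each parent lies strictly above
#' all of its children (the topological constraint). Three levelings are
#' provided:
#'
#' * `root_bound_levels()`: level = longest path length from any root.
#' * `leaf_bound_levels()`: longest distance to the leaves, re-indexed so
#'   leaves sit at the bottom and 0 stays at the top.
#' * [buoyant_levels()]: additionally satisfies the descending
#'   node-size constraint — a term annotated with fewer genes is never
#'   placed above a term with more.
#'
#' @param dag an [ontology_dag()] (acyclic by construction).
#' @return a `leveled_layout`: list with `level_of` (named integer,
#'   0-based), `levels` (list of character vectors, one per level, top
#'   first) and `kind`.
#' @examples
#' dag <- ontology_dag(c("A", "B", "C"),
#'                     edges = data.frame(child = c("B", "C"), parent = c("A", "B")))
#' root_bound_levels(dag)$level_of
#' @export
root_bound_levels <- function(dag) {
  lv <- stats::setNames(integer(length(dag$term_ids)), dag$term_ids)
  # parents-first order: reverse of the children-first topological order
  for (id in rev(topo_children_first(dag))) {
    pa <- parents_of(dag, id)
    lv[id] <- if (length(pa)) max(lv[pa]) + 1L else 0L
  }
  new_leveled_layout(lv, "root_bound")
}

#' @rdname root_bound_levels
#' @export
leaf_bound_levels <- function(dag) {
  d <- stats::setNames(integer(length(dag$term_ids)), dag$term_ids)
  for (id in topo_children_first(dag)) {
    ch <- children_of(dag, id)
    d[id] <- if (length(ch)) max(d[ch]) + 1L else 0L
  }
  lv <- if (length(d)) max(d) - d else d
  new_leveled_layout(lv, "leaf_bound")
}

new_leveled_layout <- function(level_of, kind, order_hint = NULL) {
  lv_ids <- if (is.null(order_hint)) names(sort(level_of)) else order_hint
  levels <- split(lv_ids, level_of[lv_ids])
  levels <- unname(levels[order(as.integer(names(levels)))])
  structure(list(level_of = level_of, levels = levels, kind = kind),
            class = "leveled_layout")
}

#' @export
print.leveled_layout <- function(x, ...) {
  cat(sprintf("leveled_layout (%s): %d terms in %d levels\n",
              x$kind, length(x$level_of), length(x$levels)))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  level %d: %s\n", i - 1L,
                paste(x$levels[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Buoyant leveling by the bubble-float algorithm
#'
#' The buoyant layout satisfies two constraints simultaneously: parents
#' strictly above children (topological constraint), and no term with a
#' smaller annotation count ever above a term with a larger one
#' (descending node-size constraint). Under the true-path superset
#' invariant such a leveling always exists.
#'
#' The bubble-float algorithm first sorts all terms lexicographically by
#' (1) node size, descending, (2) longest distance to the root,
#' ascending, with ties broken by term id. It then walks this order from
#' the bottom, greedily floating each term into the current bottom-most
#' layer whenever no strict descendant of the term is already in that
#' layer and, if `max_span` is set, the layer's size range stays within
#' `max_span`; otherwise the layer is closed and a new one started
#' above. Levels are therefore contiguous blocks of the initialization
#' order, and the level count is never smaller than the root-bound
#' layout's.
#'
#' @param dag an [ontology_dag()].
#' @param ann an `annotation_map` satisfying the superset invariant over
#'   `dag` (checked; violation is an error naming the offending edge).
#' @param max_span optional non-negative number: maximum allowed
#'   difference between the largest and smallest node size within one
#'   level. `NULL` (default) disables the cap.
#' @return a `leveled_layout` with `kind = "buoyant"`.
#' @export
buoyant_levels <- function(dag, ann, max_span = NULL) {
  check_superset_invariant(dag, ann)
  sz <- term_sizes(ann, dag$term_ids)
  depth <- root_bound_levels(dag)$level_of
  init <- dag$term_ids[order(-sz[dag$term_ids], depth[dag$term_ids],
                             dag$term_ids)]
  desc <- strict_descendants(dag)

  blocks <- list()                 # built bottom-up
  layer <- character()
  layer_min <- Inf; layer_max <- -Inf
  for (id in rev(init)) {
    span_ok <- is.null(max_span) ||
      (max(layer_max, sz[[id]]) - min(layer_min, sz[[id]])) <= max_span
    if (length(layer) && (!span_ok || any(desc[[id]] %in% layer))) {
      blocks[[length(blocks) + 1L]] <- layer
      layer <- character()
      layer_min <- Inf; layer_max <- -Inf
    }
    layer <- c(id, layer)          # keep initialization order within layer
    layer_min <- min(layer_min, sz[[id]])
    layer_max <- max(layer_max, sz[[id]])
  }
  if (length(layer)) blocks[[length(blocks) + 1L]] <- layer
  blocks <- rev(blocks)            # index 0 at the top

  lv <- stats::setNames(rep(seq_along(blocks) - 1L, lengths(blocks)),
                        unlist(blocks))
  lv <- lv[dag$term_ids]
  out <- new_leveled_layout(lv, "buoyant", order_hint = unlist(blocks))
  out
}

#' Order nodes within levels
#'
#' Determines the left-to-right order of terms on each level of a
#' leveled layout. Anchors that share a non-root common ancestor are
#' grouped, together with the nodes that are exclusively related
#' (ancestor or descendant) to a single group; groups are kept
#' contiguous on every level. The residual ordering freedom is resolved
#' by iterative barycenter sweeps (downward passes using parent
#' positions, upward passes using child positions, four rounds), the
#' classical Sugiyama crossing-reduction heuristic; exact bipartite
#' crossing minimization is NP-hard. Ties are broken by term id, so the
#' result is deterministic.
#'
#' @param dag an [ontology_dag()] covered by `layout`.
#' @param layout a `leveled_layout` over `dag`.
#' @param anchors optional [anchor_spec()] whose terms induce the
#'   semantic groups; NULL for plain barycenter ordering.
#' @return a `leveled_layout` with the same `level_of` but reordered
#'   `levels`, plus a `group_of` component (named integer, 0 =
#'   ungrouped).
#' @export
order_within_levels <- function(dag, layout, anchors = NULL) {
  ids <- dag$term_ids
  group_of <- stats::setNames(rep(0L, length(ids)), ids)
  if (!is.null(anchors) && nrow(anchors)) {
    group_of <- anchor_groups(dag, anchors$term)
  }

  # positions: start from current level order, ties by id
  levels <- lapply(layout$levels, function(l) l[order(l)])
  pos <- level_positions(levels)

  for (sweep in seq_len(4L)) {
    for (i in seq_along(levels)[-1]) {              # downward: use parents
      levels[[i]] <- reorder_level(levels[[i]], dag, pos, group_of, "parents")
      pos <- level_positions(levels)
    }
    for (i in rev(seq_along(levels)[-length(levels)])) {  # upward: children
      levels[[i]] <- reorder_level(levels[[i]], dag, pos, group_of, "children")
      pos <- level_positions(levels)
    }
  }
  structure(list(level_of = layout$level_of, levels = levels,
                 kind = layout$kind, group_of = group_of),
            class = "leveled_layout")
}

level_positions <- function(levels) {
  pos <- integer()
  for (l in levels) pos[l] <- seq_along(l)
  pos
}

reorder_level <- function(nodes, dag, pos, group_of, side) {
  if (length(nodes) <= 1L) return(nodes)
  bary <- vapply(nodes, function(id) {
    nb <- if (side == "parents") parents_of(dag, id) else children_of(dag, id)
    nb <- nb[!is.na(pos[nb])]
    if (length(nb)) mean(pos[nb]) else pos[[id]]
  }, numeric(1))
  grp <- group_of[nodes]
  # group barycenter keeps members of one group contiguous
  gbary <- stats::ave(bary, grp, FUN = mean)
  gbary[grp == 0L] <- bary[grp == 0L]     # ungrouped nodes move freely
  nodes[order(gbary, grp, bary, nodes)]
}

# union-find grouping of anchors sharing a non-root common ancestor,
# then exclusive relatives join the group of their unique anchor set
anchor_groups <- function(dag, anchor_terms) {
  ids <- dag$term_ids
  rt <- roots(dag)
  anc <- lapply(stats::setNames(anchor_terms, anchor_terms),
                function(t) setdiff(ancestors_of(dag, t), rt))
  n <- length(anchor_terms)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (length(intersect(anc[[i]], anc[[j]]))) {
        comp[find(j)] <- find(i)
      }
    }
  }
  grp_of_anchor <- vapply(seq_len(n), find, integer(1))
  grp_of_anchor <- match(grp_of_anchor, unique(grp_of_anchor))

  group_of <- stats::setNames(rep(0L, length(ids)), ids)
  group_of[anchor_terms] <- grp_of_anchor
  # exclusive ancestors/descendants: related to exactly one group
  for (id in setdiff(ids, anchor_terms)) {
    rel <- unique(c(ancestors_of(dag, id), descendants_of(dag, id)))
    gs <- unique(group_of[intersect(rel, anchor_terms)])
    gs <- gs[gs != 0L]
    if (length(gs) == 1L) group_of[id] <- gs
  }
  group_of
}

#' Count edge crossings of a leveled layout
#'
#' The number of pairwise edge crossings between consecutive levels,
#' the quantity the barycenter sweeps heuristically reduce.
#'
#' @param dag an [ontology_dag()].
#' @param layout a `leveled_layout` over `dag`.
#' @return integer crossing count.
#' @export
count_crossings <- function(dag, layout) {
  pos <- level_positions(layout$levels)
  lv <- layout$level_of
  total <- 0L
  e <- dag$edges[abs(lv[dag$edges$child] - lv[dag$edges$parent]) == 1L, ,
                 drop = FALSE]
  between <- pmin(lv[e$child], lv[e$parent])
  for (b in unique(between)) {
    sub <- e[between == b, , drop = FALSE]
    top <- ifelse(lv[sub$child] == b, sub$child, sub$parent)
    bot <- ifelse(lv[sub$child] == b, sub$parent, sub$child)
    m <- nrow(sub)
    if (m > 1L) for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if ((pos[top[i]] - pos[top[j]]) * (pos[bot[i]] - pos[bot[j]]) < 0) {
        total <- total + 1L
      }
    }
  }
  total
}

#' Context silhouette
#'
#' The context graph is summarized as a bar chart: the number of terms
#' on each level of the reference DAG, with the subset related to a
#' highlight set (its ancestors and descendants, including the
#' highlighted terms themselves) counted separately.
#'
#' @param context an [ontology_dag()].
#' @param layout a `leveled_layout` over `context`.
#' @param highlight character vector of highlighted term ids (subset of
#'   the context's terms).
#' @return a `context_silhouette`: list with `total_per_level` and
#'   `highlighted_per_level` (integer vectors, one entry per level).
#' @export
context_silhouette <- function(context, layout, highlight = character()) {
  stopifnot(all(highlight %in% context$term_ids))
  related <- unique(unlist(lapply(highlight, function(t)
    c(ancestors_of(context, t), descendants_of(context, t)))))
  nlev <- length(layout$levels)
  total <- vapply(layout$levels, length, integer(1))
  hi <- vapply(layout$levels, function(l) sum(l %in% related), integer(1))
  structure(list(total_per_level = total, highlighted_per_level = hi),
            class = "context_silhouette")
}

#' @export
print.context_silhouette <- function(x, ...) {
  cat("context_silhouette:\n")
  for (i in seq_along(x$total_per_level)) {
    cat(sprintf("  level %d: %d total, %d highlighted\n", i - 1L,
                x$total_per_level[i], x$highlighted_per_level[i]))
  }
  invisible(x)
}

#' @param x a `context_silhouette`.
#' @param ... passed to [graphics::barplot()].
#' @rdname context_silhouette
#' @export
plot.context_silhouette <- function(x, ...) {
  m <- rbind(highlighted = x$highlighted_per_level,
             other = x$total_per_level - x$highlighted_per_level)
  graphics::barplot(m, names.arg = seq_along(x$total_per_level) - 1L,
                    horiz = TRUE, col = c("#6a51a3", "grey80"),
                    xlab = "terms per level", ylab = "level", ...)
  invisible(x)
}

#' Binder ordering of terms
#'
#' Arranges terms linearly by descending node size — the order the
#' buoyant layout induces — with ties broken by buoyant level (shallower
#' first) then term id, and records where the buoyant level changes so a
#' rendering can alternate background bands per level.
#'
#' @param terms character vector of term ids (subset of the layout).
#' @param ann an `annotation_map`.
#' @param layout a buoyant `leveled_layout` covering `terms`.
#' @return a `binder_order`: list with `sequence` (ordered term ids),
#'   `level_of` (named integer for the sequence) and `band_starts`
#'   (integer indices in `sequence` where a new level begins).
#' @export
binder_order <- function(terms, ann, layout) {
  stopifnot(all(terms %in% names(layout$level_of)))
  sz <- term_sizes(ann, terms)
  lv <- layout$level_of[terms]
  sequence <- terms[order(-sz, lv, terms)]
  lv_seq <- layout$level_of[sequence]
  band_starts <- unname(which(c(TRUE, diff(lv_seq) != 0)))
  structure(list(sequence = sequence, level_of = lv_seq,
                 band_starts = band_starts),
            class = "binder_order")
}

#' @export
print.binder_order <- function(x, ...) {
  cat(sprintf("binder_order: %d terms, %d level bands\n",
              length(x$sequence), length(x$band_starts)))
  invisible(x)
}

#' Export a leveled layout
#'
#' Writes the layout as a data.frame (term, level, position in level,
#' node size, group), and optionally to JSON or TSV.
#'
#' @param dag an [ontology_dag()].
#' @param layout a `leveled_layout`.
#' @param ann optional `annotation_map` supplying node sizes.
#' @param path optional output path; `.json` or `.tsv` chosen by
#'   extension.
#' @return the layout data.frame, invisibly when `path` is given.
#' @export
layout_table <- function(dag, layout, ann = NULL, path = NULL) {
  pos <- level_positions(layout$levels)
  ids <- unlist(layout$levels)
  df <- data.frame(term = ids,
                   name = unname(dag$term_names[ids]),
                   level = unname(layout$level_of[ids]),
                   position = unname(pos[ids]),
                   size = if (is.null(ann)) NA_integer_
                          else unname(term_sizes(ann, ids)),
                   group = if (is.null(layout$group_of)) 0L
                           else unname(layout$group_of[ids]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$level, df$position), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(df))
  }
  df
}
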