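# Independent brute-force oracles used across the suite. These are written
# against the raw edge lists / p-vectors, not against the package's own
# graph helpers, so they stay independent of the code paths they check.

# ancestor pairs (strict) by naive DFS on a child->parent edge data.frame
oracle_ancestor_pairs <- function(term_ids, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = term_ids))
  anc_of <- function(t) {
    seen <- character()
    stack <- parents[[t]]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, parents[[v]])
    }
    seen
  }
  out <- list()
  for (t in term_ids) {
    for (a in anc_of(t)) out[[length(out) + 1L]] <- c(t, a)
  }
  if (!length(out)) return(data.frame(term = character(), anc = character()))
  m <- do.call(rbind, out)
  unique(data.frame(term = m[, 1], anc = m[, 2], stringsAsFactors = FALSE))
}

# longest distance from any root, by exhaustive path extension
oracle_root_depth <- function(term_ids, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = term_ids))
  depth <- function(t) {
    pa <- parents[[t]]
    if (!length(pa)) return(0L)
    1L + max(vapply(pa, depth, integer(1)))
  }
  vapply(stats::setNames(term_ids, term_ids), depth, integer(1))
}

# the buoyant initialization order, recomputed from first principles
oracle_init_order <- function(term_ids, edges, sizes) {
  depth <- oracle_root_depth(term_ids, edges)
  term_ids[order(-sizes[term_ids], depth[term_ids], term_ids)]
}

# all constraint-valid contiguous-block partitions of the init order,
# returned as a list of integer block-length vectors (top block first)
oracle_valid_partitions <- function(term_ids, edges, sizes, max_span = NULL) {
  init <- oracle_init_order(term_ids, edges, sizes)
  n <- length(init)
  anc <- oracle_ancestor_pairs(term_ids, edges)
  is_anc <- function(a, t) any(anc$term == t & anc$anc == a)
  valid <- list()
  # enumerate compositions of n via subsets of n-1 possible cut points
  cuts_sets <- if (n == 1L) list(integer()) else {
    unlist(lapply(0:(n - 1L), function(k)
      if (k == 0L) list(integer()) else
        utils::combn(n - 1L, k, simplify = FALSE)), recursive = FALSE)
  }
  for (cuts in cuts_sets) {
    bounds <- c(0L, cuts, n)
    blocks <- lapply(seq_len(length(bounds) - 1L),
                     function(i) init[(bounds[i] + 1L):bounds[i + 1L]])
    lv <- integer(); for (i in seq_along(blocks)) lv[blocks[[i]]] <- i
    ok <- TRUE
    # topological: every ancestor strictly above
    for (r in seq_len(nrow(anc))) {
      if (lv[[anc$anc[r]]] >= lv[[anc$term[r]]]) { ok <- FALSE; break }
    }
    # descending size: smaller never above larger
    if (ok) {
      for (u in term_ids) for (v in term_ids) {
        if (sizes[[u]] < sizes[[v]] && lv[[u]] < lv[[v]]) { ok <- FALSE; break }
      }
    }
    # span cap within blocks
    if (ok && !is.null(max_span)) {
      for (b in blocks) {
        if (max(sizes[b]) - min(sizes[b]) > max_span) { ok <- FALSE; break }
      }
    }
    if (ok) valid[[length(valid) + 1L]] <- lapply(blocks, sort)
  }
  valid
}

# Simes by direct k-scan
oracle_simes <- function(p) {
  p <- sort(p); m <- length(p)
  best <- 1
  for (k in seq_len(m)) best <- min(best, m * p[k] / k)
  best
}

# hypergeometric upper tail by enumerating every possible significant set
oracle_hyper_enum <- function(k_in_sig, term_size, n_sig, universe) {
  genes <- seq_len(universe)
  term <- seq_len(term_size)           # which genes are in the term is arbitrary
  sets <- utils::combn(universe, n_sig, simplify = FALSE)
  mean(vapply(sets, function(s) length(intersect(s, term)) >= k_in_sig,
              logical(1)))
}

# BH step-up by the quadratic-time definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  kstar <- 0L
  for (k in seq_len(m)) if (p[ord[k]] <= q * k / m) kstar <- k
  if (kstar == 0L) character() else names(p)[ord[seq_len(kstar)]]
}

# crossing count for a 2-level layout given explicit orders
oracle_crossings2 <- function(edges, top_order, bottom_order) {
  pos_t <- stats::setNames(seq_along(top_order), top_order)
  pos_b <- stats::setNames(seq_along(bottom_order), bottom_order)
  n <- nrow(edges); total <- 0L
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d1 <- pos_t[[edges$parent[i]]] - pos_t[[edges$parent[j]]]
    d2 <- pos_b[[edges$child[i]]] - pos_b[[edges$child[j]]]
    if (d1 * d2 < 0) total <- total + 1L
  }
  total
}

# all permutations of a character vector (small n only)
oracle_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in oracle_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

expect_within_se <- function(observed, expected, se, k = 4) {
  expect_lt(abs(observed - expected), k * se)
}
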