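#' Designate ground-truth differentially expressed genes
#'
#' Builds the DE gene set for a power study by sampling, for each chosen
#' term, a fixed fraction of its annotated genes (all of them when
#' `fraction = 1`), and taking the union.
#'
#' @param ann an `annotation_map`.
#' @param chosen_terms term ids whose annotations carry the signal.
#' @param fraction fraction in (0, 1] of each term's genes to mark as
#'   differentially expressed; `ceiling(fraction * size)` genes are
#'   drawn uniformly per term.
#' @param seed optional integer for reproducible sampling.
#' @return character vector of DE gene ids.
#' @export
designate_ground_truth <- function(ann, chosen_terms, fraction = 1, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  empty <- chosen_terms[lengths(ann$genes_of[chosen_terms]) == 0L]
  if (length(empty)) stop("term(s) with no annotated genes: ",
                          paste(empty, collapse = ", "))
  if (!is.null(seed)) local_seed(seed)
  de <- character()
  for (t in chosen_terms) {
    g <- ann$genes_of[[t]]
    k <- ceiling(fraction * length(g))
    de <- c(de, if (k >= length(g)) g else sample(g, k))
  }
  sort(unique(de))
}

#' Classify terms as null or non-null
#'
#' Determines the set of non-null terms (`A1`) implied by a DE gene set
#' under one of the two standard gene-set null hypotheses. A term is a
#' *self-contained* null when none of its genes is differentially
#' expressed, so its non-nulls are the terms intersecting the DE set. A
#' term is a *competitive* null when its genes are at most as often
#' differentially expressed as the genes outside it; its non-nulls are
#' the terms whose internal DE fraction strictly exceeds the DE fraction
#' of their complement. Terms annotated with the whole universe have an
#' empty complement and are excluded from the competitive family.
#'
#' @param ann an `annotation_map`.
#' @param de_genes character vector of truly DE genes (subset of the
#'   universe).
#' @param framework `"self_contained"` or `"competitive"`.
#' @param terms term ids to classify (default: all terms in `ann`).
#' @return character vector of non-null term ids.
#' @export
classify_nulls <- function(ann, de_genes,
                           framework = c("self_contained", "competitive"),
                           terms = names(ann$genes_of)) {
  framework <- match.arg(framework)
  uni <- ann$universe
  nonnull <- logical(length(terms))
  for (i in seq_along(terms)) {
    g <- ann$genes_of[[terms[i]]]
    if (framework == "self_contained") {
      nonnull[i] <- any(g %in% de_genes)
    } else {
      comp <- setdiff(uni, g)
      if (!length(comp) || !length(g)) next   # excluded from the family
      frac_in <- sum(g %in% de_genes) / length(g)
      frac_out <- sum(comp %in% de_genes) / length(comp)
      nonnull[i] <- frac_in > frac_out
    }
  }
  terms[nonnull]
}

#' Simulate a two-group expression matrix
#'
#' Controls are drawn from N(0, I); cases from N(mu, I), where mu equals
#' `beta_effect` at the DE genes and 0 elsewhere — the vanilla normal
#' model used for power analysis of enrichment tests. An optional
#' equicorrelation `rho` induces a shared per-sample factor, relaxing
#' the independence assumption while keeping unit marginal variance.
#'
#' @param genes character vector of gene ids (the rows).
#' @param de_genes subset of `genes` carrying the mean shift.
#' @param beta_effect mean shift (in expression units) at DE genes in
#'   the case group.
#' @param n_control,n_case sample counts per group (each >= 2).
#' @param rho equicorrelation of genes within a sample, in [0, 1);
#'   default 0 (independent genes).
#' @param seed optional integer for reproducibility.
#' @return an `expression_dataset`: list with `matrix` (genes x samples)
#'   and `group` (factor, `"control"`/`"case"`).
#' @export
simulate_expression <- function(genes, de_genes, beta_effect,
                                n_control, n_case, rho = 0, seed = NULL) {
  stopifnot(n_control >= 2, n_case >= 2, rho >= 0, rho < 1)
  if (length(bad <- setdiff(de_genes, genes))) {
    stop("DE genes not in the gene universe: ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) local_seed(seed)
  g <- length(genes); n <- n_control + n_case
  x <- matrix(stats::rnorm(g * n), nrow = g, ncol = n,
              dimnames = list(genes, NULL))
  if (rho > 0) {
    shared <- stats::rnorm(n)
    x <- sqrt(1 - rho) * x + sqrt(rho) * matrix(shared, g, n, byrow = TRUE)
  }
  mu <- numeric(g); names(mu) <- genes
  mu[de_genes] <- beta_effect
  case_cols <- seq(n_control + 1L, n)
  x[, case_cols] <- x[, case_cols] + mu
  grp <- factor(rep(c("control", "case"), c(n_control, n_case)),
                levels = c("control", "case"))
  structure(list(matrix = x, group = grp), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$group == "control"), sum(x$group == "case")))
  invisible(x)
}

#' Per-gene two-sample t-test p-values
#'
#' Two-sided pooled-variance two-sample t-tests, one per gene, computed
#' vectorized across the matrix. The pooled (equal-variance) statistic
#' matches the generative model, which draws both groups with unit
#' variance. A gene with zero pooled variance is degenerate; it gets
#' p = 1 with a warning.
#'
#' @param data an `expression_dataset`.
#' @return named numeric vector of p-values in [0, 1], one per gene.
#' @export
gene_pvalues <- function(data) {
  x <- data$matrix
  a <- x[, data$group == "control", drop = FALSE]
  b <- x[, data$group == "case", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- rep(1, nrow(x)); names(p) <- rownames(x)
  ok <- se > 0
  if (!all(ok)) warning(sum(!ok), " gene(s) with zero pooled variance; p set to 1")
  tt <- (m2[ok] - m1[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(abs(tt), df = n1 + n2 - 2L, lower.tail = FALSE)
  p
}

#' Simes combination p-value
#'
#' Combines the p-values of the genes annotated to one term into a
#' term-level p-value for the self-contained null:
#' min over k of m * p_(k) / k for the sorted p_(1) <= ... <= p_(m),
#' capped at 1.
#'
#' @param pvals non-empty numeric vector of p-values in [0, 1].
#' @return a single p-value.
#' @examples
#' simes_pvalue(c(0.01, 0.04, 0.9))  # 0.03
#' @export
simes_pvalue <- function(pvals) {
  if (!length(pvals)) stop("Simes rule needs at least one p-value")
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  m <- length(pvals)
  min(1, min(m * sort(pvals) / seq_len(m)))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that at least `k_in_sig` of the `n_sig`
#' significant genes fall in a term of `term_size` genes, when the
#' significant genes are drawn without replacement from a universe of
#' `universe` genes — the competitive enrichment test.
#'
#' @param k_in_sig observed overlap between significant genes and the
#'   term's genes.
#' @param term_size number of genes annotated to the term.
#' @param n_sig number of significant genes.
#' @param universe size of the gene universe.
#' @return a single p-value, P(X >= k_in_sig).
#' @export
hypergeom_pvalue <- function(k_in_sig, term_size, n_sig, universe) {
  if (k_in_sig < 0 || term_size > universe || n_sig > universe ||
      k_in_sig > min(term_size, n_sig)) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(k_in_sig - 1, m = term_size, n = universe - term_size,
                k = n_sig, lower.tail = FALSE)
}

#' Multiplicity-corrected rejection
#'
#' Applies a multiple-testing procedure to a family of term p-values at
#' level `q` and returns the rejected terms. The Benjamini-Hochberg
#' step-up rule (the default) controls the false discovery rate;
#' Bonferroni controls the family-wise error rate. A custom procedure
#' can be plugged in as a function `(pvalues, q) -> logical`.
#'
#' @param term_pvalues named numeric vector of term p-values.
#' @param q level of the procedure, in (0, 1).
#' @param method `"bh"`, `"bonferroni"`, or a function.
#' @return character vector of rejected term ids.
#' @examples
#' bh_reject(c(a = 0.01, b = 0.02, c = 0.05, d = 0.8), q = 0.1)
#' @export
bh_reject <- function(term_pvalues, q, method = "bh") {
  stopifnot(length(term_pvalues) >= 1, q > 0, q < 1)
  rej <- if (is.function(method)) {
    method(term_pvalues, q)
  } else {
    adj <- switch(match.arg(method, c("bh", "bonferroni")),
                  bh = stats::p.adjust(term_pvalues, method = "BH"),
                  bonferroni = stats::p.adjust(term_pvalues, method = "bonferroni"))
    adj <= q
  }
  names(term_pvalues)[rej]
}

#' Empirical power and false discovery proportion
#'
#' Power = |A1 ∩ R| / max(|A1|, 1) and FDP = |R \ A1| / max(|R|, 1),
#' where A1 is the set of non-null terms and R the rejected set; the
#' max(., 1) guards make the empty cases well defined (power 0 when
#' nothing is non-null, FDP 0 when nothing is rejected).
#'
#' @param a1 character vector of non-null term ids.
#' @param r character vector of rejected term ids.
#' @return named numeric vector `c(power = ..., fdp = ...)`.
#' @export
power_fdp <- function(a1, r) {
  a1 <- unique(a1); r <- unique(r)
  c(power = length(intersect(a1, r)) / max(length(a1), 1),
    fdp = length(setdiff(r, a1)) / max(length(r), 1))
}

#' Term-level p-values for one simulated dataset
#'
#' Self-contained framework: Simes combination of each term's gene
#' p-values. Competitive framework: genes are first called significant
#' by `gene_threshold` (default: Bonferroni at 0.05 over the universe),
#' then each term is tested for over-representation of significant
#' genes with the hypergeometric test.
#'
#' @param gene_p named numeric vector of gene p-values (the universe).
#' @param ann an `annotation_map`.
#' @param terms term ids to test (must have non-empty annotations).
#' @param framework `"self_contained"` or `"competitive"`.
#' @param gene_threshold for the competitive framework: a fixed numeric
#'   cutoff, or `"bonferroni"` (0.05 / g), or a function
#'   `(gene_p) -> logical`.
#' @return named numeric vector of term p-values.
#' @export
term_pvalues <- function(gene_p, ann, terms,
                         framework = c("self_contained", "competitive"),
                         gene_threshold = "bonferroni") {
  framework <- match.arg(framework)
  sizes <- lengths(ann$genes_of[terms])
  if (any(sizes == 0L)) {
    stop("term(s) with empty annotation cannot be tested: ",
         paste(terms[sizes == 0L], collapse = ", "))
  }
  if (framework == "self_contained") {
    vapply(terms, function(t) {
      simes_pvalue(gene_p[intersect(ann$genes_of[[t]], names(gene_p))])
    }, numeric(1))
  } else {
    sig <- if (is.function(gene_threshold)) gene_threshold(gene_p)
           else if (identical(gene_threshold, "bonferroni"))
             gene_p <= 0.05 / length(gene_p)
           else gene_p <= gene_threshold
    sig_genes <- names(gene_p)[sig]
    uni_n <- length(gene_p)
    vapply(terms, function(t) {
      g <- ann$genes_of[[t]]
      hypergeom_pvalue(length(intersect(g, sig_genes)), length(g),
                       length(sig_genes), uni_n)
    }, numeric(1))
  }
}

#' Run a power study over a sample-size grid
#'
#' The full pipeline: for each (n_control, n_case) grid point and each
#' replication, simulate expression data with the fixed ground truth,
#' compute gene p-values (two-sample t), term p-values (Simes or
#' hypergeometric according to the framework), apply the multiplicity
#' correction at level `q`, and record the rejection set. The ground
#' truth and the non-null set A1 are fixed across replications; the
#' mean FDP across replications estimates the FDR. One master seed
#' spawns an independent substream per grid point and replication, so
#' any sub-grid reruns reproducibly.
#'
#' @param dag an [ontology_dag()] — typically refined
#'   ([refine_dag()]) first, so no two tested terms share an identical
#'   gene set.
#' @param ann an `annotation_map` over `dag`.
#' @param de_genes the ground-truth DE gene set
#'   (see [designate_ground_truth()]).
#' @param n_grid list (or 2-column matrix) of `c(n_control, n_case)`
#'   pairs; a plain numeric vector n is shorthand for n/n per group.
#' @param beta_effect mean shift at DE genes.
#' @param reps replications per grid point.
#' @param framework `"self_contained"` or `"competitive"`.
#' @param q FDR (or FWER) level in (0, 1).
#' @param method `"bh"` or `"bonferroni"` (or a function; see
#'   [bh_reject()]).
#' @param gene_threshold competitive gene-significance rule (see
#'   [term_pvalues()]).
#' @param seed master integer seed.
#' @return a `power_report`: list with `grid` (data.frame n_control,
#'   n_case, mean_power, mean_fdp), `per_rep` (data.frame of one row
#'   per grid point x rep with power and fdp), `rejection_freq`
#'   (terms x grid points matrix of rejection fractions), `a1`,
#'   `tested_terms`, and the call parameters.
#' @export
run_power_study <- function(dag, ann, de_genes, n_grid, beta_effect = 1,
                            reps = 100,
                            framework = c("self_contained", "competitive"),
                            q = 0.1, method = "bh",
                            gene_threshold = "bonferroni", seed = 1) {
  framework <- match.arg(framework)
  if (is.numeric(n_grid) && is.null(dim(n_grid))) {
    n_grid <- lapply(n_grid, function(n) c(n, n))
  } else if (is.matrix(n_grid)) {
    n_grid <- lapply(seq_len(nrow(n_grid)), function(i) n_grid[i, ])
  }
  terms <- dag$term_ids[lengths(ann$genes_of[dag$term_ids]) > 0L]
  if (framework == "competitive") {
    # full-universe terms have no complement and leave the family
    terms <- terms[lengths(ann$genes_of[terms]) < length(ann$universe)]
  }
  if (!length(terms)) stop("no testable terms (all annotations empty)")
  genes <- ann$universe
  a1 <- classify_nulls(ann, de_genes, framework, terms)

  # one substream per (grid point, rep), derived from the master seed
  local_seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max, length(n_grid) * reps),
                     nrow = reps)

  grid_lab <- vapply(n_grid, function(n) sprintf("%d/%d", n[1], n[2]),
                     character(1))
  rej_freq <- matrix(0, nrow = length(terms), ncol = length(n_grid),
                     dimnames = list(terms, grid_lab))
  per_rep <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- n_grid[[i]]
    pw <- fd <- numeric(reps)
    for (r in seq_len(reps)) {
      dat <- simulate_expression(genes, de_genes, beta_effect,
                                 n_control = n[1], n_case = n[2],
                                 seed = seed_tab[r, i])
      gp <- gene_pvalues(dat)
      tp <- term_pvalues(gp, ann, terms, framework, gene_threshold)
      rej <- bh_reject(tp, q, method)
      rej_freq[rej, i] <- rej_freq[rej, i] + 1
      res <- power_fdp(a1, rej)
      pw[r] <- res[["power"]]; fd[r] <- res[["fdp"]]
    }
    per_rep[[i]] <- data.frame(n_control = n[1], n_case = n[2],
                               rep = seq_len(reps), power = pw, fdp = fd)
  }
  rej_freq <- rej_freq / reps
  per_rep <- do.call(rbind, per_rep)
  grid <- do.call(rbind, lapply(split(per_rep, per_rep$n_control * 1e6 +
                                        per_rep$n_case), function(d) {
    data.frame(n_control = d$n_control[1], n_case = d$n_case[1],
               mean_power = mean(d$power), mean_fdp = mean(d$fdp))
  }))
  ord <- match(vapply(n_grid, function(n) n[1] * 1e6 + n[2], numeric(1)),
               grid$n_control * 1e6 + grid$n_case)
  grid <- grid[ord, ]; rownames(grid) <- NULL
  structure(list(grid = grid, per_rep = per_rep, rejection_freq = rej_freq,
                 a1 = a1, tested_terms = terms,
                 params = list(beta_effect = beta_effect, reps = reps,
                               framework = framework, q = q,
                               method = if (is.function(method)) "custom" else method,
                               seed = seed)),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("power_report: %s framework, %d tested terms (%d non-null), q = %g, %d reps\n",
              x$params$framework, length(x$tested_terms), length(x$a1),
              x$params$q, x$params$reps))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' @export
summary.power_report <- function(object, ...) {
  print(object)
  cat("\nper-term rejection frequency (head):\n")
  print(utils::head(object$rejection_freq))
  invisible(object)
}

#' @param x a `power_report`.
#' @param ann optional `annotation_map` to order terms as a binder plot
#'   (descending node size); default keeps the stored order.
#' @param ... unused.
#' @rdname run_power_study
#' @export
plot.power_report <- function(x, ann = NULL, ...) {
  m <- x$rejection_freq
  if (!is.null(ann)) {
    m <- m[order(-term_sizes(ann, rownames(m))), , drop = FALSE]
  }
  op <- graphics::par(mar = c(4, 8, 2, 2)); on.exit(graphics::par(op))
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  axes = FALSE, col = grDevices::hcl.colors(50, "YlGnBu", rev = TRUE),
                  zlim = c(0, 1), xlab = "sample size (control/case)")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  graphics::title("per-term rejection frequency")
  invisible(x)
}

#' Export a power report
#'
#' Writes the per-term rejection frequencies as TSV and the whole
#' report as JSON.
#'
#' @param report a `power_report`.
#' @param tsv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_power_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    df <- data.frame(term = rownames(report$rejection_freq),
                     report$rejection_freq, check.names = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(grid = report$grid, per_rep = report$per_rep,
                              rejection_freq = as.data.frame(report$rejection_freq),
                              a1 = report$a1, params = report$params),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

# set the RNG for the rest of the calling function, restoring the
# caller's stream on exit
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}
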