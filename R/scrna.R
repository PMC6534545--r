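#' Select signature genes from ontology terms
#'
#' Picks, for each chosen term, a seeded uniform sample of
#' `genes_per_term` of its annotated genes to serve as that cell type's
#' expression signature. A gene annotating several chosen terms is
#' assigned to the first term that samples it and removed from later
#' terms' pools, so the signature sets are disjoint.
#'
#' @param ann an `annotation_map`.
#' @param signature_terms character vector of term ids, in assignment
#'   order.
#' @param genes_per_term number of signature genes per term.
#' @param seed optional integer.
#' @return named character vector: names are gene ids, values the term
#'   (cell-type) each gene signs for.
#' @export
select_signatures <- function(ann, signature_terms, genes_per_term = 10,
                              seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  taken <- character()
  out <- character()
  for (t in signature_terms) {
    pool <- setdiff(ann$genes_of[[t]], taken)
    if (length(pool) < genes_per_term) {
      stop("term ", t, " has only ", length(pool),
           " unassigned annotated genes; ", genes_per_term, " needed")
    }
    g <- if (length(pool) == genes_per_term) pool else sample(pool, genes_per_term)
    out[g] <- t
    taken <- c(taken, g)
  }
  out
}

#' Simulate a single-cell count matrix with signature structure
#'
#' Draws a genes x cells matrix from a zero-inflated negative binomial
#' model. Each cell belongs to one cell type; each signature gene
#' belongs to one type. A gene's negative binomial mean is
#' `signature_mean` in cells of its own type and `baseline_mean`
#' everywhere else (non-signature genes always use the baseline mean),
#' with common size (dispersion) parameter. Drop-outs are imposed by
#' zeroing each entry independently with probability `dropout_prob`, so
#' the marginal mean of an entry is (1 - dropout_prob) times its
#' negative binomial mean.
#'
#' @param signatures named character vector from [select_signatures()]
#'   (gene -> type); the cell types are
#'   `unique(signatures)` plus a `"baseline"` type with no signature.
#' @param cells_per_type integer vector of cell counts, one per
#'   signature type in `unique(signatures)` order, plus one final count
#'   for the baseline type.
#' @param extra_genes number of additional non-signature genes to
#'   simulate at baseline mean in all cells.
#' @param baseline_mean,signature_mean negative binomial means (counts).
#' @param dispersion negative binomial size parameter (> 0).
#' @param dropout_prob zero-inflation probability in [0, 1].
#' @param seed optional integer.
#' @return an `sc_dataset`: list with `counts` (integer matrix, genes x
#'   cells), `cell_type` (character per cell) and `signature`
#'   (character per gene, `NA` for non-signature genes).
#' @export
simulate_sc <- function(signatures, cells_per_type,
                        extra_genes = 10, baseline_mean = 1,
                        signature_mean = 8, dispersion = 2,
                        dropout_prob = 0.3, seed = NULL) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, dispersion > 0)
  types <- unique(unname(signatures))
  if (length(cells_per_type) != length(types) + 1L) {
    stop("cells_per_type must give one count per signature type plus baseline")
  }
  if (!is.null(seed)) local_seed(seed)
  all_types <- c(types, "baseline")
  cell_type <- rep(all_types, cells_per_type)
  genes <- c(names(signatures),
             if (extra_genes > 0) sprintf("bg_gene%03d", seq_len(extra_genes)))
  sig_of <- c(unname(signatures), rep(NA_character_, extra_genes))
  g <- length(genes); n <- length(cell_type)
  mu <- matrix(baseline_mean, g, n, dimnames = list(genes, NULL))
  for (i in seq_len(g)) {
    if (!is.na(sig_of[i])) mu[i, cell_type == sig_of[i]] <- signature_mean
  }
  counts <- matrix(stats::rnbinom(g * n, size = dispersion, mu = mu), g, n,
                   dimnames = list(genes, NULL))
  if (dropout_prob > 0) {
    counts[stats::runif(g * n) < dropout_prob] <- 0L
  }
  structure(list(counts = counts, cell_type = cell_type, signature = sig_of),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells; types: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (%d)", names(table(x$cell_type)),
                            table(x$cell_type)), collapse = ", ")))
  invisible(x)
}

#' Write a single-cell dataset to MTX with TSV sidecars
#'
#' Sparse MatrixMarket triplet export of the count matrix plus
#' tab-separated cell-label and gene-signature sidecars.
#'
#' @param sc an `sc_dataset`.
#' @param prefix output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>_cells.tsv`, `<prefix>_genes.tsv`.
#' @return the three paths, invisibly.
#' @export
write_sc_mtx <- function(sc, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(Matrix::Matrix(sc$counts, sparse = TRUE), mtx)
  cells <- paste0(prefix, "_cells.tsv")
  utils::write.table(
    data.frame(cell = sprintf("cell%04d", seq_along(sc$cell_type)),
               cell_type = sc$cell_type),
    cells, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- paste0(prefix, "_genes.tsv")
  utils::write.table(
    data.frame(gene = rownames(sc$counts),
               signature = ifelse(is.na(sc$signature), "", sc$signature)),
    genes, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, cells, genes))
}
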