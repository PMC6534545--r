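#' Parse an OBO (format-version 1.2) ontology file
#'
#' A minimal line-oriented parser covering the tags this package needs:
#' `id`, `name`, `namespace`, `is_a`, `relationship`, `is_obsolete`,
#' `alt_id`. `is_a` lines always yield a relation of type `"is_a"`;
#' `relationship:` lines yield relations of their stated type. Only
#' relation types in `relation_whitelist` are kept. Obsolete terms are
#' recorded but carry no relations; `alt_id` values are recorded as
#' aliases resolving to the canonical id. Relations whose endpoints are
#' not known (non-obsolete) terms are dropped with a warning.
#'
#' @param con a file path or text connection, or a character vector of
#'   lines.
#' @param relation_whitelist non-empty character vector of relation type
#'   names to keep, e.g. `"is_a"` alone for a biological-process style
#'   ontology or `c("is_a", "part_of", "regulates")`.
#' @return a `raw_ontology` list: `terms` (data.frame id/name/namespace),
#'   `relations` (data.frame child/parent/type), `obsolete_ids`
#'   (character), `alt_ids` (named character, alias -> canonical).
#' @examples
#' obo <- c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'          "name: alpha", "namespace: biological_process",
#'          "is_a: GO:0000002 ! beta", "", "[Term]", "id: GO:0000002",
#'          "name: beta", "namespace: biological_process")
#' parse_obo(obo, "is_a")
#' @export
parse_obo <- function(con, relation_whitelist = "is_a") {
  if (!length(relation_whitelist)) stop("relation whitelist must be non-empty")
  lines <- if (is.character(con) && length(con) != 1L) con
           else if (is.character(con) && !file.exists(con))
             strsplit(con, "\n", fixed = TRUE)[[1]]
           else readLines(con, warn = FALSE)

  # split into stanzas; only [Term] stanzas are interpreted
  hdr <- grepl("^\\[.*\\]\\s*$", lines)
  stanza_id <- cumsum(hdr)
  terms <- list(); rels <- list(); obsolete <- character(); alt <- character()

  for (s in split(seq_along(lines), stanza_id)) {
    if (!length(s) || !hdr[s[1]]) next           # preamble before first stanza
    if (trimws(lines[s[1]]) != "[Term]") next
    body <- lines[s[-1]]
    body <- body[nzchar(trimws(body))]
    tag <- sub("^([^:]+):.*$", "\\1", body)
    val <- trimws(sub("^[^:]+:", "", body))
    val <- trimws(sub("!.*$", "", val))          # strip trailing comments
    ids <- val[tag == "id"]
    if (!length(ids)) {
      stop("malformed [Term] stanza missing id near line ", s[1])
    }
    id <- ids[1]
    is_obs <- any(tag == "is_obsolete" & tolower(val) == "true")
    if (is_obs) {
      obsolete <- c(obsolete, id)
      next                                        # no relations for obsolete terms
    }
    name <- if (any(tag == "name")) val[tag == "name"][1] else id
    ns <- if (any(tag == "namespace")) val[tag == "namespace"][1] else NA_character_
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = name, namespace = ns, stringsAsFactors = FALSE)
    for (a in val[tag == "alt_id"]) alt[a] <- id
    for (p in val[tag == "is_a"]) {
      rels[[length(rels) + 1L]] <- data.frame(
        child = id, parent = p, type = "is_a", stringsAsFactors = FALSE)
    }
    for (r in val[tag == "relationship"]) {
      parts <- strsplit(r, "\\s+")[[1]]
      if (length(parts) >= 2L) {
        rels[[length(rels) + 1L]] <- data.frame(
          child = id, parent = parts[2], type = parts[1],
          stringsAsFactors = FALSE)
      }
    }
  }

  terms_df <- if (length(terms)) do.call(rbind, terms)
              else data.frame(id = character(), name = character(),
                              namespace = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(terms_df$id)) {
    stop("duplicate term id in OBO input: ",
         terms_df$id[duplicated(terms_df$id)][1])
  }
  rel_df <- if (length(rels)) do.call(rbind, rels)
            else data.frame(child = character(), parent = character(),
                            type = character(), stringsAsFactors = FALSE)
  rel_df <- rel_df[rel_df$type %in% relation_whitelist, , drop = FALSE]
  known <- rel_df$child %in% terms_df$id & rel_df$parent %in% terms_df$id
  if (any(!known)) {
    warning(sum(!known), " relation(s) dropped: endpoint not a known term")
    rel_df <- rel_df[known, , drop = FALSE]
  }
  rownames(rel_df) <- NULL
  structure(list(terms = terms_df, relations = unique(rel_df),
                 obsolete_ids = unique(obsolete), alt_ids = alt),
            class = "raw_ontology")
}

#' @export
print.raw_ontology <- function(x, ...) {
  cat(sprintf("raw_ontology: %d terms, %d relations, %d obsolete\n",
              nrow(x$terms), nrow(x$relations), length(x$obsolete_ids)))
  invisible(x)
}

#' Build an ontology DAG from a parsed ontology
#'
#' Collapses the typed relations of a `raw_ontology` into the plain
#' child-to-parent edge set of an [ontology_dag()] (relation types were
#' already filtered at parse time).
#'
#' @param raw a `raw_ontology` from [parse_obo()].
#' @return an `ontology_dag`.
#' @export
as_ontology_dag <- function(raw) {
  ontology_dag(raw$terms$id,
               stats::setNames(raw$terms$name, raw$terms$id),
               raw$relations[, c("child", "parent")])
}

#' Serialize an ontology to OBO text
#'
#' Writes the minimal OBO 1.2 dialect that [parse_obo()] reads, so the
#' pair round-trips term ids, names, namespaces and whitelisted
#' relations.
#'
#' @param raw a `raw_ontology`.
#' @return a character vector of OBO lines.
#' @export
write_obo <- function(raw) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(raw$terms))) {
    id <- raw$terms$id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", raw$terms$name[i]))
    if (!is.na(raw$terms$namespace[i])) {
      out <- c(out, paste0("namespace: ", raw$terms$namespace[i]))
    }
    al <- names(raw$alt_ids)[raw$alt_ids == id]
    out <- c(out, if (length(al)) paste0("alt_id: ", al))
    r <- raw$relations[raw$relations$child == id, , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      out <- c(out, if (r$type[j] == "is_a") paste0("is_a: ", r$parent[j])
                    else paste0("relationship: ", r$type[j], " ", r$parent[j]))
    }
    out <- c(out, "")
  }
  for (id in raw$obsolete_ids) {
    out <- c(out, "[Term]", paste0("id: ", id), "is_obsolete: true", "")
  }
  out
}

#' Parse a gene2go-style annotation table
#'
#' Reads the NCBI gene2go tab-separated layout (columns `tax_id`,
#' `GeneID`, `GO_ID`, `Evidence`, optionally `Qualifier`, ...) into a
#' deduplicated set of gene/term pairs. All evidence codes are kept by
#' default; rows whose qualifier contains NOT are dropped by default.
#'
#' @param con a file path, connection, or character vector of lines.
#' @param taxon optional integer; keep only rows of this taxon.
#' @param evidence optional character vector of evidence codes to keep
#'   (default: all).
#' @param drop_not logical; drop NOT-qualified annotations (default TRUE).
#' @return a `direct_annotations` list: `pairs` (data.frame gene/term)
#'   and `taxon`.
#' @export
parse_gene2go <- function(con, taxon = NULL, evidence = NULL, drop_not = TRUE) {
  lines <- if (is.character(con) && length(con) > 1L) con
           else readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # NCBI ships the header as a "#tax_id ..." comment line
  if (length(lines)) lines[1] <- sub("^#", "", lines[1])
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("tax_id", "GeneID", "GO_ID", "Evidence")) {
    if (!col %in% names(tab)) stop("gene2go input missing column: ", col)
  }
  if (!is.null(taxon)) tab <- tab[tab$tax_id == taxon, , drop = FALSE]
  if (!is.null(evidence)) tab <- tab[tab$Evidence %in% evidence, , drop = FALSE]
  if (drop_not && "Qualifier" %in% names(tab)) {
    tab <- tab[!grepl("\\bNOT\\b", tab$Qualifier), , drop = FALSE]
  }
  pairs <- unique(data.frame(gene = as.character(tab$GeneID),
                             term = as.character(tab$GO_ID),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, taxon = taxon), class = "direct_annotations")
}

#' @export
print.direct_annotations <- function(x, ...) {
  cat(sprintf("direct_annotations: %d gene-term pairs (%d genes, %d terms)%s\n",
              nrow(x$pairs), length(unique(x$pairs$gene)),
              length(unique(x$pairs$term)),
              if (is.null(x$taxon)) "" else paste0(", taxon ", x$taxon)))
  invisible(x)
}

#' Write / read the versioned JSON DAG document
#'
#' The package's on-disk interchange format: term table, edge list and
#' direct annotation pairs in one JSON document, used by the command-line
#' interface and the fixtures.
#'
#' @param dag an `ontology_dag`.
#' @param direct optional `direct_annotations`.
#' @param path output (resp. input) file path.
#' @return `write_dag_json` returns `path` invisibly; `read_dag_json`
#'   returns a list with `dag` and `direct` (possibly NULL).
#' @export
write_dag_json <- function(dag, direct = NULL, path) {
  doc <- list(
    format = "goscape-dag", version = 1L,
    terms = data.frame(id = dag$term_ids,
                       name = unname(dag$term_names[dag$term_ids]),
                       stringsAsFactors = FALSE),
    edges = dag$edges,
    direct = if (!is.null(direct)) direct$pairs else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "goscape-dag")) {
    stop("not a goscape DAG document: ", path)
  }
  dag <- ontology_dag(doc$terms$id,
                      stats::setNames(doc$terms$name, doc$terms$id),
                      doc$edges)
  direct <- NULL
  if (!is.null(doc$direct) && NROW(doc$direct)) {
    direct <- structure(list(pairs = doc$direct, taxon = NULL),
                        class = "direct_annotations")
  }
  list(dag = dag, direct = direct)
}
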