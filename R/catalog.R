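# Gene and disease catalogs (HGNC/OMIM/CGD-like) supporting the
# known-disease-gene restriction and disease-driven gene panels.

#' Load a gene catalog
#'
#' Reads an HGNC-like tab-separated catalog with columns `symbol` (unique,
#' uppercase gene symbol) and `name` (descriptive gene name).
#'
#' @param path path to the TSV file (header required).
#' @return A data frame of class `GeneCatalog`.
#' @export
load_gene_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "name") %in% names(tab))) {
    stop("gene catalog must have columns 'symbol' and 'name': ", path)
  }
  tab$symbol <- toupper(tab$symbol)
  dup <- unique(tab$symbol[duplicated(tab$symbol)])
  if (length(dup)) {
    stop("duplicate gene symbol(s) in catalog: ", paste(dup, collapse = ", "))
  }
  structure(tab[, c("symbol", "name")], class = c("GeneCatalog", "data.frame"))
}

#' Load a disease catalog
#'
#' Reads an OMIM/CGD-like tab-separated catalog with columns `disease_name`,
#' `source` (`omim` or `cgd`), `inheritance` (optional label such as AD, AR,
#' XL) and `genes` (semicolon-separated gene symbols, nonempty).
#'
#' @param path path to the TSV file (header required).
#' @return A data frame of class `DiseaseCatalog`; the `genes` column is a
#'   list of uppercase symbol vectors.
#' @export
load_disease_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("disease_name", "source", "inheritance", "genes")
  if (!all(need %in% names(tab))) {
    stop("disease catalog must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  genes <- lapply(strsplit(tab$genes, ";", fixed = TRUE), toupper)
  if (any(lengths(genes) == 0L)) {
    stop("disease catalog rows must list at least one gene: ", path)
  }
  out <- tab[, c("disease_name", "source", "inheritance")]
  out$genes <- genes
  structure(out, class = c("DiseaseCatalog", "data.frame"))
}

#' Search a disease catalog
#'
#' Matches diseases by case-insensitive substring on the disease name, or by
#' exact (case-insensitive) match against any associated gene symbol — e.g.
#' a query of a gene symbol returns every disease listing that gene, and a
#' fragment of a syndrome name returns the syndromes containing it. Results
#' are sorted by disease name; an empty query returns no results.
#'
#' @param catalog a [load_disease_catalog()] result.
#' @param query search string.
#' @return A `DiseaseCatalog` subset (possibly zero rows).
#' @export
search_diseases <- function(catalog, query) {
  stopifnot(inherits(catalog, "DiseaseCatalog"))
  query <- trimws(query)
  if (nchar(query) == 0L) return(catalog[0, , drop = FALSE])
  by_name <- grepl(tolower(query), tolower(catalog$disease_name), fixed = TRUE)
  q <- toupper(query)
  by_gene <- vapply(catalog$genes, function(g) q %in% g, logical(1))
  hit <- catalog[by_name | by_gene, , drop = FALSE]
  hit <- hit[order(hit$disease_name), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Construct a gene panel
#'
#' @param symbols character vector of gene symbols (uppercased, deduplicated).
#' @param label short description of the panel.
#' @return An object of class `GenePanel`.
#' @export
gene_panel <- function(symbols, label = "panel") {
  structure(list(label = label,
                 symbols = sort(unique(toupper(as.character(symbols))))),
            class = "GenePanel")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("<GenePanel '%s'> %d gene(s)\n", x$label, length(x$symbols)))
  invisible(x)
}

#' Gene panel from selected diseases
#'
#' Unions the gene symbols of a nonempty disease selection into one panel,
#' so that filtering can be restricted to genes associated with the chosen
#' diseases.
#'
#' @param selection a nonzero-row subset of a `DiseaseCatalog` (e.g. from
#'   [search_diseases()]).
#' @return A [gene_panel()].
#' @export
panel_from_diseases <- function(selection) {
  stopifnot(inherits(selection, "DiseaseCatalog"))
  if (nrow(selection) == 0L) stop("disease selection is empty")
  gene_panel(unlist(selection$genes),
             label = paste0("diseases:", nrow(selection)))
}

#' Panel of all genes with a known Mendelian-disease association
#'
#' Unions the gene symbols across one or more disease catalogs (typically an
#' OMIM-like and a CGD-like source). Used by the default candidate pipeline
#' to restrict reporting to genes previously associated with Mendelian
#' disorders.
#'
#' @param ... one or more `DiseaseCatalog` objects.
#' @return A [gene_panel()]; empty catalogs yield an empty panel with a
#'   warning.
#' @export
known_disease_genes <- function(...) {
  catalogs <- list(...)
  if (length(catalogs) == 1L && is.list(catalogs[[1L]]) &&
      !inherits(catalogs[[1L]], "DiseaseCatalog")) {
    catalogs <- catalogs[[1L]]
  }
  symbols <- unlist(lapply(catalogs, function(cat) {
    stopifnot(inherits(cat, "DiseaseCatalog"))
    unlist(cat$genes)
  }))
  if (length(symbols) == 0L) {
    warning("disease catalogs contain no genes; known-gene panel is empty")
  }
  gene_panel(symbols, label = "known_disease_genes")
}
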