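# Gene lists: labelled, duplicate-free, order-preserving.

#' Construct a gene list
#'
#' @param genes character vector of gene ids; duplicates are removed keeping
#'   first occurrence.
#' @param label a label for the list.
#' @return object of class `gene_list`: list with `label` and `genes`.
#' @export
gene_list <- function(genes, label = "list") {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  structure(list(label = label, genes = unique(genes)), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d genes\n", x$label, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$genes)

#' Read a gene list from a plain-text file (one identifier per line)
#'
#' @param path file path.
#' @param label label; defaults to the file name without extension.
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  gene_list(trimws(readLines(path, warn = FALSE)), label = label)
}

#' Write a gene list as plain text, one identifier per line
#'
#' @param x a [gene_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$genes, path)
  invisible(path)
}
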