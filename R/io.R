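# Ingestion of foreign enrichment-result tables.

#' Column mapping for a foreign enrichment-result table
#'
#' @param term_id column name holding term ids.
#' @param p_raw column name of raw p-values (may be `NULL` if only adjusted
#'   values are present).
#' @param p_adj column name of adjusted p-values (may be `NULL`: they are
#'   then recomputed from `p_raw` by Benjamini-Hochberg).
#' @param delimiter field delimiter (default tab).
#' @param comment comment-line prefix (default `"#"`).
#' @return object of class `result_table_schema`.
#' @export
result_table_schema <- function(term_id = "term_id", p_raw = "p_raw",
                                p_adj = "p_adj", delimiter = "\t",
                                comment = "#") {
  if (is.null(term_id) || is.null(p_raw) && is.null(p_adj))
    stop("schema must map term_id and at least one p-value column")
  structure(list(term_id = term_id, p_raw = p_raw, p_adj = p_adj,
                 delimiter = delimiter, comment = comment),
            class = "result_table_schema")
}

#' Read a foreign enrichment-result table
#'
#' Builds an [enrichment_result()] from any delimited table with a header.
#' A missing adjusted-p column is recomputed from the raw p-values by
#' Benjamini-Hochberg (with a message); term ids that do not resolve in the
#' graph (after alt-id mapping) are dropped and counted.
#'
#' @param path file path or character vector of lines.
#' @param schema a [result_table_schema()].
#' @param graph an [ontology_graph()].
#' @param label result label (defaults to the file name).
#' @param alpha significance level carried with the result.
#' @return an [enrichment_result()].
#' @export
read_result_table <- function(path, schema = result_table_schema(), graph,
                              label = NULL, alpha = 0.05) {
  stopifnot(inherits(schema, "result_table_schema"))
  from_file <- length(path) == 1L && file.exists(path)
  if (is.null(label)) label <- if (from_file) basename(path) else "ingested"
  df <- utils::read.table(if (from_file) path else textConnection(path),
                          sep = schema$delimiter, header = TRUE,
                          comment.char = schema$comment,
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c(term_id = schema$term_id,
            if (!is.null(schema$p_raw)) c(p_raw = schema$p_raw),
            if (!is.null(schema$p_adj)) c(p_adj = schema$p_adj))
  missing_cols <- need[!need %in% names(df)]
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "))
  rec <- data.frame(term_id = as.character(df[[schema$term_id]]),
                    stringsAsFactors = FALSE)
  rec$p_raw <- if (!is.null(schema$p_raw)) as.numeric(df[[schema$p_raw]])
               else as.numeric(df[[schema$p_adj]])
  if (!is.null(schema$p_adj)) {
    rec$p_adj <- as.numeric(df[[schema$p_adj]])
  } else {
    message("no adjusted-p column mapped; recomputing by Benjamini-Hochberg")
    rec$p_adj <- adjust_pvalues(rec$p_raw)
  }
  resolved <- resolve_term(graph, rec$term_id)
  n_dropped <- sum(is.na(resolved))
  if (n_dropped)
    warning(n_dropped, " record(s) with term ids unknown to the ontology dropped")
  rec <- rec[!is.na(resolved), , drop = FALSE]
  rec$term_id <- resolved[!is.na(resolved)]
  if (!nrow(rec)) stop("no ingested record resolves in the ontology")
  enrichment_result(rec, label = label, alpha = alpha)
}
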