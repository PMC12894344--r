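# Reference overrepresentation analysis: upper-tail hypergeometric test,
# EASE variant, BH correction, minimum-gene filter.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): the probability that a
#' size-`n` draw from a population of `N` genes containing `K` annotated
#' genes hits the term at least `k` times. Computed via the survival
#' function, numerically stable for large parameters.
#'
#' @param k study count (hits in the drawn list), vectorised.
#' @param n study size (draws).
#' @param K population count (annotated genes in background).
#' @param N population size (background).
#' @return p-value in \[0, 1\].
#' @export
#' @examples
#' hypergeom_upper(4, 4, 5, 10)   # 1/42
hypergeom_upper <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("negative parameter")
  if (any(n > N)) stop("study size n exceeds population N")
  if (any(K > N)) stop("population count K exceeds population N")
  if (any(k > n)) stop("count k exceeds study size n")
  if (any(k > K)) stop("count k exceeds population count K")
  # P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' EASE score (conservative hypergeometric variant)
#'
#' The hypergeometric upper tail with the study hit count decremented by one,
#' always at least as large as the plain hypergeometric p-value. `k = 0`
#' returns 1.
#'
#' @inheritParams hypergeom_upper
#' @return p-value in \[0, 1\].
#' @export
ease_score <- function(k, n, K, N) {
  p <- hypergeom_upper(pmax(k - 1, 0), n, K, N)
  p[k == 0] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: sort ascending, adj_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, returned in the input order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param method only `"bh"` ("FDR" and "BH" name the same step-up
#'   procedure).
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = "bh") {
  if (!identical(tolower(method), "bh")) stop("unsupported method: ", method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Construct an enrichment result table
#'
#' Normalises and orders records: ascending by (p_adj, p_raw, term_id), a
#' deterministic total order; `rank` is the 1-based position.
#'
#' @param records data.frame with at least `term_id`, `p_raw`, `p_adj`;
#'   typically also `study_count`, `study_n`, `pop_count`, `pop_n`.
#' @param label tool or input identifier.
#' @param alpha significance level carried with the result (default 0.05).
#' @param order_by `"adjusted"` (default): sort key (p_adj, p_raw, term_id);
#'   `"raw"`: sort key (p_raw, p_adj, term_id).
#' @return data.frame of class `enrichment_result` with attributes `label`
#'   and `alpha`, ordered, with a `rank` column.
#' @export
enrichment_result <- function(records, label = "result", alpha = 0.05,
                              order_by = c("adjusted", "raw")) {
  order_by <- match.arg(order_by)
  stopifnot(all(c("term_id", "p_raw", "p_adj") %in% names(records)))
  ord <- if (order_by == "raw")
    order(records$p_raw, records$p_adj, records$term_id)
  else order(records$p_adj, records$p_raw, records$term_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records$rank <- seq_len(nrow(records))
  structure(records, class = c("enrichment_result", "data.frame"),
            label = label, alpha = alpha)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result '%s': %d records, alpha %g\n",
              attr(x, "label"), nrow(x), attr(x, "alpha")))
  NextMethod()
}

#' Run the reference overrepresentation analysis
#'
#' Tests every term with at least one background gene (after true-path
#' propagation) for overrepresentation in the study list with the upper-tail
#' hypergeometric test (or the EASE variant), removes terms with fewer than
#' `min_count` study genes, and applies Benjamini-Hochberg correction over
#' the emitted records. Genes absent from the background are dropped and the
#' mapped count reported.
#'
#' @param study a [gene_list()] or character vector of gene ids.
#' @param annset an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param background optional custom background gene set; defaults to
#'   `annset$background`.
#' @param min_count minimum study genes per term (default 2).
#' @param statistic `"hypergeometric"` (default) or `"ease"`.
#' @param alpha significance level stored with the result (default 0.05).
#' @param adjust_before_filter if `TRUE`, BH correction is applied over all
#'   tested terms before the `min_count` filter (the behaviour of some
#'   tools); default `FALSE` corrects over exactly the emitted records.
#' @return an [enrichment_result()] with columns `term_id`, `name`, `depth`,
#'   `annotation_size`, `study_count`, `study_n`, `pop_count`, `pop_n`,
#'   `p_raw`, `p_adj`, `rank`.
#' @export
run_ora <- function(study, annset, graph, background = NULL, min_count = 2L,
                    statistic = c("hypergeometric", "ease"), alpha = 0.05,
                    adjust_before_filter = FALSE) {
  statistic <- match.arg(statistic)
  label <- if (inherits(study, "gene_list")) study$label else "study"
  genes <- if (inherits(study, "gene_list")) study$genes else unique(as.character(study))
  if (!length(genes)) stop("empty study list")
  if (is.null(background)) background <- annset$background
  background <- unique(as.character(background))
  mapped <- intersect(genes, background)
  if (!length(mapped)) stop("zero study genes map to the background")
  if (length(mapped) < length(genes))
    message(sprintf("%s: %d/%d study genes mapped to background",
                    label, length(mapped), length(genes)))
  if (length(background) < length(mapped))
    stop("background smaller than the mapped study list")

  n <- length(mapped); N <- length(background)
  # universe: every term with pop_count >= 1 in the chosen background
  pop_genes <- lapply(annset$genes_by_term, intersect, background)
  pop_count <- lengths(pop_genes)
  keep <- pop_count >= 1L
  term_ids <- names(pop_genes)[keep]
  if (!length(term_ids)) stop("no term has annotated genes in this background")
  pop_count <- pop_count[keep]
  study_count <- vapply(pop_genes[keep], function(g)
    length(intersect(g, mapped)), integer(1))

  p_raw <- if (statistic == "ease") ease_score(study_count, n, pop_count, N)
           else hypergeom_upper(study_count, n, pop_count, N)

  rec <- data.frame(term_id = term_ids,
                    study_count = as.integer(study_count),
                    study_n = n,
                    pop_count = as.integer(pop_count),
                    pop_n = N,
                    p_raw = p_raw,
                    stringsAsFactors = FALSE)
  if (adjust_before_filter) {
    rec$p_adj <- adjust_pvalues(rec$p_raw)
    rec <- rec[rec$study_count >= min_count, , drop = FALSE]
  } else {
    rec <- rec[rec$study_count >= min_count, , drop = FALSE]
    rec$p_adj <- adjust_pvalues(rec$p_raw)
  }
  idx <- match(rec$term_id, graph$terms$term_id)
  rec$name <- graph$terms$name[idx]
  rec$depth <- term_depth(graph, rec$term_id)
  rec$annotation_size <- vapply(rec$term_id, function(t)
    annotation_size(annset, t), integer(1))
  rec <- rec[, c("term_id", "name", "depth", "annotation_size", "study_count",
                 "study_n", "pop_count", "pop_n", "p_raw", "p_adj")]
  enrichment_result(rec, label = label, alpha = alpha)
}

#' Write an enrichment result as TSV
#'
#' @param result an [enrichment_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  write_tsv_plain(as.data.frame(result), path)
}
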