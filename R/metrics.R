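# Benchmark metrics: significant-term counts, the semantic-similarity
# confusion matrix (accuracy, FPR), target identification/ranking, and top-k
# term-specificity profiles.

#' Count significant records in an enrichment result
#'
#' Strict inequality: a record is significant when its (adjusted) p-value is
#' strictly below `alpha`.
#'
#' @param result an [enrichment_result()].
#' @param alpha significance level (default 0.05).
#' @param use_adjusted use `p_adj` (default) or `p_raw`.
#' @return integer count.
#' @export
count_significant <- function(result, alpha = 0.05, use_adjusted = TRUE) {
  if (!nrow(result)) return(0L)
  p <- if (use_adjusted) result$p_adj else result$p_raw
  sum(p < alpha)
}

#' Semantic-similarity confusion matrix of an enrichment result
#'
#' Each record's maximum Wang similarity `m` to the target terms, together
#' with its significance (`p_adj < alpha`), classifies it:
#' \itemize{
#'   \item `m >= hi` and significant: true positive (an expected term, found);
#'   \item `m >= hi`, not significant: false negative (expected, missed);
#'   \item `m < lo` and significant: false positive (unrelated, yet called);
#'   \item `m < lo`, not significant: true negative;
#'   \item `lo <= m < hi`: excluded from the matrix but counted.
#' }
#' Records whose term id does not resolve in the graph are dropped with a
#' message. Accuracy = (TP+TN)/(TP+TN+FP+FN) and FPR = FP/(FP+TN); either is
#' `NA` (an explicit undefined marker) when its denominator is zero.
#'
#' @param result an [enrichment_result()].
#' @param targets nonempty character vector of target term ids.
#' @param graph an [ontology_graph()].
#' @param weights a [wang_weights()].
#' @param alpha significance level (default 0.05).
#' @param hi high similarity threshold (default 0.7).
#' @param lo low similarity threshold (default 0.3).
#' @return object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`, `n_excluded_mid_ss`, `n_dropped`, `accuracy`, `fpr`.
#' @export
confusion_matrix <- function(result, targets, graph, weights = wang_weights(),
                             alpha = 0.05, hi = 0.7, lo = 0.3) {
  if (!length(targets)) stop("empty target set")
  ids <- resolve_term(graph, result$term_id)
  dropped <- sum(is.na(ids))
  if (dropped)
    message(dropped, " record(s) with unresolvable term ids dropped")
  keep <- !is.na(ids)
  if (!any(keep)) {
    out <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L, n_excluded_mid_ss = 0L,
                n_dropped = dropped, accuracy = NA_real_, fpr = NA_real_)
    return(structure(out, class = "confusion_matrix"))
  }
  ids <- ids[keep]
  sig <- result$p_adj[keep] < alpha
  m <- vapply(ids, max_similarity_to_targets, numeric(1),
              graph = graph, targets = targets, weights = weights)
  tp <- sum(m >= hi & sig); fn <- sum(m >= hi & !sig)
  fp <- sum(m < lo & sig);  tn <- sum(m < lo & !sig)
  excl <- sum(m >= lo & m < hi)
  acc_den <- tp + tn + fp + fn
  fpr_den <- fp + tn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_excluded_mid_ss = excl, n_dropped = dropped,
                 accuracy = if (acc_den > 0) (tp + tn) / acc_den else NA_real_,
                 fpr = if (fpr_den > 0) fp / fpr_den else NA_real_),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: TP %d  FP %d  TN %d  FN %d  (mid-SS excluded %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_excluded_mid_ss))
  cat(sprintf("  accuracy %s  FPR %s\n",
              format(x$accuracy, digits = 4), format(x$fpr, digits = 4)))
  invisible(x)
}

#' Target identification and ranking report
#'
#' A target is identified when its exact term id appears in the result with
#' an adjusted p-value below `alpha`; its rank is the 1-based position in
#' the (p_adj, p_raw, term_id)-ordered table. The median over identified
#' targets uses the mean of the two central ranks for even counts, so
#' half-integer medians are possible.
#'
#' @param result an [enrichment_result()].
#' @param targets nonempty character vector of target term ids.
#' @param graph optional [ontology_graph()] used to resolve alternate ids.
#' @param alpha significance level (default 0.05).
#' @param rank_within `"all"` (default): rank within the full result table;
#'   `"significant"`: rank within significant records only.
#' @return object of class `target_report`: list with `n_targets`,
#'   `n_identified`, `ranks` (named numeric over identified targets),
#'   `median_rank` (`NA` when nothing identified).
#' @export
target_report <- function(result, targets, graph = NULL, alpha = 0.05,
                          rank_within = c("all", "significant")) {
  rank_within <- match.arg(rank_within)
  if (!length(targets)) stop("empty target set")
  ids <- result$term_id
  if (!is.null(graph)) {
    res <- resolve_term(graph, ids)
    ids <- ifelse(is.na(res), ids, res)
  }
  pos <- if (rank_within == "significant") {
    sig_idx <- which(result$p_adj < alpha)
    stats::setNames(seq_along(sig_idx), ids[sig_idx])
  } else {
    stats::setNames(seq_along(ids), ids)
  }
  ranks <- numeric(0)
  for (t in targets) {
    i <- match(t, ids)
    if (!is.na(i) && result$p_adj[i] < alpha) ranks[[t]] <- unname(pos[[t]])
  }
  structure(list(n_targets = length(targets),
                 n_identified = length(ranks),
                 ranks = ranks,
                 median_rank = if (length(ranks)) stats::median(ranks) else NA_real_),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("target_report: %d/%d targets identified, median rank %s\n",
              x$n_identified, x$n_targets, format(x$median_rank)))
  invisible(x)
}

#' Top-k specificity profile of an enrichment result
#'
#' Takes the first `min(k, #significant)` significant records in result
#' order (ascending p) and reports the median and mean of their propagated
#' annotation sizes and longest-path depths -- small annotation sizes and
#' large depths indicate specific, informative terms.
#'
#' @param result an [enrichment_result()].
#' @param annset an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param k profile size, typically 20 or 100.
#' @param alpha significance level (default 0.05).
#' @return object of class `specificity_profile`: list with `k`, `n_used`,
#'   `median_annotation_size`, `mean_annotation_size`, `median_depth`,
#'   `mean_depth` (all `NA` when no record is significant).
#' @export
specificity_profile <- function(result, annset, graph, k, alpha = 0.05) {
  stopifnot(k >= 1)
  sig <- result[result$p_adj < alpha, , drop = FALSE]
  n_used <- min(k, nrow(sig))
  if (n_used == 0L) {
    return(structure(list(k = k, n_used = 0L,
                          median_annotation_size = NA_real_,
                          mean_annotation_size = NA_real_,
                          median_depth = NA_real_, mean_depth = NA_real_),
                     class = "specificity_profile"))
  }
  top <- sig[seq_len(n_used), , drop = FALSE]
  sizes <- vapply(top$term_id, function(t) annotation_size(annset, t), integer(1))
  depths <- term_depth(graph, top$term_id)
  structure(list(k = k, n_used = n_used,
                 median_annotation_size = stats::median(sizes),
                 mean_annotation_size = mean(sizes),
                 median_depth = stats::median(depths),
                 mean_depth = mean(depths)),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf(
    "specificity_profile (top %d, %d used): annotation size med %s mean %s; depth med %s mean %s\n",
    x$k, x$n_used, format(x$median_annotation_size),
    format(x$mean_annotation_size), format(x$median_depth),
    format(x$mean_depth)))
  invisible(x)
}

#' Evaluate one or more enrichment results against targets
#'
#' Convenience wrapper producing one metrics row per result: significant
#' counts, confusion matrix with accuracy/FPR, target report, and top-20 /
#' top-100 specificity profiles.
#'
#' @param results a named list of [enrichment_result()] objects (or one).
#' @param targets character vector of target term ids, or `NULL` to skip the
#'   confusion/rank stages.
#' @param annset an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param weights a [wang_weights()].
#' @param alpha,hi,lo thresholds (see [confusion_matrix()]).
#' @param ks specificity profile sizes (default `c(20, 100)`).
#' @return data.frame, one row per result.
#' @export
evaluate_results <- function(results, targets, annset, graph,
                             weights = wang_weights(), alpha = 0.05,
                             hi = 0.7, lo = 0.3, ks = c(20L, 100L)) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r)
      attr(r, "label") %||% "result", character(1))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    row <- data.frame(label = nm,
                      n_records = nrow(r),
                      n_significant = count_significant(r, alpha),
                      n_significant_raw = count_significant(r, alpha,
                                                            use_adjusted = FALSE))
    if (!is.null(targets) && length(targets)) {
      cm <- confusion_matrix(r, targets, graph, weights, alpha, hi, lo)
      tr <- target_report(r, targets, graph, alpha)
      row <- cbind(row, data.frame(
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        excluded = cm$n_excluded_mid_ss, accuracy = cm$accuracy,
        fpr = cm$fpr, n_targets = tr$n_targets,
        n_identified = tr$n_identified, median_rank = tr$median_rank))
    }
    for (k in ks) {
      sp <- specificity_profile(r, annset, graph, k, alpha)
      kdf <- data.frame(sp$n_used, sp$median_annotation_size,
                        sp$mean_annotation_size, sp$median_depth, sp$mean_depth)
      names(kdf) <- paste0(c("n_used_top", "median_size_top", "mean_size_top",
                             "median_depth_top", "mean_depth_top"), k)
      row <- cbind(row, kdf)
    }
    row
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
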