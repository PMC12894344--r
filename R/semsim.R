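# Wang's graph-based semantic similarity between ontology terms.
#
# Each term A defines semantic contributions (S-values) over its ancestor
# closure: S_A(A) = 1 and, walking upward, S_A(t) is the best
# weight-discounted contribution over edges into t from within the closure
# (is_a edges contribute a factor 0.8, part_of 0.6 by default). The
# similarity of two terms is the summed S-values over their shared closure,
# normalised by the total semantic values SV(A) + SV(B).

#' Wang edge-contribution weights
#'
#' @param is_a contribution factor for `is_a` edges (default 0.8).
#' @param part_of contribution factor for `part_of` edges (default 0.6).
#' @return object of class `wang_weights`.
#' @export
wang_weights <- function(is_a = 0.8, part_of = 0.6) {
  if (!(is_a > 0 && is_a < 1 && part_of > 0 && part_of < 1))
    stop("contribution factors must lie in (0, 1)")
  structure(list(is_a = is_a, part_of = part_of), class = "wang_weights")
}

#' Semantic contributions (S-values) of a term's ancestor closure
#'
#' @param graph an [ontology_graph()].
#' @param term_id the anchor term (must not be obsolete).
#' @param weights a [wang_weights()].
#' @return list with `anchor`, `svalues` (named numeric: anchor and each
#'   ancestor -> S-value in (0, 1\]) and `sv_total` (their sum, >= 1).
#' @export
wang_svalues <- function(graph, term_id, weights = wang_weights()) {
  if (!term_id %in% graph$terms$term_id) stop("unknown term id: ", term_id)
  if (graph$terms$is_obsolete[match(term_id, graph$terms$term_id)])
    stop("obsolete term: ", term_id)
  closure <- c(term_id, graph$ancestors[[term_id]])
  s <- stats::setNames(rep(0, length(closure)), closure)
  s[[term_id]] <- 1
  # decreasing depth is a valid reverse-topological order within the closure
  # (every child is strictly deeper than each of its parents)
  ord <- closure[order(graph$depth[closure], decreasing = TRUE)]
  w <- c(is_a = weights$is_a, part_of = weights$part_of)
  for (t in ord) {
    ps <- graph$parents[[t]]
    if (!length(ps)) next
    contrib <- w[graph$relations[[t]]] * s[[t]]
    for (j in seq_along(ps)) {
      if (contrib[[j]] > s[[ps[[j]]]]) s[[ps[[j]]]] <- contrib[[j]]
    }
  }
  list(anchor = term_id, svalues = s, sv_total = sum(s))
}

#' Wang semantic similarity between two terms
#'
#' sim(a, b) = sum over shared closure terms t of (S_a(t) + S_b(t)),
#' divided by SV(a) + SV(b). Symmetric, in (0, 1\] for same-namespace terms
#' (which always share at least the namespace root).
#'
#' @param graph an [ontology_graph()].
#' @param a,b term ids (same namespace).
#' @param weights a [wang_weights()].
#' @return similarity score in \[0, 1\].
#' @export
#' @examples
#' obo <- c("[Term]", "id: T:r", "name: root",
#'          "namespace: biological_process",
#'          "", "[Term]", "id: T:a", "name: a",
#'          "namespace: biological_process", "is_a: T:r",
#'          "", "[Term]", "id: T:b", "name: b",
#'          "namespace: biological_process", "is_a: T:a")
#' g <- parse_obo(obo)
#' wang_similarity(g, "T:a", "T:b")   # 3.24 / 4.24
wang_similarity <- function(graph, a, b, weights = wang_weights()) {
  ns <- graph$terms$namespace[match(c(a, b), graph$terms$term_id)]
  if (anyNA(ns)) stop("unknown term id: ", c(a, b)[is.na(ns)][1])
  if (ns[1] != ns[2])
    stop("namespace mismatch: ", a, " (", ns[1], ") vs ", b, " (", ns[2], ")")
  sa <- wang_svalues(graph, a, weights)
  sb <- wang_svalues(graph, b, weights)
  wang_sim_from_svalues(sa, sb)
}

# shared-closure combination, reused by similarity_matrix on cached S-values
wang_sim_from_svalues <- function(sa, sb) {
  shared <- intersect(names(sa$svalues), names(sb$svalues))
  sum(sa$svalues[shared] + sb$svalues[shared]) / (sa$sv_total + sb$sv_total)
}

#' Maximum similarity of a term to a set of target terms
#'
#' The per-record statistic of the benchmark's confusion matrix: how close
#' an enriched term comes to the closest planted target.
#'
#' @param graph an [ontology_graph()].
#' @param term_id a term id.
#' @param targets nonempty character vector of target term ids.
#' @param weights a [wang_weights()].
#' @return max over targets of [wang_similarity()]; 1 when the term is
#'   itself a target.
#' @export
max_similarity_to_targets <- function(graph, term_id, targets,
                                      weights = wang_weights()) {
  if (!length(targets)) stop("empty target set")
  if (term_id %in% targets) return(1)
  max(vapply(targets, function(t)
    wang_similarity(graph, term_id, t, weights), numeric(1)))
}

#' Pairwise Wang similarity matrix
#'
#' S-value maps are computed once per term, so cost is linear in terms for
#' the closures plus quadratic for the pairwise overlaps.
#'
#' @param graph an [ontology_graph()].
#' @param term_ids character vector of term ids (>= 1).
#' @param weights a [wang_weights()].
#' @return symmetric numeric matrix with unit diagonal, dimnames =
#'   `term_ids`.
#' @export
similarity_matrix <- function(graph, term_ids, weights = wang_weights()) {
  if (!length(term_ids)) stop("need at least one term")
  sv <- lapply(unique(term_ids), wang_svalues, graph = graph, weights = weights)
  names(sv) <- unique(term_ids)
  n <- length(term_ids)
  m <- diag(1, n)
  dimnames(m) <- list(term_ids, term_ids)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- if (term_ids[i] == term_ids[j]) 1
           else wang_sim_from_svalues(sv[[term_ids[i]]], sv[[term_ids[j]]])
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Write a similarity matrix as TSV
#'
#' @param m matrix from [similarity_matrix()].
#' @param path output path.
#' @param shape `"long"` (`term_a`, `term_b`, `score`; upper triangle incl.
#'   diagonal) or `"square"`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(m, path, shape = c("long", "square")) {
  shape <- match.arg(shape)
  if (shape == "square") {
    df <- data.frame(term_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    return(write_tsv_plain(df, path))
  }
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(term_a = rownames(m)[idx[, 1]],
                   term_b = colnames(m)[idx[, 2]],
                   score = m[idx])
  write_tsv_plain(df[order(df$term_a, df$term_b), ], path)
}
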