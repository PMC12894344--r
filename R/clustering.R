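# Term-similarity networks and Markov Clustering of enriched terms.

#' Build a Wang-similarity network over a set of terms
#'
#' Computes all pairwise Wang similarities and keeps edges with weight at or
#' above `cutoff` (inclusive); nodes that lose all their edges remain as
#' isolated nodes so the downstream clustering always partitions the full
#' term set. Duplicate term ids are removed.
#'
#' @param terms character vector of term ids (same namespace).
#' @param graph an [ontology_graph()].
#' @param weights a [wang_weights()].
#' @param cutoff edge-weight pruning threshold (default 0.5).
#' @return object of class `term_network`: list with `nodes` (character) and
#'   `edges` (data.frame `a`, `b`, `weight`, with `a < b`).
#' @export
build_network <- function(terms, graph, weights = wang_weights(),
                          cutoff = 0.5) {
  terms <- unique(terms)
  m <- similarity_matrix(graph, terms, weights)
  idx <- which(upper.tri(m) & m >= cutoff, arr.ind = TRUE)
  edges <- data.frame(a = terms[idx[, 1]], b = terms[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(terms), edges = edges), class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf("term_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a term network as an edge-list TSV
#'
#' @param network a `term_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  write_tsv_plain(network$edges, path)
}

#' Markov Clustering (MCL) of a weighted term network
#'
#' Canonical MCL on the weighted adjacency matrix with unit self-loops:
#' column-normalise, then alternate expansion (matrix power) and inflation
#' (entry-wise power followed by pruning of entries below `prune_eps` and
#' column renormalisation) until the largest entry change falls below `tol`
#' or `max_iter` is reached (non-convergence yields the current
#' interpretation with a warning, never an error). Clusters are read from
#' attractor rows (positive diagonal): each attractor's cluster is the set
#' of columns it attracts; a node attracted by several attractors goes to
#' the largest cluster (tie: the cluster with the lexicographically smallest
#' member). High inflation yields fine-grained clusters.
#'
#' @param network a `term_network` from [build_network()].
#' @param inflation inflation exponent r (default 5.0).
#' @param expansion expansion power (default 2).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param prune_eps entries below this are zeroed after inflation
#'   (default 1e-8).
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   character vectors, sorted members; ordered by decreasing size then
#'   lexicographically smallest member), `inflation`, `converged`,
#'   `iterations`.
#' @export
mcl <- function(network, inflation = 5.0, expansion = 2L, max_iter = 100L,
                tol = 1e-6, prune_eps = 1e-8) {
  nodes <- sort(network$nodes)
  n <- length(nodes)
  if (!n) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges)) {
    ia <- match(network$edges$a, nodes); ib <- match(network$edges$b, nodes)
    A[cbind(ia, ib)] <- network$edges$weight
    A[cbind(ib, ia)] <- network$edges$weight
  }
  diag(A) <- 1   # self-loops before normalisation
  M <- normalise_columns(A)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_eps] <- 0
    Minf <- normalise_columns(Minf)
    if (max(abs(Minf - M)) < tol) {
      M <- Minf; converged <- TRUE; break
    }
    M <- Minf
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; interpreting current matrix")
  clusters <- interpret_mcl(M, nodes)
  structure(list(clusters = clusters, inflation = inflation,
                 converged = converged, iterations = it),
            class = "cluster_set")
}

normalise_columns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1   # a fully pruned column stays zero rather than NaN
  sweep(M, 2, cs, "/")
}

# Read a partition from a (near-)idempotent MCL matrix.
interpret_mcl <- function(M, nodes) {
  eps <- 1e-9
  attractors <- which(diag(M) > eps)
  raw <- lapply(attractors, function(i) nodes[M[i, ] > eps])
  raw <- unique(raw)
  # deterministic precedence: larger cluster first, then smallest member
  if (length(raw)) {
    key <- vapply(raw, function(cl) min(cl), character(1))
    ord <- order(-lengths(raw), key)
    raw <- raw[ord]
  }
  assigned <- character(0)
  clusters <- list()
  for (cl in raw) {
    cl <- setdiff(cl, assigned)   # overlap goes to the earlier (larger) cluster
    if (length(cl)) {
      clusters[[length(clusters) + 1L]] <- sort(cl)
      assigned <- c(assigned, cl)
    }
  }
  leftover <- setdiff(nodes, assigned)   # safety: keep the partition total
  for (x in leftover) clusters[[length(clusters) + 1L]] <- x
  key <- vapply(clusters, function(cl) min(cl), character(1))
  clusters[order(-lengths(clusters), key)]
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (inflation %g, %s in %d iterations)\n",
              length(x$clusters), x$inflation,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  sizes:", paste(lengths(x$clusters), collapse = " "), "\n")
  invisible(x)
}

#' Select the major clusters of a partition
#'
#' Up to `n` clusters with at least `min_size` members, in the `cluster_set`
#' ordering (decreasing size, then smallest member).
#'
#' @param clusters a `cluster_set` from [mcl()].
#' @param n maximum number of clusters (default 15).
#' @param min_size minimum cluster size (default 3).
#' @return list of character vectors (possibly empty).
#' @export
select_major_clusters <- function(clusters, n = 15L, min_size = 3L) {
  big <- clusters$clusters[lengths(clusters$clusters) >= min_size]
  big[seq_len(min(n, length(big)))]
}

#' Summarise clusters with labelling hints
#'
#' Per cluster: size, members, the deepest member, the member with the
#' largest annotation size, and the deepest common ancestor of all members
#' (ties broken by smallest term id) as a suggested label.
#'
#' @param clusters a `cluster_set` or plain list of term-id vectors.
#' @param graph an [ontology_graph()].
#' @param annset optional [annotation_set()].
#' @return data.frame, one row per cluster: `cluster_id`, `size`, `members`
#'   (comma-joined), `deepest_member`, `largest_member`, `common_ancestor`,
#'   `common_ancestor_name`.
#' @export
annotate_clusters <- function(clusters, graph, annset = NULL) {
  cls <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  rows <- lapply(seq_along(cls), function(i) {
    cl <- cls[[i]]
    depths <- term_depth(graph, cl)
    deepest <- cl[order(-depths, cl)][1]
    largest <- if (!is.null(annset)) {
      sizes <- vapply(cl, function(t) annotation_size(annset, t), integer(1))
      cl[order(-sizes, cl)][1]
    } else NA_character_
    # self-or-ancestor closure intersection = common ancestors
    common <- Reduce(intersect, lapply(cl, function(t)
      c(t, graph$ancestors[[t]])))
    ca <- if (length(common)) {
      cd <- term_depth(graph, common)
      common[order(-cd, common)][1]
    } else NA_character_
    data.frame(cluster_id = i, size = length(cl),
               members = paste(cl, collapse = ","),
               deepest_member = deepest, largest_member = largest,
               common_ancestor = ca,
               common_ancestor_name = if (is.na(ca)) NA_character_ else
                 graph$terms$name[match(ca, graph$terms$term_id)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write clusters as TSV (one row per member term)
#'
#' @param clusters a `cluster_set` or list of term-id vectors.
#' @param graph an [ontology_graph()].
#' @param path output path.
#' @param annset optional [annotation_set()] for annotation sizes.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, graph, path, annset = NULL) {
  cls <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  rows <- lapply(seq_along(cls), function(i) {
    cl <- cls[[i]]
    data.frame(cluster_id = i, size = length(cl), term_id = cl,
               name = graph$terms$name[match(cl, graph$terms$term_id)],
               depth = term_depth(graph, cl),
               annotation_size = if (is.null(annset)) NA_integer_ else
                 vapply(cl, function(t) annotation_size(annset, t), integer(1)),
               stringsAsFactors = FALSE)
  })
  write_tsv_plain(do.call(rbind, rows), path)
}
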