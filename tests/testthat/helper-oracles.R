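# Independent oracles, implemented from definitions and kept separate from
# the package code paths they check.

# All ancestors by iterated one-step parent expansion (reachability closure).
oracle_ancestors <- function(graph, term_id) {
  seen <- character(0)
  frontier <- graph$parents[[term_id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier],
                                      use.names = FALSE)), seen)
  }
  seen
}

# Longest-path depth by exhaustive enumeration of every ascending path.
oracle_depth <- function(graph, term_id) {
  best <- 0L
  walk <- function(node, len) {
    ps <- graph$parents[[node]]
    if (!length(ps)) {
      best <<- max(best, len)
    } else {
      for (p in ps) walk(p, len + 1L)
    }
  }
  walk(term_id, 0L)
  best
}

# Wang S-values as max-over-all-ascending-paths product of edge weights.
oracle_svalues <- function(graph, anchor, w_is_a = 0.8, w_part_of = 0.6) {
  best <- new.env(parent = emptyenv())
  assign(anchor, 1, envir = best)
  walk <- function(node, val) {
    ps <- graph$parents[[node]]
    rs <- graph$relations[[node]]
    for (j in seq_along(ps)) {
      v <- val * if (rs[[j]] == "is_a") w_is_a else w_part_of
      prev <- if (exists(ps[[j]], envir = best)) get(ps[[j]], envir = best) else 0
      if (v > prev) assign(ps[[j]], v, envir = best)
      walk(ps[[j]], v)
    }
  }
  walk(anchor, 1)
  vals <- mget(ls(best), envir = best)
  unlist(vals)
}

oracle_wang_similarity <- function(graph, a, b, w_is_a = 0.8, w_part_of = 0.6) {
  sa <- oracle_svalues(graph, a, w_is_a, w_part_of)
  sb <- oracle_svalues(graph, b, w_is_a, w_part_of)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# Upper-tail hypergeometric by exhaustive enumeration of every size-n draw
# from a population whose first K elements are successes.
oracle_hyper_tail_table <- function(N, K, n) {
  if (n == 0L) return(stats::setNames(1, "0"))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  ks <- 0:min(n, K)
  tails <- vapply(ks, function(k) mean(succ >= k), numeric(1))
  stats::setNames(tails, as.character(ks))
}

# Benjamini-Hochberg step-up straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dense, loop-based MCL written independently of the package implementation.
oracle_mcl <- function(network, inflation = 5, expansion = 2L,
                       max_iter = 200L, tol = 1e-6, prune_eps = 1e-8) {
  nodes <- sort(network$nodes)
  n <- length(nodes)
  M <- matrix(0, n, n)
  ed <- network$edges
  for (r in seq_len(nrow(ed))) {
    i <- which(nodes == ed$a[r]); j <- which(nodes == ed$b[r])
    M[i, j] <- ed$weight[r]; M[j, i] <- ed$weight[r]
  }
  for (i in seq_len(n)) M[i, i] <- 1
  colnorm <- function(X) {
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) s <- s + X[i, j]
      if (s > 0) for (i in seq_len(n)) X[i, j] <- X[i, j] / s
    }
    X
  }
  M <- colnorm(M)
  for (it in seq_len(max_iter)) {
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    I <- E
    for (i in seq_len(n)) for (j in seq_len(n)) {
      v <- E[i, j]^inflation
      I[i, j] <- if (v < prune_eps) 0 else v
    }
    I <- colnorm(I)
    delta <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      delta <- max(delta, abs(I[i, j] - M[i, j]))
    M <- I
    if (delta < tol) break
  }
  # attractor rows -> clusters; overlaps to the larger cluster (tie: smallest
  # member); uncovered nodes become singletons
  eps <- 1e-9
  raw <- list()
  for (i in seq_len(n)) if (M[i, i] > eps) {
    cl <- nodes[M[i, ] > eps]
    dup <- any(vapply(raw, function(x) identical(sort(x), sort(cl)), logical(1)))
    if (!dup) raw[[length(raw) + 1L]] <- cl
  }
  if (length(raw)) {
    ord <- order(-vapply(raw, length, integer(1)),
                 vapply(raw, min, character(1)))
    raw <- raw[ord]
  }
  clusters <- list(); assigned <- character(0)
  for (cl in raw) {
    cl <- setdiff(cl, assigned)
    if (length(cl)) {
      clusters[[length(clusters) + 1L]] <- sort(cl)
      assigned <- c(assigned, cl)
    }
  }
  for (x in setdiff(nodes, assigned)) clusters[[length(clusters) + 1L]] <- x
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, character(1)))
  clusters[ord]
}

# canonical form for comparing partitions regardless of ordering
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, min, character(1)))]
}
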