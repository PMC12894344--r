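# Synthetic benchmark construction: miniature ontologies with heavy-tailed
# annotations, random negative-control lists, planted-target positive
# controls, and nested downsampling series. Everything is a pure function of
# (parameters, seed); the global RNG state is left untouched.

# Derive a purpose-specific sub-seed so that passing the same user seed to
# different generators (ontology synthesis, list sampling, ...) never reuses
# overlapping segments of one RNG stream: distinct Mersenne-Twister seeds
# give effectively independent streams, identical (seed, purpose) pairs stay
# fully reproducible.
derive_seed <- function(seed, purpose) {
  as.integer((as.numeric(seed) %% 48271 * 48271 + purpose * 8191) %% 2147483647)
}

# run code under a local RNG seeded with `seed`, restoring global state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for a synthetic ontology
#'
#' Describes a single-rooted, layered DAG in the biological_process
#' namespace with genes annotated to leaf terms under a heavy-tailed
#' (log-normal) annotation-size distribution, emulating the skewed
#' annotation sizes of the real GO.
#'
#' @param n_terms total number of terms including the root (default 80).
#' @param max_depth deepest layer (default 5); every depth 1..max_depth is
#'   populated.
#' @param branching numeric length-2 range for the per-layer growth factor
#'   (default `c(2, 3)`).
#' @param part_of_fraction probability an edge is `part_of` rather than
#'   `is_a` (default 0.2).
#' @param second_parent_prob probability a term gets a second parent from a
#'   shallower layer (default 0.15).
#' @param n_genes size of the synthetic genome / default background
#'   (default 2000, a 1:10 miniature of the human protein-coding genome so
#'   that term sizes, list sizes and genome keep realistic proportions at 80
#'   terms).
#' @param ann_meanlog,ann_sdlog log-normal parameters of leaf annotation
#'   sizes (defaults `log(60)` and `1`: median 60 genes with a heavy right
#'   tail, mirroring the skewed annotation-size distribution of the GO).
#' @param annotated_fraction fraction of the genome eligible for direct
#'   annotation (default 0.9, matching the high GO coverage of protein-coding
#'   genes). Leaves draw their genes from this shared pool, so genes belong
#'   to 2-3 terms on average -- the multifunctionality that makes real
#'   enrichment results contain weakly overlapping, non-significant records.
#' @param seed RNG seed (default 1).
#' @return object of class `synthetic_ontology_spec`.
#' @export
synthetic_ontology_spec <- function(n_terms = 80L, max_depth = 5L,
                                    branching = c(2, 3),
                                    part_of_fraction = 0.2,
                                    second_parent_prob = 0.15,
                                    n_genes = 2000L,
                                    ann_meanlog = log(60), ann_sdlog = 1,
                                    annotated_fraction = 0.9,
                                    seed = 1L) {
  stopifnot(n_terms >= 2, max_depth >= 1, length(branching) == 2,
            branching[1] <= branching[2],
            part_of_fraction >= 0, part_of_fraction <= 1, n_genes >= 1,
            annotated_fraction > 0, annotated_fraction <= 1)
  structure(list(n_terms = as.integer(n_terms),
                 max_depth = as.integer(max_depth),
                 branching = branching,
                 part_of_fraction = part_of_fraction,
                 second_parent_prob = second_parent_prob,
                 n_genes = as.integer(n_genes),
                 ann_meanlog = ann_meanlog, ann_sdlog = ann_sdlog,
                 annotated_fraction = annotated_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_ontology_spec")
}

#' Synthesize a miniature ontology and annotation set
#'
#' Builds a layered, single-rooted DAG: terms are placed at depths
#' 1..max_depth, each with one parent in the previous layer and, with
#' probability `second_parent_prob`, a second parent in any shallower layer;
#' edge relations are `part_of` with probability `part_of_fraction`, else
#' `is_a`. Genes are annotated directly to leaf terms with log-normal
#' (heavy-tailed) set sizes and propagated by the true-path rule; the
#' background is the full synthetic genome.
#'
#' @param spec a [synthetic_ontology_spec()].
#' @return list with elements `graph` (an [ontology_graph()]) and `annset`
#'   (an [annotation_set()]).
#' @export
synthesize_ontology <- function(spec = synthetic_ontology_spec()) {
  stopifnot(inherits(spec, "synthetic_ontology_spec"))
  if (spec$n_terms - 1L < spec$max_depth)
    stop("infeasible spec: need at least one term per depth layer (",
         spec$n_terms - 1L, " non-root terms for depth ", spec$max_depth, ")")
  with_local_seed(derive_seed(spec$seed, 1L), {
    # layer sizes: geometric-ish growth within the branching range, with one
    # term reserved for every deeper layer so each depth is populated
    remaining <- spec$n_terms - 1L
    layer_sizes <- integer(spec$max_depth)
    prev <- 1L
    for (d in seq_len(spec$max_depth)) {
      reserve <- spec$max_depth - d
      cap <- remaining - reserve
      if (cap < 1L) stop("infeasible spec: branching cannot reach n_terms")
      want <- max(1L, round(prev * stats::runif(1, spec$branching[1],
                                                spec$branching[2])))
      layer_sizes[d] <- min(want, cap)
      remaining <- remaining - layer_sizes[d]
      prev <- layer_sizes[d]
    }
    layer_sizes[spec$max_depth] <- layer_sizes[spec$max_depth] + remaining

    ids <- sprintf("SYN:%07d", seq_len(spec$n_terms))
    root <- ids[1]
    layers <- vector("list", spec$max_depth + 1L)
    layers[[1]] <- root
    nxt <- 2L
    erec <- vector("list", 2L * spec$n_terms)
    ne <- 0L
    pick_rel <- function() if (stats::runif(1) < spec$part_of_fraction)
      "part_of" else "is_a"
    for (d in seq_len(spec$max_depth)) {
      layer <- ids[nxt:(nxt + layer_sizes[d] - 1L)]
      nxt <- nxt + layer_sizes[d]
      layers[[d + 1L]] <- layer
      shallower <- unlist(layers[seq_len(d)], use.names = FALSE)
      for (t in layer) {
        p1 <- if (length(layers[[d]]) == 1L) layers[[d]] else
          sample(layers[[d]], 1L)
        ne <- ne + 1L
        erec[[ne]] <- data.frame(child = t, parent = p1, relation = pick_rel())
        others <- setdiff(shallower, p1)
        if (length(others) && stats::runif(1) < spec$second_parent_prob) {
          p2 <- if (length(others) == 1L) others else sample(others, 1L)
          ne <- ne + 1L
          erec[[ne]] <- data.frame(child = t, parent = p2,
                                   relation = pick_rel())
        }
      }
    }
    edges <- do.call(rbind, erec[seq_len(ne)])
    terms <- data.frame(term_id = ids,
                        name = c("synthetic biological process root",
                                 paste("synthetic process", ids[-1])),
                        namespace = "biological_process",
                        is_obsolete = FALSE, stringsAsFactors = FALSE)
    graph <- ontology_graph(terms, edges)

    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    pool <- sample(genes, max(2L, round(spec$annotated_fraction * spec$n_genes)))
    leaves <- ids[lengths(graph$children[ids]) == 0L]
    drec <- lapply(leaves, function(t) {
      size <- max(2L, min(length(pool),
                          round(stats::rlnorm(1, spec$ann_meanlog,
                                              spec$ann_sdlog))))
      data.frame(gene_id = sample(pool, size), term_id = t,
                 stringsAsFactors = FALSE)
    })
    annset <- annotation_set(do.call(rbind, drec), graph, background = genes)
    list(graph = graph, annset = annset)
  })
}

#' Bundle of benchmark gene lists with planted targets
#'
#' @param gene_lists named list of [gene_list()] objects.
#' @param targets named list (label -> character vector of target term ids);
#'   may be empty for negative controls.
#' @param provenance list of generation parameters (including the seed).
#' @return object of class `benchmark_bundle`.
#' @export
benchmark_bundle <- function(gene_lists, targets = list(), provenance = list()) {
  structure(list(gene_lists = gene_lists, targets = targets,
                 provenance = provenance),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("benchmark_bundle: %d lists (%d with targets)\n",
              length(x$gene_lists), sum(names(x$gene_lists) %in% names(x$targets))))
  invisible(x)
}

#' Random negative-control gene lists
#'
#' Samples genes uniformly without replacement from the background:
#' `replicates` lists per size, no targets attached, reproducible under
#' `seed`.
#'
#' @param background character vector of background gene ids.
#' @param sizes list sizes (default `c(500, 200, 100, 50)`).
#' @param replicates lists per size (default 5).
#' @param seed RNG seed.
#' @return a [benchmark_bundle()] with labels `random<size>_r<replicate>`.
#' @export
make_random_lists <- function(background, sizes = c(500L, 200L, 100L, 50L),
                              replicates = 5L, seed = 1L) {
  background <- unique(as.character(background))
  if (length(background) < max(sizes))
    stop("background (", length(background),
         ") smaller than the largest requested size (", max(sizes), ")")
  with_local_seed(derive_seed(seed, 2L), {
    lists <- list()
    for (size in sizes) for (r in seq_len(replicates)) {
      lab <- sprintf("random%d_r%d", size, r)
      lists[[lab]] <- gene_list(sample(background, size), label = lab)
    }
    benchmark_bundle(lists, provenance = list(kind = "random", sizes = sizes,
                                              replicates = replicates,
                                              seed = seed))
  })
}

#' Planted-target positive-control gene lists
#'
#' Each list is the deduplicated union of the target terms' propagated gene
#' sets, brought to the requested size by seeded sampling within those sets
#' (every target keeps a share proportional to its set size, at least one
#' gene). Pairwise Jaccard overlaps of the target gene sets are recorded in
#' the provenance so "minimal overlap" between chosen targets is auditable.
#'
#' @param annset an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param targets character vector of target term ids (used for every size),
#'   or a named list size -> term ids.
#' @param sizes requested list sizes.
#' @param seed RNG seed.
#' @return a [benchmark_bundle()] with labels `target<size>`; `targets`
#'   maps each label to its target terms.
#' @export
make_target_lists <- function(annset, graph, targets, sizes, seed = 1L) {
  by_size <- if (is.list(targets)) targets else
    stats::setNames(rep(list(targets), length(sizes)), as.character(sizes))
  with_local_seed(derive_seed(seed, 3L), {
    lists <- list(); tgt <- list(); jacc <- list()
    for (size in sizes) {
      tt <- by_size[[as.character(size)]]
      if (is.null(tt)) stop("no targets given for size ", size)
      bad <- tt[!tt %in% graph$terms$term_id]
      if (length(bad)) stop("unknown target term: ", bad[1])
      sets <- lapply(tt, function(t) annset$genes_by_term[[t]])
      if (any(lengths(sets) == 0L))
        stop("target term with no annotated genes: ", tt[lengths(sets) == 0L][1])
      u <- unique(unlist(sets, use.names = FALSE))
      if (length(u) < size)
        stop("union of target gene sets (", length(u),
             ") smaller than requested size ", size,
             "; shortfall ", size - length(u))
      if (length(u) == size) {
        genes <- u
      } else {
        # proportional quota per target, >= 1, then top up from the remainder
        quota <- pmax(1L, floor(size * lengths(sets) / sum(lengths(sets))))
        genes <- character(0)
        for (i in seq_along(sets)) {
          pool <- setdiff(sets[[i]], genes)
          take <- min(quota[i], length(pool))
          if (take > 0L)
            genes <- c(genes, if (length(pool) == 1L) pool else
              sample(pool, take))
        }
        rest <- setdiff(u, genes)
        need <- size - length(genes)
        if (need > 0L)
          genes <- c(genes, if (length(rest) == 1L) rest else
            sample(rest, need))
        genes <- genes[seq_len(size)]
      }
      lab <- sprintf("target%d", size)
      lists[[lab]] <- gene_list(genes, label = lab)
      tgt[[lab]] <- tt
      if (length(sets) >= 2) {
        jm <- outer(seq_along(sets), seq_along(sets), Vectorize(function(i, j)
          length(intersect(sets[[i]], sets[[j]])) /
            length(union(sets[[i]], sets[[j]]))))
        dimnames(jm) <- list(tt, tt)
        jacc[[lab]] <- jm
      }
    }
    benchmark_bundle(lists, targets = tgt,
                     provenance = list(kind = "target", sizes = sizes,
                                       seed = seed, target_jaccard = jacc))
  })
}

#' Downsample a gene list into a (nested) size series
#'
#' @param x a [gene_list()].
#' @param sizes decreasing sizes, each at most `length(x)`.
#' @param seed RNG seed.
#' @param nested if `TRUE` (default) each smaller list is a subset of the
#'   next larger one.
#' @return named list of [gene_list()] objects (one per size).
#' @export
downsample_series <- function(x, sizes, seed = 1L, nested = TRUE) {
  stopifnot(inherits(x, "gene_list"))
  if (any(sizes > length(x$genes)))
    stop("requested size exceeds list size ", length(x$genes))
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  with_local_seed(derive_seed(seed, 4L), {
    out <- list()
    current <- x$genes
    for (size in sizes) {
      pool <- if (nested) current else x$genes
      current <- if (size == length(pool)) pool else sample(pool, size)
      lab <- sprintf("%s_%d", x$label, size)
      out[[lab]] <- gene_list(current, label = lab)
    }
    out
  })
}

#' Write a benchmark bundle to a directory
#'
#' One plain-text gene list per file plus a JSON manifest recording labels,
#' sizes, targets and provenance.
#'
#' @param bundle a [benchmark_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(bundle$gene_lists))
    write_gene_list(bundle$gene_lists[[lab]], file.path(dir, paste0(lab, ".txt")))
  manifest <- list(
    lists = lapply(bundle$gene_lists, function(gl)
      list(label = gl$label, size = length(gl$genes))),
    targets = bundle$targets,
    provenance = bundle$provenance[setdiff(names(bundle$provenance),
                                           "target_jaccard")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Exclusive branches of a single-rooted ontology
#'
#' For each child of the root ("branch head"), the terms whose whole ancestor
#' closure stays inside that head's subtree (plus the root). Such terms share
#' no ancestors with other branches except the root, so their Wang similarity
#' across branches is minimal.
#'
#' @param graph a single-rooted [ontology_graph()].
#' @return named list head term id -> character vector of exclusive branch
#'   members (the head included).
#' @export
exclusive_branches <- function(graph) {
  if (length(graph$roots) != 1L) stop("graph must have a single root")
  root <- graph$roots
  heads <- graph$children[[root]]
  out <- lapply(heads, function(h) {
    desc <- names(Filter(function(anc) h %in% anc, graph$ancestors))
    desc <- c(h, desc)
    desc[vapply(desc, function(t)
      all(graph$ancestors[[t]] %in% c(root, h, desc)), logical(1))]
  })
  names(out) <- heads
  out
}

#' Select benchmark target terms with minimal overlap
#'
#' Picks one deep, moderately sized term per exclusive branch (largest
#' branches first): targets in different branches share no ancestors except
#' the root, emulating the minimal-overlap target selection of benchmark
#' gene lists built from distinct biological processes.
#'
#' @param graph a single-rooted [ontology_graph()].
#' @param annset an [annotation_set()].
#' @param n_targets number of targets wanted (default 3).
#' @param depth_min minimum longest-path depth of a target (default 3).
#' @param size_range admissible propagated annotation sizes (default
#'   `c(15, 120)`): specific enough to be informative, large enough to seed a
#'   gene list.
#' @return character vector of up to `n_targets` term ids (one per branch).
#' @export
select_branch_targets <- function(graph, annset, n_targets = 3L,
                                  depth_min = 3L, size_range = c(15L, 120L)) {
  branches <- exclusive_branches(graph)
  branches <- branches[order(-lengths(branches))]
  tg <- character(0)
  for (b in branches) {
    cand <- b[term_depth(graph, b) >= depth_min]
    if (!length(cand)) next
    sz <- vapply(cand, function(t) annotation_size(annset, t), integer(1))
    keep <- sz >= size_range[1] & sz <= size_range[2]
    if (any(keep)) {
      cand <- cand[keep]; sz <- sz[keep]
      tg <- c(tg, cand[order(sz, cand)][1])
    }
    if (length(tg) == n_targets) break
  }
  tg
}
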