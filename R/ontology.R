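# Ontology DAG container and OBO parsing.
#
# The graph is stored as parallel adjacency lists keyed by term id: for each
# term a character vector of parent ids and an equally long vector of edge
# relations ("is_a" / "part_of"). Ancestor closures and longest-path depths
# are precomputed at construction time in one topological pass, so downstream
# semantic-similarity and propagation code is lookup-only.

#' Construct an ontology graph from term and edge tables
#'
#' Low-level constructor used by [parse_obo()] and [synthesize_ontology()].
#' Validates acyclicity, resolves roots, and precomputes ancestor closures
#' and longest-path depths.
#'
#' @param terms data.frame with columns `term_id`, `name`, `namespace`,
#'   `is_obsolete` (logical).
#' @param edges data.frame with columns `child`, `parent`,
#'   `relation` (`"is_a"` or `"part_of"`). May have zero rows.
#' @param namespace_filter optional namespace; terms of other namespaces are
#'   dropped (edges touching them too).
#' @param alt_ids optional named character vector mapping alternate ids to
#'   primary ids (kept for annotation resolution).
#'
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (data.frame), `parents`, `relations`, `children`,
#'   `ancestors` (named lists), `depth` (named integer), `roots`
#'   (character), `alt_ids`, `namespace_filter`.
#' @export
ontology_graph <- function(terms, edges, namespace_filter = NULL,
                           alt_ids = character()) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "name", "namespace", "is_obsolete") %in% names(terms)))
  if (anyDuplicated(terms$term_id))
    stop("duplicate term ids: ", terms$term_id[duplicated(terms$term_id)][1])
  if (!is.null(namespace_filter)) {
    keep <- terms$namespace == namespace_filter
    terms <- terms[keep, , drop = FALSE]
    if (nrow(edges)) {
      edges <- edges[edges$child %in% terms$term_id &
                     edges$parent %in% terms$term_id, , drop = FALSE]
    }
  }
  if (nrow(terms) == 0L) stop("ontology has no terms (after namespace filter)")
  ids <- terms$term_id

  if (nrow(edges)) {
    missing_parent <- setdiff(edges$parent, ids)
    # parents outside the namespace filter were dropped above, so any leftover
    # unknown parent is a real referential error
    if (length(missing_parent))
      stop("unknown parent id referenced: ", missing_parent[1])
    missing_child <- setdiff(edges$child, ids)
    if (length(missing_child))
      stop("unknown child id referenced: ", missing_child[1])
    bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
    if (length(bad_rel)) stop("unsupported relation: ", bad_rel[1])
    # obsolete terms carry no edges
    obs <- terms$term_id[terms$is_obsolete]
    edges <- edges[!(edges$child %in% obs) & !(edges$parent %in% obs), , drop = FALSE]
  }

  parents <- rep(list(character()), length(ids)); names(parents) <- ids
  relations <- rep(list(character()), length(ids)); names(relations) <- ids
  children <- rep(list(character()), length(ids)); names(children) <- ids
  if (nrow(edges)) {
    sp <- split(seq_len(nrow(edges)), edges$child)
    for (ch in names(sp)) {
      parents[[ch]] <- edges$parent[sp[[ch]]]
      relations[[ch]] <- edges$relation[sp[[ch]]]
    }
    sc <- split(edges$child, edges$parent)
    for (pa in names(sc)) children[[pa]] <- sc[[pa]]
  }

  topo <- topological_order(ids, parents)   # errors on cycles
  n_par <- lengths(parents)
  roots <- ids[n_par == 0L & !terms$is_obsolete]

  depth <- stats::setNames(rep(0L, length(ids)), ids)
  ancestors <- rep(list(character()), length(ids)); names(ancestors) <- ids
  for (id in topo) {   # parents before children
    ps <- parents[[id]]
    if (length(ps)) {
      depth[[id]] <- max(depth[ps]) + 1L
      ancestors[[id]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
    }
  }

  structure(list(terms = terms, parents = parents, relations = relations,
                 children = children, ancestors = ancestors, depth = depth,
                 roots = roots, alt_ids = alt_ids,
                 namespace_filter = namespace_filter),
            class = "ontology_graph")
}

# Kahn topological sort over the parent adjacency (edges child -> parent);
# returned order lists every parent before its children. Errors with one
# cycle member named if the graph is cyclic.
topological_order <- function(ids, parents) {
  n_unmet <- lengths(parents)
  names(n_unmet) <- ids
  ready <- ids[n_unmet == 0L]
  children <- rep(list(character()), length(ids)); names(children) <- ids
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  out <- character(0)
  while (length(ready)) {
    id <- ready[[1]]; ready <- ready[-1]
    out <- c(out, id)
    for (ch in children[[id]]) {
      n_unmet[[ch]] <- n_unmet[[ch]] - 1L
      if (n_unmet[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) != length(ids)) {
    cyc <- ids[!(ids %in% out)]
    stop("cycle detected in ontology involving term ", cyc[1])
  }
  out
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%d obsolete), %d roots, max depth %d\n",
              nrow(x$terms), sum(x$terms$is_obsolete), length(x$roots),
              max(x$depth)))
  if (!is.null(x$namespace_filter))
    cat("  namespace filter:", x$namespace_filter, "\n")
  invisible(x)
}

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, `is_a`, `relationship:
#' part_of`, `alt_id`, `replaced_by`, `is_obsolete`). Obsolete terms are
#' retained but flagged and stripped of edges; `alt_id` and `replaced_by`
#' map to the primary id; `consider` lines are ignored. Other relationship
#' types (e.g. regulates) are ignored.
#'
#' @param path path to an OBO file, or a character vector of its lines.
#' @param namespace optional namespace filter
#'   (e.g. `"biological_process"`); terms in other namespaces are dropped.
#' @return an [ontology_graph()].
#' @export
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root", "namespace: biological_process",
#'          "", "[Term]", "id: T:2", "name: leaf",
#'          "namespace: biological_process", "is_a: T:1 ! root")
#' g <- parse_obo(obo)
#' g$roots
parse_obo <- function(path, namespace = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE)
           else as.character(path)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("no stanzas found: not an OBO file?")
  bounds <- c(stanza_starts, length(lines) + 1L)
  default_ns <- sub("^default-namespace:\\s*", "",
                    grep("^default-namespace:", lines, value = TRUE)[1])
  if (is.na(default_ns)) default_ns <- "biological_process"

  rec <- list(); erec <- list(); alt <- character(); repl <- character()
  for (i in seq_along(stanza_starts)) {
    if (lines[stanza_starts[i]] != "[Term]") next
    body <- lines[(stanza_starts[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    val <- function(key) {
      m <- grep(paste0("^", key, ":\\s*"), body, value = TRUE)
      sub("\\s*(!.*)?$", "", sub(paste0("^", key, ":\\s*"), "", m))
    }
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    name <- val("name")[1]; if (is.na(name)) name <- id
    ns <- val("namespace")[1]; if (is.na(ns)) ns <- default_ns
    obsolete <- isTRUE(tolower(val("is_obsolete")[1]) == "true")
    rec[[id]] <- data.frame(term_id = id, name = name, namespace = ns,
                            is_obsolete = obsolete, stringsAsFactors = FALSE)
    for (a in val("alt_id")) alt[[a]] <- id
    rb <- val("replaced_by")
    if (obsolete && length(rb)) repl[[id]] <- rb[1]
    if (!obsolete) {
      for (p in val("is_a"))
        erec[[length(erec) + 1L]] <- data.frame(child = id, parent = p,
                                                relation = "is_a")
      rel <- val("relationship")
      for (r in rel) {
        pieces <- strsplit(trimws(r), "\\s+")[[1]]
        if (length(pieces) >= 2 && pieces[1] == "part_of")
          erec[[length(erec) + 1L]] <- data.frame(child = id, parent = pieces[2],
                                                  relation = "part_of")
      }
    }
  }
  if (!length(rec)) stop("no [Term] stanzas with ids found")
  terms <- do.call(rbind, rec); rownames(terms) <- NULL
  edges <- if (length(erec)) do.call(rbind, erec)
           else data.frame(child = character(), parent = character(),
                           relation = character())
  # replaced_by of an obsolete term acts like an alt_id pointing at the
  # replacement, so annotations to the dead id resolve
  for (dead in names(repl)) if (repl[[dead]] %in% terms$term_id) alt[[dead]] <- repl[[dead]]
  ontology_graph(terms, edges, namespace_filter = namespace, alt_ids = alt)
}

#' Write an ontology graph to OBO format
#'
#' Emits minimal OBO 1.2 `[Term]` stanzas round-trippable by [parse_obo()].
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "default-namespace: biological_process", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$term_id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", graph$terms$namespace[i]))
    if (graph$terms$is_obsolete[i]) out <- c(out, "is_obsolete: true")
    ps <- graph$parents[[id]]; rs <- graph$relations[[id]]
    for (j in seq_along(ps)) {
      out <- c(out, if (rs[j] == "is_a") paste0("is_a: ", ps[j])
                    else paste0("relationship: part_of ", ps[j]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Resolve a term id against a graph (following alt_id mappings)
#'
#' @param graph an [ontology_graph()].
#' @param term_id character vector of term ids.
#' @return character vector: primary ids, `NA` where unresolvable.
#' @export
resolve_term <- function(graph, term_id) {
  out <- ifelse(term_id %in% graph$terms$term_id, term_id,
                unname(graph$alt_ids[term_id]))
  as.character(out)
}

#' Ancestors of a term
#'
#' All terms reachable from `term_id` by following `is_a` and `part_of`
#' edges upward, excluding `term_id` itself.
#'
#' @param graph an [ontology_graph()].
#' @param term_id a single term id.
#' @return character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(graph, term_id) {
  if (!term_id %in% names(graph$ancestors))
    stop("unknown term id: ", term_id)
  graph$ancestors[[term_id]]
}

#' Depth of a term (longest path from a root)
#'
#' Depth counts edges on the LONGEST path from any root down to the term
#' ("maximal level in the ontology"); roots have depth 0. Longest-path depth
#' is the specificity proxy used throughout the benchmark metrics.
#'
#' @param graph an [ontology_graph()].
#' @param term_id one or more term ids.
#' @return integer vector of depths.
#' @export
term_depth <- function(graph, term_id) {
  unknown <- setdiff(term_id, names(graph$depth))
  if (length(unknown)) stop("unknown term id: ", unknown[1])
  unname(graph$depth[term_id])
}

#' Term summary table
#'
#' One row per non-obsolete term: id, name, namespace, longest-path depth and
#' (if an annotation set is supplied) propagated annotation size.
#'
#' @param graph an [ontology_graph()].
#' @param annset optional [annotation_set()] for annotation sizes.
#' @return data.frame with columns `term_id`, `name`, `namespace`, `depth`
#'   and optionally `annotation_size`.
#' @export
term_table <- function(graph, annset = NULL) {
  tt <- graph$terms[!graph$terms$is_obsolete, , drop = FALSE]
  out <- data.frame(term_id = tt$term_id, name = tt$name,
                    namespace = tt$namespace,
                    depth = term_depth(graph, tt$term_id),
                    stringsAsFactors = FALSE)
  if (!is.null(annset))
    out$annotation_size <- vapply(out$term_id, function(t)
      annotation_size(annset, t), integer(1))
  out
}

#' Write the term summary table as TSV
#'
#' @inheritParams term_table
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_table <- function(graph, path, annset = NULL) {
  write_tsv_plain(term_table(graph, annset), path)
}

# deterministic TSV writer shared by all output surfaces
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
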