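# Fixture graphs and generators shared across test files. All built in code.

BP <- "biological_process"

make_terms <- function(ids, namespace = BP, obsolete = FALSE) {
  data.frame(term_id = ids, name = paste("term", ids), namespace = namespace,
             is_obsolete = obsolete, stringsAsFactors = FALSE)
}

make_edges <- function(...) {
  triples <- list(...)
  if (!length(triples))
    return(data.frame(child = character(), parent = character(),
                      relation = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(triples, function(x)
    data.frame(child = x[[1]], parent = x[[2]],
               relation = if (length(x) > 2) x[[3]] else "is_a",
               stringsAsFactors = FALSE)))
}

# root <- A <- B, all is_a: the worked Wang chain
chain_graph <- function() {
  ontology_graph(make_terms(c("R", "A", "B")),
                 make_edges(c("A", "R"), c("B", "A")))
}

# B -> {A1, A2} -> root
diamond_graph <- function() {
  ontology_graph(make_terms(c("R", "A1", "A2", "B")),
                 make_edges(c("A1", "R"), c("A2", "R"),
                            c("B", "A1"), c("B", "A2")))
}

# two siblings under the root
sibling_graph <- function() {
  ontology_graph(make_terms(c("R", "B1", "B2")),
                 make_edges(c("B1", "R"), c("B2", "R")))
}

# two deep chains A1..A4 and B1..B4 under one root: SS to A4 spans the
# high / mid / low similarity bands
two_chain_graph <- function() {
  ontology_graph(
    make_terms(c("R", paste0("A", 1:4), paste0("B", 1:4))),
    make_edges(c("A1", "R"), c("A2", "A1"), c("A3", "A2"), c("A4", "A3"),
               c("B1", "R"), c("B2", "B1"), c("B3", "B2"), c("B4", "B3")))
}

# random DAG with mixed edge relations; <= 30 terms, guaranteed acyclic by
# construction (parents always have smaller index)
random_dag <- function(n_terms = 12L, p_extra = 0.3, part_of_prob = 0.3) {
  ids <- sprintf("N%02d", seq_len(n_terms))
  rows <- list()
  for (i in 2:n_terms) {
    np <- 1L + stats::rbinom(1, 1, p_extra)
    parents <- sample(seq_len(i - 1L), min(np, i - 1L))
    for (p in parents)
      rows[[length(rows) + 1L]] <- data.frame(
        child = ids[i], parent = ids[p],
        relation = if (stats::runif(1) < part_of_prob) "part_of" else "is_a",
        stringsAsFactors = FALSE)
  }
  ontology_graph(make_terms(ids), do.call(rbind, rows))
}

# default synthetic ontology used by several suites (cached per session)
synth_fixture <- local({
  cache <- NULL
  function(seed = 7L) {
    if (is.null(cache) || cache$seed != seed)
      cache <<- c(synthesize_ontology(synthetic_ontology_spec(seed = seed)),
                  list(seed = seed))
    cache
  }
})

# thin wrappers over the package's branch utilities, kept for test brevity
exclusive_branch <- function(graph, head) {
  setdiff(exclusive_branches(graph)[[head]], head)
}

pick_branch_targets <- function(graph, annset, n_targets = 3L,
                                depth_min = 3L, size_range = c(15L, 120L)) {
  select_branch_targets(graph, annset, n_targets, depth_min, size_range)
}

# a term_network built directly from an explicit edge table
direct_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}

# planted two-block network: 6 + 6 nodes, intra-weight 0.9, one 0.55 bridge
two_block_network <- function(intra = 0.9, bridge = 0.55) {
  a <- sprintf("a%d", 1:6); b <- sprintf("b%d", 1:6)
  block_edges <- function(nodes, w) {
    idx <- utils::combn(length(nodes), 2)
    data.frame(a = nodes[idx[1, ]], b = nodes[idx[2, ]], weight = w,
               stringsAsFactors = FALSE)
  }
  ed <- rbind(block_edges(a, intra), block_edges(b, intra),
              data.frame(a = "a1", b = "b1", weight = bridge))
  direct_network(c(a, b), ed)
}
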