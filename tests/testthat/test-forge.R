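# Synthetic ontology generation and benchmark-list construction.

test_that("random lists honor sizes, dedup, and seeded reproducibility", {
  bg <- sprintf("g%04d", 1:800)
  b <- make_random_lists(bg, sizes = c(100, 50), replicates = 3, seed = 9)
  expect_length(b$gene_lists, 6L)
  for (gl in b$gene_lists) {
    expect_true(length(gl$genes) %in% c(100L, 50L))
    expect_false(anyDuplicated(gl$genes) > 0)
  }
  b2 <- make_random_lists(bg, sizes = c(100, 50), replicates = 3, seed = 9)
  expect_identical(b, b2)
  # replicates under one seed differ from each other
  expect_false(identical(b$gene_lists$random100_r1$genes,
                         b$gene_lists$random100_r2$genes))
  expect_error(make_random_lists(bg[1:40], sizes = 50), "smaller than")
})

test_that("target lists are exact unions when sizes allow", {
  g <- ontology_graph(make_terms(c("R", "T1", "T2")),
                      make_edges(c("T1", "R"), c("T2", "R")))
  a <- annotation_set(
    data.frame(gene_id = c(sprintf("p%02d", 1:30), sprintf("q%02d", 1:30)),
               term_id = rep(c("T1", "T2"), each = 30)), g)
  b <- make_target_lists(a, g, c("T1", "T2"), sizes = 60, seed = 1)
  expect_equal(length(b$gene_lists$target60$genes), 60L)
  expect_setequal(b$gene_lists$target60$genes,
                  union(a$genes_by_term$T1, a$genes_by_term$T2))
  expect_equal(b$targets$target60, c("T1", "T2"))
})

test_that("overlapping target sets deduplicate and report Jaccard overlap", {
  g <- ontology_graph(make_terms(c("R", "T1", "T2")),
                      make_edges(c("T1", "R"), c("T2", "R")))
  a <- annotation_set(
    data.frame(gene_id = c(sprintf("g%02d", 1:10), sprintf("g%02d", 6:15)),
               term_id = rep(c("T1", "T2"), each = 10)), g)
  b <- make_target_lists(a, g, c("T1", "T2"), sizes = 15, seed = 1)
  expect_equal(length(unique(b$gene_lists$target15$genes)), 15L)
  jm <- b$provenance$target_jaccard$target15
  expect_equal(unname(jm["T1", "T2"]), 5 / 15, tolerance = 1e-12)
  expect_error(make_target_lists(a, g, c("T1", "T2"), sizes = 40, seed = 1),
               "smaller than requested")
})

test_that("planted targets are all recovered by the reference ORA", {
  s <- synth_fixture()
  tg <- pick_branch_targets(s$graph, s$annset)
  expect_length(tg, 3L)
  b <- make_target_lists(s$annset, s$graph, tg, sizes = 50, seed = 13)
  r <- run_ora(b$gene_lists$target50, s$annset, s$graph)
  expect_true(all(tg %in% r$term_id))
  expect_true(all(r$p_adj[match(tg, r$term_id)] < 0.05))
})

test_that("downsampling is nested, size-checked, and reproducible", {
  gl <- gene_list(sprintf("g%03d", 1:200), label = "hypoxia")
  series <- downsample_series(gl, c(100, 50), seed = 4)
  expect_equal(lengths(lapply(series, `[[`, "genes")),
               c(hypoxia_100 = 100L, hypoxia_50 = 50L))
  expect_true(all(series$hypoxia_50$genes %in% series$hypoxia_100$genes))
  expect_identical(downsample_series(gl, c(100, 50), seed = 4), series)
  same <- downsample_series(gl, 200, seed = 4)
  expect_setequal(same[[1]]$genes, gl$genes)   # size = |list| is identity
  expect_error(downsample_series(gl, 300), "exceeds")
  loose <- downsample_series(gl, c(100, 50), seed = 4, nested = FALSE)
  expect_length(loose$hypoxia_50$genes, 50L)
})

test_that("synthesized ontologies respect the structural contract", {
  spec <- synthetic_ontology_spec(n_terms = 40, max_depth = 4,
                                  part_of_fraction = 0, seed = 3)
  s <- synthesize_ontology(spec)
  g <- s$graph
  expect_length(g$roots, 1L)
  expect_true(all(term_depth(g, g$terms$term_id) <= 4))
  expect_equal(max(term_depth(g, g$terms$term_id)), 4L)
  rels <- unlist(g$relations)
  expect_true(all(rels == "is_a"))   # part_of_fraction 0
  expect_true(all(g$terms$namespace == "biological_process"))
  # acyclic by construction: topological order exists (constructor enforces)
  expect_s3_class(g, "ontology_graph")
  expect_error(
    synthesize_ontology(synthetic_ontology_spec(n_terms = 4, max_depth = 8)),
    "infeasible")
})

test_that("generation is a pure function of (spec, seed)", {
  s1 <- synthesize_ontology(synthetic_ontology_spec(seed = 21))
  s2 <- synthesize_ontology(synthetic_ontology_spec(seed = 21))
  expect_identical(s1$graph$terms, s2$graph$terms)
  expect_identical(s1$annset$genes_by_term, s2$annset$genes_by_term)
  s3 <- synthesize_ontology(synthetic_ontology_spec(seed = 22))
  expect_false(identical(s1$annset$genes_by_term, s3$annset$genes_by_term))
  # the global RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(synthesize_ontology(synthetic_ontology_spec(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("emitted OBO and GAF round-trip through the parsers losslessly", {
  s <- synth_fixture()
  obo <- withr::local_tempfile(fileext = ".obo")
  gaf <- withr::local_tempfile(fileext = ".gaf")
  write_obo(s$graph, obo)
  write_gaf(s$annset, gaf)
  g2 <- parse_obo(obo)
  expect_setequal(g2$terms$term_id, s$graph$terms$term_id)
  expect_identical(g2$depth[s$graph$terms$term_id],
                   s$graph$depth[s$graph$terms$term_id])
  a2 <- load_annotations(gaf, "gaf", g2, background = s$annset$background)
  expect_equal(a2$n_dropped, 0L)   # zero skipped lines
  for (t in names(s$annset$genes_by_term))
    expect_equal(annotation_size(a2, t), annotation_size(s$annset, t))
})

test_that("planted branches are separated across the similarity thresholds", {
  s <- synth_fixture()
  g <- s$graph; a <- s$annset
  # two targets so at least one sizeable branch stays target-free
  tg <- pick_branch_targets(g, a, n_targets = 2L)
  # target-branch terms: the targets and everything below them
  below <- names(Filter(function(anc) any(tg %in% anc), g$ancestors))
  branch_terms <- unique(c(tg, below))
  mx <- vapply(branch_terms, function(t)
    max_similarity_to_targets(g, t, tg), numeric(1))
  expect_gte(mean(mx), 0.7)
  # a disjoint exclusive branch sits below the low threshold
  heads <- g$children[[g$roots]]
  branches <- lapply(heads, exclusive_branch, graph = g)
  free <- branches[vapply(branches, function(b)
    length(b) > 3 && !any(b %in% branch_terms), logical(1))]
  expect_gt(length(free), 0L)
  other <- setdiff(free[[1]][term_depth(g, free[[1]]) >= 2], branch_terms)
  mx2 <- vapply(other, function(t)
    max_similarity_to_targets(g, t, tg), numeric(1))
  expect_lte(mean(mx2), 0.3)
})

test_that("bundle writing produces loadable lists and a manifest", {
  s <- synth_fixture()
  tg <- pick_branch_targets(s$graph, s$annset)
  b <- make_target_lists(s$annset, s$graph, tg, sizes = c(50, 30), seed = 2)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "target50.txt")))
  gl <- read_gene_list(file.path(dir, "target50.txt"))
  expect_identical(gl$genes, b$gene_lists$target50$genes)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$lists$target50$size, 50L)
  expect_setequal(manifest$targets$target50, tg)
})
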